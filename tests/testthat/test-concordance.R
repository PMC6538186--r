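test_that("standardize: examples and the degenerate condition", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(17)
  v <- rnorm(50, 10, 3)
  expect_equal(mean(standardize(v)), 0, tolerance = 1e-12)
  expect_equal(sd(standardize(v)), 1, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), class = "ivive_degenerate_comparison")
  expect_error(standardize(3), "n >= 2")
})

test_that("ormse: identity, symmetry and the closed-form oracle", {
  set.seed(19)
  v <- standardize(rnorm(10))
  expect_equal(ormse(v, v), 0)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    x <- rnorm(n)
    y <- 2 * x + rnorm(n)
    o_xy <- ormse(standardize(x), standardize(y))
    o_yx <- ormse(standardize(y), standardize(x))
    expect_equal(o_xy, o_yx, tolerance = 1e-12)
    expect_equal(o_xy^2, (n - 1) / n * (1 - cor(x, y)), tolerance = 1e-10)
  }
  expect_error(ormse(1:3, 1:4), "length")
})

test_that("build_comparisons enforces min_n and deduplicates", {
  ac50 <- data.frame(
    chemical_id = c("A", "B", "C", "D", "E", "A"),
    assay_endpoint = "ASSAY_1",
    ac50 = c(5, 2, 3, 4, 1, 2), stringsAsFactors = FALSE)
  invivo <- data.frame(
    chemical_id = c("A", "B", "C", "D", "E"),
    endpoint_id = "EP", dose = 1:5, study_length = 90,
    stringsAsFactors = FALSE)
  cs <- build_comparisons(ac50, invivo, min_n = 5)
  expect_length(cs, 1)
  expect_equal(cs[[1]]$n, 5)
  # duplicate (A, ASSAY_1) collapses to the minimum AC50
  expect_equal(cs[[1]]$ac50s[cs[[1]]$chemical_ids == "A"], 2)
  # below the threshold: excluded
  expect_length(build_comparisons(ac50[1:4, ], invivo, min_n = 5), 0)
})

test_that("randomization plans are reproducible and uniform", {
  cmp <- structure(list(assay_endpoint = "A1", in_vivo_endpoint = "E1",
                        chemical_ids = paste0("C", 1:8), n = 8L),
                   class = "comparison_set")
  p1 <- make_randomization_plan(cmp, 42L)
  p2 <- make_randomization_plan(cmp, 42L)
  expect_identical(p1$index, p2$index)
  expect_equal(dim(p1$index), c(8L, 10L))
  expect_true(all(p1$index >= 1 & p1$index <= 8))
  # uniformity: chi-square over many draws
  big <- make_randomization_plan(cmp, 7L, n_sets = 1250L)
  counts <- tabulate(big$index, nbins = 8)
  expect_gt(chisq.test(counts)$p.value, 1e-4)
})

test_that("allocate_wins uses strict minima with conservative ties", {
  expect_equal(allocate_wins(0.5, 0.9, 0.8), "pbtk")
  expect_equal(allocate_wins(0.8, 0.8, 0.9), "random")
  expect_equal(allocate_wins(0.8, 0.8, 0.8), "untransformed")
  expect_equal(allocate_wins(0.9, 0.8, 0.8), "untransformed")
})

test_that("count_wins matches per-contest allocate_wins and conserves totals", {
  set.seed(23)
  recs <- list()
  for (cmp in c("X::1", "Y::2", "Z::3")) {
    parts <- strsplit(cmp, "::", fixed = TRUE)[[1]]
    for (dir in c("forward", "reverse")) {
      o <- runif(12, 0.2, 1.2)
      recs[[length(recs) + 1L]] <- data.frame(
        assay_endpoint = parts[1], in_vivo_endpoint = parts[2],
        assumption_label = "lab", direction = dir,
        predictor = c("pbtk", "untransformed", rep("random", 10)),
        set = c(NA, NA, 1:10), ormse = o, n = 6, stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, recs)
  wt <- count_wins(rec)
  # conservation: per (direction, set) the wins sum to the contest count
  for (s in 1:10) {
    for (dir in c("forward", "reverse")) {
      g <- wt[wt$set == s & wt$direction == dir, ]
      expect_equal(sum(g$wins), 3)
    }
  }
  # spot-check against the scalar allocator
  for (dir in c("forward", "reverse")) {
    sub <- rec[rec$direction == dir & rec$assay_endpoint == "X", ]
    w <- allocate_wins(sub$ormse[sub$predictor == "pbtk"],
                       sub$ormse[sub$predictor == "random" & sub$set == 4],
                       sub$ormse[sub$predictor == "untransformed"])
    g <- wt[wt$set == 4 & wt$direction == dir & wt$predictor == w, ]
    expect_gte(g$wins, 1)
  }
})

test_that("aggregate_counts medians, sds and fractions", {
  wt <- expand.grid(set = 1:10, predictor = c("pbtk", "random",
                                              "untransformed"),
                    stringsAsFactors = FALSE)
  wt$assumption_label <- "lab"
  wt$direction <- "forward"
  wt$n_comparisons <- 10L
  wt$wins <- ifelse(wt$predictor == "pbtk", wt$set, # counts 1..10
                    ifelse(wt$predictor == "random", 10L - wt$set, 0L))
  ag <- aggregate_counts(wt)
  expect_equal(ag$median_wins[ag$predictor == "pbtk"], 5.5)
  expect_equal(ag$sd_wins[ag$predictor == "untransformed"], 0)
  # fractions of the three predictors sum to 1 per set, hence medians of
  # per-set fractions sum to 1 here (complementary counts)
  expect_equal(sum(ag$fraction), 1)
})

test_that("pod10_aed10 quantiles, identities and conservatism", {
  # single POD value: the quantile is that value
  res <- pod10_aed10(data.frame(chemical_id = "A", dose = 7),
                     data.frame(chemical_id = "A", aed = 7))
  expect_equal(res$records$pod10, 7)
  expect_equal(res$rmse, 0)
  expect_equal(res$conservatism, 1)
  # interpolated quantile: {1, 10, 100} at q = 0.1 -> 2.8
  res2 <- pod10_aed10(data.frame(chemical_id = "B", dose = c(100, 1, 10)),
                      data.frame(chemical_id = "B", aed = 1))
  expect_equal(res2$records$pod10, 2.8)
  # exact agreement over several chemicals: RMSE = ORMSE = 0
  pods <- data.frame(chemical_id = rep(c("A", "B", "C"), each = 2),
                     dose = c(1, 2, 5, 10, 20, 40))
  aeds <- data.frame(chemical_id = c("A", "B", "C"),
                     aed = sapply(split(pods$dose, pods$chemical_id),
                                  quantile, 0.1, type = 7))
  res3 <- pod10_aed10(pods, aeds)
  expect_equal(res3$rmse, 0)
  expect_equal(res3$ormse, 0)
  expect_equal(res3$conservatism, 1)
})

test_that("residual correlations recover a planted dependence", {
  set.seed(29)
  n <- 200
  chems <- data.frame(id = paste0("C", 1:n), name = "x", mw = runif(n, 100, 500),
                      logp = rnorm(n, 2, 1.5), logd = rnorm(n, 1, 1.5),
                      fup = runif(n), clint = rlnorm(n, 2, 1))
  records <- data.frame(chemical_id = chems$id,
                        residual = 2 * chems$logp + rnorm(n, 0, 1e-6))
  cors <- residual_param_correlations(records, chems)
  expect_equal(cors$abs_cor[cors$parameter == "logP"], 1, tolerance = 1e-6)
  expect_lt(cors$abs_cor[cors$parameter == "MW"], 0.2) # independent
  expect_true(all(cors$abs_cor >= 0 & cors$abs_cor <= 1, na.rm = TRUE))
  expect_equal(nrow(cors), 5)
})
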