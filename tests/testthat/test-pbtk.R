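phys <- rat_physiology()

test_that("physiology validation enforces positivity and flow balance", {
  expect_s3_class(phys, "rat_physiology")
  expect_error(rat_physiology(gfr = -1), "positive")
  expect_error(rat_physiology(plasma_flows = list(gut = 99)), "cardiac")
  expect_error(rat_physiology(nonsense = 1), "unknown")
})

test_that("default partition scheme closed forms", {
  # fully aqueous hypothetical tissue, neutral chemical, fup = 1
  ch <- fix_chem(fup = 1, logp = 2)
  comp <- list(water = 1, neutral_lipid = 0, phospholipid = 0, protein = 0)
  expect_equal(kp_schmitt(ch, comp), 1)
  # two-phase tissue: Kp = w + l * 10^logP
  comp2 <- list(water = 0.7, neutral_lipid = 0.1, phospholipid = 0,
                protein = 0)
  expect_equal(kp_schmitt(ch, comp2), 0.7 + 0.1 * 10^2)
  # monotone in logP for neutral chemicals
  kp_a <- kp_schmitt(fix_chem(logp = 1, fup = 1), comp2)
  kp_b <- kp_schmitt(fix_chem(logp = 4, fup = 1), comp2)
  expect_gt(kp_b, kp_a)
})

test_that("tissue partition coefficients are positive and logP-monotone", {
  kps <- lapply(c(0, 2, 4), function(lp) {
    tissue_partition_coefficients(fix_chem(logp = lp, fup = 1), phys)
  })
  for (kp in kps) expect_true(all(kp > 0))
  for (t in names(kps[[1]])) {
    expect_true(kps[[1]][[t]] < kps[[2]][[t]])
    expect_true(kps[[2]][[t]] < kps[[3]][[t]])
  }
})

test_that("hepatic clearance limits and the well-stirred bound", {
  q_liver <- phys$plasma_flows$liver + phys$plasma_flows$gut
  # zero intrinsic clearance -> zero for both modes
  ch0 <- fix_chem(clint_1 = 0)
  expect_equal(hepatic_clearance(ch0, phys, restrictive = TRUE), 0)
  expect_equal(hepatic_clearance(ch0, phys, restrictive = FALSE), 0)
  # fup = 1: restrictive and nonrestrictive coincide
  ch1 <- fix_chem(fup = 1)
  expect_equal(hepatic_clearance(ch1, phys, TRUE),
               hepatic_clearance(ch1, phys, FALSE))
  # flow-limited asymptote: Clint_u -> Inf gives CLh -> Q_liver
  chbig <- fix_chem(fup = 1, clint_1 = 1e6 * q_liver / 0.2244)
  expect_equal(hepatic_clearance(chbig, phys, FALSE, fu_hep = NULL),
               q_liver, tolerance = 1e-4)
  # bound holds for random chemicals
  set.seed(5)
  for (i in 1:20) {
    ch <- rand_chem(paste0("R", i))
    expect_lt(hepatic_clearance(ch, phys, runif(1) < 0.5), q_liver)
  }
})

test_that("renal clearance is GFR times fup", {
  expect_equal(renal_clearance(fix_chem(fup = 0.005),
                               rat_physiology(gfr = 0.312)), 0.00156)
  expect_equal(renal_clearance(fix_chem(fup = 1), phys), phys$gfr)
  expect_equal(renal_clearance(fix_chem(fup = 0.005), phys), 0.005 * phys$gfr)
})

test_that("zero dose yields the zero solution", {
  p <- pbtk_parameters(fix_chem(), phys)
  tc <- simulate_pbtk(p, dose_regimen(0, 1, 5))
  expect_true(all(tc$conc == 0))
  expect_true(all(tc$auc == 0))
  expect_true(all(tc$cmax == 0))
})

test_that("the model is linear in dose", {
  p <- pbtk_parameters(fix_chem(), phys)
  tc1 <- simulate_pbtk(p, dose_regimen(1, 1, 30))
  tc2 <- simulate_pbtk(p, dose_regimen(2, 1, 30))
  expect_equal(tc2$conc, 2 * tc1$conc, tolerance = 1e-10)
  expect_equal(tc2$auc, 2 * tc1$auc, tolerance = 1e-10)
  expect_equal(tc2$cmax, 2 * tc1$cmax, tolerance = 1e-10)
})

test_that("no-clearance chemical conserves the administered amount", {
  # hepatic and renal clearance both (effectively) zero: everything
  # administered stays in the compartments once absorption completes
  ch <- fix_chem(clint_1 = 0, fup = 0.5)
  p <- pbtk_parameters(ch, rat_physiology(gfr = 1e-12))
  tc <- simulate_pbtk(p, dose_regimen(1, 1, 10))
  n <- length(tc$times)
  retained <- rowSums(tc$amounts)
  expect_equal(retained + tc$cleared, tc$administered, tolerance = 1e-9)
  expect_lt(tc$cleared[n] / tc$administered[n], 1e-9)
})

test_that("mass balance holds at every output time with clearance", {
  set.seed(7)
  for (i in 1:5) {
    p <- pbtk_parameters(rand_chem(paste0("M", i)), phys)
    tc <- simulate_pbtk(p, dose_regimen(1, 2, 14))
    expect_equal(rowSums(tc$amounts) + tc$cleared, tc$administered,
                 tolerance = 1e-9)
  }
})

test_that("restrictive equals nonrestrictive when fup = 1", {
  ch <- fix_chem(fup = 1)
  tc_r <- simulate_pbtk(pbtk_parameters(ch, phys, restrictive = TRUE),
                        dose_regimen(1, 1, 28))
  tc_n <- simulate_pbtk(pbtk_parameters(ch, phys, restrictive = FALSE),
                        dose_regimen(1, 1, 28))
  expect_equal(tc_r$conc, tc_n$conc, tolerance = 1e-12)
})

test_that("extract_concentration: mean, max, free scaling, errors", {
  # constant series at 2 uM
  tc_const <- time_course(0:10, rep(2, 11))
  m_mean <- concentration_metric("mean", "venous_plasma", "total")
  expect_equal(extract_concentration(tc_const, m_mean), 2)
  # triangular series rising 0 -> 4 linearly: mean 2, max 4
  tc_tri <- time_course(seq(0, 10, length.out = 101),
                        seq(0, 4, length.out = 101))
  expect_equal(extract_concentration(tc_tri, m_mean), 2)
  m_max <- concentration_metric("max", "venous_plasma", "total")
  expect_equal(extract_concentration(tc_tri, m_max), 4)
  # free scaling
  m_free <- concentration_metric("mean", "venous_plasma", "free")
  expect_equal(extract_concentration(tc_const, m_free, fup = 0.25), 0.5)
  expect_error(extract_concentration(tc_const, m_free), "fup")
  expect_error(extract_concentration(
    tc_const, concentration_metric("mean", "liver", "total")), "compartment")
  expect_error(concentration_metric("mean", "liver", "free"), "plasma")
})

test_that("steady-state oracle identities", {
  p <- pbtk_parameters(fix_chem(), phys)
  css <- steady_state_mean_oracle(p, 1)
  # linear in dose, inverse in clearance
  expect_equal(steady_state_mean_oracle(p, 2), 2 * css)
  p_half <- p
  p_half$cl_hepatic <- p$cl_hepatic / 2
  p_half$cl_renal <- p$cl_renal / 2
  expect_equal(steady_state_mean_oracle(p_half, 1), 2 * css)
  p0 <- p
  p0$cl_hepatic <- 0
  p0$cl_renal <- 0
  expect_error(steady_state_mean_oracle(p0, 1), "undefined")
})

test_that("long-horizon mean approaches the analytic steady state", {
  # low-extraction, fast-equilibrating chemical (oracle validity domain)
  ch <- fix_chem(fup = 0.05, clint_1 = 5, logp = 1)
  p <- pbtk_parameters(ch, phys)
  tc <- simulate_pbtk(p, dose_regimen(1, 1, 90))
  n <- length(tc$times)
  final_day_mean <- unname(tc$cum_auc[n, "venous_plasma"] -
                             tc$cum_auc[n - 1, "venous_plasma"]) / 24
  expect_equal(final_day_mean, steady_state_mean_oracle(p, 1),
               tolerance = 0.05)
})
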