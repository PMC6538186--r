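test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(n_chemicals = 10, n_assays = 3, seed = 5)
  c1 <- gen_chemicals(cfg)
  c2 <- gen_chemicals(cfg)
  expect_identical(c1, c2)
  a1 <- gen_ac50(c1, cfg)
  a2 <- gen_ac50(c2, cfg)
  expect_identical(a1, a2)
})

test_that("chemical marginals respect the configured shapes", {
  cfg <- synthetic_config(n_chemicals = 1000, seed = 31)
  chems <- gen_chemicals(cfg)
  fups <- vapply(chems, `[[`, numeric(1), "fup")
  expect_true(all(fups >= 0.005 & fups <= 1))
  clints <- vapply(chems, `[[`, numeric(1), "clint")
  expect_true(all(clints >= 0))
  # point mass at zero clearance within binomial error of the target
  p0 <- mean(clints == 0)
  expect_lt(abs(p0 - cfg$clint_zero_frac),
            3 * sqrt(0.2 * 0.8 / 1000) + 0.01)
  mws <- vapply(chems, `[[`, numeric(1), "mw")
  expect_true(all(mws >= 100 & mws <= 500))
})

test_that("gen_ac50 respects hit and flag rates", {
  chems <- gen_chemicals(synthetic_config(n_chemicals = 50, seed = 37))
  cfg0 <- synthetic_config(n_chemicals = 50, n_assays = 4, hit_rate = 0,
                           seed = 37)
  expect_equal(nrow(filter_ac50(gen_ac50(chems, cfg0))), 0)
  cfg1 <- synthetic_config(n_chemicals = 50, n_assays = 4, hit_rate = 1,
                           flag_rate = 0, seed = 37)
  expect_equal(nrow(filter_ac50(gen_ac50(chems, cfg1))), 50 * 4)
  cfg3 <- synthetic_config(n_chemicals = 50, n_assays = 20, hit_rate = 1,
                           flag_rate = 0.3, seed = 37)
  tab <- gen_ac50(chems, cfg3)
  frac_removed <- 1 - nrow(filter_ac50(tab)) / sum(tab$hit_call)
  expect_lt(abs(frac_removed - 0.3), 0.05)
})

test_that("generated tables pass the io validation round trip", {
  cfg <- synthetic_config(n_chemicals = 15, n_assays = 4, seed = 41,
                          noise_sd = 0.3)
  chems <- gen_chemicals(cfg)
  ac50 <- gen_ac50(chems, cfg)
  invivo <- gen_invivo(chems, ac50, cfg)
  d <- tempfile()
  write_results(list(ac50 = ac50, endpoint = invivo$endpoint,
                     pod = invivo$pod), d)
  ac50_back <- read_ac50(file.path(d, "ac50.csv"))
  expect_equal(nrow(filter_ac50(ac50_back)), nrow(filter_ac50(ac50)))
  expect_equal(filter_ac50(ac50_back)$ac50, filter_ac50(ac50)$ac50,
               tolerance = 1e-14)
  ep_back <- utils::read.csv(file.path(d, "endpoint.csv"))
  expect_equal(derive_endpoint_doses(ep_back)$dose,
               derive_endpoint_doses(invivo$endpoint)$dose,
               tolerance = 1e-14)
  pod_back <- utils::read.csv(file.path(d, "pod.csv"))
  expect_equal(derive_pod(pod_back)$pod, derive_pod(invivo$pod)$pod,
               tolerance = 1e-14)
})

test_that("noiseless generation is an exact fixed point of reverse dosimetry", {
  cfg <- synthetic_config(n_chemicals = 25, n_assays = 4, n_endpoints = 4,
                          noise_sd = 0, hit_rate = 0.6,
                          endpoint_active_rate = 0.8, seed = 43)
  chems <- gen_chemicals(cfg)
  ac50 <- gen_ac50(chems, cfg)
  invivo <- gen_invivo(chems, ac50, cfg)
  rc <- run_config(chems, ac50, endpoint = invivo$endpoint, seed = 43,
                   assumption_sets = list(cfg$true_assumptions))
  res <- run_endpoint_analysis(rc)
  pbtk <- res$ormse[res$ormse$predictor == "pbtk", ]
  # the correlation-based ORMSE evaluation amplifies machine epsilon by a
  # square root near r = 1, so "zero" means below ~1e-6 here
  expect_true(all(pbtk$ormse < 1e-6))
  # and the PBTK predictor wins every contest in both directions
  expect_equal(pbtk_win_fraction(res, cfg$true_assumptions$label), 1)
})
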