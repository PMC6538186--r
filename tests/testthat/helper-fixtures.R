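# Shared fixtures and a memoized full-scale calibration run (used by the
# acceptance suite and the calibration property tests; computed once per
# test session).

.test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# a plain, well-behaved neutral chemical
fix_chem <- function(id = "FIX-1", mw = 300, logp = 2, fup = 0.2,
                     clint_1 = 10, ...) {
  chemical_record(id, id, mw = mw, logp = logp, fup = fup,
                  clint_1 = clint_1, ...)
}

rand_chem <- function(id) {
  chemical_record(
    id, id, mw = runif(1, 100, 500), logp = runif(1, -1, 5),
    pka_donor = if (runif(1) < 0.25) runif(1, 3, 10) else numeric(),
    pka_acceptor = if (runif(1) < 0.25) runif(1, 3, 10) else numeric(),
    fup = runif(1, 0.005, 1), clint_1 = runif(1, 0, 50),
    loghenry = rnorm(1, -9, 1.5))
}

# Calibration world: the stated synthetic scale (200 chemicals, 20
# assays, log10-dose noise sd 0.3, fixed seed).
calibration_cfg <- function(seed = 101L, ...) {
  synthetic_config(n_chemicals = 200L, n_assays = 20L, noise_sd = 0.3,
                   seed = seed, ...)
}

calibration_world <- function(key = "cal", ...) {
  memo(key, {
    cfg <- calibration_cfg(...)
    chems <- gen_chemicals(cfg)
    ac50 <- gen_ac50(chems, cfg)
    invivo <- gen_invivo(chems, ac50, cfg)
    list(cfg = cfg, chems = chems, ac50 = ac50, invivo = invivo)
  })
}

calibration_endpoint_run <- function() {
  memo("cal_run", {
    w <- calibration_world()
    rc <- run_config(w$chems, w$ac50, endpoint = w$invivo$endpoint,
                     seed = w$cfg$seed)
    run_endpoint_analysis(rc)
  })
}

shuffled_endpoint_run <- function() {
  memo("cal_run_shuffled", {
    w <- calibration_world("cal_shuffled", shuffle_labels = TRUE)
    rc <- run_config(w$chems, w$ac50, endpoint = w$invivo$endpoint,
                     seed = w$cfg$seed)
    run_endpoint_analysis(rc, kappas = calibration_endpoint_run()$kappas)
  })
}

pbtk_win_fraction <- function(run, label, direction = NULL) {
  w <- run$wins[run$wins$assumption_label == label, , drop = FALSE]
  if (!is.null(direction)) w <- w[w$direction == direction, , drop = FALSE]
  sum(w$wins[w$predictor == "pbtk"]) / sum(w$wins)
}
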