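phys <- rat_physiology()

test_that("assumption labels encode the triple and round-trip", {
  a <- assumption_set("restrictive", "mean", "venous_plasma", "free",
                      armitage = TRUE)
  expect_equal(a$label, "res.-free-vein-mean-Armitage")
  b <- assumption_set("nonrestrictive", "max", "liver", "total")
  expect_equal(b$label, "nres.-tot.-tis.-max")
  for (lab in names(default_assumption_sets())) {
    expect_equal(parse_assumption_label(lab)$label, lab)
  }
  grid <- default_assumption_sets()
  expect_equal(length(grid), 16L)
  expect_equal(anyDuplicated(names(grid)), 0L)
})

test_that("kappa is definitional: forward at 1 mg/kg/day returns the metric", {
  ch <- fix_chem()
  a <- assumption_set("restrictive", "mean", "venous_plasma", "total")
  ke <- compute_kappa(ch, 28, a, phys)
  p <- pbtk_parameters(ch, phys, restrictive = TRUE)
  tc <- simulate_pbtk(p, dose_regimen(1, 1, 28))
  expect_equal(forward_concentration(1, ke),
               extract_concentration(tc, a$metric))
})

test_that("free venous kappa is fup times total venous kappa", {
  ch <- fix_chem(fup = 0.31, loghenry = -9)
  kt <- kappa_table(list(ch), 90, default_assumption_sets(), phys)
  k_tot <- kt$kappa[kt$assumption_label == "res.-tot.-vein-mean"]
  k_free <- kt$kappa[kt$assumption_label == "res.-free-vein-mean"]
  expect_equal(k_free, 0.31 * k_tot)
})

test_that("kappa accumulates with study length for a no-clearance chemical", {
  ch <- fix_chem(clint_1 = 0)
  ph0 <- rat_physiology(gfr = 1e-12)
  a <- assumption_set("restrictive", "mean", "venous_plasma", "total")
  k1 <- compute_kappa(ch, 1, a, ph0)$kappa
  k2 <- compute_kappa(ch, 2, a, ph0)$kappa
  expect_gt(k2, k1)
})

test_that("forward and reverse transforms are exact inverses", {
  k <- 0.8
  expect_equal(forward_concentration(1, k), 0.8)
  expect_equal(forward_concentration(10, k), 8.0)
  expect_equal(reverse_aed(0.8, k), 1.0)
  expect_equal(reverse_aed(8.0, k), 10.0)
  for (d in 10^runif(20, -3, 3)) {
    expect_equal(reverse_aed(forward_concentration(d, k), k), d)
  }
})

test_that("forward and reverse residuals are equal and opposite", {
  set.seed(13)
  for (i in 1:20) {
    r <- dosimetry_result(dose = 10^runif(1, -2, 3), ac50 = 10^runif(1, -2, 2),
                          kappa = 10^runif(1, -3, 1))
    expect_equal(log10(r$ac50) - log10(r$c_pbtk),
                 -(log10(r$dose) - log10(r$aed_pbtk)), tolerance = 1e-12)
    expect_equal(r$residual, log10(r$ac50) - log10(r$c_pbtk))
  }
})

test_that("kappa_table agrees with compute_kappa and covers the grid", {
  ch <- fix_chem(loghenry = -9)
  sets <- default_assumption_sets()
  kt <- kappa_table(list(ch), c(28, 90), sets, phys)
  expect_equal(nrow(kt), 2 * length(sets))
  for (lab in c("res.-tot.-vein-mean", "nres.-tot.-tis.-max",
                "res.-free-vein-mean-Armitage")) {
    expect_equal(
      kt$kappa[kt$assumption_label == lab & kt$study_length == 90],
      compute_kappa(ch, 90, sets[[lab]], phys)$kappa,
      tolerance = 1e-12)
  }
})

test_that("kappa lookup joins exactly and falls back to nearest length", {
  ch <- fix_chem()
  kt <- kappa_table(list(ch), c(28, 730),
                    list(assumption_set("restrictive", "mean")), phys)
  lab <- "res.-tot.-vein-mean"
  k28 <- kt$kappa[kt$study_length == 28]
  expect_equal(kappa_lookup(kt, "FIX-1", 28, lab), k28)
  expect_equal(kappa_lookup(kt, "FIX-1", 21, lab), k28) # nearest
  expect_error(kappa_lookup(kt, "UNKNOWN", 28, lab), "UNKNOWN")
  expect_error(kappa_lookup(kt, "FIX-1", 28, "no-such-label"), "assumption")
})
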