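test_that("phase masses are conserved and nonnegative", {
  set.seed(11)
  for (i in 1:20) {
    ch <- rand_chem(paste0("A", i))
    w <- assay_well(sample(c(96, 384, 1536), 1),
                    fbs_fraction = runif(1, 0, 0.2),
                    cell_count = sample(c(0, 1e4, 1e5), 1))
    d <- distribute_in_vitro(ch, w, nominal = 10^runif(1, -2, 2))
    expect_true(all(d$masses >= 0))
    expect_equal(sum(d$masses), d$total, tolerance = 1e-12)
    expect_gt(d$factor, 0)
  }
})

test_that("no-sorption limit recovers the nominal concentration", {
  w0 <- assay_well(384, fbs_fraction = 0, cell_count = 0,
                   headspace_volume = 0, well_area = 1e-9)
  ch <- chemical_record("LOW", mw = 300, logp = -20, fup = 0.5,
                        clint_1 = 1, loghenry = -30)
  d <- distribute_in_vitro(ch, w0, 1)
  expect_equal(d$factor, 1, tolerance = 1e-9)
  expect_equal(sum(d$masses) - d$masses[["aqueous"]], 0, tolerance = 1e-12)
  # and adjust_kappa then leaves kappa unchanged
  expect_equal(adjust_kappa(0.8, d$factor), 0.8, tolerance = 1e-9)
})

test_that("two-phase closed form matches the general solver", {
  # aqueous + one serum lipid phase, negligible plastic, no headspace
  ch <- chemical_record("TP", mw = 300, logp = 2, fup = 0.5, clint_1 = 1,
                        loghenry = -30)
  w <- assay_well(96, fbs_fraction = 0.5, cell_count = 0,
                  headspace_volume = 0, well_area = 1e-9,
                  serum_lipid_frac = 0.1, serum_protein_frac = 0)
  v_l <- 100 * 0.5 * 0.1
  v_aq <- 100 - v_l
  k_l <- 10^2
  d <- distribute_in_vitro(ch, w, 1)
  expect_equal(d$c_aqueous, 100 / (v_aq + v_l * k_l), tolerance = 1e-9)
})

test_that("sorption is monotone in logP and the factor scale-invariant", {
  w <- assay_well(384)
  mk <- function(lp) chemical_record(paste0("L", lp), mw = 300, logp = lp,
                                     fup = 0.5, clint_1 = 1, loghenry = -9)
  f2 <- distribute_in_vitro(mk(2), w, 1)$factor
  f5 <- distribute_in_vitro(mk(5), w, 1)$factor
  expect_lt(f5, f2)
  # linear model: factor independent of the nominal concentration
  expect_equal(distribute_in_vitro(mk(3), w, 0.01)$factor,
               distribute_in_vitro(mk(3), w, 100)$factor, tolerance = 1e-12)
  # adding a sorbing phase (cells) never increases the aqueous conc
  w_cells <- assay_well(384, cell_count = 1e5)
  w_none <- assay_well(384, cell_count = 0)
  expect_lte(distribute_in_vitro(mk(3), w_cells, 1)$c_aqueous,
             distribute_in_vitro(mk(3), w_none, 1)$c_aqueous)
})

test_that("volatile chemical without Henry constant falls back with warning", {
  ch <- chemical_record("NOH", mw = 300, logp = 2, fup = 0.5, clint_1 = 1)
  expect_warning(d <- distribute_in_vitro(ch, assay_well(96), 1),
                 "nonvolatile")
  expect_equal(unname(d$masses[["headspace"]]), 0)
})

test_that("adjust_kappa arithmetic and validation", {
  expect_equal(adjust_kappa(0.8, 1.0), 0.8)
  expect_equal(adjust_kappa(0.8, 0.5), 1.6)
  expect_error(adjust_kappa(0.8, 0), "> 0")
  expect_error(adjust_kappa(0.8, -2), "> 0")
})
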