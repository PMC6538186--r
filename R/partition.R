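#' Default tissue:unbound-plasma partition coefficient scheme
#'
#' A Schmitt-style composition-based calculator. For a tissue with
#' water, neutral-lipid, phospholipid and protein volume fractions
#' (fw, fnl, fpl, fpr), the partition coefficient against the unbound
#' aqueous plasma concentration is
#'
#'   Kp = fw + fn * (fnl * P + fpl * Pmem) + fpr * Ka
#'
#' where P = 10^logP, Pmem = 10^(0.3 + 0.9 * logP) is the
#' membrane-lipid affinity, fn is the neutral fraction at pH 7.4
#' (only neutral species partition into lipid), and Ka is a tissue
#' protein association constant back-calculated from the measured
#' plasma binding: Ka = max(0, 1/fup - 1) / fpr_plasma. Ionized species
#' are assumed to stay in the aqueous phase.
#'
#' @param chemical A `chemical_record`.
#' @param composition One tissue's composition (list with `water`,
#'   `neutral_lipid`, `phospholipid`, `protein`).
#' @param plasma_protein_frac Plasma protein volume fraction used to
#'   scale the protein association constant.
#' @return Unitless Kp > 0.
#' @export
kp_schmitt <- function(chemical, composition, plasma_protein_frac = 0.074) {
  fn <- neutral_fraction(chemical$pka_donor, chemical$pka_acceptor, ph = 7.4)
  p <- 10^chemical$logp
  pmem <- 10^(0.3 + 0.9 * chemical$logp)
  ka <- max(0, 1 / chemical$fup - 1) / plasma_protein_frac
  composition$water +
    fn * (composition$neutral_lipid * p + composition$phospholipid * pmem) +
    composition$protein * ka
}

#' Tissue partition coefficients for all PBTK compartments
#'
#' @param chemical A `chemical_record`.
#' @param physiology A `rat_physiology` (tissue set is taken from its
#'   volume table).
#' @param scheme Function `(chemical, composition, plasma_protein_frac)`
#'   returning one Kp; defaults to [kp_schmitt()].
#' @param composition Tissue composition table, defaults to the shipped
#'   config.
#' @return Named numeric vector of tissue:unbound-plasma partition
#'   coefficients, one per tissue.
#' @export
tissue_partition_coefficients <- function(chemical,
                                          physiology = rat_physiology(),
                                          scheme = kp_schmitt,
                                          composition = tissue_composition()) {
  tissues <- names(physiology$tissue_volumes)
  fpr_plasma <- composition$plasma$protein
  kp <- vapply(tissues, function(t) {
    scheme(chemical, composition[[t]], plasma_protein_frac = fpr_plasma)
  }, numeric(1))
  if (any(!is.finite(kp)) || any(kp <= 0)) {
    stop("non-finite or non-positive partition coefficient for chemical ",
         chemical$id, call. = FALSE)
  }
  kp
}
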