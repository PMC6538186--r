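#' Unbound fraction in the hepatocyte clearance assay
#'
#' logP-dependent correction for non-specific binding of chemical in the
#' in vitro clearance incubation (Kilford-style relation):
#' fu_hep = 1 / (1 + 125 * VR * 10^(0.072 logP^2 + 0.067 logP - 1.126)),
#' with VR the hepatocyte volume ratio of the incubation.
#'
#' @param logp Octanol-water partition coefficient (log10).
#' @param vr Hepatocyte volume ratio of the incubation (default 0.005).
#' @return Fraction unbound in the incubation, in (0, 1].
#' @export
fu_hep_kilford <- function(logp, vr = 0.005) {
  1 / (1 + 125 * vr * 10^(0.072 * logp^2 + 0.067 * logp - 1.126))
}

# uL/min/10^6 cells -> L/h/kg body weight
scale_clint_whole_body <- function(clint, physiology) {
  cells_per_kg <- physiology$hepatocellularity * physiology$liver_mass_frac # 10^6 cells/kg
  clint * cells_per_kg * 60 / 1e6
}

#' Whole-body hepatic clearance via the well-stirred model
#'
#' The measured intrinsic clearance (uL/min/10^6 cells) is divided by
#' the unbound fraction in the incubation (pluggable, Kilford-style by
#' default), scaled by hepatocellularity and liver mass to whole-body
#' units, and passed through the well-stirred liver model
#' CLh = Q * fub * Clu / (Q + fub * Clu), with Q the total liver plasma
#' flow (portal + arterial). Under restrictive clearance fub = fup
#' (only unbound chemical is available for metabolism); under
#' nonrestrictive clearance fub = 1.
#'
#' @param chemical A `chemical_record` (uses `clint`, `fup`, `logp`).
#' @param physiology A `rat_physiology`.
#' @param restrictive Logical; restrictive (fup-limited) clearance.
#' @param fu_hep Function of logP returning the incubation unbound
#'   fraction, or `NULL` to disable the correction.
#' @return Hepatic plasma clearance, L/h/kg body weight. Always strictly
#'   less than the liver plasma flow.
#' @export
hepatic_clearance <- function(chemical, physiology = rat_physiology(),
                              restrictive = TRUE, fu_hep = fu_hep_kilford) {
  if (is.na(chemical$clint) || chemical$clint < 0) {
    stop("intrinsic clearance must be >= 0 for chemical ", chemical$id,
         call. = FALSE)
  }
  fuh <- if (is.null(fu_hep)) 1 else fu_hep(chemical$logp)
  clint_u <- chemical$clint / fuh
  clw <- scale_clint_whole_body(clint_u, physiology)
  q_liver <- physiology$plasma_flows$liver + physiology$plasma_flows$gut
  fub <- if (restrictive) chemical$fup else 1
  q_liver * fub * clw / (q_liver + fub * clw)
}

#' Renal clearance by passive glomerular filtration
#'
#' CLr = GFR * fup: only unbound chemical in plasma is filtered; active
#' renal transport is not modeled.
#'
#' @param chemical A `chemical_record` (uses `fup`).
#' @param physiology A `rat_physiology` (uses `gfr`).
#' @return Renal plasma clearance, L/h/kg body weight.
#' @export
renal_clearance <- function(chemical, physiology = rat_physiology()) {
  physiology$gfr * chemical$fup
}
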