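#' Resolve the fraction unbound in plasma
#'
#' Measured fup values below the limit of detection of the rapid
#' equilibrium dialysis (RED) assay are replaced by a default of 0.005
#' (half the minimum detectable level). Values above the LOD pass
#' through unchanged.
#'
#' @param measured_value Measured fraction unbound in plasma, in (0, 1],
#'   or `NA` when not determinable.
#' @param below_lod Logical; `TRUE` when the measurement fell below the
#'   assay limit of detection (or is missing).
#' @param default Default fup used for below-LOD/missing values.
#' @return Resolved fup in (0, 1].
#' @export
resolve_fup <- function(measured_value, below_lod = FALSE, default = 0.005) {
  if (is.na(measured_value) || isTRUE(below_lod)) {
    return(default)
  }
  if (!is.numeric(measured_value) || measured_value <= 0 || measured_value > 1) {
    stop("fup must lie in (0, 1], got ", measured_value, call. = FALSE)
  }
  measured_value
}

#' Apply a non-specific binding correction to fup
#'
#' The RED assay can underestimate the free fraction because of
#' non-specific binding to the dialysis device. The published correction
#' is not reproduced here; the default is the identity, and any
#' monotone correction mapping (0,1] -> (0,1] can be injected.
#'
#' @param fup Fraction unbound in plasma, in (0, 1].
#' @param correction Function applied to `fup`; must return a value in
#'   (0, 1].
#' @return Corrected fup.
#' @export
correct_fup_nonspecific_binding <- function(fup, correction = identity) {
  if (fup <= 0 || fup > 1) {
    stop("fup must lie in (0, 1], got ", fup, call. = FALSE)
  }
  out <- correction(fup)
  if (!is.numeric(out) || is.na(out) || out <= 0 || out > 1) {
    stop("fup correction returned a value outside (0, 1]: ", out, call. = FALSE)
  }
  out
}

#' Select the intrinsic clearance measurement
#'
#' Intrinsic hepatic clearance is assayed at substrate concentrations of
#' 1 and 10 uM. The 1 uM value is used when measured successfully,
#' otherwise the 10 uM value. A chemical that was measurable but showed
#' no parent disappearance carries an explicit value of 0.
#'
#' @param clint_1 Clearance at 1 uM (uL/min/10^6 cells) or `NA`.
#' @param clint_10 Clearance at 10 uM (uL/min/10^6 cells) or `NA`.
#' @return Resolved intrinsic clearance (uL/min/10^6 cells).
#' @export
select_clint <- function(clint_1, clint_10) {
  if (is.na(clint_1) && is.na(clint_10)) {
    stop("no intrinsic clearance measurement available", call. = FALSE)
  }
  out <- if (!is.na(clint_1)) clint_1 else clint_10
  if (out < 0) stop("intrinsic clearance must be >= 0, got ", out, call. = FALSE)
  out
}

#' Ionization factor at a given pH
#'
#' Henderson-Hasselbalch factor Z = 1 + sum over acidic sites of
#' 10^(pH - pKa) + sum over basic sites of 10^(pKa - pH). The neutral
#' fraction is 1/Z; multiprotic chemicals are treated by summing the
#' per-site ionized-fraction terms independently.
#'
#' @param pka_donor Acidic pKa values (proton donors), numeric vector.
#' @param pka_acceptor Basic pKa values (proton acceptors), numeric vector.
#' @param ph pH of the medium, in [0, 14].
#' @return Ionization factor Z >= 1.
#' @keywords internal
ionization_factor <- function(pka_donor = numeric(), pka_acceptor = numeric(),
                              ph = 7.4) {
  stopifnot(ph >= 0, ph <= 14)
  1 + sum(10^(ph - pka_donor)) + sum(10^(pka_acceptor - ph))
}

#' Neutral fraction of a chemical at a given pH
#'
#' @inheritParams ionization_factor
#' @return Fraction of chemical in the neutral form, in (0, 1].
#' @export
neutral_fraction <- function(pka_donor = numeric(), pka_acceptor = numeric(),
                             ph = 7.4) {
  1 / ionization_factor(pka_donor, pka_acceptor, ph)
}

#' Derive logD from logP and ionization state
#'
#' logD = logP - log10(Z) where Z is the Henderson-Hasselbalch
#' ionization factor at the requested pH. For a neutral chemical
#' logD = logP at every pH; ionization can only lower the distribution
#' coefficient under this convention.
#'
#' @param logp Octanol-water partition coefficient (log10).
#' @param pka_donor Acidic pKa values.
#' @param pka_acceptor Basic pKa values.
#' @param ph pH, default 7.4 (physiological).
#' @return logD at the given pH.
#' @export
compute_logd <- function(logp, pka_donor = numeric(), pka_acceptor = numeric(),
                         ph = 7.4) {
  logp - log10(ionization_factor(pka_donor, pka_acceptor, ph))
}

#' Construct a chemical record
#'
#' Canonical container for one chemical's toxicokinetic and
#' physicochemical parameters. The measurement-handling rules are
#' applied at construction: below-LOD fup defaults to 0.005, intrinsic
#' clearance is resolved from the 1 uM measurement with 10 uM fallback,
#' and logD at pH 7.4 is derived from logP and the pKa values.
#'
#' @param id Chemical identifier (CAS or DTXSID string).
#' @param name Chemical name.
#' @param mw Molecular weight (g/mol), > 0.
#' @param logp Octanol-water partition coefficient (log10).
#' @param pka_donor Acidic pKa values (numeric vector, possibly empty).
#' @param pka_acceptor Basic pKa values (numeric vector, possibly empty).
#' @param fup Measured fraction unbound in plasma or `NA`.
#' @param fup_below_lod Logical; measurement below limit of detection.
#' @param clint_1,clint_10 Intrinsic clearance at 1 and 10 uM
#'   (uL/min/10^6 cells) or `NA`.
#' @param logwsol Water solubility (log10 mol/L) or `NA`.
#' @param loghenry Henry's law constant (log10 atm m^3/mol) or `NA`.
#' @return An object of class `chemical_record`.
#' @export
chemical_record <- function(id, name = id, mw, logp,
                            pka_donor = numeric(), pka_acceptor = numeric(),
                            fup = NA_real_, fup_below_lod = is.na(fup),
                            clint_1 = NA_real_, clint_10 = NA_real_,
                            logwsol = NA_real_, loghenry = NA_real_) {
  if (!is.numeric(mw) || is.na(mw) || mw <= 0) {
    stop("mw must be > 0 for chemical ", id, call. = FALSE)
  }
  pka_donor <- as.numeric(pka_donor[!is.na(pka_donor)])
  pka_acceptor <- as.numeric(pka_acceptor[!is.na(pka_acceptor)])
  rec <- structure(
    list(
      id = as.character(id),
      name = as.character(name),
      mw = mw,
      logp = logp,
      pka_donor = pka_donor,
      pka_acceptor = pka_acceptor,
      fup = resolve_fup(fup, fup_below_lod),
      fup_below_lod = isTRUE(fup_below_lod) || is.na(fup),
      clint_1 = clint_1,
      clint_10 = clint_10,
      clint = select_clint(clint_1, clint_10),
      logwsol = logwsol,
      loghenry = loghenry,
      logd = compute_logd(logp, pka_donor, pka_acceptor, ph = 7.4)
    ),
    class = "chemical_record"
  )
  rec
}

#' @export
print.chemical_record <- function(x, ...) {
  cat(sprintf(
    "<chemical_record> %s (%s)\n  MW %.1f g/mol, logP %.2f, logD(7.4) %.2f\n  fup %.4g%s, Clint %.4g uL/min/10^6 cells\n",
    x$name, x$id, x$mw, x$logp, x$logd, x$fup,
    if (x$fup_below_lod) " (below LOD, default)" else "", x$clint
  ))
  invisible(x)
}

#' Coerce a list of chemical records to a parameter data frame
#'
#' One row per chemical with the scalar parameters used downstream
#' (residual-correlation analysis, reporting).
#'
#' @param chems List of `chemical_record` objects.
#' @return data.frame with columns id, name, mw, logp, logd, fup, clint.
#' @export
chem_param_frame <- function(chems) {
  data.frame(
    id = vapply(chems, `[[`, character(1), "id"),
    name = vapply(chems, `[[`, character(1), "name"),
    mw = vapply(chems, `[[`, numeric(1), "mw"),
    logp = vapply(chems, `[[`, numeric(1), "logp"),
    logd = vapply(chems, `[[`, numeric(1), "logd"),
    fup = vapply(chems, `[[`, numeric(1), "fup"),
    clint = vapply(chems, `[[`, numeric(1), "clint"),
    stringsAsFactors = FALSE
  )
}
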