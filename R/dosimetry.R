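#' Assumption set for IVIVE
#'
#' One combination of the evaluated extrapolation assumptions:
#' restrictive vs nonrestrictive hepatic clearance, the internal
#' concentration selection (mean or max; total or free venous plasma, or
#' a tissue), and whether the in vitro disposition model supplies the
#' free assay concentration. The label uniquely encodes the triple with
#' the grammar used in reporting, e.g. `"res.-free-vein-mean-Armitage"`
#' or `"nres.-tot.-tis.-max"`.
#'
#' @param clearance `"restrictive"` or `"nonrestrictive"`.
#' @param statistic `"mean"` or `"max"`.
#' @param compartment `"venous_plasma"` or a tissue name; tissues are
#'   reported as `tis.` in the label.
#' @param binding `"total"` or `"free"` (plasma only).
#' @param armitage Logical; apply the in vitro disposition factor.
#' @return An object of class `assumption_set`.
#' @export
assumption_set <- function(clearance = c("restrictive", "nonrestrictive"),
                           statistic = c("mean", "max"),
                           compartment = "venous_plasma",
                           binding = c("total", "free"),
                           armitage = FALSE) {
  clearance <- match.arg(clearance)
  statistic <- match.arg(statistic)
  binding <- match.arg(binding)
  metric <- concentration_metric(statistic, compartment, binding)
  label <- paste0(
    if (clearance == "restrictive") "res." else "nres.", "-",
    if (binding == "total") "tot." else "free", "-",
    if (compartment == "venous_plasma") "vein" else "tis.", "-",
    statistic,
    if (armitage) "-Armitage" else ""
  )
  structure(list(clearance = clearance, metric = metric,
                 armitage = isTRUE(armitage), label = label),
            class = "assumption_set")
}

#' @export
print.assumption_set <- function(x, ...) {
  cat("<assumption_set>", x$label, "\n")
  invisible(x)
}

#' Parse an assumption-set label
#'
#' Inverse of the label grammar produced by [assumption_set()].
#'
#' @param label Label string, e.g. `"res.-free-vein-mean-Armitage"`.
#' @param tissue Tissue compartment substituted for `tis.` labels
#'   (default `"liver"`).
#' @return An `assumption_set`.
#' @export
parse_assumption_label <- function(label, tissue = "liver") {
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  if (length(parts) < 4) stop("malformed assumption label: ", label,
                              call. = FALSE)
  assumption_set(
    clearance = if (parts[1] == "res.") "restrictive" else "nonrestrictive",
    binding = if (parts[2] == "tot.") "total" else "free",
    compartment = if (parts[3] == "vein") "venous_plasma" else tissue,
    statistic = parts[4],
    armitage = length(parts) > 4 && parts[5] == "Armitage"
  )
}

#' The default evaluated assumption grid
#'
#' Restrictive and nonrestrictive clearance crossed with total/free
#' venous plasma and (total) tissue concentration, mean and max; the in
#' vitro disposition model is combined only with the mean venous plasma
#' selections (free and total), mirroring how results are reported.
#'
#' @param tissue Tissue compartment used for the `tis.` selections.
#' @return Named list of `assumption_set` objects keyed by label.
#' @export
default_assumption_sets <- function(tissue = "liver") {
  sets <- list()
  for (cl in c("restrictive", "nonrestrictive")) {
    for (stat in c("mean", "max")) {
      sets <- c(sets, list(
        assumption_set(cl, stat, "venous_plasma", "total"),
        assumption_set(cl, stat, "venous_plasma", "free"),
        assumption_set(cl, stat, tissue, "total")
      ))
    }
    sets <- c(sets, list(
      assumption_set(cl, "mean", "venous_plasma", "free", armitage = TRUE),
      assumption_set(cl, "mean", "venous_plasma", "total", armitage = TRUE)
    ))
  }
  stats::setNames(sets, vapply(sets, `[[`, character(1), "label"))
}

#' Concentration-to-dose ratio for one chemical and assumption set
#'
#' Simulates the PBTK model at the reference dose of 1 mg/kg/day given
#' once daily over the study length, extracts the selected concentration
#' metric, and (when the assumption set includes the in vitro
#' disposition model) divides by the well distribution factor. By
#' construction kappa is the selected concentration per unit dose, so
#' C = dose * kappa and AED = AC50 / kappa.
#'
#' @param chemical A `chemical_record`.
#' @param study_length Study length in days.
#' @param assumptions An `assumption_set`.
#' @param physiology A `rat_physiology`.
#' @param well An `assay_well` used when `assumptions$armitage` is TRUE.
#' @return One-row data.frame: chemical_id, study_length,
#'   assumption_label, kappa (uM per mg/kg/day).
#' @export
compute_kappa <- function(chemical, study_length, assumptions,
                          physiology = rat_physiology(),
                          well = assay_well()) {
  params <- pbtk_parameters(
    chemical, physiology,
    restrictive = assumptions$clearance == "restrictive"
  )
  tc <- simulate_pbtk(params, dose_regimen(1, 1L, study_length))
  kappa <- extract_concentration(tc, assumptions$metric, fup = chemical$fup)
  if (assumptions$armitage) {
    kappa <- adjust_kappa(kappa, distribute_in_vitro(chemical, well, 1)$factor)
  }
  if (!is.finite(kappa) || kappa <= 0) {
    stop("kappa must be positive and finite for chemical ", chemical$id,
         call. = FALSE)
  }
  data.frame(chemical_id = chemical$id, study_length = study_length,
             assumption_label = assumptions$label, kappa = kappa,
             stringsAsFactors = FALSE)
}

#' Kappa table across chemicals, study lengths and assumption sets
#'
#' Efficient batch computation: the PBTK model is simulated once per
#' (chemical, study length, clearance mode) and all concentration
#' metrics are extracted from the same solution; the in vitro
#' distribution factor is computed once per chemical. This mirrors the
#' workflow in which kappa is computed once and reused across all
#' regression evaluations.
#'
#' @param chemicals List of `chemical_record` objects.
#' @param study_lengths Integer vector of study lengths (days).
#' @param assumption_sets List of `assumption_set` objects (default full
#'   grid).
#' @param physiology A `rat_physiology`.
#' @param well An `assay_well` for the disposition factor.
#' @return data.frame with columns chemical_id, study_length,
#'   assumption_label, kappa.
#' @export
kappa_table <- function(chemicals, study_lengths,
                        assumption_sets = default_assumption_sets(),
                        physiology = rat_physiology(),
                        well = assay_well()) {
  study_lengths <- sort(unique(as.integer(study_lengths)))
  specs <- lapply(assumption_sets, function(a) {
    list(label = a$label, clearance = a$clearance, metric = a$metric,
         armitage = a$armitage)
  })
  need_armitage <- any(vapply(specs, `[[`, logical(1), "armitage"))
  out <- vector("list", length(chemicals) * length(study_lengths) * 2L)
  k <- 0L
  for (chem in chemicals) {
    factor <- if (need_armitage) {
      distribute_in_vitro(chem, well, 1)$factor
    } else NA_real_
    kp <- tissue_partition_coefficients(chem, physiology)
    for (restrictive in c(TRUE, FALSE)) {
      cl_mode <- if (restrictive) "restrictive" else "nonrestrictive"
      use <- specs[vapply(specs, function(s) s$clearance == cl_mode,
                          logical(1))]
      if (length(use) == 0) next
      params <- pbtk_parameters(chem, physiology, restrictive = restrictive,
                                kp = kp)
      for (len in study_lengths) {
        tc <- simulate_pbtk(params, dose_regimen(1, 1L, len))
        for (s in use) {
          kappa <- extract_concentration(tc, s$metric, fup = chem$fup)
          if (s$armitage) kappa <- adjust_kappa(kappa, factor)
          k <- k + 1L
          out[[k]] <- data.frame(
            chemical_id = chem$id, study_length = len,
            assumption_label = s$label, kappa = kappa,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Forward dosimetry: dose to internal concentration
#'
#' @param dose Dose in mg/kg/day.
#' @param kappa Concentration-to-dose ratio (numeric, or a kappa-table
#'   row).
#' @return Concentration in uM.
#' @export
forward_concentration <- function(dose, kappa) {
  if (is.data.frame(kappa)) kappa <- kappa$kappa
  dose * kappa
}

#' Reverse dosimetry: AC50 to administered equivalent dose
#'
#' @param ac50 In vitro bioactive concentration (uM).
#' @param kappa Concentration-to-dose ratio (numeric, or a kappa-table
#'   row).
#' @return Administered equivalent dose in mg/kg/day.
#' @export
reverse_aed <- function(ac50, kappa) {
  if (is.data.frame(kappa)) kappa <- kappa$kappa
  ac50 / kappa
}

#' Forward/reverse dosimetry residual bookkeeping
#'
#' For one record, the forward residual log10(AC50) - log10(C) and the
#' reverse residual log10(dose) - log10(AED) are equal and opposite,
#' because C = dose * kappa and AED = AC50 / kappa share the same kappa.
#'
#' @param dose Dose (mg/kg/day).
#' @param ac50 AC50 (uM).
#' @param kappa Concentration-to-dose ratio.
#' @return data.frame with c_pbtk, aed_pbtk, residual (forward
#'   convention).
#' @export
dosimetry_result <- function(dose, ac50, kappa) {
  if (is.data.frame(kappa)) kappa <- kappa$kappa
  c_pbtk <- forward_concentration(dose, kappa)
  aed <- reverse_aed(ac50, kappa)
  data.frame(dose = dose, ac50 = ac50, kappa = kappa,
             c_pbtk = c_pbtk, aed_pbtk = aed,
             residual = log10(ac50) - log10(c_pbtk))
}

# exact (chemical, study length) kappa lookup with nearest-length
# fallback, vectorized over records
kappa_lookup <- function(kappas, chemical_ids, study_lengths, label) {
  kt <- kappas[kappas$assumption_label == label, , drop = FALSE]
  if (nrow(kt) == 0) stop("no kappa entries for assumption set ", label,
                          call. = FALSE)
  key <- paste(kt$chemical_id, kt$study_length)
  want <- paste(chemical_ids, study_lengths)
  idx <- match(want, key)
  if (anyNA(idx)) {
    # nearest simulated study length for that chemical
    for (j in which(is.na(idx))) {
      sub <- which(kt$chemical_id == chemical_ids[j])
      if (length(sub) == 0) {
        stop("no kappa for chemical ", chemical_ids[j], " under ", label,
             call. = FALSE)
      }
      idx[j] <- sub[which.min(abs(kt$study_length[sub] - study_lengths[j]))]
    }
  }
  kt$kappa[idx]
}
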