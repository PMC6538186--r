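#' Run configuration for the concordance pipeline
#'
#' Bundles the input tables, the assumption grid, thresholds and the
#' master seed. All randomness downstream (randomization plans) is
#' derived from the master seed and per-comparison identifiers, so a run
#' is fully deterministic given the config.
#'
#' @param chems List of `chemical_record` objects.
#' @param ac50 AC50 table (unfiltered; cleaned internally).
#' @param endpoint Endpoint-level in vivo table (raw rows accepted;
#'   passed through [derive_endpoint_doses()]).
#' @param pod POD-level record table (raw rows accepted).
#' @param assumption_sets Named list of `assumption_set` objects.
#' @param min_n Minimum chemicals per comparison (default 5).
#' @param n_random_sets Random evaluation subsets (default 10).
#' @param seed Master seed.
#' @param physiology A `rat_physiology`.
#' @param well An `assay_well` for disposition-adjusted sets.
#' @param tissue Tissue compartment for `tis.` assumption labels.
#' @return An object of class `run_config`.
#' @export
run_config <- function(chems, ac50, endpoint = NULL, pod = NULL,
                       assumption_sets = default_assumption_sets(),
                       min_n = 5L, n_random_sets = 10L, seed = 1L,
                       physiology = rat_physiology(), well = assay_well(),
                       tissue = "liver") {
  stopifnot(length(assumption_sets) >= 1, min_n >= 2)
  structure(
    list(chems = chems, ac50 = ac50, endpoint = endpoint, pod = pod,
         assumption_sets = assumption_sets, min_n = as.integer(min_n),
         n_random_sets = as.integer(n_random_sets), seed = as.integer(seed),
         physiology = physiology, well = well, tissue = tissue),
    class = "run_config")
}

pipeline_kappas <- function(cfg, study_lengths) {
  kappa_table(cfg$chems, study_lengths, cfg$assumption_sets,
              cfg$physiology, cfg$well)
}

score_comparisons <- function(comparisons, kappas, cfg) {
  labels <- vapply(cfg$assumption_sets, `[[`, character(1), "label")
  ki <- build_kappa_index(kappas)
  recs <- list()
  skipped <- character()
  for (comparison in comparisons) {
    res <- tryCatch(
      evaluate_comparison_core(
        comparison, ki,
        make_randomization_plan(comparison,
                                comparison_seed(cfg$seed, comparison),
                                cfg$n_random_sets),
        labels),
      ivive_degenerate_comparison = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped, paste(comparison$assay_endpoint,
                                  comparison$in_vivo_endpoint, sep = "::"))
      next
    }
    recs[[length(recs) + 1L]] <- res
  }
  if (length(recs) == 0) stop("all comparisons degenerate", call. = FALSE)
  ormse_records <- do.call(rbind, recs)
  wins <- count_wins(ormse_records)
  list(ormse = ormse_records, wins = wins,
       summary = aggregate_counts(wins), skipped = skipped)
}

#' Endpoint-level concordance analysis
#'
#' Full workflow for the endpoint-level in vivo data: filter hits,
#' derive endpoint doses, build comparisons per (assay endpoint x
#' in vivo endpoint) within each study type, compute the kappa table,
#' score every comparison under every assumption set and dosimetry
#' direction against the untransformed and randomized comparators, and
#' aggregate win counts across the random evaluation subsets.
#'
#' @param cfg A `run_config` with an `endpoint` table.
#' @param kappas Optional precomputed kappa table (reused across
#'   analyses).
#' @return List: `comparisons`, `kappas`, `ormse` (long table), `wins`
#'   (per-set counts), `summary` (medians, sds, win fractions),
#'   `variances` (median log10 variances), `skipped`.
#' @export
run_endpoint_analysis <- function(cfg, kappas = NULL) {
  hits <- filter_ac50(cfg$ac50)
  doses <- derive_endpoint_doses(cfg$endpoint)
  doses$endpoint_id <- paste(doses$study_type, doses$effect_category,
                             doses$effect_type, doses$effect_target,
                             sep = "|")
  comparisons <- build_comparisons(hits, doses, cfg$min_n)
  if (length(comparisons) == 0) stop("no comparisons meet the min_n threshold",
                                     call. = FALSE)
  if (is.null(kappas)) {
    kappas <- pipeline_kappas(cfg, unique(doses$study_length))
  }
  out <- score_comparisons(comparisons, kappas, cfg)
  out$comparisons <- comparisons
  out$kappas <- kappas
  out$variances <- variance_summary(comparisons)
  out
}

#' POD-level concordance analysis
#'
#' As [run_endpoint_analysis()] but with one comparison per assay
#' endpoint against the per-chemical point of departure (minimum of the
#' pooled LOEL/LOAEL values), and with the median log10 variance
#' summary of the comparisons.
#'
#' @param cfg A `run_config` with a `pod` table.
#' @param kappas Optional precomputed kappa table.
#' @return As [run_endpoint_analysis()].
#' @export
run_pod_analysis <- function(cfg, kappas = NULL) {
  hits <- filter_ac50(cfg$ac50)
  podmap <- derive_pod(cfg$pod)
  invivo <- data.frame(chemical_id = podmap$chemical_id, dose = podmap$pod,
                       study_length = podmap$study_length,
                       stringsAsFactors = FALSE)
  comparisons <- build_comparisons(hits, invivo, cfg$min_n)
  if (length(comparisons) == 0) stop("no comparisons meet the min_n threshold",
                                     call. = FALSE)
  if (is.null(kappas)) {
    kappas <- pipeline_kappas(cfg, unique(invivo$study_length))
  }
  out <- score_comparisons(comparisons, kappas, cfg)
  out$comparisons <- comparisons
  out$kappas <- kappas
  out$variances <- variance_summary(comparisons)
  out
}

#' Lower-percentile POD vs AED comparison across assumption sets
#'
#' Per assumption set: per-chemical AEDs from every clean positive AC50
#' (kappa at the time scale of the chemical's minimum-dose POD record),
#' the lower 10th percentile POD and AED per chemical, RMSE/ORMSE of the
#' log10 pairs, the conservatism rate (fraction of chemicals with
#' AED10 <= POD10), and the residual |correlation| against each model
#' input parameter.
#'
#' @param cfg A `run_config` with `pod` data.
#' @param kappas Optional precomputed kappa table.
#' @param q Quantile (default 0.10).
#' @return List: `records` (long per-chemical table), `metrics` (per
#'   assumption set), `correlations` (|COR| long table), `kappas`.
#' @export
run_pod10_comparison <- function(cfg, kappas = NULL, q = 0.10) {
  hits <- filter_ac50(cfg$ac50)
  pool <- filter_pod_records(cfg$pod)
  podmap <- derive_pod(cfg$pod)
  if (is.null(kappas)) {
    kappas <- pipeline_kappas(cfg, unique(podmap$study_length))
  }
  chems_with_both <- intersect(unique(hits$chemical_id), podmap$chemical_id)
  hits <- hits[hits$chemical_id %in% chems_with_both, , drop = FALSE]
  pool <- pool[pool$chemical_id %in% chems_with_both, , drop = FALSE]
  lens <- stats::setNames(podmap$study_length, podmap$chemical_id)

  metrics <- list()
  cors <- list()
  records <- list()
  for (a in cfg$assumption_sets) {
    k <- kappa_lookup(kappas, hits$chemical_id,
                      unname(lens[hits$chemical_id]), a$label)
    aeds <- data.frame(chemical_id = hits$chemical_id,
                       aed = reverse_aed(hits$ac50, k),
                       stringsAsFactors = FALSE)
    res <- pod10_aed10(pool, aeds, q = q)
    metrics[[length(metrics) + 1L]] <- data.frame(
      assumption_label = a$label, rmse = res$rmse, ormse = res$ormse,
      conservatism = res$conservatism, n_chemicals = nrow(res$records),
      stringsAsFactors = FALSE)
    cc <- residual_param_correlations(res$records, cfg$chems)
    cc$assumption_label <- a$label
    cors[[length(cors) + 1L]] <- cc
    rr <- res$records
    rr$assumption_label <- a$label
    records[[length(records) + 1L]] <- rr
  }
  list(records = do.call(rbind, records),
       metrics = do.call(rbind, metrics),
       correlations = do.call(rbind, cors),
       kappas = kappas)
}
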