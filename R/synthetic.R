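#' Configuration for the synthetic data generator
#'
#' Describes the stated world the generator emulates: a chemical library
#' with realistic TK/physchem marginals, a chemical-level latent potency
#' that all of a chemical's assay AC50 values share (assays differ by an
#' assay-level shift, which standardization removes within a
#' comparison), and in vivo doses coupled to the potency through the
#' true concentration-to-dose ratio plus lognormal noise:
#' dose = (potency / kappa_true) * 10^eps, eps ~ Normal(0, noise_sd).
#' With noise_sd = 0 the generated tables are an exact fixed point of
#' the reverse dosimetry pipeline under the true assumption set.
#'
#' @param n_chemicals,n_assays,n_endpoints Library dimensions.
#' @param hit_rate Probability a (chemical, assay) pair is active.
#' @param flag_rate Fraction of positive rows carrying a synthetic
#'   curve-fit flag (removed by [filter_ac50()]).
#' @param ac50_log_mean,ac50_log_sd Mean and sd of the latent log10
#'   potency (uM).
#' @param assay_shift_sd sd of the per-assay log10 shift.
#' @param noise_sd sd of the lognormal (log10) dose noise.
#' @param true_assumptions The generating `assumption_set`.
#' @param endpoint_active_rate Probability an active chemical shows a
#'   given in vivo endpoint.
#' @param study_type_mix Named probabilities for chronic, subchronic,
#'   developmental endpoint studies.
#' @param fup_logit_mean,fup_logit_sd Logit-normal fup parameters.
#' @param clint_zero_frac Point mass at Clint = 0 (chemicals with no
#'   observed parent disappearance).
#' @param clint_meanlog,clint_sdlog Lognormal Clint parameters (natural
#'   log, uL/min/10^6 cells).
#' @param logp_mean,logp_sd Normal logP parameters.
#' @param acid_frac,base_frac Fractions of acids and bases (remainder
#'   neutral).
#' @param pod_types Study types available to the POD-level generator.
#' @param shuffle_labels Permute chemical labels on the generated in
#'   vivo tables (null world: doses decoupled from both TK and
#'   bioactivity).
#' @param seed Generator seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chemicals = 200L, n_assays = 20L,
                             n_endpoints = 12L, hit_rate = 0.3,
                             flag_rate = 0.1, ac50_log_mean = 0.5,
                             ac50_log_sd = 1.0, assay_shift_sd = 0.5,
                             noise_sd = 0.3,
                             true_assumptions = assumption_set(
                               "restrictive", "mean", "venous_plasma", "free"),
                             endpoint_active_rate = 0.5,
                             study_type_mix = c(chronic = 0.4,
                                                subchronic = 0.4,
                                                developmental = 0.2),
                             fup_logit_mean = -2.2, fup_logit_sd = 1.5,
                             clint_zero_frac = 0.2, clint_meanlog = 2.3,
                             clint_sdlog = 1.2, logp_mean = 2.5,
                             logp_sd = 1.5, acid_frac = 0.25,
                             base_frac = 0.25,
                             pod_types = c("subacute", "subchronic",
                                           "chronic"),
                             shuffle_labels = FALSE, seed = 1L) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, flag_rate >= 0, flag_rate <= 1,
            noise_sd >= 0, ac50_log_sd >= 0, assay_shift_sd >= 0,
            abs(sum(study_type_mix) - 1) < 1e-9)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic chemical library
#'
#' fup is logit-normal clipped to \[0.005, 1\]; Clint is lognormal with a
#' configurable point mass at zero (assigned to the 1 uM column, with a
#' fraction measured only at 10 uM to exercise the fallback); logP is
#' normal; chemicals are assigned acid/base/neutral ionization classes;
#' MW is uniform on \[100, 500\].
#'
#' @param cfg A `synthetic_config`.
#' @return List of `chemical_record` objects.
#' @export
gen_chemicals <- function(cfg) {
  n <- cfg$n_chemicals
  with_seed(cfg$seed, {
    fup <- pmin(1, pmax(0.005, stats::plogis(
      stats::rnorm(n, cfg$fup_logit_mean, cfg$fup_logit_sd))))
    clint <- ifelse(stats::runif(n) < cfg$clint_zero_frac, 0,
                    stats::rlnorm(n, cfg$clint_meanlog, cfg$clint_sdlog))
    only10 <- stats::runif(n) < 0.2
    logp <- stats::rnorm(n, cfg$logp_mean, cfg$logp_sd)
    cls <- sample(c("acid", "base", "neutral"), n, replace = TRUE,
                  prob = c(cfg$acid_frac, cfg$base_frac,
                           1 - cfg$acid_frac - cfg$base_frac))
    pka <- stats::runif(n, 3, 10)
    mw <- stats::runif(n, 100, 500)
    logwsol <- stats::rnorm(n, -3.5, 1)
    loghenry <- stats::rnorm(n, -9, 1.5)
    lapply(seq_len(n), function(i) {
      chemical_record(
        id = sprintf("SYN-%04d", i), name = sprintf("synthetic-%04d", i),
        mw = mw[i], logp = logp[i],
        pka_donor = if (cls[i] == "acid") pka[i] else numeric(),
        pka_acceptor = if (cls[i] == "base") pka[i] else numeric(),
        fup = fup[i], fup_below_lod = FALSE,
        clint_1 = if (only10[i]) NA_real_ else clint[i],
        clint_10 = if (only10[i]) clint[i] else NA_real_,
        logwsol = logwsol[i], loghenry = loghenry[i])
    })
  })
}

#' Generate a synthetic AC50 table
#'
#' Each (chemical, assay) pair is active with probability `hit_rate`;
#' active pairs get log10 AC50 = potency(chemical) + shift(assay), so
#' the marginal is Normal(ac50_log_mean, sqrt(ac50_log_sd^2 +
#' assay_shift_sd^2)). A `flag_rate` fraction of positive rows carries a
#' synthetic curve-fit flag; inactive pairs are emitted with a negative
#' hit call.
#'
#' @param chems Chemical list from [gen_chemicals()].
#' @param cfg A `synthetic_config`.
#' @return data.frame in the assay-hit schema, with the latent potency
#'   attached as attribute `"potency"` (named log10 uM vector).
#' @export
gen_ac50 <- function(chems, cfg) {
  n <- length(chems)
  m <- cfg$n_assays
  ids <- vapply(chems, `[[`, character(1), "id")
  with_seed(cfg$seed + 1L, {
    potency <- stats::setNames(
      stats::rnorm(n, cfg$ac50_log_mean, cfg$ac50_log_sd), ids)
    shift <- stats::rnorm(m, 0, cfg$assay_shift_sd)
    active <- matrix(stats::runif(n * m) < cfg$hit_rate, n, m)
    flagged <- matrix(stats::runif(n * m) < cfg$flag_rate, n, m)
    rows <- cbind(rep(seq_len(n), times = m), rep(seq_len(m), each = n))
    df <- data.frame(
      chemical_id = ids[rows[, 1]],
      assay_endpoint = sprintf("ASSAY_%02d", rows[, 2]),
      ac50 = ifelse(active[rows], 10^(potency[rows[, 1]] + shift[rows[, 2]]),
                    NA_real_),
      hit_call = active[rows],
      flags = ifelse(active[rows] & flagged[rows], "noisy", ""),
      stringsAsFactors = FALSE)
    df <- df[order(df$chemical_id, df$assay_endpoint), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "potency") <- potency
    df
  })
}

#' Generate synthetic in vivo dose tables
#'
#' Couples in vivo doses to in vitro potency through the true
#' concentration-to-dose ratio: dose = (10^potency / kappa_true) *
#' 10^eps with eps ~ Normal(0, noise_sd), kappa_true evaluated for the
#' chemical at the study-type length under `cfg$true_assumptions`.
#' Emits an endpoint-level table (crossed effect taxonomy, study types
#' from the configured mixture) and a POD-level LOEL/LOAEL table whose
#' pooled minima mirror the POD derivation. With `cfg$shuffle_labels`
#' the chemical labels of both tables are permuted after generation,
#' decoupling doses from both the labelled chemical's TK and its AC50.
#'
#' @param chems Chemical list.
#' @param ac50_table Table from [gen_ac50()] (uses its potency
#'   attribute).
#' @param cfg A `synthetic_config`.
#' @param physiology A `rat_physiology` for the kappa computation.
#' @param kappas Optional precomputed kappa table containing the true
#'   assumption label at the canonical study lengths.
#' @return List with elements `endpoint` (endpoint-dose schema) and
#'   `pod` (POD-record schema).
#' @export
gen_invivo <- function(chems, ac50_table, cfg,
                       physiology = rat_physiology(), kappas = NULL) {
  potency <- attr(ac50_table, "potency")
  ids <- names(potency)
  active_ids <- unique(filter_ac50(ac50_table)$chemical_id)
  if (is.null(kappas)) {
    lengths_needed <- unique(.study_type_lengths[
      c(names(cfg$study_type_mix), cfg$pod_types)])
    kappas <- kappa_table(chems, lengths_needed,
                          list(cfg$true_assumptions), physiology)
  }
  label <- cfg$true_assumptions$label
  kap <- function(chem_ids, lengths) {
    kappa_lookup(kappas, chem_ids, lengths, label)
  }

  # endpoint taxonomy: crossed factors, n_endpoints combos
  tax <- expand.grid(effect_category = c("systemic", "reproductive",
                                         "neurological"),
                     effect_type = c("pathology", "clinical"),
                     effect_target = c("liver", "kidney", "body_weight"),
                     stringsAsFactors = FALSE)
  tax <- tax[seq_len(min(nrow(tax), cfg$n_endpoints)), , drop = FALSE]
  types <- names(cfg$study_type_mix)

  with_seed(cfg$seed + 2L, {
    ep <- list()
    for (id in active_ids) {
      st <- sample(types, 1, prob = cfg$study_type_mix)
      show <- stats::runif(nrow(tax)) < cfg$endpoint_active_rate
      if (!any(show)) next
      len <- .study_type_lengths[[st]]
      k <- kap(id, len)
      eps <- stats::rnorm(sum(show), 0, cfg$noise_sd)
      ep[[length(ep) + 1L]] <- data.frame(
        chemical_id = id,
        study_id = paste0("STUDY-", id, "-", st),
        study_type = st,
        tax[show, , drop = FALSE],
        dose = 10^potency[[id]] / k * 10^eps,
        study_length = len,
        stringsAsFactors = FALSE)
    }
    endpoint <- do.call(rbind, ep)
    rownames(endpoint) <- NULL

    pod <- list()
    for (id in active_ids) {
      n_rec <- 1L + stats::rpois(1, 2)
      st <- sample(cfg$pod_types, n_rec, replace = TRUE)
      len <- .study_type_lengths[st]
      k <- kap(rep(id, n_rec), len)
      eps <- stats::rnorm(n_rec, 0, cfg$noise_sd)
      pod[[length(pod) + 1L]] <- data.frame(
        chemical_id = id,
        pod_type = sample(c("LOEL", "LOAEL"), n_rec, replace = TRUE),
        dose = 10^potency[[id]] / k * 10^eps,
        dose_units = "mg/kg/day",
        study_type = st,
        route = "oral",
        duration_days = unname(len),
        stringsAsFactors = FALSE)
    }
    pod <- do.call(rbind, pod)
    rownames(pod) <- NULL

    if (isTRUE(cfg$shuffle_labels)) {
      perm <- stats::setNames(sample(ids), ids)
      endpoint$chemical_id <- unname(perm[endpoint$chemical_id])
      pod$chemical_id <- unname(perm[pod$chemical_id])
    }
    list(endpoint = endpoint, pod = pod)
  })
}
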