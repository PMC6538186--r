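#' Build in vitro - in vivo comparison sets
#'
#' Merges filtered bioactivity hits with in vivo doses by chemical. For
#' endpoint-level data one comparison is built per (assay endpoint x
#' in vivo endpoint) combination; for POD-level data (no `endpoint_id`
#' column) one comparison per assay endpoint against the per-chemical
#' POD. Only comparisons with at least `min_n` unique chemicals having
#' both a clean positive AC50 and an in vivo dose are retained.
#' Duplicate (chemical, assay) AC50 rows collapse to the minimum AC50;
#' multiple in vivo records per (chemical, endpoint) collapse to the
#' minimum dose (with its study length).
#'
#' @param ac50_table Filtered hits (see [filter_ac50()]): chemical_id,
#'   assay_endpoint, ac50.
#' @param invivo_table data.frame with chemical_id, dose, study_length
#'   and optionally endpoint_id.
#' @param min_n Minimum number of unique chemicals (default 5).
#' @return List of `comparison_set` objects.
#' @export
build_comparisons <- function(ac50_table, invivo_table, min_n = 5L) {
  # collapse AC50 duplicates to the minimum per (chemical, assay)
  akey <- paste(ac50_table$chemical_id, ac50_table$assay_endpoint, sep = "\r")
  ao <- ac50_table[order(akey, ac50_table$ac50), , drop = FALSE]
  ao <- ao[!duplicated(paste(ao$chemical_id, ao$assay_endpoint, sep = "\r")), ,
           drop = FALSE]

  if (!"endpoint_id" %in% names(invivo_table)) {
    invivo_table$endpoint_id <- "POD"
  }
  ikey <- paste(invivo_table$chemical_id, invivo_table$endpoint_id, sep = "\r")
  io <- invivo_table[order(ikey, invivo_table$dose), , drop = FALSE]
  io <- io[!duplicated(paste(io$chemical_id, io$endpoint_id, sep = "\r")), ,
           drop = FALSE]

  out <- list()
  for (assay in unique(ao$assay_endpoint)) {
    a <- ao[ao$assay_endpoint == assay, , drop = FALSE]
    for (ep in unique(io$endpoint_id)) {
      v <- io[io$endpoint_id == ep, , drop = FALSE]
      m <- merge(a[, c("chemical_id", "ac50")],
                 v[, c("chemical_id", "dose", "study_length")],
                 by = "chemical_id")
      if (nrow(m) < min_n) next
      m <- m[order(m$chemical_id), , drop = FALSE]
      out[[length(out) + 1L]] <- structure(
        list(assay_endpoint = assay, in_vivo_endpoint = ep,
             chemical_ids = m$chemical_id, doses = m$dose,
             ac50s = m$ac50, study_lengths = m$study_length,
             n = nrow(m)),
        class = "comparison_set")
    }
  }
  out
}

#' @export
print.comparison_set <- function(x, ...) {
  cat(sprintf("<comparison_set> %s vs %s (n = %d chemicals)\n",
              x$assay_endpoint, x$in_vivo_endpoint, x$n))
  invisible(x)
}

#' Standardize a vector
#'
#' Subtracts the mean and divides by the sample (n-1 denominator)
#' standard deviation.
#'
#' @param values Numeric vector, length >= 2.
#' @return Standardized vector with mean 0 and sample sd 1.
#' @export
standardize <- function(values) {
  if (length(values) < 2) stop("standardize needs n >= 2", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s <= .Machine$double.eps^0.5 * max(1, abs(mean(values)))) {
    stop(structure(
      class = c("ivive_degenerate_comparison", "error", "condition"),
      list(message = "zero variance in comparison variable", call = NULL)))
  }
  (values - mean(values)) / s
}

#' Orthogonal root mean square error
#'
#' RMS of the orthogonal distances of the standardized points from the
#' identity line: sqrt(sum(((phi_i - theta_i)/sqrt(2))^2) / n). Always
#' measured against the phi = theta line. For standardized inputs with
#' the sample-sd convention, ORMSE^2 = ((n-1)/n) (1 - r) with r the
#' Pearson correlation.
#'
#' @param phi Standardized y vector.
#' @param theta Standardized x vector (same length).
#' @return ORMSE >= 0.
#' @export
ormse <- function(phi, theta) {
  if (length(phi) != length(theta)) {
    stop("phi and theta must have equal length", call. = FALSE)
  }
  sqrt(mean(((phi - theta) / sqrt(2))^2))
}

# FNV-1a 32-bit string hash folded into [0, 2^31): used to derive
# per-comparison seeds from the master seed so comparisons are
# independent and reproducible.
string_hash31 <- function(s) {
  h <- 2166136261
  for (code in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2^31)
}

comparison_seed <- function(master_seed, comparison) {
  id <- paste(comparison$assay_endpoint, comparison$in_vivo_endpoint,
              sep = "::")
  as.integer((as.numeric(master_seed) + string_hash31(id)) %% (2^31 - 1))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Randomization plan for one comparison
#'
#' Draws `n_sets` vectors of chemicals, each of the comparison's length,
#' sampled with replacement from the comparison's chemical vector. Only
#' TK and physicochemical parameters are randomized downstream: the
#' randomized kappa is looked up for the substituted chemical at the
#' original record's study length, while dose, AC50 and study length
#' stay with the original record.
#'
#' @param comparison A `comparison_set`.
#' @param seed Integer seed (typically derived from the master seed and
#'   the comparison identifier).
#' @param n_sets Number of random sets (default 10).
#' @return An object of class `randomization_plan` with an `n x n_sets`
#'   index matrix and the corresponding chemical ids.
#' @export
make_randomization_plan <- function(comparison, seed, n_sets = 10L) {
  n <- comparison$n
  idx <- with_seed(seed, {
    matrix(sample.int(n, n * n_sets, replace = TRUE), nrow = n)
  })
  structure(
    list(seed = seed, n_sets = as.integer(n_sets), index = idx,
         permuted_chemicals = matrix(comparison$chemical_ids[idx], nrow = n)),
    class = "randomization_plan")
}

# Indexed log10-kappa lookup structure for fast batch scoring: an
# (chemical x study length) x label matrix with positional access.
build_kappa_index <- function(kappas) {
  chems <- sort(unique(kappas$chemical_id))
  lengths <- sort(unique(kappas$study_length))
  labels <- unique(kappas$assumption_label)
  arr <- matrix(NA_real_, length(chems) * length(lengths), length(labels),
                dimnames = list(NULL, labels))
  ci <- match(kappas$chemical_id, chems)
  li <- match(kappas$study_length, lengths)
  lab <- match(kappas$assumption_label, labels)
  arr[cbind(ci + (li - 1L) * length(chems), lab)] <- log10(kappas$kappa)
  list(chems = chems, lengths = lengths, labels = labels, arr = arr,
       n_chems = length(chems))
}

# rows into the kappa index for given (chemical, study length) pairs,
# with nearest-length fallback
kappa_index_rows <- function(ki, chemical_ids, study_lengths) {
  ci <- match(chemical_ids, ki$chems)
  if (anyNA(ci)) {
    stop("no kappa entries for chemical(s) ",
         paste(unique(chemical_ids[is.na(ci)]), collapse = ", "),
         call. = FALSE)
  }
  li <- match(study_lengths, ki$lengths)
  if (anyNA(li)) {
    for (j in which(is.na(li))) {
      li[j] <- which.min(abs(ki$lengths - study_lengths[j]))
    }
  }
  ci + (li - 1L) * ki$n_chems
}

# Core scorer: all assumption labels and random sets at once for one
# comparison, using the exact identity ORMSE^2 = ((n-1)/n) (1 - r) for
# standardized (sample-sd) inputs, with r the Pearson correlation. The
# direct ormse()/standardize() route is kept independent and the two are
# cross-checked in the test suite.
evaluate_comparison_core <- function(comparison, kappas, plan, labels) {
  n <- comparison$n
  lac <- log10(comparison$ac50s)
  ldose <- log10(comparison$doses)
  # degenerate-variance guard (standardize() signals the same condition)
  invisible(standardize(lac))
  invisible(standardize(ldose))
  ormse_from_r <- function(r) sqrt(pmax(0, (n - 1) / n * (1 - r)))
  ormse_untr <- ormse_from_r(stats::cor(lac, ldose))

  ki <- if (is.list(kappas) && !is.null(kappas$arr)) kappas else
    build_kappa_index(kappas)
  rows <- kappa_index_rows(ki, comparison$chemical_ids,
                           comparison$study_lengths)
  li <- (rows - 1L) %/% ki$n_chems # length index per record
  ci_perm <- match(comparison$chemical_ids, ki$chems)[plan$index]
  rows_rand <- matrix(ci_perm + li * ki$n_chems, nrow = n)

  lab_idx <- match(labels, ki$labels)
  if (anyNA(lab_idx)) stop("kappa table lacks assumption set(s): ",
                           paste(labels[is.na(lab_idx)], collapse = ", "),
                           call. = FALSE)
  n_sets <- plan$n_sets
  of <- matrix(NA_real_, n_sets + 1L, length(labels))
  orv <- matrix(NA_real_, n_sets + 1L, length(labels))
  for (j in seq_along(labels)) {
    lk <- ki$arr[rows, lab_idx[j]]
    lkr <- matrix(ki$arr[as.vector(rows_rand), lab_idx[j]], nrow = n)
    xf <- ldose + cbind(lk, lkr)  # forward: log10 C
    xr <- lac - cbind(lk, lkr)    # reverse: log10 AED
    of[, j] <- ormse_from_r(as.vector(stats::cor(lac, xf)))
    orv[, j] <- ormse_from_r(as.vector(stats::cor(ldose, xr)))
  }
  k <- n_sets + 2L
  data.frame(
    assay_endpoint = comparison$assay_endpoint,
    in_vivo_endpoint = comparison$in_vivo_endpoint,
    assumption_label = rep(labels, each = 2L * k),
    direction = rep(rep(c("forward", "reverse"), each = k), length(labels)),
    predictor = rep(c("pbtk", "untransformed", rep("random", n_sets)),
                    2L * length(labels)),
    set = rep(c(NA_integer_, NA_integer_, seq_len(n_sets)),
              2L * length(labels)),
    ormse = as.vector(vapply(seq_along(labels), function(j) {
      c(of[1, j], ormse_untr, of[-1, j], orv[1, j], ormse_untr, orv[-1, j])
    }, numeric(2L * k))),
    n = n, stringsAsFactors = FALSE)
}

#' Score one comparison under one assumption set
#'
#' Computes the ORMSE of the standardized log10 variables for the three
#' predictors. Forward dosimetry compares log10 AC50 against log10 of
#' the predicted concentration (PBTK and each random set) and against
#' log10 dose (untransformed); reverse dosimetry compares log10 dose
#' against log10 AED and against log10 AC50. The untransformed ORMSE is
#' identical in the two directions.
#'
#' @param comparison A `comparison_set`.
#' @param kappas Kappa table (see [kappa_table()]).
#' @param plan A `randomization_plan` for this comparison.
#' @param direction `"forward"` or `"reverse"`.
#' @param label Assumption-set label to evaluate.
#' @return data.frame of ORMSE records (predictor, set, ormse).
#' @export
evaluate_comparison <- function(comparison, kappas, plan,
                                direction = c("forward", "reverse"),
                                label) {
  direction <- match.arg(direction)
  rec <- evaluate_comparison_core(comparison, kappas, plan, label)
  out <- rec[rec$direction == direction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allocate a win among the three predictors
#'
#' The predictor with the strictly lowest ORMSE wins; exact ties break
#' by the fixed priority untransformed > random > pbtk (conservative
#' against the model under evaluation).
#'
#' @param ormse_pbtk,ormse_random,ormse_untransformed ORMSE values for
#'   one (comparison, random set, direction) contest.
#' @return `"pbtk"`, `"random"` or `"untransformed"`.
#' @export
allocate_wins <- function(ormse_pbtk, ormse_random, ormse_untransformed) {
  cand <- c(untransformed = ormse_untransformed, random = ormse_random,
            pbtk = ormse_pbtk)
  names(cand)[which.min(cand)]
}

# Long win table from an ORMSE record table: one row per
# (assumption label, direction, set) x predictor with the win count.
# Vectorized; the tie semantics are exactly those of allocate_wins
# (untransformed > random > pbtk on exact ties), cross-checked in the
# test suite.
count_wins <- function(ormse_records) {
  rec <- ormse_records
  contest <- paste(rec$assumption_label, rec$direction,
                   rec$assay_endpoint, rec$in_vivo_endpoint, sep = "\r")
  is_p <- rec$predictor == "pbtk"
  is_u <- rec$predictor == "untransformed"
  is_r <- rec$predictor == "random"
  keys <- sort(unique(contest))
  op <- rec$ormse[is_p][match(keys, contest[is_p])]
  ou <- rec$ormse[is_u][match(keys, contest[is_u])]
  sets <- sort(unique(rec$set[is_r]))
  rk <- paste(contest[is_r], rec$set[is_r], sep = "\r")
  orand <- vapply(sets, function(s) {
    rec$ormse[is_r][match(paste(keys, s, sep = "\r"), rk)]
  }, numeric(length(keys)))
  orand <- matrix(orand, nrow = length(keys))

  group <- sub("\r[^\r]*\r[^\r]*$", "", keys) # label \r direction
  glevels <- unique(group)
  out <- list()
  for (s in seq_along(sets)) {
    osr <- orand[, s]
    winner <- ifelse(ou <= pmin(osr, op), "untransformed",
                     ifelse(osr <= op, "random", "pbtk"))
    for (g in glevels) {
      in_g <- group == g
      parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
      for (pred in c("pbtk", "random", "untransformed")) {
        out[[length(out) + 1L]] <- data.frame(
          assumption_label = parts[1], direction = parts[2],
          set = sets[s], predictor = pred,
          wins = sum(winner[in_g] == pred),
          n_comparisons = sum(in_g), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$assumption_label, res$direction, res$set, res$predictor), ,
      drop = FALSE]
}

#' Aggregate win counts across the random evaluation sets
#'
#' Per (assumption label, direction, predictor): the median and standard
#' deviation of the counts across the random sets, and the fraction of
#' contested comparisons won (median count over the number of
#' comparisons).
#'
#' @param win_table Long win table from the pipeline (columns
#'   assumption_label, direction, set, predictor, wins, n_comparisons).
#' @return data.frame with median, sd and fraction columns.
#' @export
aggregate_counts <- function(win_table) {
  key <- interaction(win_table$assumption_label, win_table$direction,
                     win_table$predictor, drop = TRUE)
  out <- do.call(rbind, lapply(split(win_table, key), function(g) {
    data.frame(
      assumption_label = g$assumption_label[1],
      direction = g$direction[1],
      predictor = g$predictor[1],
      median_wins = stats::median(g$wins),
      sd_wins = stats::sd(g$wins),
      fraction = stats::median(g$wins / g$n_comparisons),
      n_comparisons = g$n_comparisons[1],
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$assumption_label, out$direction, out$predictor), ,
      drop = FALSE]
}

#' Lower-percentile POD vs AED comparison
#'
#' Per chemical, the empirical lower `q` quantile (linear interpolation
#' at rank 1 + (n-1) q) of the pooled in vivo POD values and of the AED
#' values; reports the per-chemical records, the RMSE of the log10
#' pairs, the ORMSE of the standardized log10 pairs, and the
#' conservatism rate (fraction of chemicals with AED10 <= POD10).
#'
#' @param pods data.frame with chemical_id and dose columns (pooled
#'   LOEL/LOAEL values, possibly several per chemical).
#' @param aeds data.frame with chemical_id and aed columns.
#' @param q Quantile (default 0.10).
#' @return List with `records` (chemical_id, pod10, aed10, residual),
#'   `rmse`, `ormse`, `conservatism`.
#' @export
pod10_aed10 <- function(pods, aeds, q = 0.10) {
  p10 <- vapply(split(pods$dose, pods$chemical_id),
                function(v) unname(stats::quantile(v, q, type = 7)),
                numeric(1))
  a10 <- vapply(split(aeds$aed, aeds$chemical_id),
                function(v) unname(stats::quantile(v, q, type = 7)),
                numeric(1))
  shared <- intersect(names(p10), names(a10))
  rec <- data.frame(chemical_id = shared, pod10 = p10[shared],
                    aed10 = a10[shared],
                    residual = log10(p10[shared]) - log10(a10[shared]),
                    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  rmse <- sqrt(mean(rec$residual^2))
  orm <- if (nrow(rec) >= 2 && stats::sd(log10(rec$pod10)) > 0 &&
             stats::sd(log10(rec$aed10)) > 0) {
    ormse(standardize(log10(rec$pod10)), standardize(log10(rec$aed10)))
  } else NA_real_
  list(records = rec, rmse = rmse, ormse = orm,
       conservatism = mean(rec$aed10 <= rec$pod10))
}

#' Correlation of extrapolation residuals with model input parameters
#'
#' Absolute Pearson correlation between the per-chemical residuals
#' (log10 POD10 - log10 AED10) and each of the model input parameters
#' fup, Clint, logP, logD and MW. High |COR| flags model bias with
#' respect to that parameter.
#'
#' @param records POD/AED records (from [pod10_aed10()]).
#' @param chems List of `chemical_record` objects or a
#'   [chem_param_frame()] data.frame.
#' @return data.frame with columns parameter, abs_cor, n.
#' @export
residual_param_correlations <- function(records, chems) {
  if (!is.data.frame(chems)) chems <- chem_param_frame(chems)
  m <- merge(records, chems, by.x = "chemical_id", by.y = "id")
  params <- c(fup = "fup", clint = "clint", logP = "logp", logD = "logd",
              MW = "mw")
  out <- do.call(rbind, lapply(names(params), function(pn) {
    v <- m[[params[[pn]]]]
    ok <- is.finite(v) & is.finite(m$residual)
    ac <- if (sum(ok) >= 3 && stats::sd(v[ok]) > 0 &&
              stats::sd(m$residual[ok]) > 0) {
      abs(stats::cor(m$residual[ok], v[ok]))
    } else NA_real_
    data.frame(parameter = pn, abs_cor = ac, n = sum(ok),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Median log10 variance summary across comparisons
#'
#' Medians, across comparison sets, of the variance of the log10 AC50
#' vector and of the log10 dose vector.
#'
#' @param comparisons List of `comparison_set` objects.
#' @return data.frame with median_var_log_ac50 and median_var_log_dose.
#' @export
variance_summary <- function(comparisons) {
  va <- vapply(comparisons, function(cc) stats::var(log10(cc$ac50s)),
               numeric(1))
  vd <- vapply(comparisons, function(cc) stats::var(log10(cc$doses)),
               numeric(1))
  data.frame(median_var_log_ac50 = stats::median(va),
             median_var_log_dose = stats::median(vd),
             n_comparisons = length(comparisons))
}
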