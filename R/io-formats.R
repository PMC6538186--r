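# Column alias maps so supplementary-style CSVs drop in without editing.
.chem_aliases <- list(
  id = c("id", "chemical_id", "casrn", "cas", "dtxsid"),
  name = c("name", "chemical_name", "preferred_name", "compound"),
  mw = c("mw", "molecular_weight", "mol_weight"),
  logp = c("logp", "log_p", "logkow"),
  pka_donor = c("pka_donor", "pka_accept_donor", "pka_acid"),
  pka_acceptor = c("pka_acceptor", "pka_base"),
  fup = c("fup", "funbound_plasma", "fu"),
  fup_below_lod = c("fup_below_lod", "fup_lod", "below_lod"),
  clint_1 = c("clint_1", "clint_1um", "clint1"),
  clint_10 = c("clint_10", "clint_10um", "clint10"),
  logwsol = c("logwsol", "log_water_sol", "logsw"),
  loghenry = c("loghenry", "log_henry", "loghl")
)

match_column <- function(df, aliases, required = TRUE, field = aliases[1]) {
  hit <- intersect(aliases, tolower(names(df)))
  if (length(hit) == 0) {
    if (required) stop("missing required column for '", field,
                       "' (accepted: ", paste(aliases, collapse = ", "), ")",
                       call. = FALSE)
    return(NULL)
  }
  names(df)[match(hit[1], tolower(names(df)))]
}

parse_pka_list <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || s == "") return(numeric())
    as.numeric(strsplit(s, "[;|]")[[1]])
  })
}

#' Read a chemical-parameter CSV
#'
#' Parses the chemical TK/physchem schema (identifier, name, MW, logP,
#' semicolon-separated pKa lists, fup with below-LOD flag, Clint at 1
#' and 10 uM, water solubility, Henry constant). Measurement-handling
#' rules (fup LOD default, Clint selection, logD derivation) are applied
#' via the `chemical_record` constructor.
#'
#' @param path CSV path.
#' @return List of `chemical_record` objects (empty list for an empty
#'   file).
#' @export
read_chem_params <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(list())
  col <- function(f, required = TRUE) {
    match_column(df, .chem_aliases[[f]], required = required, field = f)
  }
  num <- function(cn) if (is.null(cn)) rep(NA_real_, nrow(df)) else {
    suppressWarnings(as.numeric(df[[cn]]))
  }
  ids <- df[[col("id")]]
  mws <- num(col("mw"))
  logps <- num(col("logp"))
  bad <- which(is.na(mws) | is.na(logps))
  if (length(bad)) {
    stop("unparseable numeric mw/logp at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  name_c <- col("name", required = FALSE)
  don <- parse_pka_list(if (is.null(col("pka_donor", FALSE))) rep("", nrow(df))
                        else df[[col("pka_donor", FALSE)]])
  acc <- parse_pka_list(if (is.null(col("pka_acceptor", FALSE))) rep("", nrow(df))
                        else df[[col("pka_acceptor", FALSE)]])
  fups <- num(col("fup", required = FALSE))
  lod_c <- col("fup_below_lod", required = FALSE)
  lods <- if (is.null(lod_c)) is.na(fups) else {
    as.logical(df[[lod_c]]) | is.na(fups)
  }
  c1 <- num(col("clint_1", required = FALSE))
  c10 <- num(col("clint_10", required = FALSE))
  ws <- num(col("logwsol", required = FALSE))
  hl <- num(col("loghenry", required = FALSE))
  lapply(seq_len(nrow(df)), function(i) {
    chemical_record(
      id = ids[i],
      name = if (is.null(name_c)) ids[i] else df[[name_c]][i],
      mw = mws[i], logp = logps[i],
      pka_donor = don[[i]], pka_acceptor = acc[[i]],
      fup = fups[i], fup_below_lod = lods[i],
      clint_1 = c1[i], clint_10 = c10[i],
      logwsol = ws[i], loghenry = hl[i]
    )
  })
}

#' Read an in vitro AC50 table
#'
#' @param path CSV with columns chemical_id, assay_endpoint, ac50
#'   (uM), hit_call (logical), flags (semicolon-separated curve-fit
#'   flags, empty when clean).
#' @return data.frame of assay hits (unfiltered).
#' @export
read_ac50 <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(flags = "character"))
  need <- c("chemical_id", "assay_endpoint", "ac50", "hit_call")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("AC50 table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"flags" %in% names(df)) df$flags <- ""
  df$flags[is.na(df$flags)] <- ""
  df$hit_call <- as.logical(df$hit_call)
  df
}

#' Filter bioactivity hits to clean positives
#'
#' Keeps only rows with a positive hit call and no curve-fitting flags;
#' the analysis is restricted to positive in vitro results. Idempotent.
#'
#' @param hits data.frame with `hit_call` and `flags` columns.
#' @return Filtered data.frame; positive rows have ac50 > 0.
#' @export
filter_ac50 <- function(hits) {
  keep <- hits$hit_call & (is.na(hits$flags) | trimws(hits$flags) == "")
  out <- hits[keep, , drop = FALSE]
  if (any(out$ac50 <= 0)) stop("positive hit with non-positive AC50",
                               call. = FALSE)
  rownames(out) <- NULL
  out
}

.study_type_lengths <- c(chronic = 730L, subchronic = 90L,
                         developmental = 21L, subacute = 28L)

normalize_duration_days <- function(value, unit) {
  mult <- c(day = 1, days = 1, week = 7, weeks = 7, month = 30.4,
            months = 30.4, year = 365, years = 365)
  m <- mult[tolower(unit)]
  out <- value * unname(m)
  out[is.na(m)] <- NA_real_
  out
}

#' Derive endpoint-level doses from raw study rows
#'
#' An in vivo endpoint is each unique combination of study type,
#' effect category, effect type and effect target. Per (study, chemical,
#' endpoint) the lowest dose at which the response was observed is kept;
#' multigenerational studies are excluded; records from multiple studies
#' of the same chemical/endpoint are retained separately (both sexes and
#' all strains are used upstream). Output order is canonical, so the
#' result is invariant to input row order and the operation is
#' idempotent.
#'
#' @param records data.frame with columns chemical_id, study_id,
#'   study_type (chronic, subchronic, developmental; multigenerational
#'   rows dropped), effect_category, effect_type, effect_target, dose
#'   (mg/kg/day), optional study_length (days; defaulted from the study
#'   type when absent).
#' @return data.frame, one row per (study, chemical, endpoint) with the
#'   minimum dose.
#' @export
derive_endpoint_doses <- function(records) {
  keep_types <- c("chronic", "subchronic", "developmental")
  records <- records[records$study_type %in% keep_types, , drop = FALSE]
  records <- records[records$dose > 0, , drop = FALSE]
  if (nrow(records) == 0) return(records)
  if (!"study_length" %in% names(records)) records$study_length <- NA_real_
  records$study_length[is.na(records$study_length)] <-
    .study_type_lengths[records$study_type[is.na(records$study_length)]]
  key <- interaction(records$study_id, records$chemical_id,
                     records$study_type, records$effect_category,
                     records$effect_type, records$effect_target, drop = TRUE)
  idx <- unsplit(lapply(split(seq_len(nrow(records)), key), function(i) {
    rep(i[which.min(records$dose[i])], length(i))
  }), key)
  out <- unique(records[idx, , drop = FALSE])
  out <- out[order(out$chemical_id, out$study_id, out$study_type,
                   out$effect_category, out$effect_type, out$effect_target), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter POD-level records to usable entries
#'
#' Keeps rat oral records with dose units of mg/kg/day, a usable study
#' duration, study type subacute/subchronic/chronic, and non-zero dose.
#'
#' @param records data.frame with columns chemical_id, pod_type
#'   (LOEL/LOAEL), dose, dose_units, study_type, route, duration_days.
#' @return Filtered data.frame.
#' @export
filter_pod_records <- function(records) {
  keep <- records$dose > 0 &
    !is.na(records$dose) &
    tolower(records$route) == "oral" &
    records$study_type %in% c("subacute", "subchronic", "chronic") &
    !is.na(records$duration_days)
  if ("dose_units" %in% names(records)) {
    keep <- keep & records$dose_units == "mg/kg/day"
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive per-chemical points of departure
#'
#' After filtering (see [filter_pod_records()]), the minimum dose over
#' the pooled LOEL and LOAEL values per chemical is the POD; the study
#' duration accompanying that minimum record is retained as the time
#' scale for dosimetry.
#'
#' @param records Raw POD-level data.frame.
#' @return data.frame with columns chemical_id, pod (mg/kg/day),
#'   study_length (days), n_records.
#' @export
derive_pod <- function(records) {
  records <- filter_pod_records(records)
  if (nrow(records) == 0) {
    return(data.frame(chemical_id = character(), pod = numeric(),
                      study_length = numeric(), n_records = integer(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(records)), records$chemical_id)
  out <- do.call(rbind, lapply(sp, function(i) {
    j <- i[which.min(records$dose[i])]
    data.frame(chemical_id = records$chemical_id[j],
               pod = records$dose[j],
               study_length = records$duration_days[j],
               n_records = length(i), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chemical_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write result tables as CSVs
#'
#' Deterministic column order, round-trip readable at full double
#' precision (15 significant digits).
#'
#' @param tables Named list of data.frames.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    # write.csv serializes doubles at 15 significant digits
    utils::write.csv(tables[[nm]], p, row.names = FALSE, quote = TRUE)
    p
  }, character(1))
  invisible(paths)
}
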