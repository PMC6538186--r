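.ivive_cache <- new.env(parent = emptyenv())

read_config_yaml <- function(name) {
  key <- paste0("config_", name)
  if (!is.null(.ivive_cache[[key]])) return(.ivive_cache[[key]])
  path <- system.file("config", name, package = "ivive")
  if (path == "") {
    # during development (pkgload), inst/ may be on the path directly
    path <- file.path("inst", "config", name)
  }
  cfg <- yaml::read_yaml(path)
  .ivive_cache[[key]] <- cfg
  cfg
}

#' Rat physiology for the PBTK model
#'
#' Loads the default rat physiological constants (plasma flows, tissue
#' volumes, glomerular filtration rate, hepatocellularity, oral
#' absorption rate) from the package configuration and applies any
#' overrides. Flows are plasma flows in L/h/kg body weight; volumes in
#' L/kg.
#'
#' @param ... Named overrides of the top-level config entries, e.g.
#'   `gfr = 0.25` or `k_gutabs = 1`.
#' @param config_path Optional path to an alternative YAML file with the
#'   same structure.
#' @return An object of class `rat_physiology`.
#' @export
rat_physiology <- function(..., config_path = NULL) {
  cfg <- if (is.null(config_path)) {
    read_config_yaml("rat_physiology.yaml")
  } else {
    yaml::read_yaml(config_path)
  }
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) stop("unknown physiology field: ", nm, call. = FALSE)
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  phys <- structure(cfg, class = "rat_physiology")
  validate_physiology(phys)
  phys
}

validate_physiology <- function(phys) {
  q <- phys$plasma_flows
  v <- phys$tissue_volumes
  vals <- c(unlist(q), unlist(v), unlist(phys$plasma_volume),
            phys$gfr, phys$hepatocellularity, phys$liver_mass_frac,
            phys$k_gutabs, phys$body_weight)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all physiological volumes and flows must be strictly positive",
         call. = FALSE)
  }
  qsum <- q$gut + q$liver + q$kidney + q$rest
  if (abs(qsum - q$cardiac_output) > 1e-6 * q$cardiac_output) {
    stop("tissue plasma flows (", qsum, ") must sum to cardiac output (",
         q$cardiac_output, ")", call. = FALSE)
  }
  invisible(phys)
}

#' @export
print.rat_physiology <- function(x, ...) {
  cat(sprintf(
    "<rat_physiology> BW %.2f kg, cardiac plasma flow %.2f L/h/kg, GFR %.3f L/h/kg, ka %.1f /h\n",
    x$body_weight, x$plasma_flows$cardiac_output, x$gfr, x$k_gutabs
  ))
  invisible(x)
}

#' Tissue composition table for partition-coefficient estimation
#'
#' @param config_path Optional alternative YAML file.
#' @return Named list of tissues, each a list with `water`,
#'   `neutral_lipid`, `phospholipid`, `protein` volume fractions.
#' @export
tissue_composition <- function(config_path = NULL) {
  if (is.null(config_path)) {
    read_config_yaml("tissue_composition.yaml")
  } else {
    yaml::read_yaml(config_path)
  }
}
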