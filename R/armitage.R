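#' Assay well specification for the in vitro disposition model
#'
#' Describes the physical composition of one assay well: medium with a
#' serum fraction (lipid and protein content), cells (storage lipid,
#' membrane lipid, protein, water), headspace, and plastic surface.
#' Geometry defaults are keyed by plate footprint from the shipped
#' vendor-specification table; composition defaults are averages of
#' reported serum and cell contents.
#'
#' @param well_format Plate footprint: 96, 384 or 1536.
#' @param media_volume Medium volume (uL); default from the geometry
#'   table.
#' @param well_area Plastic contact area (mm^2).
#' @param headspace_volume Headspace (uL); default total well volume
#'   minus medium.
#' @param cell_count Number of cells in the well (0 for cell-free).
#' @param fbs_fraction Serum volume fraction of the medium.
#' @param ... Overrides of the remaining composition fields
#'   (`serum_lipid_frac`, `serum_protein_frac`, `cell_storage_lipid_frac`,
#'   `cell_membrane_lipid_frac`, `cell_protein_frac`, `cell_water_frac`,
#'   `cell_volume_per_cell`).
#' @return An object of class `assay_well`.
#' @export
assay_well <- function(well_format = 384, media_volume = NULL,
                       well_area = NULL, headspace_volume = NULL,
                       cell_count = NULL, fbs_fraction = NULL, ...) {
  cfg <- read_config_yaml("assay_wells.yaml")
  geo <- cfg$geometry[[as.character(well_format)]]
  if (is.null(geo)) {
    stop("unknown well format: ", well_format, call. = FALSE)
  }
  w <- list(
    well_format = as.integer(well_format),
    media_volume = media_volume %||% geo$media_volume,
    well_area = well_area %||% geo$well_area,
    cell_count = cell_count %||% cfg$cell_count,
    fbs_fraction = fbs_fraction %||% cfg$fbs_fraction,
    serum_lipid_frac = cfg$serum_lipid_frac,
    serum_protein_frac = cfg$serum_protein_frac,
    cell_storage_lipid_frac = cfg$cell_storage_lipid_frac,
    cell_membrane_lipid_frac = cfg$cell_membrane_lipid_frac,
    cell_protein_frac = cfg$cell_protein_frac,
    cell_water_frac = cfg$cell_water_frac,
    cell_volume_per_cell = cfg$cell_volume_per_cell
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(w)) stop("unknown assay_well field: ", nm, call. = FALSE)
    w[[nm]] <- dots[[nm]]
  }
  w$headspace_volume <- headspace_volume %||%
    max(0, geo$total_volume - w$media_volume)
  w$cell_volume <- w$cell_count * w$cell_volume_per_cell * 1e-6 # uL total
  cell_fracs <- w$cell_storage_lipid_frac + w$cell_membrane_lipid_frac +
    w$cell_protein_frac + w$cell_water_frac
  if (any(unlist(w[c("media_volume", "headspace_volume", "cell_volume",
                     "well_area")]) < 0) || cell_fracs > 1 + 1e-9) {
    stop("invalid assay well specification", call. = FALSE)
  }
  structure(w, class = "assay_well")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Equilibrium chemical distribution in an assay well
#'
#' Solves the linear (non-saturable) equilibrium mass balance for the
#' dosed amount over the well phases: aqueous medium, serum lipid,
#' serum protein, cell storage lipid, cell membrane lipid, cell protein,
#' headspace and plastic. The free aqueous concentration is
#' C_aq = N_total / (V_aq + sum_i V_i K_i), with phase partition
#' coefficients from configurable QSPRs: storage lipid 10^logP, membrane
#' lipid a membrane-water relation, serum/cell protein albumin-type
#' binding, headspace the dimensionless Henry constant, and plastic an
#' area-based relation. Only the neutral species leaves the aqueous
#' phase (config switch). The `factor` is C_aq divided by the nominal
#' concentration (total amount over medium volume) and is
#' scale-invariant in the dosed amount.
#'
#' @param chemical A `chemical_record`.
#' @param well An `assay_well`.
#' @param nominal Nominal concentration (uM), > 0.
#' @return An object of class `in_vitro_distribution`: phase masses
#'   (pmol), `c_aqueous` and `c_nominal` (uM), and `factor`.
#' @export
distribute_in_vitro <- function(chemical, well, nominal) {
  stopifnot(nominal > 0)
  rel <- read_config_yaml("assay_wells.yaml")$relations
  fn <- if (isTRUE(rel$ions_partition)) 1 else
    neutral_fraction(chemical$pka_donor, chemical$pka_acceptor, ph = 7.4)
  logp <- chemical$logp

  k_storage <- fn * 10^(rel$storage_lipid$a * logp + rel$storage_lipid$b)
  k_membrane <- fn * 10^(rel$membrane_lipid$a * logp + rel$membrane_lipid$b)
  k_serum_prot <- fn * 10^(rel$serum_protein$a * logp + rel$serum_protein$b)
  k_cell_prot <- rel$cell_protein_scale * k_serum_prot

  if (well$headspace_volume > 0 && is.na(chemical$loghenry)) {
    warning("missing Henry constant for ", chemical$id,
            "; treating chemical as nonvolatile", call. = FALSE)
    k_air <- 0
  } else if (well$headspace_volume > 0) {
    # H (atm m^3/mol) -> dimensionless air:water ratio H / (R T)
    k_air <- fn * 10^chemical$loghenry / (8.2057e-5 * rel$temperature_K)
  } else {
    k_air <- 0
  }

  v_serum <- well$media_volume * well$fbs_fraction
  v <- c(
    serum_lipid = v_serum * well$serum_lipid_frac,
    serum_protein = v_serum * well$serum_protein_frac,
    cell_storage_lipid = well$cell_volume * well$cell_storage_lipid_frac,
    cell_membrane_lipid = well$cell_volume * well$cell_membrane_lipid_frac,
    cell_protein = well$cell_volume * well$cell_protein_frac,
    headspace = well$headspace_volume
  )
  k <- c(
    serum_lipid = k_storage,
    serum_protein = k_serum_prot,
    cell_storage_lipid = k_storage,
    cell_membrane_lipid = k_membrane,
    cell_protein = k_cell_prot,
    headspace = k_air
  )
  # aqueous = medium minus serum sorbing material, plus cell water
  v_aq <- well$media_volume - v[["serum_lipid"]] - v[["serum_protein"]] +
    well$cell_volume * well$cell_water_frac
  # plastic: equivalent sorbing volume from an area-based coefficient
  # (log10 K in m); mm^2 * m -> uL via 1e-6 m^3/mm^2/m * 1e9 uL/m^3
  v_plastic_eq <- fn * 10^(rel$plastic$a * logp + rel$plastic$b) *
    well$well_area * 1e3

  n_total <- nominal * well$media_volume # pmol (uM * uL)
  denom <- v_aq + sum(v * k) + v_plastic_eq
  c_aq <- n_total / denom
  masses <- c(aqueous = c_aq * v_aq, c_aq * v * k, plastic = c_aq * v_plastic_eq)
  structure(
    list(masses = masses, c_aqueous = c_aq, c_nominal = nominal,
         factor = c_aq / nominal, total = n_total),
    class = "in_vitro_distribution"
  )
}

#' @export
print.in_vitro_distribution <- function(x, ...) {
  cat(sprintf(
    "<in_vitro_distribution> nominal %.3g uM -> aqueous %.3g uM (factor %.3g)\n",
    x$c_nominal, x$c_aqueous, x$factor
  ))
  invisible(x)
}

#' Adjust a concentration-to-dose ratio for in vitro disposition
#'
#' When the free aqueous concentration in the assay well is taken as
#' bioactive, the PBTK concentration-to-dose ratio is divided by the
#' well distribution factor (aqueous / nominal), giving an
#' assumption-set-specific ratio.
#'
#' @param kappa Concentration-to-dose ratio, uM per mg/kg/day.
#' @param factor Distribution factor, > 0.
#' @return Adjusted ratio.
#' @export
adjust_kappa <- function(kappa, factor) {
  if (!is.numeric(factor) || any(factor <= 0)) {
    stop("distribution factor must be > 0", call. = FALSE)
  }
  kappa / factor
}
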