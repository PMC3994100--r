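#' Food-alga descriptor
#'
#' Bundles the measurements needed to dose an algal food by carbon content:
#' mean cell diameter (cells are treated as spheres), growth form (diatoms
#' carry less carbon per unit biovolume than other algae), the current stock
#' culture density, and optionally the source isotope signatures used by the
#' mixing model.
#'
#' @param name Species label.
#' @param diameter_um Mean cell diameter, micrometres. Must be positive.
#' @param growth_form `"diatom"` or `"non_diatom"`; selects the
#'   carbon-biovolume regression.
#' @param stock_density_cells_per_ml Stock culture density, cells per mL.
#'   Must be positive.
#' @param diameter_sd_um Optional SD of the diameter measurements, micrometres.
#' @param delta13C_source,delta15N_source Optional source isotope signatures,
#'   permil vs PDB (carbon) and air N2 (nitrogen).
#'
#' @return An object of class `"algal_species"` (a named list).
#' @examples
#' chlorella <- algal_species("C. vulgaris", 3.84, "non_diatom", 4333.3)
#' @export
algal_species <- function(name, diameter_um, growth_form,
                          stock_density_cells_per_ml,
                          diameter_sd_um = NA_real_,
                          delta13C_source = NA_real_,
                          delta15N_source = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  growth_form <- match.arg(growth_form, c("diatom", "non_diatom"))
  if (!is.numeric(diameter_um) || length(diameter_um) != 1L || diameter_um <= 0)
    stop("'diameter_um' must be a single positive number", call. = FALSE)
  if (!is.numeric(stock_density_cells_per_ml) ||
      length(stock_density_cells_per_ml) != 1L ||
      stock_density_cells_per_ml <= 0)
    stop("'stock_density_cells_per_ml' must be a single positive number",
         call. = FALSE)
  structure(
    list(name = name,
         diameter_um = diameter_um,
         diameter_sd_um = diameter_sd_um,
         growth_form = growth_form,
         stock_density_cells_per_ml = stock_density_cells_per_ml,
         delta13C_source = delta13C_source,
         delta15N_source = delta15N_source),
    class = "algal_species"
  )
}

#' @export
print.algal_species <- function(x, ...) {
  cat(sprintf("<algal_species> %s (%s)\n", x$name, x$growth_form))
  cat(sprintf("  diameter: %.2f um   stock density: %.1f cells/mL\n",
              x$diameter_um, x$stock_density_cells_per_ml))
  if (!is.na(x$delta13C_source) || !is.na(x$delta15N_source))
    cat(sprintf("  source d13C: %s permil   d15N: %s permil\n",
                format(x$delta13C_source), format(x$delta15N_source)))
  invisible(x)
}

#' Carbon-biovolume regression constants
#'
#' Log-log regression of cellular carbon (pg) on biovolume (um^3):
#' `log10 C = intercept + slope * log10 V`. The defaults are the classical
#' literature constants, with a separate fit for diatoms whose vacuole-rich
#' cells carry less carbon per unit volume: non-diatoms
#' `log10 C = 0.866 log10 V - 0.460`, diatoms `log10 C = 0.758 log10 V - 0.422`.
#' Both are configuration, not constants of the method — substitute your own
#' fit if you have one for your strains.
#'
#' @param growth_form `"diatom"` or `"non_diatom"`.
#' @param intercept_log10_pg,slope_log10 Override the default constants.
#' @return An object of class `"carbon_regression"`.
#' @examples
#' carbon_regression("diatom")
#' @export
carbon_regression <- function(growth_form = c("non_diatom", "diatom"),
                              intercept_log10_pg = NULL, slope_log10 = NULL) {
  growth_form <- match.arg(growth_form)
  defaults <- list(non_diatom = c(intercept = -0.460, slope = 0.866),
                   diatom     = c(intercept = -0.422, slope = 0.758))
  d <- defaults[[growth_form]]
  intercept <- if (is.null(intercept_log10_pg)) d[["intercept"]] else intercept_log10_pg
  slope <- if (is.null(slope_log10)) d[["slope"]] else slope_log10
  if (slope <= 0) stop("'slope_log10' must be positive", call. = FALSE)
  structure(list(intercept_log10_pg = intercept, slope_log10 = slope,
                 applicable_form = growth_form),
            class = "carbon_regression")
}

#' Spherical cell biovolume
#'
#' @param diameter_um Cell diameter, micrometres (non-negative).
#' @return Biovolume `(pi/6) d^3`, cubic micrometres.
#' @examples
#' sphere_volume(3.84)
#' @export
sphere_volume <- function(diameter_um) {
  if (any(!is.finite(diameter_um)) || any(diameter_um < 0))
    stop("'diameter_um' must be finite and non-negative", call. = FALSE)
  (pi / 6) * diameter_um^3
}

#' Carbon content of a single cell
#'
#' Evaluates the log-log carbon-biovolume regression at a given biovolume.
#'
#' @param biovolume_um3 Cell biovolume, cubic micrometres (positive).
#' @param regression A [carbon_regression()] object.
#' @return Carbon per cell, picograms.
#' @examples
#' carbon_per_cell(sphere_volume(4.03), carbon_regression("diatom"))
#' @export
carbon_per_cell <- function(biovolume_um3, regression) {
  stopifnot(inherits(regression, "carbon_regression"))
  if (any(!is.finite(biovolume_um3)) || any(biovolume_um3 <= 0))
    stop("'biovolume_um3' must be finite and positive", call. = FALSE)
  10^(regression$intercept_log10_pg +
        regression$slope_log10 * log10(biovolume_um3))
}

#' Cells needed to reach a target carbon concentration
#'
#' @param target_mgC_per_L Target carbon concentration, mg C per litre.
#' @param medium_volume_L Medium volume, litres.
#' @param carbon_pg_per_cell Carbon per cell, picograms (positive).
#' @return Required cell number (real; round only at reporting).
#' @examples
#' cells_for_target(2.5, 0.5, 6.5)
#' @export
cells_for_target <- function(target_mgC_per_L, medium_volume_L,
                             carbon_pg_per_cell) {
  if (!is.finite(carbon_pg_per_cell) || carbon_pg_per_cell <= 0)
    stop("'carbon_pg_per_cell' must be positive", call. = FALSE)
  if (target_mgC_per_L < 0 || medium_volume_L < 0)
    stop("target and medium volume must be non-negative", call. = FALSE)
  # 1 mg = 1e9 pg
  target_mgC_per_L * medium_volume_L * 1e9 / carbon_pg_per_cell
}

#' Stock injection volume for a cell dose
#'
#' @param cells_required Cell number to deliver (non-negative).
#' @param stock_density_cells_per_ml Stock density, cells per mL (positive).
#' @return Injection volume in mL, rounded to 0.01 mL.
#' @examples
#' injection_volume(8802, 687) # 12.81
#' @export
injection_volume <- function(cells_required, stock_density_cells_per_ml) {
  if (!is.finite(stock_density_cells_per_ml) || stock_density_cells_per_ml <= 0)
    stop("'stock_density_cells_per_ml' must be positive", call. = FALSE)
  if (any(cells_required < 0))
    stop("'cells_required' must be non-negative", call. = FALSE)
  round(cells_required / stock_density_cells_per_ml, 2)
}

#' Daily carbon dose plan
#'
#' Allocates a target carbon concentration across one or more algal foods and
#' works out, per species, the carbon per cell, the daily cell dose, and the
#' stock injection volume. In a two-species mixture at equal carbon the
#' fractions are (0.5, 0.5), i.e. each food supplied at half the target.
#'
#' @param species List of [algal_species()] objects (a single object is
#'   accepted).
#' @param carbon_fractions Numeric vector, one entry per species, summing to 1:
#'   the fraction of the carbon target carried by each species.
#' @param target_mgC_per_L Target carbon concentration, mg C per litre
#'   (default 2.5).
#' @param medium_volume_L Medium volume per beaker, litres (default 0.5).
#' @param regressions Optional list of [carbon_regression()] objects, one per
#'   species; defaults to each species' growth-form default.
#' @return An object of class `"carbon_dose_plan"`: the targets plus a
#'   `per_species` data frame with columns `species`, `carbon_fraction`,
#'   `carbon_pg_per_cell`, `cells_required`, `injection_volume_mL`.
#' @examples
#' ste <- algal_species("S. hantzschii", 4.03, "diatom", 687.3)
#' build_dose_plan(list(ste), 1)
#' @export
build_dose_plan <- function(species, carbon_fractions,
                            target_mgC_per_L = 2.5, medium_volume_L = 0.5,
                            regressions = NULL) {
  if (inherits(species, "algal_species")) species <- list(species)
  stopifnot(length(species) >= 1L,
            all(vapply(species, inherits, logical(1), "algal_species")))
  if (length(carbon_fractions) != length(species))
    stop("one carbon fraction per species is required", call. = FALSE)
  if (any(carbon_fractions < 0))
    stop("carbon fractions must be non-negative", call. = FALSE)
  if (abs(sum(carbon_fractions) - 1) > 1e-9)
    stop("carbon fractions must sum to 1", call. = FALSE)
  if (is.null(regressions))
    regressions <- lapply(species, function(s) carbon_regression(s$growth_form))
  stopifnot(length(regressions) == length(species))

  rows <- lapply(seq_along(species), function(i) {
    sp <- species[[i]]
    pg <- carbon_per_cell(sphere_volume(sp$diameter_um), regressions[[i]])
    cells <- cells_for_target(carbon_fractions[i] * target_mgC_per_L,
                              medium_volume_L, pg)
    data.frame(species = sp$name,
               carbon_fraction = carbon_fractions[i],
               carbon_pg_per_cell = pg,
               cells_required = cells,
               injection_volume_mL =
                 injection_volume(cells, sp$stock_density_cells_per_ml),
               stringsAsFactors = FALSE)
  })
  structure(
    list(target_mgC_per_L = target_mgC_per_L,
         medium_volume_L = medium_volume_L,
         per_species = do.call(rbind, rows)),
    class = "carbon_dose_plan"
  )
}

#' @export
print.carbon_dose_plan <- function(x, ...) {
  cat(sprintf("<carbon_dose_plan> %.2f mg C/L in %.2f L\n",
              x$target_mgC_per_L, x$medium_volume_L))
  df <- x$per_species
  df$cells_required <- round(df$cells_required) # report whole cells, half-up
  print(df, row.names = FALSE)
  invisible(x)
}

#' Total planned carbon of a dose plan
#'
#' Sums `cells_required * carbon_pg_per_cell` across species; by construction
#' this equals `target * volume * 1e9` pg before any rounding of cell counts.
#'
#' @param plan A [build_dose_plan()] result.
#' @return Planned carbon, picograms.
#' @export
plan_total_carbon_pg <- function(plan) {
  stopifnot(inherits(plan, "carbon_dose_plan"))
  sum(plan$per_species$cells_required * plan$per_species$carbon_pg_per_cell)
}
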