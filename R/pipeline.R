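#' Run configuration for the full analysis pipeline
#'
#' A run either simulates a dataset from a [generator_config()] or ingests
#' CSV tables from a directory (exactly one of the two). The dosing, mixing
#' and statistics settings travel with the run so a report is regenerable
#' from (config, seed) alone.
#'
#' @param simulate `TRUE` to generate data with `generator` (default), or
#'   `FALSE` to read tables from `input_dir`.
#' @param generator A [generator_config()]; its seed is overridden by `seed`.
#' @param input_dir Directory holding `individuals.csv`, `beakers.csv`,
#'   `guts.csv`, `isotope_samples.csv` when `simulate = FALSE`.
#' @param seed Integer master seed for the run.
#' @param species List of [algal_species()] used for dose planning; defaults
#'   to the two foods of the experiment the package emulates (a 3.84 um
#'   green alga at 4333.3 cells/mL and a 4.03 um diatom at 687.3 cells/mL).
#' @param target_mgC_per_L,medium_volume_L Dosing targets (defaults 2.5 and
#'   0.5).
#' @param fractionations_permil Trophic fractionation values for the mixing
#'   stage (default `c(3.4, 2.4)`); must be non-empty.
#' @param n_boot Bootstrap replicates for mixing uncertainty (default 2000).
#' @param tukey_aggregate `"individual"` or `"beaker_mean"` error unit for
#'   Tukey tests on body length.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(simulate = TRUE, generator = generator_config(),
                       input_dir = NULL, seed = 1L,
                       species = default_species(),
                       target_mgC_per_L = 2.5, medium_volume_L = 0.5,
                       fractionations_permil = c(3.4, 2.4), n_boot = 2000,
                       tukey_aggregate = c("individual", "beaker_mean")) {
  if (simulate && !is.null(input_dir))
    stop("choose exactly one input mode: simulate or input_dir", call. = FALSE)
  if (!simulate && is.null(input_dir))
    stop("'input_dir' is required when simulate = FALSE", call. = FALSE)
  if (length(fractionations_permil) == 0L)
    stop("at least one fractionation value is required", call. = FALSE)
  generator$seed <- as.integer(seed)
  structure(
    list(simulate = simulate, generator = generator, input_dir = input_dir,
         seed = as.integer(seed), species = species,
         target_mgC_per_L = target_mgC_per_L,
         medium_volume_L = medium_volume_L,
         fractionations_permil = fractionations_permil, n_boot = n_boot,
         tukey_aggregate = match.arg(tukey_aggregate)),
    class = "run_config")
}

#' Default food-species descriptors
#'
#' The two foods of the emulated experiment, with measured diameters and
#' mean stock densities, and the generator's placeholder source signatures.
#'
#' @return List of two [algal_species()].
#' @export
default_species <- function() {
  list(
    algal_species("C. vulgaris", diameter_um = 3.84, growth_form = "non_diatom",
                  stock_density_cells_per_ml = 4333.3, diameter_sd_um = 0.6,
                  delta13C_source = -30, delta15N_source = 5.0),
    algal_species("S. hantzschii", diameter_um = 4.03, growth_form = "diatom",
                  stock_density_cells_per_ml = 687.3, diameter_sd_um = 0.4,
                  delta13C_source = -18, delta15N_source = 6.0))
}

table_schemas <- function() {
  list(
    individuals = c("individual_id", "treatment", "beaker_id", "role",
                    "body_length_mm"),
    beakers = c("treatment", "beaker_id", "n_adults", "total_offspring",
                "offspring_per_adult"),
    guts = c("individual_id", "treatment", "cells_C_vulgaris",
             "cells_S_hantzschii"),
    isotope_samples = c("sample_id", "group", "isotope", "delta_permil",
                        "lipid_extracted"))
}

#' Write an experiment dataset as a CSV bundle
#'
#' @param dataset An `"experiment_dataset"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (four CSVs and `provenance.json`
#'   written as plain JSON text).
#' @export
write_experiment_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "experiment_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(table_schemas())) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(dataset[[nm]], p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  prov <- file.path(dir, "provenance.json")
  writeLines(sprintf('{"seed": %d, "config_hash": "%s"}',
                     dataset$provenance$seed, dataset$provenance$config_hash),
             prov)
  invisible(c(paths, prov))
}

#' Read an experiment dataset from a CSV bundle
#'
#' @param dir Directory holding the four tables written by
#'   [write_experiment_csv()].
#' @return An `"experiment_dataset"` (provenance taken from
#'   `provenance.json` when present).
#' @export
read_experiment_csv <- function(dir) {
  tabs <- list()
  for (nm in names(table_schemas())) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    tabs[[nm]] <- utils::read.csv(p, stringsAsFactors = FALSE)
  }
  prov <- list(seed = NA_integer_, config_hash = NA_character_)
  pj <- file.path(dir, "provenance.json")
  if (file.exists(pj)) {
    txt <- paste(readLines(pj, warn = FALSE), collapse = "")
    m <- regmatches(txt, regexec('"seed": *([0-9]+).*"config_hash": *"([^"]*)"',
                                 txt))[[1]]
    if (length(m) == 3L)
      prov <- list(seed = as.integer(m[2]), config_hash = m[3])
  }
  structure(c(tabs, list(provenance = prov)), class = "experiment_dataset")
}

#' Validate experiment input tables
#'
#' Schema and referential-integrity checks on the four experiment tables:
#' required columns, known treatment labels and enumerations, positive body
#' lengths, non-negative counts, the offspring-per-adult quotient, beakers
#' referenced by individuals, and gut records referencing existing adult
#' individuals.
#'
#' @param dataset An `"experiment_dataset"` (or a directory path, which is
#'   read first).
#' @return A data frame of violations (`table`, `row`, `column`, `message`);
#'   zero rows means the dataset passes.
#' @export
validate_input_tables <- function(dataset) {
  if (is.character(dataset)) dataset <- read_experiment_csv(dataset)
  stopifnot(inherits(dataset, "experiment_dataset") || is.list(dataset))
  v <- list()
  flag <- function(table, row, column, message)
    v[[length(v) + 1L]] <<- data.frame(table = table, row = row,
                                       column = column, message = message,
                                       stringsAsFactors = FALSE)
  schemas <- table_schemas()
  for (nm in names(schemas)) {
    tab <- dataset[[nm]]
    if (is.null(tab)) { flag(nm, NA, NA, "table missing"); next }
    for (col in setdiff(schemas[[nm]], names(tab)))
      flag(nm, NA, col, "required column missing")
  }
  treatments <- c("CHL", "STE", "MIX")
  ind <- dataset$individuals
  if (!is.null(ind) && all(schemas$individuals %in% names(ind))) {
    for (i in which(!ind$treatment %in% treatments))
      flag("individuals", i, "treatment",
           paste0("unknown treatment label '", ind$treatment[i], "'"))
    for (i in which(!ind$role %in% c("adult", "offspring")))
      flag("individuals", i, "role", "role must be adult or offspring")
    for (i in which(!is.finite(ind$body_length_mm) | ind$body_length_mm <= 0))
      flag("individuals", i, "body_length_mm",
           "body length must be positive")
    if (anyDuplicated(ind$individual_id))
      flag("individuals", anyDuplicated(ind$individual_id), "individual_id",
           "duplicated individual_id")
  }
  bk <- dataset$beakers
  if (!is.null(bk) && all(schemas$beakers %in% names(bk))) {
    for (i in which(!bk$treatment %in% treatments))
      flag("beakers", i, "treatment",
           paste0("unknown treatment label '", bk$treatment[i], "'"))
    for (i in which(bk$n_adults <= 0))
      flag("beakers", i, "n_adults", "n_adults must be positive")
    for (i in which(bk$total_offspring < 0))
      flag("beakers", i, "total_offspring", "negative offspring count")
    ok <- bk$n_adults > 0
    off <- which(ok & abs(bk$offspring_per_adult -
                            bk$total_offspring / bk$n_adults) > 1e-8)
    for (i in off)
      flag("beakers", i, "offspring_per_adult",
           "offspring_per_adult != total_offspring / n_adults")
    if (!is.null(ind) && all(c("treatment", "beaker_id") %in% names(ind))) {
      ind_key <- unique(paste(ind$treatment, ind$beaker_id))
      bk_key <- paste(bk$treatment, bk$beaker_id)
      for (k in setdiff(ind_key, bk_key)) {
        i <- which(paste(ind$treatment, ind$beaker_id) == k)[1]
        flag("individuals", i, "beaker_id",
             paste0("beaker '", k, "' has no beaker record"))
      }
    }
  }
  gt <- dataset$guts
  if (!is.null(gt) && all(schemas$guts %in% names(gt))) {
    for (i in which(gt$cells_C_vulgaris < 0 | gt$cells_S_hantzschii < 0))
      flag("guts", i, "cells", "negative cell count")
    if (!is.null(ind) && "individual_id" %in% names(ind)) {
      for (i in which(!gt$individual_id %in% ind$individual_id))
        flag("guts", i, "individual_id",
             paste0("references nonexistent individual '",
                    gt$individual_id[i], "'"))
    }
  }
  iso <- dataset$isotope_samples
  if (!is.null(iso) && all(schemas$isotope_samples %in% names(iso))) {
    groups <- c(treatments, "source_C_vulgaris", "source_S_hantzschii")
    for (i in which(!iso$group %in% groups))
      flag("isotope_samples", i, "group",
           paste0("unknown group '", iso$group[i], "'"))
    for (i in which(!iso$isotope %in% c("13C", "15N")))
      flag("isotope_samples", i, "isotope", "isotope must be 13C or 15N")
    for (i in which(!is.finite(iso$delta_permil)))
      flag("isotope_samples", i, "delta_permil", "non-finite delta value")
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(table = character(0), row = integer(0), column = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

#' Run the full feeding-experiment analysis
#'
#' Executes the stages in order — dose planning, data simulation or CSV
#' ingestion (with validation), growth statistics (nested ANOVA on adult and
#' offspring length, one-way ANOVA plus Tukey on offspring per adult, Tukey
#' on lengths, pooled t-test on MIX gut contents), and isotope mixing at each
#' configured fractionation — and collects everything into a report that is
#' fully determined by (config, seed).
#'
#' @param config A [run_config()].
#' @return An object of class `"run_report"` with elements `dose_plan`,
#'   `dataset`, `endpoint_stats` (data frame: endpoint, test, statistic, df,
#'   p, significant), `pairwise` (Tukey rows per endpoint), `mixing`
#'   (contribution table) and `provenance`.
#' @examples
#' rep <- run_pipeline(run_config(seed = 1, n_boot = 200))
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  # stage 1: dosing (equal carbon split across the configured foods)
  nsp <- length(config$species)
  plan <- build_dose_plan(config$species, rep(1 / nsp, nsp),
                          config$target_mgC_per_L, config$medium_volume_L)

  # stage 2: data
  dataset <- if (config$simulate) generate_experiment(config$generator)
             else read_experiment_csv(config$input_dir)
  viol <- validate_input_tables(dataset)
  if (nrow(viol) > 0L)
    stop("input validation failed at stage 'data': ",
         nrow(viol), " violation(s); first: [", viol$table[1], " row ",
         viol$row[1], " ", viol$column[1], "] ", viol$message[1],
         call. = FALSE)

  # stage 3: growth statistics
  adults <- dataset$individuals[dataset$individuals$role == "adult", ]
  offspring <- dataset$individuals[dataset$individuals$role == "offspring", ]
  stats_rows <- list()
  pairwise_rows <- list()
  add_stat <- function(endpoint, test, statistic, df, p) {
    stats_rows[[length(stats_rows) + 1L]] <<- data.frame(
      endpoint = endpoint, test = test, statistic = statistic, df = df,
      p = p, significant = is.finite(p) & p < 0.05, stringsAsFactors = FALSE)
  }
  add_pairs <- function(endpoint, tk) {
    tk$endpoint <- endpoint
    pairwise_rows[[length(pairwise_rows) + 1L]] <<-
      tk[, c("endpoint", "comparison", "diff", "statistic", "p_adjusted",
             "significant")]
  }
  for (role_df in list(list(name = "adult_length_mm", d = adults),
                       list(name = "offspring_length_mm", d = offspring))) {
    na <- nested_anova(role_df$d, "body_length_mm", "treatment", "beaker_id")
    add_stat(role_df$name, "nested_anova_treatment", na$f_treatment,
             sprintf("%d, %d", na$df_treatment, na$df_beaker), na$p_treatment)
    add_stat(role_df$name, "nested_anova_beaker", na$f_beaker,
             sprintf("%d, %d", na$df_beaker, na$df_residual), na$p_beaker)
    add_pairs(role_df$name,
              tukey_hsd(role_df$d$body_length_mm, role_df$d$treatment,
                        aggregate = config$tukey_aggregate,
                        beaker = role_df$d$beaker_id))
  }
  ow <- one_way_anova(dataset$beakers$offspring_per_adult,
                      dataset$beakers$treatment)
  add_stat("offspring_per_adult", "one_way_anova", ow$f,
           sprintf("%d, %d", ow$df_between, ow$df_within), ow$p)
  add_pairs("offspring_per_adult",
            tukey_hsd(dataset$beakers$offspring_per_adult,
                      dataset$beakers$treatment))
  mix_guts <- dataset$guts[dataset$guts$treatment == "MIX", ]
  if (nrow(mix_guts) >= 2L) {
    tt <- t_test_raw(mix_guts$cells_C_vulgaris, mix_guts$cells_S_hantzschii)
    add_stat("gut_cells_CHL_vs_STE", "t_test_pooled", tt$statistic,
             as.character(tt$df), tt$p)
  }

  # stage 4: isotope mixing (seeded from the run seed)
  mixing <- contribution_report(
    dataset$isotope_samples,
    source_X_group = "source_S_hantzschii",
    source_Y_group = "source_C_vulgaris",
    fractionations_permil = config$fractionations_permil,
    n_boot = config$n_boot, seed = config$seed)

  structure(
    list(dose_plan = plan, dataset = dataset,
         endpoint_stats = do.call(rbind, stats_rows),
         pairwise = do.call(rbind, pairwise_rows),
         mixing = mixing,
         provenance = list(seed = config$seed,
                           config_hash = rlang::hash(unclass(config)),
                           package_version =
                             as.character(utils::packageVersion("daphniafeed")))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$provenance$seed, "\n\n")
  print(x$dose_plan)
  cat("\nEndpoint statistics:\n")
  print(x$endpoint_stats, row.names = FALSE, digits = 4)
  cat("\nDietary contributions (source X = S. hantzschii):\n")
  print(x$mixing, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a run report as a CSV bundle plus text summary
#'
#' Emits `dose_plan.csv`, `endpoint_stats.csv`, `pairwise.csv`, `mixing.csv`,
#' the four dataset tables, and `summary.txt` (the printed report). Output
#' contains no timestamps or machine-dependent values, so two runs with the
#' same (config, seed) produce byte-identical bundles.
#'
#' @param report A `"run_report"`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$dose_plan$per_species,
                   file.path(dir, "dose_plan.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(report$endpoint_stats,
                   file.path(dir, "endpoint_stats.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(report$pairwise, file.path(dir, "pairwise.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$mixing, file.path(dir, "mixing.csv"),
                   row.names = FALSE, quote = FALSE)
  write_experiment_csv(report$dataset, file.path(dir, "data"))
  con <- file(file.path(dir, "summary.txt"), open = "w")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(dir)
}
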