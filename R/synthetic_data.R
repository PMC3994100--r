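#' Configuration for the synthetic feeding experiment
#'
#' Parameters of the seeded generator that emulates a three-treatment algal
#' feeding experiment: single-species diets of a green alga (CHL) and a
#' diatom (STE), and a 50/50-by-carbon mixture (MIX), with replicate beakers
#' nested in treatments and several adults per beaker. Body lengths are
#' normal with a shared beaker-level random effect; per-beaker fecundity is
#' normal truncated at zero; MIX foregut contents split binomially by the
#' *ingestion* proportion; consumer isotope signatures are
#' fractionation-shifted mixtures of the source signatures under the
#' *assimilation* proportion. Ingestion and assimilation are independent
#' knobs — a consumer can ingest the two foods 50/50 yet assimilate them
#' 92/8 — which is exactly the contrast the analysis is built to detect.
#'
#' Source X is the diatom (*S. hantzschii*), source Y the green alga
#' (*C. vulgaris*) throughout.
#'
#' @param seed Integer master seed; spawns independent per-table substreams.
#' @param n_beakers_per_treatment Beakers per treatment (default 10).
#' @param n_adults_per_beaker Adults per beaker (default 5).
#' @param n_offspring_measured_per_beaker Offspring measured for length per
#'   beaker (default 2).
#' @param n_gut_individuals_per_beaker Adults per beaker whose foregut is
#'   enumerated (default 2).
#' @param n_isotope_replicates Replicate isotope samples per group and
#'   isotope (default 3).
#' @param treatment_params Named list (CHL, STE, MIX), each a list with
#'   `adult_mean_mm`, `adult_sd_mm`, `offspring_mean_mm`, `offspring_sd_mm`,
#'   `offspring_per_adult_mean`, `offspring_per_adult_sd`. Defaults are the
#'   endpoint means/SDs of the experiment the generator emulates.
#' @param beaker_sd_mm SD of the beaker-level random effect on length, mm
#'   (default 0.03).
#' @param gut_total_cells_mean,gut_total_cells_sd Total foregut cell count
#'   distribution (default 4096 +/- 500).
#' @param ingestion_prop_X Proportion of ingested cells that are source X in
#'   the MIX diet (default 0.5).
#' @param assimilation_prop_X Proportion of assimilated (tissue-incorporated)
#'   carbon from source X in the MIX diet (default 0.92).
#' @param source_deltas Named list (`S_hantzschii`, `C_vulgaris`) of
#'   `c(d13C = , d15N = )` source signatures, permil. Defaults are
#'   well-separated placeholders (-18 vs -30 permil d13C).
#' @param fractionation_permil Carbon trophic fractionation used by the
#'   generator, permil (default 2.4).
#' @param fractionation_n_permil Nitrogen trophic fractionation, permil
#'   (default 3.4).
#' @param delta_noise_sd Analytical noise SD on delta values, permil
#'   (default 0.1).
#' @return An object of class `"generator_config"` (a validated named list).
#' @examples
#' cfg <- generator_config(seed = 42)
#' @export
generator_config <- function(
    seed = 1L,
    n_beakers_per_treatment = 10L,
    n_adults_per_beaker = 5L,
    n_offspring_measured_per_beaker = 2L,
    n_gut_individuals_per_beaker = 2L,
    n_isotope_replicates = 3L,
    treatment_params = list(
      CHL = list(adult_mean_mm = 2.78, adult_sd_mm = 0.07,
                 offspring_mean_mm = 1.08, offspring_sd_mm = 0.06,
                 offspring_per_adult_mean = 11.4, offspring_per_adult_sd = 1.8),
      STE = list(adult_mean_mm = 3.18, adult_sd_mm = 0.05,
                 offspring_mean_mm = 1.14, offspring_sd_mm = 0.05,
                 offspring_per_adult_mean = 26.2, offspring_per_adult_sd = 1.8),
      MIX = list(adult_mean_mm = 2.99, adult_sd_mm = 0.07,
                 offspring_mean_mm = 1.08, offspring_sd_mm = 0.07,
                 offspring_per_adult_mean = 18.5, offspring_per_adult_sd = 2.67)),
    beaker_sd_mm = 0.03,
    gut_total_cells_mean = 4096,
    gut_total_cells_sd = 500,
    ingestion_prop_X = 0.5,
    assimilation_prop_X = 0.92,
    source_deltas = list(S_hantzschii = c(d13C = -18, d15N = 6.0),
                         C_vulgaris = c(d13C = -30, d15N = 5.0)),
    fractionation_permil = 2.4,
    fractionation_n_permil = 3.4,
    delta_noise_sd = 0.1) {
  cfg <- structure(
    list(seed = as.integer(seed),
         n_beakers_per_treatment = as.integer(n_beakers_per_treatment),
         n_adults_per_beaker = as.integer(n_adults_per_beaker),
         n_offspring_measured_per_beaker =
           as.integer(n_offspring_measured_per_beaker),
         n_gut_individuals_per_beaker =
           as.integer(n_gut_individuals_per_beaker),
         n_isotope_replicates = as.integer(n_isotope_replicates),
         treatment_params = treatment_params,
         beaker_sd_mm = beaker_sd_mm,
         gut_total_cells_mean = gut_total_cells_mean,
         gut_total_cells_sd = gut_total_cells_sd,
         ingestion_prop_X = ingestion_prop_X,
         assimilation_prop_X = assimilation_prop_X,
         source_deltas = source_deltas,
         fractionation_permil = fractionation_permil,
         fractionation_n_permil = fractionation_n_permil,
         delta_noise_sd = delta_noise_sd),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!inherits(cfg, "generator_config"))
    stop("not a generator_config", call. = FALSE)
  counts <- c(cfg$n_beakers_per_treatment, cfg$n_adults_per_beaker,
              cfg$n_offspring_measured_per_beaker,
              cfg$n_gut_individuals_per_beaker, cfg$n_isotope_replicates)
  if (any(!is.finite(counts)) || any(counts < 1L))
    stop("design counts must be positive integers", call. = FALSE)
  if (cfg$n_gut_individuals_per_beaker > cfg$n_adults_per_beaker)
    stop("cannot enumerate more guts than adults per beaker", call. = FALSE)
  props <- c(cfg$ingestion_prop_X, cfg$assimilation_prop_X)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  sds <- c(cfg$beaker_sd_mm, cfg$gut_total_cells_sd, cfg$delta_noise_sd,
           unlist(lapply(cfg$treatment_params, function(p)
             c(p$adult_sd_mm, p$offspring_sd_mm, p$offspring_per_adult_sd))))
  if (any(sds < 0)) stop("SDs must be non-negative", call. = FALSE)
  needed <- c("adult_mean_mm", "adult_sd_mm", "offspring_mean_mm",
              "offspring_sd_mm", "offspring_per_adult_mean",
              "offspring_per_adult_sd")
  for (trt in names(cfg$treatment_params)) {
    p <- cfg$treatment_params[[trt]]
    if (!all(needed %in% names(p)))
      stop("treatment '", trt, "' lacks parameter(s): ",
           paste(setdiff(needed, names(p)), collapse = ", "), call. = FALSE)
    if (p$adult_mean_mm <= 0 || p$offspring_mean_mm <= 0)
      stop("length means must be positive (treatment '", trt, "')",
           call. = FALSE)
    if (p$offspring_per_adult_mean < 0)
      stop("offspring_per_adult_mean must be non-negative (treatment '",
           trt, "')", call. = FALSE)
  }
  if (!all(c("S_hantzschii", "C_vulgaris") %in% names(cfg$source_deltas)))
    stop("source_deltas must name S_hantzschii and C_vulgaris", call. = FALSE)
  invisible(TRUE)
}

# Out-of-range draws are resampled, not clipped, so accepted-region means
# stay closer to the configured means than clipping would.

# strictly positive lengths
rnorm_positive <- function(n, mean, sd) {
  if (sd == 0) {
    if (mean <= 0) stop("degenerate non-positive length draw", call. = FALSE)
    return(rep(mean, n))
  }
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
    if (guard > 10000L)
      stop("resampling failed to produce positive lengths", call. = FALSE)
  }
  x
}

# non-negative (closed at 0) real draws for fecundity
rnorm_nonneg <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
    guard <- guard + 1L
    if (guard > 10000L)
      stop("resampling failed to produce non-negative draws", call. = FALSE)
  }
  x
}

with_seed <- function(seed, code) {
  old <- .Random.seed_exists()
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate individual body lengths
#'
#' Adult and offspring body lengths per treatment and beaker:
#' `length = treatment mean + beaker effect + individual noise`, with the
#' beaker effect drawn once per (beaker, role) from `Normal(0, beaker_sd_mm)`
#' and non-positive lengths resampled.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for this table.
#' @return Data frame of individuals: `individual_id`, `treatment`,
#'   `beaker_id`, `role` (`"adult"`/`"offspring"`), `body_length_mm`.
#' @export
generate_sizes <- function(config, seed = config$seed) {
  validate_generator_config(config)
  with_seed(seed, {
    rows <- list()
    for (trt in names(config$treatment_params)) {
      p <- config$treatment_params[[trt]]
      for (b in seq_len(config$n_beakers_per_treatment)) {
        eff_a <- stats::rnorm(1, 0, config$beaker_sd_mm)
        eff_o <- stats::rnorm(1, 0, config$beaker_sd_mm)
        na <- config$n_adults_per_beaker
        no <- config$n_offspring_measured_per_beaker
        la <- rnorm_positive(na, p$adult_mean_mm + eff_a, p$adult_sd_mm)
        lo <- rnorm_positive(no, p$offspring_mean_mm + eff_o, p$offspring_sd_mm)
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = c(sprintf("%s_b%02d_a%d", trt, b, seq_len(na)),
                            sprintf("%s_b%02d_o%d", trt, b, seq_len(no))),
          treatment = trt,
          beaker_id = b,
          role = c(rep("adult", na), rep("offspring", no)),
          body_length_mm = c(la, lo),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate per-beaker offspring counts
#'
#' Per-beaker offspring-per-adult drawn from a zero-truncated normal at the
#' treatment's beaker-level mean/SD; total offspring is the per-adult value
#' times the number of adults, rounded to a whole count, and
#' `offspring_per_adult` is recomputed from the rounded total so the stored
#' quotient is exact.
#'
#' @inheritParams generate_sizes
#' @return Data frame of beakers: `treatment`, `beaker_id`, `n_adults`,
#'   `total_offspring`, `offspring_per_adult`.
#' @export
generate_offspring_counts <- function(config, seed = config$seed) {
  validate_generator_config(config)
  with_seed(seed, {
    rows <- list()
    for (trt in names(config$treatment_params)) {
      p <- config$treatment_params[[trt]]
      nb <- config$n_beakers_per_treatment
      opa <- rnorm_nonneg(nb, p$offspring_per_adult_mean,
                          p$offspring_per_adult_sd)
      total <- round(opa * config$n_adults_per_beaker)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = trt, beaker_id = seq_len(nb),
        n_adults = config$n_adults_per_beaker,
        total_offspring = as.integer(total),
        offspring_per_adult =
          offspring_per_adult(total, config$n_adults_per_beaker),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Generate foregut cell counts
#'
#' For each enumerated adult, a total foregut count drawn around
#' `gut_total_cells_mean` (negative draws resampled, then rounded). MIX guts
#' split binomially with probability `ingestion_prop_X` of a cell being the
#' diatom; single-diet treatments contain only their own food.
#'
#' @inheritParams generate_sizes
#' @return Data frame of gut records: `individual_id`, `treatment`,
#'   `cells_C_vulgaris`, `cells_S_hantzschii`.
#' @export
generate_gut_contents <- function(config, seed = config$seed) {
  validate_generator_config(config)
  with_seed(seed, {
    rows <- list()
    for (trt in names(config$treatment_params)) {
      for (b in seq_len(config$n_beakers_per_treatment)) {
        ng <- config$n_gut_individuals_per_beaker
        total <- round(rnorm_nonneg(ng, config$gut_total_cells_mean,
                                    config$gut_total_cells_sd))
        cells_x <- switch(trt,
          STE = total,
          CHL = rep(0, ng),
          stats::rbinom(ng, size = total, prob = config$ingestion_prop_X))
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = sprintf("%s_b%02d_a%d", trt, b, seq_len(ng)),
          treatment = trt,
          cells_C_vulgaris = as.integer(total - cells_x),
          cells_S_hantzschii = as.integer(cells_x),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate isotope samples
#'
#' Source samples are the configured signatures plus analytical noise.
#' Consumer signatures are fractionation-shifted mixtures of the source
#' signatures under the *assimilation* proportion: MIX uses
#' `assimilation_prop_X`, STE assimilates only the diatom (f = 1), CHL only
#' the green alga (f = 0). Consumer carbon samples carry the
#' `lipid_extracted` flag.
#'
#' @inheritParams generate_sizes
#' @return Data frame of samples: `sample_id`, `group` (CHL/STE/MIX/
#'   `source_C_vulgaris`/`source_S_hantzschii`), `isotope` (`"13C"`/`"15N"`),
#'   `delta_permil`, `lipid_extracted`.
#' @export
generate_isotopes <- function(config, seed = config$seed) {
  validate_generator_config(config)
  dX <- config$source_deltas$S_hantzschii
  dY <- config$source_deltas$C_vulgaris
  if (dX[["d13C"]] == dY[["d13C"]])
    stop("source d13C values are identical: mixing would be unidentifiable",
         call. = FALSE)
  nrep <- config$n_isotope_replicates
  noise <- function(n) stats::rnorm(n, 0, config$delta_noise_sd)
  with_seed(seed, {
    rows <- list()
    add <- function(group, isotope, mu, lipid) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sprintf("%s_%s_r%d", group, isotope, seq_len(nrep)),
        group = group, isotope = isotope,
        delta_permil = mu + noise(nrep),
        lipid_extracted = lipid, stringsAsFactors = FALSE)
    }
    add("source_S_hantzschii", "13C", dX[["d13C"]], FALSE)
    add("source_S_hantzschii", "15N", dX[["d15N"]], FALSE)
    add("source_C_vulgaris", "13C", dY[["d13C"]], FALSE)
    add("source_C_vulgaris", "15N", dY[["d15N"]], FALSE)
    f_by_trt <- c(CHL = 0, STE = 1, MIX = config$assimilation_prop_X)
    for (trt in names(config$treatment_params)) {
      f <- if (trt %in% names(f_by_trt)) f_by_trt[[trt]] else
        config$assimilation_prop_X
      mu_c <- f * dX[["d13C"]] + (1 - f) * dY[["d13C"]] +
        config$fractionation_permil
      mu_n <- f * dX[["d15N"]] + (1 - f) * dY[["d15N"]] +
        config$fractionation_n_permil
      add(trt, "13C", mu_c, TRUE)
      add(trt, "15N", mu_n, FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Generate a complete synthetic feeding experiment
#'
#' Composes the size, fecundity, gut-content and isotope generators under one
#' master seed. The master seed spawns an independent substream per table, so
#' adding or regenerating one table never perturbs the others.
#'
#' @param config A [generator_config()].
#' @return An object of class `"experiment_dataset"`: data frames
#'   `individuals`, `beakers`, `guts`, `isotope_samples`, plus `provenance`
#'   (seed and config hash).
#' @examples
#' ds <- generate_experiment(generator_config(seed = 7))
#' nrow(ds$individuals[ds$individuals$role == "adult", ]) # 150
#' @export
generate_experiment <- function(config) {
  validate_generator_config(config)
  subseeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, 4L))
  structure(
    list(individuals = generate_sizes(config, subseeds[1]),
         beakers = generate_offspring_counts(config, subseeds[2]),
         guts = generate_gut_contents(config, subseeds[3]),
         isotope_samples = generate_isotopes(config, subseeds[4]),
         provenance = list(seed = config$seed,
                           config_hash = rlang::hash(unclass(config)))),
    class = "experiment_dataset")
}

#' @export
print.experiment_dataset <- function(x, ...) {
  cat("<experiment_dataset>\n")
  cat(sprintf("  individuals: %d (%d adults)  beakers: %d  guts: %d  isotope samples: %d\n",
              nrow(x$individuals), sum(x$individuals$role == "adult"),
              nrow(x$beakers), nrow(x$guts), nrow(x$isotope_samples)))
  cat(sprintf("  seed: %d  config: %s\n", x$provenance$seed,
              x$provenance$config_hash))
  invisible(x)
}
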