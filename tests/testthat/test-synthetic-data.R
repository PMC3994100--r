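test_that("generator config validates its design and parameters", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(n_beakers_per_treatment = 0), "positive")
  expect_error(generator_config(ingestion_prop_X = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(delta_noise_sd = -0.1), "non-negative")
  expect_error(generator_config(n_gut_individuals_per_beaker = 9,
                                n_adults_per_beaker = 5), "guts")
})

test_that("degenerate noise collapses sizes onto the treatment means", {
  cfg <- zero_noise_config()
  ind <- generate_sizes(cfg, 1)
  for (trt in c("CHL", "STE", "MIX")) {
    p <- cfg$treatment_params[[trt]]
    a <- ind$body_length_mm[ind$treatment == trt & ind$role == "adult"]
    o <- ind$body_length_mm[ind$treatment == trt & ind$role == "offspring"]
    expect_true(all(a == p$adult_mean_mm))
    expect_true(all(o == p$offspring_mean_mm))
  }
})

test_that("size generation is seed-reproducible and calibrated", {
  cfg <- generator_config(seed = 10)
  expect_identical(generate_sizes(cfg, 10), generate_sizes(cfg, 10))
  expect_false(identical(generate_sizes(cfg, 10), generate_sizes(cfg, 11)))

  # sample means track configured means: adult length SE per treatment is
  # sqrt(beaker_sd^2/n_beakers + sd^2/n); check 4 SE over repeated seeds
  miss <- 0L; reps <- 60L
  for (s in seq_len(reps)) {
    ind <- generate_sizes(cfg, 1000 + s)
    for (trt in c("CHL", "STE", "MIX")) {
      p <- cfg$treatment_params[[trt]]
      a <- ind$body_length_mm[ind$treatment == trt & ind$role == "adult"]
      se <- sqrt(cfg$beaker_sd_mm^2 / 10 + p$adult_sd_mm^2 / length(a))
      if (abs(mean(a) - p$adult_mean_mm) > 4 * se) miss <- miss + 1L
    }
  }
  expect_lte(miss, 2L) # ~0.006% expected miss rate at 4 SE; allow slack
})

test_that("offspring counts honour the truncated-normal beaker model", {
  cfg <- zero_noise_config()
  bk <- generate_offspring_counts(cfg, 1)
  expect_true(all(bk$total_offspring[bk$treatment == "CHL"] == 57))
  expect_true(all(bk$offspring_per_adult ==
                    bk$total_offspring / bk$n_adults))

  cfg0 <- zero_noise_config()
  cfg0$treatment_params$CHL$offspring_per_adult_mean <- 0
  bk0 <- generate_offspring_counts(cfg0, 1)
  expect_true(all(bk0$total_offspring[bk0$treatment == "CHL"] == 0))

  cfg2 <- generator_config(seed = 2)
  grand <- replicate(40, {
    bk <- generate_offspring_counts(cfg2, sample.int(1e6, 1))
    mean(bk$offspring_per_adult[bk$treatment == "STE"])
  })
  se <- 1.8 / sqrt(10)
  expect_lt(abs(mean(grand) - 26.2), 4 * se / sqrt(40) + 0.1)
})

test_that("gut contents split by ingestion, not assimilation", {
  cfg <- generator_config(seed = 4, ingestion_prop_X = 1)
  gt <- generate_gut_contents(cfg, 4)
  expect_true(all(gt$cells_C_vulgaris[gt$treatment == "MIX"] == 0))
  expect_true(all(gt$cells_S_hantzschii[gt$treatment == "CHL"] == 0))
  expect_true(all(gt$cells_C_vulgaris[gt$treatment == "STE"] == 0))
  expect_identical(generate_gut_contents(cfg, 4), generate_gut_contents(cfg, 4))

  # 50/50 ingestion: per-species means agree in expectation
  cfg5 <- generator_config(seed = 5, ingestion_prop_X = 0.5)
  diffs <- replicate(200, {
    gt <- generate_gut_contents(cfg5, sample.int(1e6, 1))
    m <- gt[gt$treatment == "MIX", ]
    mean(m$cells_S_hantzschii) - mean(m$cells_C_vulgaris)
  })
  expect_lt(abs(mean(diffs)), 0.05 * cfg5$gut_total_cells_mean)

  # decoupling: changing assimilation leaves gut draws untouched
  cfg_a <- generator_config(seed = 6, assimilation_prop_X = 0.92)
  cfg_b <- generator_config(seed = 6, assimilation_prop_X = 0.10)
  expect_identical(generate_gut_contents(cfg_a, 6),
                   generate_gut_contents(cfg_b, 6))
})

test_that("isotope samples encode assimilation through the mixing model", {
  cfg <- zero_noise_config(assimilation = 0.92, fractionation = 2.4)
  iso <- generate_isotopes(cfg, 1)
  rep <- contribution_report(iso, "source_S_hantzschii", "source_C_vulgaris",
                             fractionations_permil = 2.4, n_boot = 10,
                             seed = 1)
  mix <- rep[rep$group == "MIX", ]
  expect_equal(mix$f_X, 0.92, tolerance = 1e-12)
  expect_equal(mix$pct_X, 92); expect_equal(mix$pct_Y, 8)
  ste <- rep[rep$group == "STE", ]
  expect_equal(ste$f_X, 1)
  chl <- rep[rep$group == "CHL", ]
  expect_equal(chl$f_X, 0)

  # pure-X consumer sits exactly one fractionation above its source
  cfg1 <- zero_noise_config(assimilation = 1)
  iso1 <- generate_isotopes(cfg1, 1)
  ste13 <- iso1$delta_permil[iso1$group == "STE" & iso1$isotope == "13C"]
  expect_true(all(ste13 == -18 + 2.4))

  expect_identical(generate_isotopes(cfg, 8), generate_isotopes(cfg, 8))
  cfg_bad <- generator_config(
    source_deltas = list(S_hantzschii = c(d13C = -25, d15N = 6),
                         C_vulgaris = c(d13C = -25, d15N = 5)))
  expect_error(generate_isotopes(cfg_bad, 1), "identical")
})

test_that("the composed experiment has the design's structural counts", {
  ds <- generate_experiment(generator_config(seed = 12))
  expect_equal(sum(ds$individuals$role == "adult"), 150) # 3 x 10 x 5
  expect_equal(nrow(ds$beakers), 30)
  expect_equal(sum(ds$individuals$role == "offspring"), 60)
  expect_equal(nrow(ds$guts), 60)
  expect_true(all(ds$guts$individual_id %in% ds$individuals$individual_id))
  expect_equal(ds$provenance$seed, 12L)

  ds2 <- generate_experiment(generator_config(seed = 12))
  expect_identical(ds$individuals, ds2$individuals)
  expect_identical(ds$isotope_samples, ds2$isotope_samples)
  ds3 <- generate_experiment(generator_config(seed = 13))
  expect_false(identical(ds$individuals, ds3$individuals))
})

test_that("CSV round trip is byte-identical for identical config and seed", {
  cfg <- generator_config(seed = 77)
  d1 <- file.path(tempdir(), "gen_a"); d2 <- file.path(tempdir(), "gen_b")
  write_experiment_csv(generate_experiment(cfg), d1)
  write_experiment_csv(generate_experiment(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  }
  back <- read_experiment_csv(d1)
  expect_equal(back$beakers, generate_experiment(cfg)$beakers)
  unlink(c(d1, d2), recursive = TRUE)
})
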