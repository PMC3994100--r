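# Independent oracles used to cross-check the package's closed-form and
# model-fit computations. These deliberately share no code with R/.

# Grid search over f in [0, 1] minimizing |dM - (f dX + (1-f) dY + frac)|.
grid_search_mixing <- function(delta_mixture, delta_source_X, delta_source_Y,
                               fractionation, step = 1e-6) {
  f <- seq(0, 1, by = step)
  pred <- f * delta_source_X + (1 - f) * delta_source_Y + fractionation
  f[which.min(abs(delta_mixture - pred))]
}

# Brute-force sequential SS for the nested design, from explicit group means.
brute_force_nested_ss <- function(y, trt, bkr) {
  trt <- as.character(trt)
  cell <- paste(trt, as.character(bkr), sep = ":")
  grand <- mean(y)
  ss_trt <- 0
  for (t in unique(trt)) {
    yt <- y[trt == t]
    ss_trt <- ss_trt + length(yt) * (mean(yt) - grand)^2
  }
  ss_bkr <- 0
  ss_res <- 0
  for (t in unique(trt)) {
    yt <- y[trt == t]
    ct <- cell[trt == t]
    for (cc in unique(ct)) {
      yc <- yt[ct == cc]
      ss_bkr <- ss_bkr + length(yc) * (mean(yc) - mean(yt))^2
      ss_res <- ss_res + sum((yc - mean(yc))^2)
    }
  }
  list(treatment = ss_trt, beaker_within = ss_bkr, residual = ss_res,
       total = sum((y - grand)^2))
}

brute_force_oneway_ss <- function(y, g) {
  g <- as.character(g)
  grand <- mean(y)
  ss_b <- 0; ss_w <- 0
  for (gg in unique(g)) {
    yg <- y[g == gg]
    ss_b <- ss_b + length(yg) * (mean(yg) - grand)^2
    ss_w <- ss_w + sum((yg - mean(yg))^2)
  }
  list(between = ss_b, within = ss_w)
}

# Random small nested design (balanced or unbalanced) for property tests.
random_nested_design <- function(seed, unbalanced = FALSE) {
  set.seed(seed)
  n_trt <- sample(2:4, 1)
  rows <- list()
  for (t in seq_len(n_trt)) {
    n_bkr <- sample(2:4, 1)
    mu_t <- rnorm(1, 10, 2)
    for (b in seq_len(n_bkr)) {
      n_obs <- if (unbalanced) sample(2:5, 1) else 3L
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = paste0("T", t), beaker_id = b,
        y = round(mu_t + rnorm(1, 0, 1) + rnorm(n_obs, 0, 1), 3))
    }
  }
  do.call(rbind, rows)
}

# Zero-noise generator config: every random component degenerate.
zero_noise_config <- function(seed = 1L, assimilation = 0.92,
                              fractionation = 2.4) {
  cfg <- generator_config(seed = seed,
                          assimilation_prop_X = assimilation,
                          fractionation_permil = fractionation,
                          delta_noise_sd = 0, beaker_sd_mm = 0,
                          gut_total_cells_sd = 0)
  for (t in names(cfg$treatment_params)) {
    cfg$treatment_params[[t]]$adult_sd_mm <- 0
    cfg$treatment_params[[t]]$offspring_sd_mm <- 0
    cfg$treatment_params[[t]]$offspring_per_adult_sd <- 0
  }
  cfg
}
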