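test_that("nested ANOVA matches the brute-force SS oracle on random designs", {
  for (seed in 1:8) {
    d <- random_nested_design(seed, unbalanced = seed %% 2 == 0)
    res <- nested_anova(d, "y", "treatment", "beaker_id")
    bf <- brute_force_nested_ss(d$y, d$treatment, d$beaker_id)
    expect_equal(res$ss_treatment, bf$treatment, tolerance = 1e-8)
    expect_equal(res$ss_beaker_within, bf$beaker_within, tolerance = 1e-8)
    expect_equal(res$ss_residual, bf$residual, tolerance = 1e-8)
    expect_equal(res$ss_total, bf$total, tolerance = 1e-8)
  }
})

test_that("nested ANOVA uses the beaker mean square as the treatment denominator", {
  d <- random_nested_design(3)
  res <- nested_anova(d, "y", "treatment", "beaker_id")
  expect_equal(res$f_treatment, res$ms_treatment / res$ms_beaker_within)
  expect_equal(res$f_beaker, res$ms_beaker_within / res$ms_residual)
  expect_equal(res$p_treatment,
               pf(res$f_treatment, res$df_treatment, res$df_beaker,
                  lower.tail = FALSE))
})

test_that("nested ANOVA handles degenerate variance structure", {
  d <- expand.grid(treatment = c("A", "B"), beaker_id = 1:2, rep = 1:3)
  d$y <- 5
  res <- nested_anova(d, "y", "treatment", "beaker_id")
  expect_equal(res$f_treatment, 0)
  expect_equal(res$f_beaker, 0)

  # beaker means identical within each treatment, treatments differ
  d2 <- expand.grid(treatment = c("A", "B"), beaker_id = 1:3, rep = 1:2)
  d2$y <- ifelse(d2$treatment == "A", 1, 2) + rep(c(-0.1, 0.1), each = 6)
  res2 <- nested_anova(d2, "y", "treatment", "beaker_id")
  expect_equal(res2$ss_beaker_within, 0, tolerance = 1e-12)
  expect_gt(res2$ss_treatment, 0)
})

test_that("nested ANOVA rejects invalid designs naming the offender", {
  d <- rbind(data.frame(treatment = "A", beaker_id = 1, y = rnorm(4)),
             data.frame(treatment = "B", beaker_id = 1:2,
                        y = rnorm(4)))
  expect_error(nested_anova(d, "y", "treatment", "beaker_id"), "A")
  d2 <- rbind(data.frame(treatment = "A", beaker_id = c(1, 1, 2), y = rnorm(3)),
              data.frame(treatment = "B", beaker_id = c(1, 1, 2, 2),
                         y = rnorm(4)))
  expect_error(nested_anova(d2, "y", "treatment", "beaker_id"),
               "at least two observations")
})

test_that("one-way ANOVA matches its oracle and the two-group t identity", {
  y <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9)
  g <- rep(c("a", "b", "c"), each = 5)
  res <- one_way_anova(y, g)
  bf <- brute_force_oneway_ss(y, g)
  expect_equal(res$ss_between, bf$between, tolerance = 1e-10)
  expect_equal(res$ss_within, bf$within, tolerance = 1e-10)
  expect_equal(res$f, (bf$between / 2) / (bf$within / 12), tolerance = 1e-10)

  # every group holds the same values: no between-group variance
  expect_equal(one_way_anova(rep(c(1, 2, 3), 3),
                             rep(c("a", "b", "c"), each = 3))$f, 0)

  x <- rnorm(6); z <- rnorm(6, 1)
  two <- one_way_anova(c(x, z), rep(c("x", "z"), each = 6))
  tt <- t_test_raw(x, z)
  expect_equal(two$f, tt$statistic^2, tolerance = 1e-10)
  expect_equal(two$p, tt$p, tolerance = 1e-10)
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "b")
})

test_that("Tukey HSD agrees with direct studentized-range evaluation", {
  set.seed(21)
  y <- c(rnorm(6, 0), rnorm(6, 1.5), rnorm(6, 1.7))
  g <- rep(c("a", "b", "c"), each = 6)
  res <- tukey_hsd(y, g)
  expect_equal(nrow(res), 3)

  fit <- lm(y ~ factor(g))
  mse <- sum(residuals(fit)^2) / df.residual(fit)
  means <- tapply(y, g, mean)
  for (i in seq_len(nrow(res))) {
    pair <- strsplit(res$comparison[i], "-")[[1]]
    q <- abs(means[[pair[1]]] - means[[pair[2]]]) / sqrt(mse / 6)
    p <- ptukey(q, nmeans = 3, df = 15, lower.tail = FALSE)
    expect_equal(res$p_adjusted[i], p, tolerance = 1e-6)
  }
})

test_that("Tukey HSD separates shifted groups and passes identical ones", {
  # same values in every group: no pair significant
  same <- tukey_hsd(rep(c(1, 2, 3, 4), 3), rep(c("a", "b", "c"), each = 4))
  expect_false(any(same$significant))

  set.seed(5)
  y <- c(rnorm(5), rnorm(5), rnorm(5) + 100)
  g <- rep(c("a", "b", "c"), each = 5)
  res <- tukey_hsd(y, g)
  hit <- grepl("c", res$comparison)
  expect_true(all(res$significant[hit]))
  expect_false(any(res$significant[!hit]))
})

test_that("beaker-mean aggregation averages within beakers before Tukey", {
  d <- expand.grid(trt = c("A", "B", "C"), bkr = 1:4, rep = 1:3)
  set.seed(9)
  d$y <- rnorm(nrow(d), ave(as.numeric(factor(d$trt))))
  agg <- tukey_hsd(d$y, d$trt, aggregate = "beaker_mean", beaker = d$bkr)
  means <- aggregate(y ~ trt + bkr, d, mean)
  direct <- tukey_hsd(means$y, means$trt)
  expect_equal(agg[order(agg$comparison), "p_adjusted"],
               direct[order(direct$comparison), "p_adjusted"])
  expect_error(tukey_hsd(d$y, d$trt, aggregate = "beaker_mean"), "beaker")
})

test_that("pooled t-tests from raw data and summaries agree with the formula", {
  x <- c(2, 4, 4, 5, 7); y <- c(6, 7, 8, 9, 10)
  res <- t_test_raw(x, y)
  s2 <- (4 * var(x) + 4 * var(y)) / 8
  t_hand <- (mean(x) - mean(y)) / sqrt(s2 * (2 / 5))
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 8)

  expect_equal(t_test_raw(x, x)$statistic, 0)
  # equal n and variance: pooled equals Welch
  w <- t.test(x, y)$statistic
  expect_equal(res$statistic, unname(w), tolerance = 1e-10)

  sum_res <- t_test_summary(mean(x), sd(x), 5, mean(y), sd(y), 5)
  expect_equal(sum_res$statistic, res$statistic, tolerance = 1e-10)
  expect_equal(sum_res$p, res$p, tolerance = 1e-10)
  expect_error(t_test_raw(1, y), "at least two")
})

test_that("summary t-test re-analyses printed gut-content summaries", {
  # frozen from pooled-t arithmetic on the printed means/SDs (n = 20 each);
  # the original report prints -1.457, not reproducible from its own summaries
  res <- t_test_summary(1966.0, 235.3, 20, 2130.0, 460.4, 20)
  expect_equal(res$statistic, -1.418507, tolerance = 1e-6)
  expect_equal(res$df, 38)
  expect_gt(res$p, 0.05)

  expect_equal(t_test_summary(5, 1, 10, 5, 2, 10)$statistic, 0)
  a <- t_test_summary(10, 2, 12, 8, 3, 12)
  b <- t_test_summary(10, 4, 12, 8, 6, 12)
  expect_equal(abs(a$statistic) / 2, abs(b$statistic), tolerance = 1e-12)
  expect_error(t_test_summary(1, 0, 5, 2, 1, 5), "positive")
  expect_error(t_test_summary(1, 1, 1, 2, 1, 5), "at least 2")
})

test_that("offspring per adult is the exact quotient", {
  expect_equal(offspring_per_adult(0, 5), 0)
  expect_equal(offspring_per_adult(57, 5), 11.4)
  expect_equal(offspring_per_adult(131, 5), 26.2)
  expect_error(offspring_per_adult(5, 0), "positive")
  expect_error(offspring_per_adult(-1, 5), "non-negative")
})
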