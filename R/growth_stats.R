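#' Nested ANOVA with a random beaker factor
#'
#' Analysis of variance for a feeding-experiment design in which replicate
#' beakers are nested within diet treatments and individuals are measured
#' within beakers. Sequential (Type-I) sums of squares are taken in the
#' nesting order treatment, then beaker-within-treatment, then residual.
#' Because beakers are a random factor, the treatment effect is tested
#' against the beaker-within-treatment mean square
#' (`F_treatment = MS_treatment / MS_beaker_within`), not the residual; the
#' beaker effect is tested against the residual
#' (`F_beaker = MS_beaker_within / MS_residual`). Degrees of freedom follow
#' from the actual design.
#'
#' @param data Data frame of individual-level observations.
#' @param response Name of the numeric response column (e.g. body length, mm).
#' @param treatment Name of the treatment column.
#' @param beaker Name of the beaker identifier column; beaker labels may be
#'   reused across treatments (the nesting is formed internally).
#' @return An object of class `"nested_anova_result"`: F statistics, degrees
#'   of freedom and p-values for the treatment and beaker strata, plus the
#'   sums-of-squares decomposition (`ss_treatment`, `ss_beaker_within`,
#'   `ss_residual`, `ss_total`).
#' @examples
#' d <- expand.grid(trt = c("A", "B"), bkr = 1:3, rep = 1:2)
#' d$y <- rnorm(nrow(d), ifelse(d$trt == "A", 0, 1))
#' nested_anova(d, "y", "trt", "bkr")
#' @export
nested_anova <- function(data, response, treatment, beaker) {
  stopifnot(is.data.frame(data),
            all(c(response, treatment, beaker) %in% names(data)))
  y <- data[[response]]
  trt <- factor(data[[treatment]])
  bkr <- factor(paste(as.character(data[[treatment]]),
                      as.character(data[[beaker]]), sep = ":"))
  if (anyNA(y) || !is.numeric(y))
    stop("response must be numeric without NA", call. = FALSE)
  if (nlevels(trt) < 2L)
    stop("at least two treatments are required", call. = FALSE)
  n_beakers <- tapply(bkr, trt, function(b) length(unique(b)))
  single <- names(n_beakers)[n_beakers < 2L]
  if (length(single))
    stop("treatment(s) with fewer than two beakers: ",
         paste(single, collapse = ", "), call. = FALSE)
  per_beaker <- table(bkr)
  if (any(per_beaker < 2L))
    stop("every beaker needs at least two observations", call. = FALSE)

  # sequential SS in the stated nesting order
  tab <- anova_quiet_perfect_fit(stats::lm(y ~ trt + trt:bkr))
  ss <- zap_negligible_ss(tab[["Sum Sq"]])
  df <- tab[["Df"]]
  names(ss) <- names(df) <- rownames(tab)
  ss_trt <- ss[["trt"]]; df_trt <- df[["trt"]]
  ss_bkr <- ss[["trt:bkr"]]; df_bkr <- df[["trt:bkr"]]
  ss_res <- ss[["Residuals"]]; df_res <- df[["Residuals"]]

  ratio_f <- function(ms_num, ms_den) {
    if (ms_num == 0) 0 else if (ms_den == 0) Inf else ms_num / ms_den
  }
  ms_trt <- ss_trt / df_trt
  ms_bkr <- ss_bkr / df_bkr
  ms_res <- ss_res / df_res
  f_trt <- ratio_f(ms_trt, ms_bkr)
  f_bkr <- ratio_f(ms_bkr, ms_res)
  structure(
    list(f_treatment = f_trt, df_treatment = df_trt, df_beaker = df_bkr,
         f_beaker = f_bkr, df_residual = df_res,
         p_treatment = stats::pf(f_trt, df_trt, df_bkr, lower.tail = FALSE),
         p_beaker = stats::pf(f_bkr, df_bkr, df_res, lower.tail = FALSE),
         ss_treatment = ss_trt, ss_beaker_within = ss_bkr,
         ss_residual = ss_res, ss_total = ss_trt + ss_bkr + ss_res,
         ms_treatment = ms_trt, ms_beaker_within = ms_bkr, ms_residual = ms_res),
    class = "nested_anova_result"
  )
}

#' @export
print.nested_anova_result <- function(x, ...) {
  cat("<nested_anova_result>\n")
  cat(sprintf("  treatment: F(%d, %d) = %.3f, p = %.4g  [vs beaker MS]\n",
              x$df_treatment, x$df_beaker, x$f_treatment, x$p_treatment))
  cat(sprintf("  beaker:    F(%d, %d) = %.3f, p = %.4g  [vs residual MS]\n",
              x$df_beaker, x$df_residual, x$f_beaker, x$p_beaker))
  invisible(x)
}

# Least-squares SS for an exactly null component comes back as accumulated
# rounding error, not zero; treat components negligible relative to the
# total (or to machine precision when the total itself vanishes) as zero so
# degenerate inputs give F = 0 rather than a ratio of rounding noise.
zap_negligible_ss <- function(ss) {
  total <- sum(ss)
  ifelse(ss < 1e-10 * max(total, .Machine$double.eps), 0, ss)
}

# Degenerate (zero-residual) inputs are legitimate here — F is defined as 0
# for a zero numerator SS — so the fitter's perfect-fit warning is noise.
anova_quiet_perfect_fit <- function(fit) {
  withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' One-way ANOVA
#'
#' Classical between/within decomposition for a single grouping factor.
#'
#' @param values Numeric response vector.
#' @param groups Grouping labels, same length as `values`; every group needs
#'   at least two values.
#' @return List with `f`, `df_between`, `df_within`, `p`, `ss_between`,
#'   `ss_within`.
#' @examples
#' one_way_anova(c(1, 2, 5, 6, 9, 11), rep(c("a", "b", "c"), each = 2))
#' @export
one_way_anova <- function(values, groups) {
  g <- factor(groups)
  stopifnot(length(values) == length(g))
  if (anyNA(values)) stop("values contain NA", call. = FALSE)
  if (nlevels(g) < 2L) stop("at least two groups are required", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("group(s) with fewer than two values: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  tab <- anova_quiet_perfect_fit(stats::lm(values ~ g))
  ss <- zap_negligible_ss(tab[["Sum Sq"]])
  ss_b <- ss[1]; ss_w <- ss[2]
  df_b <- tab[["Df"]][1]; df_w <- tab[["Df"]][2]
  f <- if (ss_b == 0) 0 else if (ss_w == 0) Inf else (ss_b / df_b) / (ss_w / df_w)
  list(f = f, df_between = df_b, df_within = df_w,
       p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       ss_between = ss_b, ss_within = ss_w)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group comparisons with studentized-range-adjusted p-values.
#' By default the comparison runs on individual-level values with the
#' residual mean square of the one-way fit; with `aggregate = "beaker_mean"`
#' observations are first averaged within beakers (supply `beaker`), which
#' uses the beaker as the unit of replication.
#'
#' @param values Numeric response vector.
#' @param groups Grouping labels.
#' @param alpha Significance level for the `significant_at_005`-style flag
#'   (default 0.05).
#' @param aggregate `"individual"` (default) or `"beaker_mean"`.
#' @param beaker Beaker labels, required for `aggregate = "beaker_mean"`.
#' @return Data frame with one row per pair: `comparison`, `diff`,
#'   `statistic` (studentized range q), `p_adjusted`, `significant`.
#' @examples
#' tukey_hsd(c(1, 2, 5, 6, 9, 11), rep(c("a", "b", "c"), each = 2))
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05,
                      aggregate = c("individual", "beaker_mean"),
                      beaker = NULL) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "beaker_mean") {
    if (is.null(beaker))
      stop("'beaker' is required for beaker-mean aggregation", call. = FALSE)
    agg <- stats::aggregate(
      list(values = values),
      by = list(groups = as.character(groups), beaker = as.character(beaker)),
      FUN = mean)
    values <- agg$values
    groups <- agg$groups
  }
  g <- factor(groups)
  sizes <- table(g)
  if (nlevels(g) < 2L || any(sizes < 2L))
    stop("every group needs at least two values", call. = FALSE)
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  pairs <- rownames(tk)
  ab <- strsplit(pairs, "-", fixed = TRUE)
  se_q <- vapply(ab, function(p) {
    sqrt(mse / 2 * (1 / sizes[[p[1]]] + 1 / sizes[[p[2]]]))
  }, numeric(1))
  q <- ifelse(se_q == 0, ifelse(tk[, "diff"] == 0, 0, Inf),
              abs(tk[, "diff"]) / se_q)
  data.frame(comparison = pairs,
             diff = unname(tk[, "diff"]),
             statistic = unname(q),
             p_adjusted = unname(tk[, "p adj"]),
             significant = unname(tk[, "p adj"]) < alpha,
             stringsAsFactors = FALSE)
}

#' Pooled two-sample t-test on raw values
#'
#' Student's two-sample t-test with pooled variance.
#'
#' @param x,y Numeric samples, each with at least two values.
#' @param two_tailed Two-sided p-value (default `TRUE`).
#' @return List with `statistic`, `df`, `p`.
#' @examples
#' t_test_raw(rnorm(5), rnorm(5, 1))
#' @export
t_test_raw <- function(x, y, two_tailed = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least two values", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = TRUE,
                      alternative = if (two_tailed) "two.sided" else "greater")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Re-analyses printed means and SDs (as reported in papers) without the raw
#' data: pooled variance
#' `s2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`,
#' `t = (mean1 - mean2) / sqrt(s2 (1/n1 + 1/n2))`, df `n1 + n2 - 2`.
#'
#' @param mean1,sd1,n1 First group's mean, SD (> 0) and size (>= 2).
#' @param mean2,sd2,n2 Second group's likewise.
#' @param two_tailed Two-sided p-value (default `TRUE`).
#' @return List with `statistic`, `df`, `p`.
#' @examples
#' t_test_summary(1966.0, 235.3, 20, 2130.0, 460.4, 20)
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           two_tailed = TRUE) {
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive", call. = FALSE)
  if (n1 < 2L || n2 < 2L) stop("each n must be at least 2", call. = FALSE)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(s2 * (1 / n1 + 1 / n2))
  p <- stats::pt(abs(t), df, lower.tail = FALSE) * if (two_tailed) 2 else 1
  list(statistic = t, df = df, p = min(p, 1))
}

#' Offspring per adult
#'
#' The per-beaker fecundity endpoint: total offspring in a beaker divided by
#' the number of adults kept in it.
#'
#' @param total_offspring Offspring count (non-negative).
#' @param n_adults Number of adults in the beaker (positive).
#' @return Offspring per adult (exact quotient).
#' @examples
#' offspring_per_adult(57, 5) # 11.4
#' @export
offspring_per_adult <- function(total_offspring, n_adults) {
  if (any(n_adults <= 0)) stop("'n_adults' must be positive", call. = FALSE)
  if (any(total_offspring < 0))
    stop("'total_offspring' must be non-negative", call. = FALSE)
  total_offspring / n_adults
}
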