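#' Log transform for count responses
#'
#' `ln(x + 1)`, the variance-stabilizing transform applied to capture and
#' detection counts before ANOVA; the +1 offset keeps zero counts defined.
#'
#' @param x Non-negative numeric vector.
#' @return `log(x + 1)`.
#' @export
log1_transform <- function(x) {
  if (any(x < 0)) stop("counts must be non-negative")
  log1p(x)
}

#' Column summaries of a capture table
#'
#' Mean and sample standard deviation (n - 1 denominator) of every numeric
#' column. Values are kept at full precision; the print method rounds to one
#' decimal in the conventional `mean +/- sd` report style.
#'
#' @param table A `capture_table` or any data frame with numeric columns.
#' @return Data frame of class `capture_summary` with columns `column`,
#'   `mean`, `sd`.
#' @export
summarize_captures <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  if (!any(num)) stop("no numeric columns to summarize")
  if (nrow(table) < 2L)
    stop("sd undefined: need at least 2 rows")
  cols <- names(table)[num]
  out <- data.frame(
    column = cols,
    mean = vapply(table[cols], mean, numeric(1)),
    sd = vapply(table[cols], sd, numeric(1)))
  rownames(out) <- NULL
  structure(out, class = c("capture_summary", "data.frame"))
}

#' @export
print.capture_summary <- function(x, ...) {
  cat("capture summary (mean +/- SD, n-1 denominator):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-22s %.1f ± %.1f\n", x$column[i], x$mean[i], x$sd[i]))
  invisible(x)
}

anova_table <- function(term, df, sumsq, meansq, statistic, p.value,
                        degenerate = FALSE) {
  structure(data.frame(term = term, df = df, sumsq = sumsq, meansq = meansq,
                       statistic = statistic, p.value = p.value),
            degenerate = degenerate,
            class = c("anova_table", "data.frame"))
}

#' @export
print.anova_table <- function(x, ...) {
  cat("ANOVA\n")
  y <- x
  class(y) <- "data.frame"
  y$sumsq <- signif(y$sumsq, 4); y$meansq <- signif(y$meansq, 4)
  y$statistic <- signif(y$statistic, 4); y$p.value <- signif(y$p.value, 3)
  print(y, row.names = FALSE)
  if (isTRUE(attr(x, "degenerate")))
    cat("  (degenerate: zero residual variance)\n")
  invisible(x)
}

#' One-way ANOVA for two treatment groups
#'
#' Standard between/within decomposition with `F` on
#' `(1, n_a + n_b - 2)` degrees of freedom, as used to compare capture
#' counts between two bait treatments. Zero residual variance yields an
#' infinite (or undefined) F flagged via the `degenerate` attribute rather
#' than an error.
#'
#' @param group_a,group_b Numeric response vectors (each of length >= 2),
#'   typically [log1_transform()]ed counts.
#' @param labels Length-2 labels used in the output term names.
#' @return An `anova_table` data frame (`term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`).
#' @export
one_way_anova <- function(group_a, group_b, labels = c("A", "B")) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  y <- c(group_a, group_b)
  g <- factor(rep(labels, c(length(group_a), length(group_b))))
  fit <- lm(y ~ g)
  a <- suppressWarnings(anova(fit))  # degenerate fits are flagged below
  ss <- a$`Sum Sq`; df <- a$Df; ms <- ss / df
  degenerate <- ms[2] <= .Machine$double.eps
  f <- if (degenerate) { if (ss[1] > 0) Inf else NaN } else ms[1] / ms[2]
  p <- if (is.nan(f)) NaN else pf(f, df[1], df[2], lower.tail = FALSE)
  anova_table(term = c("Treatment", "Residuals"),
              df = df, sumsq = ss, meansq = ms,
              statistic = c(f, NA), p.value = c(p, NA),
              degenerate = degenerate)
}

#' Two-way ANOVA of detections by bait and surface
#'
#' Decomposes a (possibly log-transformed) detection response by bait
#' treatment, trap surface, and their interaction. On balanced data the
#' sequential (Type I) decomposition is exact and orthogonal; for unbalanced
#' data a marginal (Type II) decomposition via [car::Anova()] is available.
#' A constant response is flagged degenerate (F undefined), never an error.
#'
#' @param data Data frame of observations.
#' @param response,bait,surface Column names (defaults `"response"`,
#'   `"bait"`, `"surface"`).
#' @param ss_type `"sequential"` (Type I, default) or `"marginal"`
#'   (Type II).
#' @return An `anova_table` with rows `Bait`, `Surface`, `Bait:Surface`,
#'   `Residuals`.
#' @export
two_way_anova <- function(data, response = "response", bait = "bait",
                          surface = "surface",
                          ss_type = c("sequential", "marginal")) {
  ss_type <- match.arg(ss_type)
  stopifnot(all(c(response, bait, surface) %in% names(data)))
  y <- data[[response]]
  if (any(!is.finite(y))) stop("response must be finite")
  f1 <- factor(data[[bait]]); f2 <- factor(data[[surface]])
  if (nlevels(f1) < 2L || nlevels(f2) < 2L)
    stop("each factor needs at least 2 levels")
  fit <- lm(y ~ f1 * f2)
  if (ss_type == "sequential") {
    a <- suppressWarnings(anova(fit))
    df <- a$Df; ss <- a$`Sum Sq`
  } else {
    a <- suppressWarnings(car::Anova(fit, type = 2))
    df <- a$Df; ss <- a$`Sum Sq`
  }
  ms <- ss / df
  degenerate <- ms[4] <= .Machine$double.eps
  f <- if (degenerate) rep(NaN, 3) else ms[1:3] / ms[4]
  p <- ifelse(is.nan(f), NaN, pf(f, df[1:3], df[4], lower.tail = FALSE))
  anova_table(term = c("Bait", "Surface", "Bait:Surface", "Residuals"),
              df = df, sumsq = ss, meansq = ms,
              statistic = c(f, NA), p.value = c(p, NA),
              degenerate = degenerate)
}

#' Fisher's Least Significant Difference post hoc test
#'
#' Unadjusted pairwise comparisons of cell means using the ANOVA residual
#' mean square: `LSD = t(1 - alpha/2, residual_df) * sqrt(ms * (1/n_i +
#' 1/n_j))`, which reduces to `t * sqrt(2 * ms / n)` for equal cell sizes.
#' A pair is significant iff `|mean difference| > LSD` (no multiplicity
#' adjustment, by the LSD convention).
#'
#' @param means Named numeric vector of cell means.
#' @param n_per_cell Cell sizes (scalar or one per cell).
#' @param residual_ms Residual mean square from the ANOVA (> 0).
#' @param residual_df Residual degrees of freedom.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param labels Cell labels; defaults to `names(means)`.
#' @return Data frame of class `lsd_result`: `group1`, `group2`, `diff`,
#'   `lsd`, `significant`.
#' @export
fisher_lsd <- function(means, n_per_cell, residual_ms, residual_df,
                       alpha = 0.05, labels = names(means)) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (residual_ms <= 0) stop("residual_ms must be > 0")
  if (any(n_per_cell < 1)) stop("n_per_cell must be >= 1")
  k <- length(means)
  stopifnot(k >= 2L)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  n <- rep_len(n_per_cell, k)
  tcrit <- qt(1 - alpha / 2, df = residual_df)
  prs <- combn(k, 2)
  out <- data.frame(
    group1 = labels[prs[1, ]], group2 = labels[prs[2, ]],
    diff = means[prs[1, ]] - means[prs[2, ]],
    lsd = tcrit * sqrt(residual_ms * (1 / n[prs[1, ]] + 1 / n[prs[2, ]])))
  out$significant <- abs(out$diff) > out$lsd
  rownames(out) <- NULL
  structure(out, alpha = alpha, residual_df = residual_df,
            class = c("lsd_result", "data.frame"))
}

#' Kolmogorov-Smirnov check of normality
#'
#' One-sample KS test of the values against a normal distribution with the
#' observed mean and standard deviation (by default; explicit reference
#' parameters may be supplied). The p-value comes from the asymptotic
#' Kolmogorov distribution without small-sample correction.
#'
#' @param values Numeric vector (n >= 3, positive variance).
#' @param mean,sd Reference normal parameters; default to the sample
#'   estimates.
#' @return List of class `ks_result`: `statistic` (D), `p.value`, `mean`,
#'   `sd`, `n`.
#' @export
ks_normality <- function(values, mean = base::mean(values),
                         sd = stats::sd(values)) {
  if (length(values) < 3L) stop("need at least 3 values")
  if (!is.finite(sd) || sd <= 0) stop("zero variance: KS check undefined")
  ks <- suppressWarnings(
    ks.test(values, "pnorm", mean = mean, sd = sd, exact = FALSE))
  structure(list(statistic = unname(ks$statistic),
                 p.value = ks$p.value, mean = mean, sd = sd,
                 n = length(values)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf(
    "KS normality check: D = %.4g, p = %.3g (n = %d, ref N(%.3g, %.3g))\n",
    x$statistic, x$p.value, x$n, x$mean, x$sd))
  invisible(x)
}
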