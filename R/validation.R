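#' Compare automatic with manual counts
#'
#' Computes the three standard agreement metrics for an automatic-counting
#' pipeline checked against manual counts of the same images: the fraction
#' of images where the automatic count matches the manual count or is off by
#' one (`|auto - manual| <= 1`), the fraction within three individuals
#' (`<= 3`), and the Pearson product-moment correlation, pooled over all
#' pairs and, when a `group` column is present (e.g. experiment date), per
#' group. A group in which either variable has zero variance yields an
#' undefined correlation flagged as degenerate, not an error.
#'
#' @param pairs Data frame with non-negative count columns `auto` and
#'   `manual`, and optionally `group` and `image` identifiers.
#' @return An object of class `validation_report`: a list with `n`,
#'   `frac_within_1`, `frac_within_3`, `r`, `r_p` (two-sided p for `r`), and
#'   `by_group` (data frame `group`, `n`, `r`, `p`, `degenerate`; `NULL`
#'   without grouping).
#' @export
validate_counts <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L) stop("empty input: no count pairs")
  if (!all(c("auto", "manual") %in% names(pairs)))
    stop("pairs must have columns 'auto' and 'manual'")
  a <- pairs$auto; m <- pairs$manual
  if (any(a < 0) || any(m < 0)) stop("counts must be non-negative")
  d <- abs(a - m)
  n <- length(d)
  r <- if (n >= 2 && sd(a) > 0 && sd(m) > 0) cor(a, m) else NA_real_
  r_p <- if (is.na(r)) NA_real_ else as.numeric(significance_of_r(r, n))
  by_group <- NULL
  if ("group" %in% names(pairs)) {
    gs <- split(pairs, pairs$group)
    by_group <- do.call(rbind, lapply(names(gs), function(g) {
      x <- gs[[g]]
      ng <- nrow(x)
      degenerate <- ng < 2 || sd(x$auto) == 0 || sd(x$manual) == 0
      rg <- if (degenerate) NA_real_ else cor(x$auto, x$manual)
      pg <- if (degenerate || ng < 3) NA_real_
            else as.numeric(significance_of_r(rg, ng))
      data.frame(group = g, n = ng, r = rg, p = pg, degenerate = degenerate)
    }))
    rownames(by_group) <- NULL
  }
  structure(list(n = n,
                 frac_within_1 = mean(d <= 1),
                 frac_within_3 = mean(d <= 3),
                 r = r, r_p = r_p, by_group = by_group),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation of automatic vs manual counts (%d images)\n", x$n))
  cat(sprintf("  within 1 of manual: %.1f%%   within 3: %.1f%%\n",
              100 * x$frac_within_1, 100 * x$frac_within_3))
  cat(sprintf("  Pearson r = %.3f (p = %.3g)\n", x$r, x$r_p))
  if (!is.null(x$by_group)) {
    cat("  per group:\n")
    print(x$by_group, row.names = FALSE)
  }
  invisible(x)
}

#' Two-sided significance of a Pearson correlation
#'
#' Uses the exact null relation `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` degrees of freedom. `|r| = 1` returns `p = 0` with the `exact`
#' attribute set (the t transform is singular there).
#'
#' @param r Pearson correlation in `[-1, 1]`.
#' @param n Number of pairs (>= 3).
#' @return Two-sided p-value.
#' @export
significance_of_r <- function(r, n) {
  if (abs(r) > 1) stop("|r| must be <= 1")
  if (n < 3) stop("need n >= 3")
  if (abs(r) == 1) return(structure(0, exact = TRUE))
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}
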