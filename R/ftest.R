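#' One-way fixed-effects ANOVA F-test
#'
#' Baseline association test under the linear model
#' `y_ij = mu + alpha_i + eps_ij`: the F statistic is the ratio of
#' between-category to within-category mean squares,
#' `F = (SSB / (a - 1)) / (SSW / (N - a))`, with the p-value from the upper
#' tail of the F distribution. Computed directly from per-category sums and
#' counts so that the same arithmetic serves the vectorized per-marker scan.
#'
#' When the within-category variance is zero while the between-category
#' variance is not (perfectly sorted data), the exact p-value is 0 and
#' `-log10(p)` is unrepresentable; the p-value is then clamped at the
#' smallest positive normal double and flagged `saturated`. The same
#' clamping applies when the p-value underflows. The HA-coefficient has no
#' such saturation, which is one of the contrasts the simulation harness
#' exhibits.
#'
#' @param obs numeric observation vector (any finite reals; positivity is a
#'   requirement of the HA-coefficient, not of the F-test).
#' @param cats categorical identifiers, same length as `obs`; at least two
#'   distinct categories and at least one residual degree of freedom are
#'   required.
#' @return An object of class `ha_anova`: list with `f_stat`, `p_value`,
#'   `neg_log10_p`, `df_between`, `df_within`, `saturated`.
#' @examples
#' anova_f(c(1, 2, 3, 4), c("A", "A", "B", "B"))  # F = 8, p ~ 0.106
#' @export
anova_f <- function(obs, cats) {
  stopifnot(length(obs) == length(cats))
  obs <- as.numeric(obs)
  if (anyNA(obs) || !all(is.finite(obs))) stop("observations must be finite")
  labels <- as.character(cats)
  idx <- split(seq_along(labels), labels)
  a <- length(idx)
  N <- length(obs)
  if (a < 2L) stop("need at least 2 categories")
  if (N - a < 1L) stop("need at least one residual degree of freedom")

  sums <- vapply(idx, function(i) sum(obs[i]), numeric(1))
  counts <- vapply(idx, length, numeric(1))
  y <- sum(obs)
  ssb <- sum(sums^2 / counts) - y^2 / N
  sst <- sum(obs^2) - y^2 / N
  ssw <- max(sst - ssb, 0)

  df1 <- a - 1L
  df2 <- N - a
  f <- if (ssw > 0) (ssb / df1) / (ssw / df2) else if (ssb > 0) Inf else 0
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)

  saturated <- FALSE
  if (!is.na(p) && p < .Machine$double.xmin) {
    p <- .Machine$double.xmin
    saturated <- TRUE
  }
  structure(
    list(f_stat = f, p_value = p, neg_log10_p = -log10(p),
         df_between = df1, df_within = df2, saturated = saturated),
    class = "ha_anova")
}

#' @export
print.ha_anova <- function(x, digits = 6, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %s, p = %s%s\n",
              x$df_between, x$df_within, format(signif(x$f_stat, digits)),
              format(signif(x$p_value, digits)),
              if (x$saturated) " (saturated: p clamped at double.xmin)" else ""))
  invisible(x)
}
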