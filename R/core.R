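#' Stratify categories by ascending mean observation
#'
#' Orders the categories of a quantitative/categorical paired sample by the
#' ascending mean of the observations in each category, the arrangement on
#' which the hierarchical association (HA) coefficient is defined. With
#' `category_order` supplied the order is taken as externally fixed
#' ("prehierarchical"): the categories are laid out in that order and no
#' ordering or tie condition on their means is checked. Without it the order
#' is derived from the data ("posthierarchical", the usual situation in a
#' marker scan), and two categories whose means coincide within `tie_tol`
#' (relative) make the statistic undefined.
#'
#' @param obs numeric vector of observations; all must be positive, finite
#'   and non-missing.
#' @param cats vector of categorical identifiers, same length as `obs`.
#'   Factors, characters and integers are all accepted; levels with zero
#'   members are dropped before the category count is taken.
#' @param tie_tol relative tolerance under which two category means count as
#'   tied (posthierarchical mode only).
#' @param category_order optional vector of category labels fixing the
#'   ascending order externally (prehierarchical mode). Must be a permutation
#'   of the categories present in `cats`.
#' @return An object of class `ha_strata`: a list with `order` (labels in
#'   ascending-mean or fixed order), `index` (member indices per category),
#'   `sums`, `counts`, `means` (aligned with `order`), `n` (category count),
#'   `y` (total sum), `mode` (`"posthierarchical"` or `"prehierarchical"`)
#'   and `status`. `status` is `"ok"` or one of `"invalid_observations"`,
#'   `"undefined_single_category"`, `"undefined_tied_means"`; when not
#'   `"ok"` the remaining fields may be incomplete and the HA-coefficient is
#'   undefined for this input.
#' @seealso [ha_coefficient()], [boundary_decompose()]
#' @examples
#' stratify(c(1, 2, 3, 10), c("A", "B", "B", "A"))
#' @export
stratify <- function(obs, cats, tie_tol = 1e-12, category_order = NULL) {
  stopifnot(length(obs) == length(cats))
  out <- structure(
    list(order = NULL, index = NULL, sums = NULL, counts = NULL,
         means = NULL, n = NA_integer_, y = NA_real_,
         mode = if (is.null(category_order)) "posthierarchical" else "prehierarchical",
         status = "ok"),
    class = "ha_strata")

  if (anyNA(obs) || !all(is.finite(obs)) || any(obs <= 0)) {
    out$status <- "invalid_observations"
    return(out)
  }

  labels <- as.character(cats)
  idx <- split(seq_along(labels), labels)   # drops absent levels by design
  if (length(idx) < 2L) {
    out$status <- "undefined_single_category"
    return(out)
  }
  sums <- vapply(idx, function(i) sum(obs[i]), numeric(1))
  counts <- vapply(idx, length, integer(1))
  means <- sums / counts

  if (is.null(category_order)) {
    if (means_tied(means, tie_tol)) {
      out$status <- "undefined_tied_means"
      return(out)
    }
    ord <- order(means)       # stable; ties already excluded
  } else {
    category_order <- as.character(category_order)
    if (!setequal(category_order, names(idx)) ||
        length(category_order) != length(idx)) {
      stop("'category_order' must be a permutation of the categories present")
    }
    ord <- match(category_order, names(idx))
  }

  out$order <- names(idx)[ord]
  out$index <- idx[ord]
  out$sums <- unname(sums[ord])
  out$counts <- unname(counts[ord])
  out$means <- unname(means[ord])
  out$n <- length(idx)
  out$y <- sum(obs)
  out
}

#' @export
print.ha_strata <- function(x, ...) {
  cat("Stratified categorization (", x$mode, ")\n", sep = "")
  cat("  status:", x$status, "\n")
  if (x$status == "ok") {
    cat("  categories (ascending mean):",
        paste(x$order, collapse = " < "), "\n")
    cat("  means:", paste(signif(x$means, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hierarchical binary decomposition at a category boundary
#'
#' Collapses all category boundaries of a stratified categorization except
#' the `k`-th, producing the two-subset split that carries the per-boundary
#' HA ratio. The decomposition records the observed right-subset sum `r1`,
#' the right-subset sums of the two sorting extremes -- `g1` when the
#' observations are ascending across the stratified categories (the "top"
#' arrangement) and `btm` when they are descending (the "bottom"
#' arrangement) -- plus `g2 = y - g1` and the member count `m` of the right
#' subset. The bracketing `btm <= r1 <= g1` always holds.
#'
#' @param strat an `ha_strata` with status `"ok"` (see [stratify()]).
#' @param obs the observation vector the stratification was built from.
#' @param k boundary index, `1 <= k <= n - 1`; boundary `k` separates the
#'   `k` lowest-mean categories (left) from the rest (right).
#' @return An object of class `ha_boundary`: list with `k`, `m`, `r1`, `r2`,
#'   `g1`, `g2`, `btm`, `y`.
#' @examples
#' s <- stratify(c(1, 2, 3, 10), c("A", "B", "B", "A"))
#' boundary_decompose(s, c(1, 2, 3, 10), 1)
#' @export
boundary_decompose <- function(strat, obs, k) {
  stopifnot(inherits(strat, "ha_strata"))
  if (strat$status != "ok") {
    stop("stratification status is '", strat$status, "'; cannot decompose")
  }
  n <- strat$n
  if (!(k >= 1L && k <= n - 1L)) stop("'k' must lie in 1..n-1")

  right <- (k + 1L):n
  m <- sum(strat$counts[right])
  r1 <- sum(strat$sums[right])
  y <- strat$y
  sorted <- sort(obs)           # ascending; stable for reproducibility
  g1 <- sum(sorted[(length(sorted) - m + 1L):length(sorted)])
  btm <- sum(sorted[seq_len(m)])
  # btm <= r1 <= g1 holds exactly in real arithmetic; summation order can
  # leave r1 an ulp outside at the extremes, so pin it back
  r1 <- min(max(r1, btm), g1)
  structure(
    list(k = as.integer(k), m = as.integer(m), r1 = r1, r2 = y - r1,
         g1 = g1, g2 = y - g1, btm = btm, y = y),
    class = "ha_boundary")
}

#' @export
print.ha_boundary <- function(x, ...) {
  cat(sprintf(
    "Boundary %d: m = %d, r1 = %g (btm = %g, top = %g), y = %g\n",
    x$k, x$m, x$r1, x$btm, x$g1, x$y))
  invisible(x)
}

#' Hierarchical association distance
#'
#' Evaluates the distance curve `d(x) = (g1/g2) * (y/x - 1)` attached to a
#' hierarchical binary decomposition. On the admissible interval
#' `[btm, g1]` the curve satisfies `d(x) >= 1`, with equality exactly at
#' `x = g1` (the top arrangement) and its maximum at `x = btm` (the bottom
#' arrangement).
#'
#' @param x positive numeric vector of right-subset sums to evaluate at.
#' @param d an `ha_boundary` (see [boundary_decompose()]), or any list with
#'   fields `g1`, `g2`, `y`.
#' @return numeric vector of distances.
#' @examples
#' d <- list(g1 = 40, g2 = 30, y = 70)
#' hierarchical_distance(c(10, 25, 40), d)  # 8, 2.4, 1
#' @export
hierarchical_distance <- function(x, d) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("'x' must be positive: the distance curve lives in quadrant I only")
  }
  if (d$g2 <= 0) stop("'g2' must be positive")
  (d$g1 / d$g2) * (d$y / x - 1)
}

#' Area under the hierarchical distance curve
#'
#' Closed-form area under `d(x) = (g1/g2) * (y/x - 1)` between two
#' right-subset sums, via the antiderivative `y * log(x) - x`:
#' `(g1/g2) * ((y log(upper) - upper) - (y log(lower) - lower))`.
#' Taking `lower = btm` and `upper = g1` gives the full area `W`; taking
#' `upper = r1` gives the observed area `R`.
#'
#' @param d an `ha_boundary`, or any list with fields `g1`, `g2`, `y`.
#' @param lower,upper integration bounds, `0 < lower <= upper`.
#' @return nonnegative area.
#' @examples
#' d <- list(g1 = 40, g2 = 30, y = 70)
#' area_between(d, 10, 40)  # W ~ 89.39
#' area_between(d, 10, 25)  # R ~ 65.52
#' @export
area_between <- function(d, lower, upper) {
  if (!is.finite(lower) || lower <= 0) stop("'lower' must be positive")
  if (!is.finite(upper) || upper < lower) stop("'upper' must be >= 'lower'")
  if (d$g2 <= 0) stop("'g2' must be positive")
  (d$g1 / d$g2) *
    (ha_antideriv(upper, d$y) - ha_antideriv(lower, d$y))
}

#' Per-boundary HA ratio
#'
#' The ratio `R/W` of the observed to the full area under the hierarchical
#' distance curve for one boundary. Equals 0 iff the observed right-subset
#' sum sits at the bottom extreme (`r1 = btm`) and 1 iff it sits at the top
#' extreme (`r1 = g1`). The prefactor `g1/g2` cancels, so the ratio is
#' computed directly from the antiderivative.
#'
#' @param d an `ha_boundary` (see [boundary_decompose()]).
#' @return ratio in `[0, 1]`, or `NA` if the full area degenerates to zero
#'   (possible only when `g1 = btm`, i.e. upstream tied-means degeneracy).
#' @export
boundary_ratio <- function(d) {
  denom <- ha_antideriv(d$g1, d$y) - ha_antideriv(d$btm, d$y)
  if (denom <= 0) return(NA_real_)
  num <- ha_antideriv(d$r1, d$y) - ha_antideriv(d$btm, d$y)
  clamp01(num / denom)
}

#' Hierarchical association coefficient
#'
#' Computes the HA-coefficient between a positive quantitative observation
#' vector and a categorical assignment: a value in `[0, 1]` measuring how
#' close the observed arrangement is to perfect ascending sorting across the
#' stratified (ascending-mean) categories. Each of the `n - 1` category
#' boundaries contributes the area ratio of [boundary_ratio()]; the
#' boundary ratios are aggregated by their geometric mean (the default,
#' recommended because it keeps coefficients on a common footing when many
#' markers are compared) or their arithmetic mean. Both aggregates are always
#' reported.
#'
#' HA = 1 when the observations are ascending across the stratified
#' categories. HA = 0 requires the observed right-subset sum to sit at the
#' bottom extreme of every boundary, which is only attainable when the
#' category order is fixed externally (`category_order`, "prehierarchical"
#' mode): an order derived from the data can never place the larger
#' observations entirely in the lower-mean categories.
#'
#' @inheritParams stratify
#' @param aggregation `"geometric"` (default) or `"arithmetic"`; selects
#'   which aggregate is reported as `ha`.
#' @param shift_nonpositive the statistic is defined for positive
#'   observations only (the distance curve lives in quadrant I). If `TRUE`,
#'   nonpositive observations are handled by shifting the whole vector so
#'   its minimum equals `shift_eps`. The shift changes the statistic's value
#'   (HA is scale invariant, not shift invariant), so it is off by default
#'   and logged when applied.
#' @param shift_eps target minimum after the opt-in shift.
#' @return An object of class `ha_result`: list with `per_boundary` (a
#'   data.frame with `k`, `m`, `r1`, `btm`, `top`, `R`, `W`, `ratio`), `ha`
#'   (the selected aggregate), `ha_geometric`, `ha_arithmetic`,
#'   `n_categories`, `aggregation`, `mode` and `status`. Any ratio equal to
#'   0 makes the geometric aggregate exactly 0 (no log-of-zero path). When
#'   `status` is not `"ok"` all coefficient fields are `NA`.
#' @examples
#' ha_coefficient(c(1, 2, 3, 4), c("A", "A", "B", "B"))    # HA = 1
#' ha_coefficient(c(1, 2, 3, 10), c("A", "B", "B", "A"))   # HA ~ 0.95
#' @export
ha_coefficient <- function(obs, cats,
                           aggregation = c("geometric", "arithmetic"),
                           tie_tol = 1e-12, category_order = NULL,
                           shift_nonpositive = FALSE, shift_eps = 1e-6) {
  aggregation <- match.arg(aggregation)
  obs <- as.numeric(obs)

  if (shift_nonpositive && length(obs) && !anyNA(obs) &&
      all(is.finite(obs)) && any(obs <= 0)) {
    shift <- shift_eps - min(obs)
    ha_log(sprintf(
      "shifting observations by %+g so the minimum is %g (departure from the positive-observation convention)",
      shift, shift_eps), level = "WARN")
    obs <- obs + shift
  }

  strat <- stratify(obs, cats, tie_tol = tie_tol,
                    category_order = category_order)

  empty <- structure(
    list(per_boundary = NULL, ha = NA_real_, ha_geometric = NA_real_,
         ha_arithmetic = NA_real_, n_categories = strat$n,
         aggregation = aggregation, mode = strat$mode,
         status = strat$status),
    class = "ha_result")
  if (strat$status != "ok") return(empty)

  n <- strat$n
  ks <- seq_len(n - 1L)
  decomps <- lapply(ks, function(k) boundary_decompose(strat, obs, k))
  ratios <- vapply(decomps, boundary_ratio, numeric(1))
  if (anyNA(ratios)) {          # degenerate W = 0 (all observations equal)
    empty$status <- "undefined_tied_means"
    return(empty)
  }
  per_boundary <- data.frame(
    k = ks,
    m = vapply(decomps, `[[`, integer(1), "m"),
    r1 = vapply(decomps, `[[`, numeric(1), "r1"),
    btm = vapply(decomps, `[[`, numeric(1), "btm"),
    top = vapply(decomps, `[[`, numeric(1), "g1"),
    R = vapply(decomps, function(d) area_between(d, d$btm, d$r1), numeric(1)),
    W = vapply(decomps, function(d) area_between(d, d$btm, d$g1), numeric(1)),
    ratio = ratios)

  geo <- if (any(ratios == 0)) 0 else exp(mean(log(ratios)))
  ari <- mean(ratios)

  structure(
    list(per_boundary = per_boundary, ha = if (aggregation == "geometric") geo else ari,
         ha_geometric = geo, ha_arithmetic = ari, n_categories = n,
         aggregation = aggregation, mode = strat$mode, status = "ok"),
    class = "ha_result")
}

#' @export
print.ha_result <- function(x, digits = 6, ...) {
  cat("Hierarchical association coefficient (", x$mode, ")\n", sep = "")
  if (x$status != "ok") {
    cat("  status:", x$status, "- coefficient undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  HA = %s  (%s mean over %d boundary ratio%s)\n",
              format(signif(x$ha, digits)), x$aggregation,
              x$n_categories - 1L, if (x$n_categories > 2L) "s" else ""))
  cat(sprintf("  geometric = %s, arithmetic = %s\n",
              format(signif(x$ha_geometric, digits)),
              format(signif(x$ha_arithmetic, digits))))
  pb <- x$per_boundary
  pb[] <- lapply(pb, function(col) if (is.double(col)) signif(col, digits) else col)
  print(pb, row.names = FALSE)
  invisible(x)
}
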