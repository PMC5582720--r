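#' Simulate a triangle-patterned categorical matrix with a sorted trait
#'
#' Generates the validation design used to benchmark the HA-coefficient: a
#' strictly increasing observation column (`obs_start`, `obs_start + 1`,
#' ...) paired with a `rows x cols` matrix of categorical identifiers
#' `0..categories-1`. The rows are partitioned into `categories` contiguous
#' equal blocks; block `b` carries identifier `b - 1`. In column `j`, the
#' topmost `round(j * blockheight / cols)` rows of each block are
#' deterministic (they carry the block's identifier; the "signal" cells),
#' and the remaining rows are drawn iid uniform over the identifier
#' alphabet (the "noise" cells). The deterministic fraction thus grows
#' linearly from ~0 in the first column to 1 in the last: across the whole
#' matrix the signal and noise regions of each block are two equal-area
#' triangles, and the final column is a perfect ascending block assignment,
#' so its HA-coefficient against the observation column is exactly 1.
#'
#' @param categories number of identifier types (the classic design uses 2,
#'   3 or 4); must divide `rows`.
#' @param rows,cols matrix dimensions (the reference design is 1200 x 1200).
#' @param obs_start first observation value (reference design: 1001, so
#'   observations run 1001..2200).
#' @param seed optional integer seed applied before drawing the noise cells.
#' @return An object of class `ha_simdata`: list with `observations`,
#'   `geno` (integer matrix), `blue_mask` (logical matrix marking the
#'   deterministic cells), `categories`, `rows`, `cols`, `obs_start`,
#'   `seed`.
#' @examples
#' d <- make_dataset(2, rows = 6, cols = 6, obs_start = 1, seed = 1)
#' d$geno[, 6]  # final column: perfect block split 0,0,0,1,1,1
#' @export
make_dataset <- function(categories, rows = 1200L, cols = 1200L,
                         obs_start = 1001L, seed = NULL) {
  categories <- as.integer(categories)
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(categories >= 2L, cols >= 1L, rows >= categories)
  if (rows %% categories != 0L) {
    stop("'rows' must be divisible by 'categories' (equal-sized blocks)")
  }
  if (!is.null(seed)) set.seed(seed)

  bh <- rows %/% categories
  nblue <- as.integer(round(seq_len(cols) * bh / cols))  # per block, per column
  geno <- matrix(0L, rows, cols)
  blue <- matrix(FALSE, rows, cols)
  for (b in seq_len(categories)) {
    offset <- (b - 1L) * bh
    for (j in seq_len(cols)) {
      nb <- nblue[j]
      if (nb > 0L) {
        geno[offset + seq_len(nb), j] <- b - 1L
        blue[offset + seq_len(nb), j] <- TRUE
      }
      if (nb < bh) {
        geno[offset + (nb + 1L):bh, j] <-
          sample.int(categories, bh - nb, replace = TRUE) - 1L
      }
    }
  }
  structure(
    list(observations = as.numeric(obs_start + 0:(rows - 1L)),
         geno = geno, blue_mask = blue, categories = categories,
         rows = rows, cols = cols, obs_start = obs_start, seed = seed),
    class = "ha_simdata")
}

#' @export
print.ha_simdata <- function(x, ...) {
  cat(sprintf(
    "Simulated dataset: %d x %d, %d categories, observations %g..%g, seed %s\n",
    x$rows, x$cols, x$categories, x$observations[1],
    x$observations[x$rows], if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Replicated per-column HA and F-test profiles for one design
#'
#' Regenerates the triangle-patterned dataset `replicates` times (replicate
#' `r` uses seed `base_seed + r`), scans every column with [ha_columns()],
#' and averages the per-column HA-coefficients and `-log10(p)` values across
#' replicates. Columns whose HA is undefined in some replicate (tied
#' category means can occur by chance in weakly structured columns) are
#' excluded from that replicate's average and counted.
#'
#' @inheritParams make_dataset
#' @param replicates number of replicate datasets (reference design: 100).
#' @param base_seed integer; replicate `r` is generated with seed
#'   `base_seed + r`.
#' @param aggregation HA aggregate passed to [ha_columns()].
#' @return An object of class `ha_simprofile`: list with `ha_profile` and
#'   `nlp_profile` (per-column means across replicates), `final_saturated`
#'   (fraction of replicates whose final column had a saturated p-value),
#'   `skipped` (per-column count of replicate/column pairs excluded as
#'   undefined), `categories`, `rows`, `cols`, `obs_start`, `replicates`,
#'   `seeds`, `aggregation`.
#' @examples
#' pr <- run_replicates(2, rows = 60, cols = 30, obs_start = 1,
#'                      replicates = 3, base_seed = 1)
#' tail(pr$ha_profile, 1)  # exactly 1: final column is perfectly sorted
#' @export
run_replicates <- function(categories, rows = 1200L, cols = 1200L,
                           obs_start = 1001L, replicates = 100L,
                           base_seed = 1L,
                           aggregation = c("geometric", "arithmetic")) {
  aggregation <- match.arg(aggregation)
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  seeds <- base_seed + seq_len(replicates)

  ha_sum <- numeric(cols); ha_n <- integer(cols)
  nlp_sum <- numeric(cols); nlp_n <- integer(cols)
  skipped <- integer(cols)
  final_sat <- 0L
  for (r in seq_len(replicates)) {
    d <- make_dataset(categories, rows, cols, obs_start, seed = seeds[r])
    sc <- ha_columns(d$observations, d$geno, aggregation = aggregation)
    ok <- sc$status == "ok"
    skipped <- skipped + !ok
    ha_sum[ok] <- ha_sum[ok] + sc$ha[ok]
    ha_n[ok] <- ha_n[ok] + 1L
    nlp_sum[ok] <- nlp_sum[ok] + sc$neg_log10_p[ok]
    nlp_n[ok] <- nlp_n[ok] + 1L
    final_sat <- final_sat + sc$saturated[cols]
  }
  total_skipped <- sum(skipped)
  if (total_skipped > 0L) {
    ha_log(sprintf(
      "%d of %d column evaluations undefined (tied means or single category) and excluded from averages",
      total_skipped, replicates * cols), level = "WARN")
  }
  structure(
    list(ha_profile = ifelse(ha_n > 0L, ha_sum / ha_n, NA_real_),
         nlp_profile = ifelse(nlp_n > 0L, nlp_sum / nlp_n, NA_real_),
         final_saturated = final_sat / replicates,
         skipped = skipped, categories = categories, rows = rows,
         cols = cols, obs_start = obs_start, replicates = replicates,
         seeds = seeds, aggregation = aggregation),
    class = "ha_simprofile")
}

#' @export
print.ha_simprofile <- function(x, ...) {
  cat(sprintf(
    "Averaged profiles: %d categories, %d x %d, %d replicates\n",
    x$categories, x$rows, x$cols, x$replicates))
  cat(sprintf("  HA profile: min %.4f, max %.4f, final %.6f\n",
              min(x$ha_profile, na.rm = TRUE),
              max(x$ha_profile, na.rm = TRUE),
              x$ha_profile[x$cols]))
  invisible(x)
}

#' Cross-design agreement of HA profiles
#'
#' Runs [run_replicates()] for several category counts under matched
#' parameters and computes the pairwise Pearson correlations of the averaged
#' HA profiles. Because the designs share the same observations and the
#' same linear growth of the deterministic fraction, a sound association
#' statistic should trace essentially the same profile regardless of how
#' many identifier types fill the matrix -- the correlations sit above
#' 0.999 at the 1200 x 1200 / 100-replicate reference scale.
#'
#' @inheritParams run_replicates
#' @param categories integer vector of category counts (default `c(2, 3, 4)`).
#' @return An object of class `ha_simsummary`: list with `profiles` (one
#'   `ha_simprofile` per category count, named `c2`, `c3`, ...),
#'   `correlations` (symmetric Pearson matrix of the HA profiles), and the
#'   shared parameters.
#' @examples
#' s <- compare_variants(rows = 60, cols = 40, obs_start = 1,
#'                       replicates = 2, base_seed = 1)
#' s$correlations
#' @export
compare_variants <- function(rows = 1200L, cols = 1200L, obs_start = 1001L,
                             replicates = 100L, base_seed = 1L,
                             categories = c(2L, 3L, 4L),
                             aggregation = c("geometric", "arithmetic")) {
  aggregation <- match.arg(aggregation)
  profiles <- lapply(categories, function(cc) {
    run_replicates(cc, rows = rows, cols = cols, obs_start = obs_start,
                   replicates = replicates, base_seed = base_seed,
                   aggregation = aggregation)
  })
  names(profiles) <- paste0("c", categories)
  mat <- vapply(profiles, `[[`, numeric(cols), "ha_profile")
  correlations <- stats::cor(mat, use = "complete.obs")
  structure(
    list(profiles = profiles, correlations = correlations,
         rows = rows, cols = cols, obs_start = obs_start,
         replicates = replicates, base_seed = base_seed,
         categories = categories, aggregation = aggregation),
    class = "ha_simsummary")
}

#' @export
print.ha_simsummary <- function(x, digits = 6, ...) {
  cat(sprintf(
    "Simulation summary: %d x %d, %d replicates, categories {%s}\n",
    x$rows, x$cols, x$replicates, paste(x$categories, collapse = ", ")))
  cat("Pearson correlations of averaged HA profiles:\n")
  print(signif(x$correlations, digits))
  invisible(x)
}

#' Write simulation summary tables
#'
#' Writes two TSV files into `dir`: `profiles.tsv` with one row per column
#' index and the averaged HA and `-log10(p)` profiles of each design, and
#' `correlations.tsv` with the pairwise Pearson matrix of the HA profiles.
#'
#' @param x an `ha_simsummary` from [compare_variants()].
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_sim_summary <- function(x, dir) {
  stopifnot(inherits(x, "ha_simsummary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof <- data.frame(column_index = seq_len(x$cols))
  for (nm in names(x$profiles)) {
    prof[[paste0("ha_mean_", nm)]] <- x$profiles[[nm]]$ha_profile
    prof[[paste0("nlp_mean_", nm)]] <- x$profiles[[nm]]$nlp_profile
  }
  p1 <- file.path(dir, "profiles.tsv")
  utils::write.table(prof, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "correlations.tsv")
  utils::write.table(
    data.frame(design = rownames(x$correlations), x$correlations,
               check.names = FALSE),
    p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(profiles = p1, correlations = p2))
}

#' Plot averaged simulation profiles
#'
#' Line plot of the averaged per-column HA profiles (left axis) for each
#' design in an `ha_simsummary`, drawn with base graphics.
#'
#' @param x an `ha_simsummary`.
#' @param what `"ha"` or `"nlp"` profile.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ha_simsummary <- function(x, what = c("ha", "nlp"), ...) {
  what <- match.arg(what)
  field <- if (what == "ha") "ha_profile" else "nlp_profile"
  mat <- vapply(x$profiles, `[[`, numeric(x$cols), field)
  graphics::matplot(seq_len(x$cols), mat, type = "l", lty = 1,
                    xlab = "column index",
                    ylab = if (what == "ha") "mean HA-coefficient"
                           else "mean -log10(p)", ...)
  graphics::legend("bottomright", legend = names(x$profiles),
                   col = seq_along(x$profiles), lty = 1, bty = "n")
  invisible(x)
}
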