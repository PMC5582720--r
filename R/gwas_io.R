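#' Read a phenotype table
#'
#' Reads a two-column TSV (sample id, trait value) into a named numeric
#' vector. Values that read as `NA` are kept as missing and excluded
#' per-marker at scan time; positivity is also validated at scan time, not
#' here.
#'
#' @param path path to the TSV file.
#' @param header whether the file has a header line.
#' @param sep field separator.
#' @return named numeric vector (names are sample ids; `NA` allowed).
#' @export
read_phenotype <- function(path, header = TRUE, sep = "\t") {
  tab <- utils::read.table(path, header = header, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("phenotype table needs two columns: sample_id, value")
  ids <- tab[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sample id(s) in phenotype table: ",
         paste(unique(dup), collapse = ", "))
  }
  raw <- tab[[2]]
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals) & !(is.na(raw) | raw %in% c("NA", "", ".")))
  if (length(bad)) {
    stop(sprintf("unparseable phenotype value '%s' at data row %d", raw[bad[1]], bad[1]))
  }
  stats::setNames(vals, ids)
}

#' Read a genotype/marker table
#'
#' Two dialects. `format = "tsv"`: rows are samples, the first column is the
#' sample id, remaining columns are markers; `NA`, empty and `.` entries are
#' missing. `format = "vcf"` (requires the vcfR package): biallelic sites
#' only, with the GT field mapped to allele-dosage categories 0/0 -> 0, 0/1
#' or 1/0 -> 1, 1/1 -> 2, missing -> `NA`; phased separators are accepted
#' and multiallelic records are skipped with a logged count. The dosage
#' coding keeps heterozygotes as their own category (the HA-coefficient
#' treats categories as unordered, so no genotype collapsing is applied).
#'
#' @param path input path.
#' @param format `"tsv"` or `"vcf"`.
#' @param header for TSV: whether a header row is present; without one,
#'   markers are named `M1..Mk`.
#' @return An object of class `marker_table`: list with `sample_ids`,
#'   `markers`, and `calls`, a samples x markers character matrix with `NA`
#'   for missing calls.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), header = TRUE) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = header, sep = "\t",
                             colClasses = "character", check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("genotype table needs a sample_id column plus markers")
    ids <- tab[[1]]
    if (anyDuplicated(ids)) stop("duplicate sample ids in genotype table")
    calls <- as.matrix(tab[, -1, drop = FALSE])
    calls[calls %in% c("NA", "", ".")] <- NA_character_
    rownames(calls) <- ids
    if (!header) colnames(calls) <- paste0("M", seq_len(ncol(calls)))
  } else {
    calls <- read_vcf_gt(path)
    ids <- rownames(calls)
  }
  structure(
    list(sample_ids = ids, markers = colnames(calls), calls = calls),
    class = "marker_table")
}

# minimal VCF -> dosage matrix via vcfR; biallelic records only
read_vcf_gt <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    ha_log(sprintf("skipping %d multiallelic VCF record(s)", sum(multi)),
           level = "WARN")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")   # markers x samples
  if (is.null(gt) || nrow(gt) == 0L) stop("no usable biallelic GT records in VCF")
  core <- sub(":.*$", "", gt)
  core <- gsub("|", "/", core, fixed = TRUE)
  dosage <- matrix(NA_character_, nrow(core), ncol(core),
                   dimnames = dimnames(core))
  dosage[core == "0/0"] <- "0"
  dosage[core %in% c("0/1", "1/0")] <- "1"
  dosage[core == "1/1"] <- "2"
  ids <- vcfR::getID(v)
  if (is.null(ids) || anyNA(ids) || anyDuplicated(ids[!is.na(ids)])) {
    ids <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
  }
  rownames(dosage) <- make.unique(ids)
  t(dosage)                                   # samples x markers
}

#' @export
print.marker_table <- function(x, ...) {
  cat(sprintf("Marker table: %d samples x %d markers (%.1f%% missing)\n",
              length(x$sample_ids), length(x$markers),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Per-marker association scan
#'
#' For every marker, aligns samples by id with the phenotype, drops samples
#' missing in either input, drops categories smaller than
#' `min_category_size`, and computes the HA-coefficient (both aggregates)
#' and the one-way ANOVA F-test on the remainder. One record per marker is
#' emitted regardless of status; markers where the coefficient is undefined
#' (monomorphic after filtering, tied category means, nonpositive
#' observations) carry `NA` statistics and the reason in `status`. No
#' multiple-testing correction is applied: the p-values are per-marker.
#'
#' @param pheno named numeric vector from [read_phenotype()].
#' @param geno a `marker_table` from [read_genotypes()].
#' @param aggregation HA aggregate reported in `ha` by downstream tools;
#'   both aggregates are always present in the records.
#' @param tie_tol relative tied-means tolerance (see [stratify()]).
#' @param min_category_size categories with fewer members are dropped (not
#'   merged) before the statistics are computed; the default 1 imposes no
#'   floor.
#' @return A data.frame of class `ha_scan` with one row per marker:
#'   `marker`, `n_used`, `n_categories`, `ha_geometric`, `ha_arithmetic`,
#'   `f_stat`, `p_value`, `neg_log10_p`, `saturated`, `status`.
#' @export
ha_scan <- function(pheno, geno, aggregation = c("geometric", "arithmetic"),
                    tie_tol = 1e-12, min_category_size = 1L) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(geno, "marker_table"))
  pheno <- pheno[!is.na(pheno)]
  common <- intersect(names(pheno), geno$sample_ids)
  if (length(common) == 0L) {
    stop("no samples shared between phenotype and genotype inputs")
  }
  ha_log(sprintf("%d shared sample(s); %d phenotype-only, %d genotype-only",
                 length(common), length(setdiff(names(pheno), common)),
                 length(setdiff(geno$sample_ids, common))))
  calls <- geno$calls[common, , drop = FALSE]
  ph <- pheno[common]

  dropped_small <- 0L
  rec <- lapply(seq_along(geno$markers), function(mi) {
    g <- calls[, mi]
    keep <- !is.na(g)
    if (min_category_size > 1L && any(keep)) {
      sizes <- table(g[keep])
      small <- names(sizes)[sizes < min_category_size]
      if (length(small)) {
        dropped_small <<- dropped_small + length(small)
        keep <- keep & !(g %in% small)
      }
    }
    obs <- ph[keep]
    cats <- g[keep]
    base <- list(marker = geno$markers[mi], n_used = sum(keep),
                 n_categories = length(unique(cats)),
                 ha_geometric = NA_real_, ha_arithmetic = NA_real_,
                 f_stat = NA_real_, p_value = NA_real_,
                 neg_log10_p = NA_real_, saturated = FALSE)
    res <- ha_coefficient(obs, cats, aggregation = aggregation,
                          tie_tol = tie_tol)
    base$status <- res$status
    if (res$status != "ok") return(base)
    base$ha_geometric <- res$ha_geometric
    base$ha_arithmetic <- res$ha_arithmetic
    if (length(obs) - length(unique(cats)) >= 1L) {  # F needs residual df
      fv <- anova_f(obs, cats)
      base$f_stat <- fv$f_stat
      base$p_value <- fv$p_value
      base$neg_log10_p <- fv$neg_log10_p
      base$saturated <- fv$saturated
    }
    base
  })
  if (dropped_small > 0L) {
    ha_log(sprintf("dropped %d undersized categor(ies) (min_category_size = %d)",
                   dropped_small, min_category_size))
  }
  out <- do.call(rbind, lapply(rec, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  class(out) <- c("ha_scan", class(out))
  out
}

#' Write / read a scan table
#'
#' `write_scan()` serializes an [ha_scan()] result as TSV with numbers at
#' `digits` significant digits (raise `digits` for lossless round-trips);
#' `read_scan()` restores it with correct column types.
#'
#' @param x an `ha_scan` data.frame.
#' @param path output/input path.
#' @param digits significant digits for numeric fields.
#' @return `write_scan()`: the path, invisibly. `read_scan()`: the restored
#'   data.frame.
#' @export
write_scan <- function(x, path, digits = 6) {
  out <- as.data.frame(x)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(marker = "character",
                                          status = "character"),
                           stringsAsFactors = FALSE)
  class(out) <- c("ha_scan", class(out))
  out
}
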