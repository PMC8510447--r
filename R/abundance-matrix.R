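#' Abundance matrix container
#'
#' An `abundance_matrix` holds a metabolite-by-sample grid of mass-spectrometry
#' abundances together with its missingness information. Missing entries are
#' stored as `NA`; the observed set (often written \eqn{\Omega}) is simply the
#' complement of the `NA` positions. On the raw scale every observed value must
#' be strictly positive, which is what makes the data admissible for
#' non-negative factorization after a log10 transform.
#'
#' @param values numeric matrix, metabolites in rows and samples in columns,
#'   with `NA` marking missing entries. Must carry unique row and column names.
#' @param scale `"raw"` (intensities) or `"log10"` (log-transformed, possibly
#'   shifted by `offset`).
#' @param offset non-negative shift that was added after the log10 transform to
#'   keep values non-negative; 0 on the raw scale.
#'
#' @return an object of class `abundance_matrix`: a list with elements
#'   `values`, `scale`, `offset`.
#' @export
abundance_matrix <- function(values, scale = c("raw", "log10"), offset = 0) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("abundance matrix needs at least 2 metabolites and 2 samples")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("metabolite (row) and sample (column) identifiers are required")
  if (anyDuplicated(rownames(values)))
    stop("duplicate metabolite identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  obs <- !is.na(values)
  if (!any(obs))
    stop("matrix has no observed entries")
  if (scale == "raw" && any(values[obs] <= 0))
    stop("raw-scale observed abundances must be strictly positive")
  if (any(!is.finite(values[obs])))
    stop("observed abundances must be finite")
  structure(list(values = values, scale = scale, offset = offset),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("abundance_matrix: %d metabolites x %d samples (%s scale)\n",
              nrow(v), ncol(v), x$scale))
  cat(sprintf("  observed: %d / %d (%.1f%% missing)\n",
              sum(!is.na(v)), length(v), 100 * mean(is.na(v))))
  if (x$offset != 0) cat(sprintf("  log10 offset: %g\n", x$offset))
  invisible(x)
}

#' Observed-entry mask
#' @param m an `abundance_matrix`
#' @return logical matrix, `TRUE` where the entry is observed
#' @export
observed_mask <- function(m) !is.na(m$values)

#' Number of observed entries
#' @param m an `abundance_matrix`
#' @export
n_observed <- function(m) sum(!is.na(m$values))

#' Per-metabolite missing fraction
#' @param m an `abundance_matrix`
#' @return named numeric vector, one fraction per metabolite
#' @export
missing_fraction <- function(m) rowMeans(is.na(m$values))

# log10 values of the observed entries regardless of stored scale; the offset
# is removed so the result is always a true log10 abundance.
log10_values <- function(m) {
  v <- m$values
  if (m$scale == "raw") log10(v) else v - m$offset
}

#' Read an abundance matrix from delimited text
#'
#' Reads a CSV/TSV table with one header row of identifiers and one leading
#' identifier column. Cells matching an NA token, or numerically equal to
#' zero, become missing: zero intensities are the usual LC-MS convention for
#' non-detection and are undefined under log10.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything else
#'   comma-separated.
#' @param orientation `"metabolites_in_rows"` (default, canonical) or
#'   `"metabolites_in_columns"` (the table is transposed on load).
#' @param na_tokens strings treated as missing in addition to numeric zero.
#' @param quiet suppress the load report.
#' @return an `abundance_matrix` on the raw scale.
#' @export
load_matrix <- function(path,
                        orientation = c("metabolites_in_rows",
                                        "metabolites_in_columns"),
                        na_tokens = c("", "NA", "NaN", "0"),
                        quiet = FALSE) {
  orientation <- match.arg(orientation)
  if (length(na_tokens) == 0L) stop("`na_tokens` must be non-empty")
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, comment.char = "",
                           stringsAsFactors = FALSE)
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) stop("duplicate row identifiers in ", path)
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(cells) <- ids
  cells[trimws(cells) %in% na_tokens] <- NA_character_
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                dimnames = dimnames(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at row '%s', column '%s'",
                 rownames(cells)[bad[1, 1]], colnames(cells)[bad[1, 2]]))
  if (any(num < 0, na.rm = TRUE))
    stop("negative abundance found; matrix must be non-negative")
  zero_coerced <- sum(num == 0, na.rm = TRUE)
  num[!is.na(num) & num == 0] <- NA_real_
  if (orientation == "metabolites_in_columns") num <- t(num)
  m <- abundance_matrix(num, scale = "raw")
  if (!quiet)
    message(sprintf(
      "loaded %d metabolites x %d samples; NA fraction %.3f; %d zero(s) coerced to NA",
      nrow(num), ncol(num), mean(is.na(num)), zero_coerced))
  m
}

#' Write an abundance matrix to delimited text
#'
#' Writes a CSV (or TSV) with sample identifiers in the header and metabolite
#' identifiers in the first column; missing entries are left empty. A JSON
#' sidecar `<path>.json` records the scale and log10 offset so a written
#' log-scale matrix can be inverted exactly.
#'
#' @param m an `abundance_matrix`
#' @param path output path; extension selects the separator as in
#'   [load_matrix()].
#' @param sidecar write the provenance sidecar (default `TRUE`).
#' @return `path`, invisibly
#' @export
write_matrix <- function(m, path, sidecar = TRUE) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(metabolite = rownames(m$values), m$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  if (sidecar)
    jsonlite::write_json(list(scale = m$scale, offset = m$offset,
                              n_metabolites = nrow(m$values),
                              n_samples = ncol(m$values)),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Remove metabolites exceeding a missingness threshold
#'
#' The "30% deletion" rule common in metabolomics preprocessing: metabolites
#' whose missing fraction is strictly above the threshold are dropped so that
#' imputation operates on a reasonable scale. A metabolite at exactly the
#' threshold is retained.
#'
#' @param m an `abundance_matrix`
#' @param threshold maximum tolerated missing fraction, default 0.30
#' @param quiet suppress the removal report
#' @return the filtered `abundance_matrix`; the sample axis is untouched
#' @export
filter_by_missing_fraction <- function(m, threshold = 0.30, quiet = FALSE) {
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  frac <- missing_fraction(m)
  keep <- frac <= threshold
  if (!any(keep))
    stop("empty matrix after 30% deletion: no metabolite has missing fraction <= ",
         threshold)
  if (!quiet && any(!keep))
    message(sprintf("removed %d metabolite(s) with missing fraction > %g: %s",
                    sum(!keep), threshold,
                    paste(utils::head(names(frac)[!keep], 10), collapse = ", ")))
  abundance_matrix(m$values[keep, , drop = FALSE], scale = m$scale,
                   offset = m$offset)
}

#' Log10 transform with a non-negativity offset
#'
#' Takes entrywise log10 of a raw-scale matrix and, when the smallest observed
#' log10 value is negative, adds the smallest integer offset that brings every
#' entry to at least zero. Non-negative log data is what the factorization
#' constraint (B, C >= 0) requires; the offset is recorded on the object so
#' that [inverse_log10()] recovers the raw scale exactly.
#'
#' @param m raw-scale `abundance_matrix`, all observed values > 0
#' @return log10-scale `abundance_matrix` with its `offset` field set
#' @export
log10_transform <- function(m) {
  if (m$scale != "raw") stop("matrix already on log10 scale")
  obs <- !is.na(m$values)
  if (any(m$values[obs] <= 0)) stop("non-positive observed value")
  lv <- log10(m$values)
  offset <- max(0, -floor(min(lv[obs])))
  abundance_matrix(lv + offset, scale = "log10", offset = offset)
}

#' Invert a log10 transform
#'
#' Entrywise 10^(value - offset), restoring the raw intensity scale.
#'
#' @param m log10-scale `abundance_matrix`
#' @param offset the recorded offset; defaults to the one stored on `m`
#' @return raw-scale `abundance_matrix`
#' @export
inverse_log10 <- function(m, offset = m$offset) {
  if (m$scale != "log10") stop("matrix is not on log10 scale")
  abundance_matrix(10^(m$values - offset), scale = "raw")
}

#' Missingness profile over log-abundance intervals
#'
#' Splits the observed log10-abundance range evenly into `n_intervals` bins
#' and reports, per bin, how many entries fall in it and what percentage of
#' them are missing. Missing entries have no abundance of their own, so they
#' are attributed to a bin either by their true value (when the complete
#' reference matrix `truth` is available, i.e. in simulations) or, for real
#' data, by the median observed log-abundance of their metabolite.
#'
#' @param m an `abundance_matrix`
#' @param n_intervals number of equal-width bins, default 20
#' @param truth optional complete raw-scale `abundance_matrix` of the same
#'   shape supplying true values for missing cells
#' @return an `interval_profile`: list with `n_intervals`, `bin_edges`
#'   (length `n_intervals + 1`), `counts`, `missing_counts`, `missing_pct`
#' @export
missingness_profile <- function(m, n_intervals = 20L, truth = NULL) {
  if (n_intervals < 1L) stop("`n_intervals` must be >= 1")
  lv <- log10_values(m)
  obs <- !is.na(m$values)
  rng <- range(lv[obs])
  if (diff(rng) == 0) {
    warning("constant matrix: degenerate single bin")
    n_intervals <- 1L
    edges <- c(rng[1], rng[1])
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_intervals + 1L)
  }
  # bin index for a vector of log10 abundances; values clamped into range
  bin_of <- function(v) {
    if (n_intervals == 1L) return(rep(1L, length(v)))
    b <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
    pmin(pmax(b, 1L), n_intervals)
  }
  obs_bins <- bin_of(lv[obs])
  if (is.null(truth)) {
    med <- apply(lv, 1L, function(r) stats::median(r[!is.na(r)]))
    miss_idx <- which(!obs, arr.ind = TRUE)
    miss_vals <- med[miss_idx[, 1L]]
  } else {
    stopifnot(identical(dim(truth$values), dim(m$values)))
    tl <- log10_values(truth)
    miss_vals <- tl[!obs]
  }
  miss_bins <- bin_of(miss_vals[is.finite(miss_vals)])
  counts <- tabulate(obs_bins, n_intervals) + tabulate(miss_bins, n_intervals)
  missing_counts <- tabulate(miss_bins, n_intervals)
  structure(list(n_intervals = n_intervals, bin_edges = edges,
                 counts = counts, missing_counts = missing_counts,
                 missing_pct = 100 * missing_counts / pmax(counts, 1L)),
            class = "interval_profile")
}

#' @export
print.interval_profile <- function(x, ...) {
  cat(sprintf("interval_profile: %d bins over log10 range [%.3g, %.3g]\n",
              x$n_intervals, x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)]))
  cat(sprintf("  total missing attributed: %d\n", sum(x$missing_counts)))
  invisible(x)
}

#' Generate a synthetic low-rank abundance fixture
#'
#' Builds a complete, strictly positive metabolite-by-sample matrix on the
#' log10 scale as a rank-`rank` structure plus noise: the first latent
#' component is each metabolite's characteristic log10 abundance (drawn
#' N(3.5, 1), i.e. a log-normal abundance spread across metabolites covering
#' several decades, constant across samples), the remaining `rank - 1`
#' components are half-normal basis/weight products rescaled so the
#' within-metabolite biological variation averages ~0.35 decades, and e is
#' i.i.d. Gaussian measurement noise of SD `noise_sd` on the log10 scale.
#' The raw matrix is 10^L. With `noise_sd = 0` the log10 matrix has
#' numerical rank exactly `rank`. This emulates the structure of MS
#' intensity tables: a wide between-metabolite dynamic range, correlated
#' fractional variation between samples, multiplicative technical noise.
#'
#' @param i,j numbers of metabolites and samples
#' @param rank latent rank, 1 <= rank <= min(i, j)
#' @param noise_sd SD of the log10-scale noise; default 0.1, a moderate
#'   technical-replicate spread for LC-MS intensities
#' @param seed integer seed; the fixture is a pure function of its arguments
#' @return a complete raw-scale `abundance_matrix`
#' @export
generate_fixture <- function(i, j, rank, noise_sd = 0.1, seed = 1L) {
  if (rank < 1L || rank > min(i, j))
    stop("`rank` must satisfy 1 <= rank <= min(i, j)")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- matrix(stats::rnorm(i, 3.5, 1), i, j)   # per-metabolite base abundance
  if (rank > 1L) {
    B <- matrix(abs(stats::rnorm(i * (rank - 1L))), i, rank - 1L)
    C <- matrix(abs(stats::rnorm((rank - 1L) * j)), rank - 1L, j)
    V <- B %*% C
    V <- V * (0.35 / mean(apply(V, 1L, stats::sd)))
    L <- L + V
  }
  if (noise_sd > 0) L <- L + matrix(stats::rnorm(i * j, 0, noise_sd), i, j)
  v <- 10^L
  dimnames(v) <- list(sprintf("met%03d", seq_len(i)),
                      sprintf("s%02d", seq_len(j)))
  abundance_matrix(v, scale = "raw")
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
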