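#' Metabolite-mean imputation
#'
#' Each missing entry is replaced by the observed mean of its metabolite.
#' The simplest fixed-value baseline; it ignores between-metabolite structure
#' entirely.
#'
#' @param x an `abundance_matrix` with every metabolite observed at least once
#' @return an `imputation_result`
#' @export
impute_mean <- function(x) {
  v <- x$values
  if (any(rowSums(!is.na(v)) == 0L)) stop("metabolite with no observed values")
  fill <- rowMeans(v, na.rm = TRUE)
  impute_rowwise(x, fill, "mean")
}

#' Half-minimum imputation
#'
#' Each missing entry is replaced by half the observed minimum of its
#' metabolite: a left-censoring heuristic common in metabolomics, built on
#' the assumption that a value is missing because it fell below detection.
#'
#' @inheritParams impute_mean
#' @return an `imputation_result`
#' @export
impute_half_min <- function(x) {
  v <- x$values
  if (any(rowSums(!is.na(v)) == 0L)) stop("metabolite with no observed values")
  fill <- apply(v, 1L, function(r) min(r, na.rm = TRUE) / 2)
  impute_rowwise(x, fill, "halfmin")
}

impute_rowwise <- function(x, fill, method) {
  v <- x$values
  mask <- is.na(v)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- fill[idx[, 1L]]
  new_imputation_result(v, mask, method)
}

#' Sample-wise k-nearest-neighbour imputation
#'
#' For a missing entry (i, j), the distance from sample j to every other
#' sample is the Euclidean distance over the metabolites observed in both,
#' computed on log10 abundances so high-intensity metabolites do not
#' dominate; the k nearest samples in which metabolite i is observed donate
#' their values, and the imputed value is their unweighted mean. Distance
#' ties are broken by sample index so the method is fully deterministic; if
#' no donor exists the metabolite's observed mean is used.
#'
#' @param x an `abundance_matrix`
#' @param k number of neighbours, default 10; must be < number of samples
#' @return an `imputation_result`
#' @export
impute_knn <- function(x, k = 10L) {
  v <- x$values
  J <- ncol(v)
  if (k >= J) stop("`k` must be smaller than the number of samples")
  if (k < 1L) stop("`k` must be >= 1")
  obs <- !is.na(v)
  lv <- log10_values(x)
  # pairwise-complete Euclidean distances between samples, log10 scale
  D <- matrix(Inf, J, J)
  for (a in seq_len(J - 1L)) {
    for (b in (a + 1L):J) {
      shared <- obs[, a] & obs[, b]
      if (any(shared))
        D[a, b] <- D[b, a] <- sqrt(sum((lv[shared, a] - lv[shared, b])^2))
    }
  }
  row_mean <- rowMeans(v, na.rm = TRUE)
  out <- v
  na_idx <- which(!obs, arr.ind = TRUE)
  for (t in seq_len(nrow(na_idx))) {
    i <- na_idx[t, 1L]; j <- na_idx[t, 2L]
    donors <- which(obs[i, ] & seq_len(J) != j & is.finite(D[, j]))
    if (length(donors) == 0L) {
      out[i, j] <- row_mean[i]
      next
    }
    ord <- donors[order(D[donors, j], donors)]
    nn <- ord[seq_len(min(k, length(ord)))]
    out[i, j] <- mean(v[i, nn])
  }
  new_imputation_result(out, !obs, "knn")
}

#' Iterative random-forest imputation
#'
#' Chained random-forest imputation in the missForest style: metabolites are
#' visited in order of increasing missingness; each one with NAs is regressed
#' (via \pkg{randomForest}) on all other metabolites over the samples where
#' it is observed, and its missing samples are predicted. Sweeps repeat until
#' the normalized change in the imputed entries increases (the previous sweep
#' is then kept) or `max_iter` sweeps have run. Regression is carried out on
#' log10 abundances, the scale on which metabolite relationships are close
#' to linear, and predictions are back-transformed. The forests themselves
#' come from the \pkg{randomForest} package; only the chaining loop lives
#' here.
#'
#' @param x an `abundance_matrix`
#' @param max_iter maximum sweeps, default 10
#' @param seed integer seed (forests are stochastic)
#' @param ntree trees per forest, default 100
#' @return an `imputation_result`
#' @export
impute_rf <- function(x, max_iter = 10L, seed = 1L, ntree = 100L) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("impute_rf needs the 'randomForest' package; install it or drop ",
         "'rf' from the method list")
  v <- x$values
  mask <- is.na(v)
  if (!any(mask)) return(new_imputation_result(v, mask, "rf", seed))
  if (any(rowSums(!mask) == 0L)) stop("metabolite with no observed values")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # samples as observations, metabolites as variables, log10 scale
  X <- t(log10_values(x))
  Xm <- t(mask)
  cur <- X
  rm <- colMeans(X, na.rm = TRUE)
  for (p in seq_len(ncol(X))) cur[Xm[, p], p] <- rm[p]
  visit <- order(colSums(Xm))
  visit <- visit[colSums(Xm)[visit] > 0L]
  prev_diff <- Inf
  best <- cur
  for (it in seq_len(max_iter)) {
    last <- cur
    for (p in visit) {
      yobs <- !Xm[, p]
      fit <- randomForest::randomForest(
        x = cur[yobs, -p, drop = FALSE], y = X[yobs, p], ntree = ntree)
      cur[!yobs, p] <- stats::predict(fit, cur[!yobs, -p, drop = FALSE])
    }
    imp <- cur[Xm]
    diff <- sum((imp - last[Xm])^2) / max(sum(imp^2), .Machine$double.eps)
    if (diff >= prev_diff) { cur <- last; break }
    prev_diff <- diff
    best <- cur
  }
  out <- if (x$scale == "raw") 10^t(best) else t(best) + x$offset
  out[!mask] <- v[!mask]
  dimnames(out) <- dimnames(v)
  new_imputation_result(out, mask, "rf", seed)
}

# registry used by the benchmark driver
imputer_registry <- function(cfg = list()) {
  list(
    mean    = function(x, seed) impute_mean(x),
    halfmin = function(x, seed) impute_half_min(x),
    knn     = function(x, seed) impute_knn(x, k = cfg$knn_k %||% 10L),
    rf      = function(x, seed) impute_rf(x, max_iter = cfg$rf_max_iter %||% 10L,
                                          seed = seed,
                                          ntree = cfg$rf_ntree %||% 100L),
    nmf     = function(x, seed) nmf_impute(x, n_models = cfg$n_models %||% 20L,
                                           seed = seed,
                                           tol = cfg$tol %||% 1e-6,
                                           max_iter = cfg$max_iter %||% 500L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
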