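#' Normalized root mean square error on simulated missing entries
#'
#' NRMSE = sqrt( (1/|Theta_s|) * sum over Theta_s of
#' ((x_ij - xtilde_ij) / x_ij)^2 ): the root mean square of the relative
#' imputation errors at the artificially removed positions. The relative
#' (ratio) form makes the metric invariant to a global intensity rescaling,
#' which suits abundances spanning several decades. Computed on the raw
#' scale by default; `scale = "log10"` applies the same formula to log10
#' abundances instead.
#'
#' @param truth complete `abundance_matrix` (raw scale) supplying the true
#'   values on `theta_s`
#' @param imputed an `imputation_result` (or completed matrix)
#' @param theta_s 2-column index matrix of simulated missing positions, as
#'   produced by the simulators
#' @param scale `"raw"` (default) or `"log10"`
#' @return the scalar NRMSE
#' @export
nrmse <- function(truth, imputed, theta_s, scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  if (is.null(nrow(theta_s)) || nrow(theta_s) == 0L)
    stop("`theta_s` is empty")
  xt <- completed_values(imputed)
  tv <- truth$values
  if (anyNA(tv[theta_s])) stop("truth is not complete on theta_s")
  if (scale == "log10") {
    tv <- log10(tv)
    xt <- log10(xt)
  }
  x <- tv[theta_s]
  if (any(x == 0)) stop("true value 0 in NRMSE denominator")
  sqrt(mean(((x - xt[theta_s]) / x)^2))
}

#' Build a correlation coefficient network
#'
#' Computes Pearson (or Spearman) correlations between every pair of
#' metabolites on the log10 scale and keeps an edge when |r| >= `r_min` and
#' the Benjamini-Hochberg-adjusted p-value is below `alpha`. Metabolites
#' still containing NAs are dropped first (a network needs complete
#' profiles); constant metabolites have no defined correlation and their
#' pairs are skipped with a warning.
#'
#' @param m an `abundance_matrix` or `imputation_result`; raw-scale values
#'   are log10-transformed internally
#' @param r_min minimum absolute correlation, default 0.6
#' @param alpha BH-adjusted significance level, default 0.05
#' @param method `"pearson"` (default) or `"spearman"`
#' @return an `edge_set`: list with `nodes` and an `edges` data frame
#'   (`from`, `to`, `r`, `p`, `padj`)
#' @export
build_ccn <- function(m, r_min = 0.6, alpha = 0.05,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (inherits(m, "imputation_result"))
    m <- abundance_matrix(m$X_tilde, scale = "raw")
  v <- log10_values(m)
  complete <- rowSums(is.na(v)) == 0L
  if (any(!complete)) {
    message(sprintf("build_ccn: dropped %d metabolite(s) containing NAs",
                    sum(!complete)))
    v <- v[complete, , drop = FALSE]
  }
  if (nrow(v) < 2L) stop("need >= 2 complete metabolites")
  if (ncol(v) < 3L) stop("need >= 3 samples")
  const <- apply(v, 1L, function(r) stats::sd(r) == 0)
  if (any(const))
    warning(sprintf("%d constant metabolite(s); their pairs skipped",
                    sum(const)))
  R <- suppressWarnings(stats::cor(t(v), method = method))
  n <- ncol(v)
  pair <- which(upper.tri(R), arr.ind = TRUE)
  ok <- !const[pair[, 1L]] & !const[pair[, 2L]]
  pair <- pair[ok, , drop = FALSE]
  r <- R[pair]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  padj <- stats::p.adjust(p, method = "BH")
  keep <- abs(r) >= r_min & padj < alpha
  edges <- data.frame(from = rownames(v)[pair[keep, 1L]],
                      to = rownames(v)[pair[keep, 2L]],
                      r = r[keep], p = p[keep], padj = padj[keep],
                      stringsAsFactors = FALSE)
  structure(list(nodes = rownames(v), edges = edges,
                 r_min = r_min, alpha = alpha, method = method),
            class = "edge_set")
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("edge_set: %d node(s), %d edge(s), sparsity %.4f\n",
              length(x$nodes), nrow(x$edges), sparsity(x)))
  invisible(x)
}

edge_keys <- function(e, nodes = NULL) {
  ed <- e$edges
  if (!is.null(nodes)) ed <- ed[ed$from %in% nodes & ed$to %in% nodes, ,
                                drop = FALSE]
  if (nrow(ed) == 0L) return(character(0))
  a <- pmin(ed$from, ed$to)
  b <- pmax(ed$from, ed$to)
  unique(paste(a, b, sep = "\r"))
}

#' Edge-recovery scores of a predicted network
#'
#' Compares the network rebuilt from imputed data against the network of the
#' complete data: TP are predicted edges present in the original, FP are
#' predicted edges absent from it, FN are original edges the prediction
#' missed. Precision = TP/(TP+FP), recall = TP/(TP+FN), and F1 is their
#' harmonic mean. When the two networks were built on different node sets,
#' the comparison is restricted to the shared nodes. Degenerate empty
#' denominators yield 0 with `degenerate = TRUE`.
#'
#' @param predicted,original `edge_set` objects
#' @return list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`,
#'   `degenerate`
#' @export
network_scores <- function(predicted, original) {
  nodes <- intersect(predicted$nodes, original$nodes)
  if (length(nodes) < length(union(predicted$nodes, original$nodes)))
    message(sprintf("network_scores: comparing on %d shared node(s)",
                    length(nodes)))
  pe <- edge_keys(predicted, nodes)
  oe <- edge_keys(original, nodes)
  tp <- length(intersect(pe, oe))
  fp <- length(setdiff(pe, oe))
  fn <- length(setdiff(oe, pe))
  degenerate <- (tp + fp == 0L) || (tp + fn == 0L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall /
          (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, degenerate = degenerate)
}

#' Network sparsity
#'
#' Fraction of possible metabolite pairs that are edges:
#' |edges| / (n (n-1) / 2).
#'
#' @param e an `edge_set`
#' @return sparsity in `[0, 1]`
#' @export
sparsity <- function(e) {
  n <- length(e$nodes)
  if (n < 2L) stop("need >= 2 nodes")
  nrow(e$edges) / choose(n, 2)
}

#' Mean score of ranking (MSR)
#'
#' A non-parametric head-to-head comparison of P >= 2 imputation methods.
#' For every simulated missing entry, the methods are ranked by the absolute
#' deviation of their imputed value from the truth (rank 1 = closest; ties
#' get the average of the tied ranks); MSR_p is method p's mean rank over
#' all entries. A method that always wins has MSR 1; with no ties the MSRs
#' sum to P(P+1)/2.
#'
#' @param truth complete `abundance_matrix`
#' @param imputations named list of >= 2 `imputation_result`s (or completed
#'   matrices)
#' @param theta_s 2-column index matrix of simulated missing positions
#' @return named numeric vector of MSR values, one per method
#' @export
msr <- function(truth, imputations, theta_s) {
  if (length(imputations) < 2L) stop("need >= 2 methods")
  if (is.null(names(imputations)) || anyDuplicated(names(imputations)))
    stop("`imputations` must be a uniquely named list")
  if (is.null(nrow(theta_s)) || nrow(theta_s) == 0L)
    stop("`theta_s` is empty")
  x <- truth$values[theta_s]
  if (anyNA(x)) stop("truth is not complete on theta_s")
  errs <- vapply(imputations,
                 function(im) abs(completed_values(im)[theta_s] - x),
                 numeric(nrow(theta_s)))
  if (nrow(theta_s) == 1L) errs <- matrix(errs, nrow = 1L,
                                          dimnames = list(NULL, names(imputations)))
  ranks <- t(apply(errs, 1L, rank))
  colMeans(ranks)
}
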