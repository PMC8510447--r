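#' Observed-entry squared loss of a factorization
#'
#' The masked NMF objective: sum over observed entries (i,j) of
#' (x_ij - sum_k b_ik c_kj)^2. Missing entries contribute nothing, which is
#' what lets the factorization be fit on incomplete data.
#'
#' @param x an `abundance_matrix` (log10 scale for the imputation pipeline)
#' @param f a `factor_pair` from [masked_nmf()], or any list with non-negative
#'   matrices `B` (I x K) and `C` (K x J)
#' @return the scalar observed loss
#' @export
observed_loss <- function(x, f) {
  obs <- !is.na(x$values)
  if (!any(obs)) stop("no observed entries")
  xhat <- f$B %*% f$C
  if (!identical(dim(xhat), dim(x$values))) stop("dimension mismatch")
  sum((x$values[obs] - xhat[obs])^2)
}

#' Masked non-negative matrix factorization
#'
#' Fits X ~ B C with B, C >= 0 by minimizing the squared loss restricted to
#' the observed entries, using multiplicative updates with a binary
#' observation mask W (the Lee-Seung rules adapted to the masked loss):
#' \deqn{B \leftarrow B \circ \frac{(W \circ X) C^T}{(W \circ (BC)) C^T},
#'       \quad
#'       C \leftarrow C \circ \frac{B^T (W \circ X)}{B^T (W \circ (BC))}.}
#' These updates never increase the observed loss. A 1e-12 guard in the
#' denominators avoids division by zero. Factors are initialized from
#' seeded uniforms scaled by sqrt(mean observed value / k), so a run is a
#' pure function of (x, k, seed).
#'
#' @param x log10-scale `abundance_matrix` with non-negative observed values;
#'   every metabolite must have at least one observed entry
#' @param k number of components, 1 <= k <= min(I, J)
#' @param seed integer seed for the initialization
#' @param tol convergence tolerance on the relative change of the observed
#'   loss between sweeps (default 1e-6)
#' @param max_iter maximum number of update sweeps (default 500)
#' @return a `factor_pair`: list with `B`, `C`, `K`, `converged`, `n_iter`,
#'   `final_loss`, and the per-iteration `loss_trace`
#' @export
masked_nmf <- function(x, k, seed = 1L, tol = 1e-6, max_iter = 500L) {
  v <- x$values
  I <- nrow(v); J <- ncol(v)
  if (k < 1L || k > min(I, J))
    stop("`k` must satisfy 1 <= k <= min(I, J)")
  obs <- !is.na(v)
  if (any(rowSums(obs) == 0L))
    stop("metabolite with zero observed entries; filter upstream")
  if (any(v[obs] < 0))
    stop("masked_nmf requires non-negative data (log10 + offset)")
  W <- obs * 1
  X0 <- v; X0[!obs] <- 0
  eps <- 1e-12

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sc <- sqrt(mean(v[obs]) / k)
  B <- matrix(pmax(stats::runif(I * k), eps), I, k) * sc
  C <- matrix(pmax(stats::runif(k * J), eps), k, J) * sc

  WX <- W * X0
  loss_of <- function(B, C) sum((X0 - B %*% C)[obs]^2)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- loss_of(B, C)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    B <- B * (WX %*% t(C)) / ((W * (B %*% C)) %*% t(C) + eps)
    C <- C * (t(B) %*% WX) / (t(B) %*% (W * (B %*% C)) + eps)
    trace[it + 1L] <- loss_of(B, C)
    prev <- trace[it]
    if (prev <= 0 || abs(prev - trace[it + 1L]) / prev < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(B = B, C = C, K = as.integer(k), converged = converged,
                 n_iter = it, final_loss = trace[it + 1L],
                 loss_trace = trace[seq_len(it + 1L)]),
            class = "factor_pair")
}

#' @export
print.factor_pair <- function(x, ...) {
  cat(sprintf("factor_pair: K = %d, %d iteration(s), loss %.6g%s\n",
              x$K, x$n_iter, x$final_loss,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Numerical rank of a (mean-filled) abundance matrix
#'
#' Singular values above max(I, J) * machine-epsilon * s_1 count towards the
#' rank (the standard numerical-rank tolerance). Missing entries, if any,
#' are filled with the metabolite's observed mean first, matching the
#' initialization step of the imputation pipeline.
#'
#' @param x an `abundance_matrix`, usually on the log10 scale
#' @return integer rank in `[1, min(I, J)]`
#' @export
estimate_rank <- function(x) {
  v <- x$values
  if (anyNA(v)) {
    rm <- rowMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- rm[idx[, 1L]]
  }
  s <- svd(v, nu = 0, nv = 0)$d
  tol <- max(dim(v)) * .Machine$double.eps * s[1L]
  max(1L, sum(s > tol))
}

#' Component-count schedule for the NMF ensemble
#'
#' Returns the consecutive component counts K fitted by the ensemble: exactly
#' `n_models` values centred on the estimated rank, starting at
#' `max(rank - floor(n_models / 2), 1)` and clamped so that no K exceeds
#' `min(i, j)` (the whole window shifts down when the clamp would shorten it;
#' it is truncated to `min(i, j)` values only when the matrix is smaller than
#' the requested ensemble).
#'
#' @param rank estimated rank of the data matrix
#' @param n_models ensemble size N, default 20
#' @param i,j matrix dimensions
#' @return integer vector of distinct consecutive K values
#' @export
k_schedule <- function(rank, n_models = 20L, i, j) {
  if (n_models < 1L) stop("`n_models` must be >= 1")
  m <- min(i, j)
  n <- min(n_models, m)
  k1 <- max(rank - floor(n_models / 2), 1L)
  if (k1 + n - 1L > m) k1 <- max(m - n + 1L, 1L)
  as.integer(seq.int(k1, k1 + n - 1L))
}

#' Mean absolute reconstruction error on observed entries
#'
#' d_K = sum over observed (i,j) of |xhat_ij - x_ij| / |Omega|: the mean
#' absolute deviation between a model's reconstruction and the data on the
#' observed set. This is the per-model error that the ensemble weights are
#' built from; values at unobserved positions never enter.
#'
#' @param x an `abundance_matrix`
#' @param x_hat numeric reconstruction matrix of the same shape
#' @return scalar mean absolute error
#' @export
reconstruction_error <- function(x, x_hat) {
  obs <- !is.na(x$values)
  if (!any(obs)) stop("no observed entries")
  if (!identical(dim(x_hat), dim(x$values))) stop("dimension mismatch")
  mean(abs(x_hat[obs] - x$values[obs]))
}

#' Softmax-weighted ensemble reconstruction
#'
#' Combines per-K reconstructions with weights
#' w_K = exp(-d_K) / sum_K exp(-d_K): models that reproduce the observed data
#' more closely dominate, but every model keeps positive weight. Computed
#' with max-subtraction so extreme errors cannot underflow the softmax.
#'
#' @param models list of models, each a list with elements `K`, `x_hat`
#'   (reconstruction matrix) and `d` (observed mean absolute error)
#' @return an `ensemble_reconstruction`: list with `models` (K, d, weight per
#'   model), `weights`, the per-model `reconstructions`, and the weighted
#'   reconstruction `X_hat`
#' @export
weighted_reconstruction <- function(models) {
  if (length(models) < 1L) stop("need at least one model")
  d <- vapply(models, function(m) m$d, numeric(1))
  if (any(!is.finite(d))) stop("non-finite reconstruction error")
  w <- exp(-(d - min(d)))
  w <- w / sum(w)
  X_hat <- Reduce(`+`, Map(function(m, wi) wi * m$x_hat, models, w))
  structure(list(
    models = data.frame(K = vapply(models, function(m) m$K, numeric(1)),
                        d = d, weight = w),
    weights = w, X_hat = X_hat,
    reconstructions = lapply(models, function(m) m$x_hat)),
    class = "ensemble_reconstruction")
}

#' @export
print.ensemble_reconstruction <- function(x, ...) {
  cat(sprintf("ensemble_reconstruction: %d model(s), K in [%d, %d]\n",
              nrow(x$models), min(x$models$K), max(x$models$K)))
  print(x$models, row.names = FALSE)
  invisible(x)
}

#' Ensemble NMF imputation
#'
#' The full imputation pipeline for a raw-scale abundance matrix with missing
#' entries:
#' \enumerate{
#'   \item Initialization: missing entries are filled with their metabolite's
#'     observed mean (used only to estimate the rank), and the data is log10
#'     transformed with a recorded non-negativity offset.
#'   \item Factorization: a masked NMF is fitted for every K in the
#'     rank-centred schedule of `n_models` consecutive component counts
#'     (per-model seeds are `seed + K`).
#'   \item Weighted reconstruction: per-model observed mean absolute errors
#'     d_K feed softmax weights exp(-d_K)/sum exp(-d_K), giving one combined
#'     reconstruction.
#'   \item Imputation: observed entries keep their original values exactly;
#'     missing entries take the combined reconstruction, and the result is
#'     mapped back to the raw scale by inverting the log10 transform.
#' }
#'
#' @param x_raw raw-scale `abundance_matrix`; every metabolite needs at least
#'   one observed value (apply [filter_by_missing_fraction()] first)
#' @param n_models ensemble size, default 20
#' @param seed integer master seed
#' @param tol,max_iter convergence controls passed to [masked_nmf()]
#' @return an `imputation_result`: list with the completed raw-scale matrix
#'   `X_tilde`, `imputed_mask` (TRUE where a value was filled in), `method`,
#'   the `ensemble_reconstruction`, the log10 `offset`, `rank`, and `seed`
#' @export
nmf_impute <- function(x_raw, n_models = 20L, seed = 1L, tol = 1e-6,
                       max_iter = 500L) {
  if (x_raw$scale != "raw") stop("`x_raw` must be on the raw scale")
  v <- x_raw$values
  obs <- !is.na(v)
  if (any(rowSums(obs) == 0L))
    stop("metabolite with no observed values; apply the 30% deletion filter first")

  xlog <- log10_transform(x_raw)

  # Step 1: metabolite-mean fill (raw scale) for rank estimation only
  filled <- v
  rm <- rowMeans(v, na.rm = TRUE)
  idx_na <- which(!obs, arr.ind = TRUE)
  if (nrow(idx_na)) filled[idx_na] <- rm[idx_na[, 1L]]
  filled_log <- log10(filled) + xlog$offset
  rk <- estimate_rank(abundance_matrix(filled_log, scale = "log10",
                                       offset = xlog$offset))

  # Steps 2-3: per-K masked factorizations, softmax-combined
  ks <- k_schedule(rk, n_models, nrow(v), ncol(v))
  models <- lapply(ks, function(K) {
    f <- masked_nmf(xlog, K, seed = seed + K, tol = tol, max_iter = max_iter)
    x_hat <- f$B %*% f$C
    list(K = K, x_hat = x_hat, d = reconstruction_error(xlog, x_hat),
         n_iter = f$n_iter, converged = f$converged)
  })
  ens <- weighted_reconstruction(models)
  if (any(!is.finite(ens$X_hat)))
    stop("non-finite ensemble reconstruction; model errors: ",
         paste(sprintf("K=%d d=%.3g", ens$models$K, ens$models$d),
               collapse = ", "))

  # Step 4: keep observed entries bit-exactly, impute the rest
  x_tilde <- 10^(ens$X_hat - xlog$offset)
  x_tilde[obs] <- v[obs]
  dimnames(x_tilde) <- dimnames(v)

  structure(list(X_tilde = x_tilde, imputed_mask = !obs, method = "nmf",
                 ensemble = ens, offset = xlog$offset, rank = rk,
                 seed = seed),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("imputation_result (%s): %d x %d, %d entr%s imputed\n",
              x$method, nrow(x$X_tilde), ncol(x$X_tilde),
              sum(x$imputed_mask), if (sum(x$imputed_mask) == 1) "y" else "ies"))
  invisible(x)
}

# wrap a completed matrix as an imputation_result (used by the baselines)
new_imputation_result <- function(x_tilde, imputed_mask, method,
                                  seed = NA_integer_) {
  structure(list(X_tilde = x_tilde, imputed_mask = imputed_mask,
                 method = method, ensemble = NULL, offset = 0, seed = seed),
            class = "imputation_result")
}

# extract the completed matrix from an imputation_result or plain matrix
completed_values <- function(x) {
  if (inherits(x, "imputation_result")) x$X_tilde
  else if (inherits(x, "abundance_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected an imputation_result or matrix")
}
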