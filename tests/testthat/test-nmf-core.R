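test_that("observed loss sums squared residuals over observed entries only", {
  x <- am(matrix(c(2, 1, 1, 1), 2, 2), scale = "log10")
  f <- list(B = matrix(1, 2, 1), C = matrix(1, 1, 2))
  expect_equal(observed_loss(x, f), 1)  # (2-1)^2, other cells exact

  # exact reconstruction -> 0
  B <- matrix(c(1, 2), 2, 1); C <- matrix(c(3, 4), 1, 2)
  xf <- am(B %*% C, scale = "log10")
  expect_equal(observed_loss(xf, list(B = B, C = C)), 0)

  # masking the erring entry removes its contribution
  xm <- x; xm$values[1, 1] <- NA
  xm <- abundance_matrix(xm$values, scale = "log10")
  expect_equal(observed_loss(xm, f), 0)
})

test_that("masked_nmf is monotone, deterministic, and recovers rank-1 data", {
  # rank-1 positive complete matrix: exact factorization exists
  b <- c(1, 2, 3, 4); cc <- c(2, 1, 3)
  x <- am(outer(b, cc), scale = "log10")
  f <- masked_nmf(x, 1, seed = 5, tol = 1e-12, max_iter = 2000)
  rel <- sqrt(f$final_loss) / sqrt(sum(x$values^2))
  expect_lt(rel, 1e-4)
  expect_true(all(f$B >= 0) && all(f$C >= 0))
  expect_true(all(diff(f$loss_trace) <= 1e-9 * max(1, f$loss_trace[1])))

  # determinism
  fx <- generate_fixture(12, 8, 3, seed = 2)
  xl <- log10_transform(fx)
  f1 <- masked_nmf(xl, 3, seed = 7)
  f2 <- masked_nmf(xl, 3, seed = 7)
  expect_identical(f1$B, f2$B)
  expect_identical(f1$C, f2$C)

  # full-rank capacity drives the loss far below the data norm
  ff <- masked_nmf(xl, 8, seed = 1, tol = 0, max_iter = 10000)
  expect_lt(ff$final_loss, 1e-6 * sum(xl$values^2))

  expect_error(masked_nmf(xl, 0, seed = 1), "k")
  expect_error(masked_nmf(xl, 9, seed = 1), "k")
  bad <- xl$values; bad[1, ] <- NA
  expect_error(masked_nmf(abundance_matrix(bad, scale = "log10"), 2),
               "zero observed")
})

test_that("masked_nmf with a full mask matches an unmasked reference NMF", {
  # independent reference: plain Lee-Seung multiplicative updates, no mask,
  # run from the identical seeded initialization
  fx <- generate_fixture(8, 6, 4, noise_sd = 0.05, seed = 11)
  x <- log10_transform(fx)
  k <- 4
  f <- masked_nmf(x, k, seed = 3, tol = 1e-10, max_iter = 800)

  set.seed(3)
  sc <- sqrt(mean(x$values) / k)
  B <- matrix(pmax(runif(nrow(x$values) * k), 1e-12), ncol = k) * sc
  C <- matrix(pmax(runif(k * ncol(x$values)), 1e-12), nrow = k) * sc
  X <- x$values
  for (it in 1:800) {
    B <- B * (X %*% t(C)) / ((B %*% C) %*% t(C) + 1e-12)
    C <- C * (t(B) %*% X) / (t(B) %*% (B %*% C) + 1e-12)
    if (it > 1 && abs(prev - sum((X - B %*% C)^2)) / prev < 1e-10) break
    prev <- sum((X - B %*% C)^2)
  }
  ref_loss <- sum((X - B %*% C)^2)
  expect_lt(abs(f$final_loss - ref_loss), 1e-6 * max(1, ref_loss))
})

test_that("rank estimation uses the standard numerical-rank tolerance", {
  fx <- generate_fixture(20, 10, 3, noise_sd = 0, seed = 6)
  expect_equal(estimate_rank(log10_transform(fx)), 3)

  # diagonal-dominant positive matrix has full rank
  v <- diag(5) + 0.01
  dimnames(v) <- list(letters[1:5], LETTERS[1:5])
  expect_equal(estimate_rank(abundance_matrix(v, scale = "log10")), 5)

  # never exceeds min(I, J); NAs are mean-filled first
  fx2 <- generate_fixture(10, 6, 4, seed = 8)
  sim <- simulate_mcar(fx2, 10, 0, seed = 9)
  r <- estimate_rank(log10_transform(sim$masked))
  expect_lte(r, 6)
  expect_gte(r, 1)
})

test_that("k_schedule centres on the rank and clamps at the matrix size", {
  expect_equal(k_schedule(15, 20, 60, 40), 5:24)   # 20 models
  expect_equal(k_schedule(3, 20, 100, 50), 1:20)   # lower clamp
  expect_equal(k_schedule(4, 20, 8, 8), 1:8)       # truncation to min(I,J)
  expect_equal(k_schedule(38, 20, 60, 40), 21:40)  # upper clamp shifts down
  expect_length(k_schedule(10, 20, 100, 40), 20)
  expect_equal(k_schedule(2, 1, 10, 10), 2L)
})

test_that("reconstruction error is the observed mean absolute deviation", {
  # X = [2, 4] observed (second row masked), X^ = [3, 3] -> (1 + 1) / 2
  xm <- am(matrix(c(2, NA, 4, NA), 2, 2), scale = "log10")
  h1 <- matrix(c(3, 0, 3, 0), 2, 2)
  expect_equal(reconstruction_error(xm, h1), 1)

  # invariant to values at unobserved positions
  h2 <- matrix(c(3, 99, 3, -99), 2, 2)
  expect_equal(reconstruction_error(xm, h2), 1)

  # perfect reconstruction on the observed set -> 0
  h3 <- matrix(c(2, 0, 4, 0), 2, 2)
  expect_equal(reconstruction_error(xm, h3), 0)
})

test_that("ensemble weights are a stable softmax of the model errors", {
  h <- matrix(1, 2, 2)
  one <- weighted_reconstruction(list(list(K = 1, x_hat = h, d = 0.3)))
  expect_equal(one$weights, 1)
  expect_equal(one$X_hat, h)

  two <- weighted_reconstruction(list(list(K = 1, x_hat = h, d = 0.5),
                                      list(K = 2, x_hat = 3 * h, d = 0.5)))
  expect_equal(two$weights, c(0.5, 0.5))
  expect_equal(two$X_hat, 2 * h)

  w <- weighted_reconstruction(list(list(K = 1, x_hat = h, d = 0),
                                    list(K = 2, x_hat = h, d = log(3))))
  expect_equal(w$weights, c(0.75, 0.25))

  # huge errors must not underflow the softmax
  big <- weighted_reconstruction(list(list(K = 1, x_hat = h, d = 5000),
                                      list(K = 2, x_hat = h, d = 5001)))
  expect_equal(sum(big$weights), 1, tolerance = 1e-12)
  expect_true(all(big$weights > 0))

  # normalization holds for any model count
  for (p in c(1, 7, 50)) {
    ms <- lapply(seq_len(p), function(k)
      list(K = k, x_hat = h, d = runif(1, 0, 10)))
    expect_equal(sum(weighted_reconstruction(ms)$weights), 1,
                 tolerance = 1e-12)
  }
})

test_that("nmf_impute preserves observed entries and recovers low-rank truth", {
  sim <- mcar_case(i = 30, j = 20, seed = 21)
  res <- nmf_impute(sim$masked, seed = 5)
  obs <- !is.na(sim$masked$values)
  expect_identical(res$X_tilde[obs], sim$masked$values[obs])
  expect_true(all(res$X_tilde > 0))
  expect_equal(sum(res$imputed_mask), nrow(sim$theta_s))

  # complete matrix in -> identical matrix out
  fx <- generate_fixture(10, 8, 3, seed = 1)
  rc <- nmf_impute(fx, seed = 2)
  expect_identical(rc$X_tilde, fx$values)

  # determinism
  res2 <- nmf_impute(sim$masked, seed = 5)
  expect_identical(res$X_tilde, res2$X_tilde)

  # recovery quality on the imputed cells
  expect_lt(nrmse(sim$truth, res, sim$theta_s), 0.5)
})

test_that("default ensemble holds exactly 20 models when the matrix allows", {
  fx <- generate_fixture(60, 40, 15, noise_sd = 0.05, seed = 13)
  sim <- simulate_mcar(fx, 5, 0, seed = 14)
  res <- nmf_impute(sim$masked, seed = 15, max_iter = 30)
  expect_equal(nrow(res$ensemble$models), 20)
  expect_equal(diff(res$ensemble$models$K), rep(1, 19))
})

test_that("the weighted ensemble is no worse on average than its worst member", {
  n_fix <- 20
  ens_err <- worst_err <- numeric(n_fix)
  for (s in seq_len(n_fix)) {
    sim <- mcar_case(i = 30, j = 16, seed = 400 + s)
    res <- nmf_impute(sim$masked, seed = 500 + s, max_iter = 200)
    ens_err[s] <- nrmse(sim$truth, res, sim$theta_s)
    # per-model imputations from the stored reconstructions
    per_model <- vapply(res$ensemble$reconstructions, function(h) {
      xt <- 10^(h - res$offset)
      obs <- !res$imputed_mask
      xt[obs] <- sim$masked$values[obs]
      nrmse(sim$truth, xt, sim$theta_s)
    }, numeric(1))
    worst_err[s] <- max(per_model)
  }
  expect_lte(mean(ens_err), mean(worst_err))
})
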