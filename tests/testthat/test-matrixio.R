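test_that("load_matrix reads values, NA tokens and zeros correctly", {
  p <- write_csv_fixture(matrix(c(1, 3, 2, 4), 2, 2))
  m <- load_matrix(p, quiet = TRUE)
  expect_s3_class(m, "abundance_matrix")
  expect_equal(n_observed(m), 4)
  expect_equal(unname(m$values), matrix(c(1, 3, 2, 4), 2, 2))

  # one empty cell -> |Omega| = 3, NA fraction 0.25
  p2 <- write_csv_fixture(matrix(1:4, 2, 2),
                          cells = matrix(c("1", "3", "", "4"), 2, 2))
  m2 <- load_matrix(p2, quiet = TRUE)
  expect_equal(n_observed(m2), 3)
  expect_equal(mean(is.na(m2$values)), 0.25)

  # zeros coerced to missing
  p3 <- write_csv_fixture(matrix(1, 2, 2),
                          cells = matrix(c("1", "0", "2", "3"), 2, 2))
  expect_equal(n_observed(load_matrix(p3, quiet = TRUE)), 3)
})

test_that("load_matrix rejects malformed tables", {
  p <- write_csv_fixture(matrix(1, 2, 2),
                         cells = matrix(c("1", "oops", "2", "3"), 2, 2))
  expect_error(load_matrix(p, quiet = TRUE), "non-numeric")
  p2 <- write_csv_fixture(matrix(1:4 * 1.0, 2, 2), ids = c("m1", "m1"))
  expect_error(load_matrix(p2, quiet = TRUE), "duplicate")
  p3 <- write_csv_fixture(matrix(c(1, -2, 3, 4), 2, 2))
  expect_error(load_matrix(p3, quiet = TRUE), "negative")
})

test_that("load_matrix honours orientation and write_matrix round-trips", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  m <- am(v)
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix(m, path)
  back <- load_matrix(path, quiet = TRUE)
  expect_equal(back$values, v)
  expect_true(file.exists(paste0(path, ".json")))
  # transposed table read with metabolites_in_columns gives the same matrix
  tm <- am(t(v))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_matrix(tm, path2, sidecar = FALSE)
  back2 <- load_matrix(path2, orientation = "metabolites_in_columns",
                       quiet = TRUE)
  expect_equal(back2$values, v)
})

test_that("30% deletion retains exactly the metabolites at or below threshold", {
  # 11 metabolites over 10 samples with missing fractions 0, 10, ..., 100%
  v <- matrix(10, 11, 10)
  for (i in 2:11) v[i, seq_len(i - 1)] <- NA
  m <- am(v)
  f <- suppressMessages(filter_by_missing_fraction(m))
  expect_equal(nrow(f$values), 4)  # 0, 10, 20, 30% retained
  expect_equal(rownames(f$values), sprintf("m%d", 1:4))
  expect_equal(ncol(f$values), 10)
  # boundary: exactly 30% (3 of 10) is retained, 40% removed
  expect_true("m4" %in% rownames(f$values))
  expect_false("m5" %in% rownames(f$values))
  # idempotence
  expect_equal(suppressMessages(filter_by_missing_fraction(f)), f)
  # all metabolites above threshold -> error
  v_all <- matrix(10, 5, 10)
  v_all[, 1:4] <- NA   # every metabolite 40% missing
  expect_error(filter_by_missing_fraction(am(v_all)), "empty matrix")
})

test_that("log10 transform offsets to non-negativity and inverts exactly", {
  v <- matrix(c(1, 10, 100, 1e6), 2, 2)
  m <- am(v)
  lt <- log10_transform(m)
  expect_equal(lt$offset, 0)
  expect_true(all(lt$values >= 0 & lt$values <= 6))

  # a value of 0.01 forces offset 2 and transformed minimum 0
  v2 <- matrix(c(0.01, 10, 100, 1e3), 2, 2)
  lt2 <- log10_transform(am(v2))
  expect_equal(lt2$offset, 2)
  expect_equal(min(lt2$values), 0)

  # round trip to 1e-12 relative error
  fx <- generate_fixture(10, 8, 3, seed = 42)
  rt <- inverse_log10(log10_transform(fx))
  expect_lt(max(abs(rt$values / fx$values - 1)), 1e-12)

  # hand inversion: log value 3 with offset 1 -> 100
  lm <- am(matrix(c(3, 3, 3, 3), 2, 2), scale = "log10", offset = 1)
  expect_equal(unname(inverse_log10(lm)$values[1, 1]), 100)
  expect_error(log10_transform(lt), "log10")
})

test_that("missingness profile bins evenly and attributes missing cells", {
  # complete matrix: no missingness anywhere
  fx <- generate_fixture(20, 10, 3, seed = 3)
  pr <- missingness_profile(fx)
  expect_length(pr$bin_edges, 21)
  expect_true(all(diff(pr$bin_edges) > 0))
  expect_true(all(pr$missing_pct == 0))
  expect_equal(sum(pr$counts), 200)

  # values 10^0..10^2 evenly, two bins -> edges {0, 1, 2}
  v <- matrix(10^seq(0, 2, length.out = 8), 2, 4)
  pr2 <- missingness_profile(am(v), n_intervals = 2)
  expect_equal(pr2$bin_edges, c(0, 1, 2))

  # NAs placed only below 10^1 land in the lower of two bins
  truth <- am(matrix(10^c(0, 0.2, 0.4, 1.6, 1.8, 2.0), 3, 2, byrow = TRUE))
  masked <- truth
  masked$values[1, 1] <- NA   # true value 10^0
  masked <- am(masked$values)
  pr3 <- missingness_profile(masked, n_intervals = 2, truth = truth)
  expect_equal(pr3$missing_counts, c(1, 0))
  expect_equal(sum(pr3$missing_counts), sum(is.na(masked$values)))
  expect_gt(pr3$missing_pct[1], 0)
  expect_equal(pr3$missing_pct[2], 0)

  # constant matrix degenerates to a single bin with a warning
  expect_warning(pc <- missingness_profile(am(matrix(5, 2, 2))), "degenerate")
  expect_equal(pc$n_intervals, 1)
})

test_that("fixture generator is deterministic, positive, and of stated rank", {
  a <- generate_fixture(15, 12, 4, noise_sd = 0.2, seed = 9)
  b <- generate_fixture(15, 12, 4, noise_sd = 0.2, seed = 9)
  expect_identical(a$values, b$values)
  expect_true(all(a$values > 0))
  expect_false(identical(
    a$values, generate_fixture(15, 12, 4, noise_sd = 0.2, seed = 10)$values))

  # SVD oracle: noiseless log10 matrix has numerical rank == rank
  for (r in c(1, 3, 6)) {
    fx <- generate_fixture(25, 12, r, noise_sd = 0, seed = r)
    s <- svd(log10(fx$values))$d
    expect_equal(sum(s > max(25, 12) * .Machine$double.eps * s[1]), r)
  }
  expect_error(generate_fixture(5, 5, 6, seed = 1), "rank")
})

test_that("abundance_matrix enforces its invariants", {
  v <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(abundance_matrix(v * -1), "positive")
  expect_error(abundance_matrix(matrix(1, 1, 2)), "at least 2")
  v2 <- v; rownames(v2) <- c("a", "a")
  expect_error(abundance_matrix(v2), "duplicate")
  expect_error(abundance_matrix(matrix(NA_real_, 2, 2,
                                       dimnames = dimnames(v))),
               "no observed")
})
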