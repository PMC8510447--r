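# Small in-code fixtures shared across the test files.

# a tiny named matrix wrapped as an abundance_matrix
am <- function(values, scale = "raw", offset = 0) {
  if (is.null(dimnames(values)))
    dimnames(values) <- list(sprintf("m%d", seq_len(nrow(values))),
                             sprintf("s%d", seq_len(ncol(values))))
  abundance_matrix(values, scale = scale, offset = offset)
}

# write a small CSV of abundances (rows = metabolites) and return its path
write_csv_fixture <- function(values, ids = NULL, samples = NULL,
                              cells = NULL) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  if (is.null(ids)) ids <- sprintf("m%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  chr <- if (is.null(cells)) format(values, trim = TRUE) else cells
  lines <- c(paste(c("metabolite", samples), collapse = ","),
             vapply(seq_len(nrow(values)), function(r)
               paste(c(ids[r], chr[r, ]), collapse = ","), character(1)))
  writeLines(lines, path)
  path
}

# a complete low-rank truth plus an MCAR-masked copy
mcar_case <- function(i = 30, j = 20, rank = 5, x_pct = 10, noise_sd = 0.05,
                      seed = 1) {
  fx <- generate_fixture(i, j, rank, noise_sd = noise_sd, seed = seed)
  simulate_mcar(fx, x_pct, 0, seed = seed + 1000)
}
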