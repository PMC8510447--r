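#' Parse a benchmark configuration
#'
#' Reads a YAML (or JSON) benchmark description, validates it, and fills in
#' defaults. Recognized keys:
#' \describe{
#'   \item{input}{path to a CSV/TSV abundance table, or}
#'   \item{fixture}{list `i`, `j`, `rank`, `noise_sd` generating a synthetic
#'     truth via [generate_fixture()]}
#'   \item{patterns}{subset of `"MCAR"`, `"MNAR"`, `"MM"` (default MCAR)}
#'   \item{x_pct}{grid of total missing percentages (default MNAR/MM-style
#'     15 to 30 by 2.5 for those patterns, 5 to 30 by 5 for MCAR)}
#'   \item{outlier_levels}{fractions of observed cells perturbed (default 0)}
#'   \item{methods}{subset of `"nmf"`, `"mean"`, `"halfmin"`, `"knn"`,
#'     `"rf"`}
#'   \item{n_repeats}{simulation repeats per grid cell (default 50)}
#'   \item{seed}{master seed}
#'   \item{lod_q, knn_k, n_models, tol, max_iter, rf_max_iter, rf_ntree,
#'     ccn, ccn_r_min, ccn_alpha, filter_threshold}{tuning knobs}
#' }
#' Unknown keys are rejected.
#'
#' @param path configuration file path
#' @return a validated `benchmark_config` list
#' @export
parse_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname parse_config
#' @param cfg a configuration list built in code
#' @export
validate_config <- function(cfg) {
  known <- c("input", "fixture", "patterns", "x_pct", "outlier_levels",
             "methods", "n_repeats", "seed", "lod_q", "knn_k", "n_models",
             "tol", "max_iter", "rf_max_iter", "rf_ntree", "ccn",
             "ccn_r_min", "ccn_alpha", "filter_threshold")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  cfg$patterns <- toupper(cfg$patterns %||% "MCAR")
  bad <- setdiff(cfg$patterns, c("MCAR", "MNAR", "MM"))
  if (length(bad)) stop("unknown pattern(s): ", paste(bad, collapse = ", "))
  cfg$x_pct <- cfg$x_pct %||%
    (if (all(cfg$patterns == "MCAR")) seq(5, 30, by = 5) else seq(15, 30, by = 2.5))
  if (length(cfg$x_pct) == 0L) stop("`x_pct` grid is empty")
  cfg$outlier_levels <- cfg$outlier_levels %||% 0
  cfg$methods <- cfg$methods %||% c("nmf", "mean", "halfmin", "knn")
  bad <- setdiff(cfg$methods, names(imputer_registry()))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  cfg$n_repeats <- as.integer(cfg$n_repeats %||% 50L)
  if (cfg$n_repeats < 1L) stop("`n_repeats` must be >= 1")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$lod_q <- cfg$lod_q %||% 0.35
  cfg$ccn <- isTRUE(cfg$ccn)
  cfg$ccn_r_min <- cfg$ccn_r_min %||% 0.6
  cfg$ccn_alpha <- cfg$ccn_alpha %||% 0.05
  cfg$filter_threshold <- cfg$filter_threshold %||% 0.30
  if (is.null(cfg$input) && is.null(cfg$fixture))
    stop("configuration needs `input` or `fixture`")
  structure(cfg, class = "benchmark_config")
}

benchmark_truth <- function(cfg) {
  if (!is.null(cfg$input)) {
    m <- load_matrix(cfg$input, quiet = TRUE)
  } else {
    fx <- cfg$fixture
    m <- generate_fixture(fx$i, fx$j, fx$rank,
                          noise_sd = fx$noise_sd %||% 0.1,
                          seed = cfg$seed)
  }
  filter_by_missing_fraction(m, cfg$filter_threshold, quiet = TRUE)
}

simulate_pattern <- function(truth, pattern, x_pct, seed, lod, profile) {
  switch(pattern,
         MCAR = simulate_mcar(truth, x_pct, seed = seed),
         MNAR = simulate_mnar(truth, x_pct, lod = lod, profile = profile,
                              seed = seed),
         MM   = simulate_mm(truth, x_pct, lod = lod, profile = profile,
                            seed = seed),
         stop("unknown pattern ", pattern))
}

#' Run a simulation benchmark of the registered imputers
#'
#' For every combination of missingness pattern, total missing percentage,
#' outlier level, and repeat, the driver simulates artificial NAs on the
#' truth, optionally perturbs the remaining observed cells with outliers,
#' runs every configured imputation method, and scores NRMSE (raw scale),
#' MSR across methods, and (optionally) correlation-network
#' precision/recall/F1 against the truth's network. Sub-seeds are derived
#' from the master seed by a counter, so the whole experiment is a pure
#' function of (input data, configuration, seed), and any grid cell can be
#' recomputed independently. Method failures are recorded per cell and do
#' not abort the run.
#'
#' @param cfg a `benchmark_config` from [parse_config()] /
#'   [validate_config()]
#' @param out_dir optional directory; when given, `results.csv` (tidy
#'   per-repeat table) and `summary.json` (mean and SD aggregates) are
#'   written there
#' @return list with `results` (tidy data frame: pattern, x_pct,
#'   outlier_level, repeat_, method, metric columns) and `summary`
#'   (aggregated means and SDs)
#' @export
run_benchmark <- function(cfg, out_dir = NULL) {
  cfg <- validate_config(unclass(cfg))
  truth <- benchmark_truth(cfg)
  lod <- determine_lod(truth, cfg$lod_q)
  profile <- missingness_profile(truth)
  imputers <- imputer_registry(cfg)[cfg$methods]
  original_ccn <- if (cfg$ccn)
    build_ccn(truth, cfg$ccn_r_min, cfg$ccn_alpha) else NULL

  rows <- list()
  counter <- 0L
  for (pattern in cfg$patterns) {
    for (x in cfg$x_pct) {
      for (ol in cfg$outlier_levels) {
        for (rep_i in seq_len(cfg$n_repeats)) {
          counter <- counter + 1L
          sub_seed <- cfg$seed + 1000L * counter
          sim <- simulate_pattern(truth, pattern, x, sub_seed, lod, profile)
          masked <- sim$masked
          if (ol > 0)
            masked <- inject_outliers(masked, ol, seed = sub_seed + 1L)$matrix
          results <- list()
          for (meth in names(imputers)) {
            res <- tryCatch(imputers[[meth]](masked, seed = sub_seed + 2L),
                            error = function(e) e)
            if (inherits(res, "error")) {
              rows[[length(rows) + 1L]] <- data.frame(
                pattern = pattern, x_pct = x, outlier_level = ol,
                repeat_ = rep_i, method = meth, nrmse = NA_real_,
                msr = NA_real_, precision = NA_real_, recall = NA_real_,
                f1 = NA_real_, error = conditionMessage(res))
              next
            }
            results[[meth]] <- res
          }
          msr_vals <- if (length(results) >= 2L)
            msr(sim$truth, results, sim$theta_s) else NULL
          for (meth in names(results)) {
            sc <- if (cfg$ccn) {
              pred <- build_ccn(results[[meth]], cfg$ccn_r_min, cfg$ccn_alpha)
              network_scores(pred, original_ccn)
            } else list(precision = NA_real_, recall = NA_real_,
                        f1 = NA_real_)
            rows[[length(rows) + 1L]] <- data.frame(
              pattern = pattern, x_pct = x, outlier_level = ol,
              repeat_ = rep_i, method = meth,
              nrmse = nrmse(sim$truth, results[[meth]], sim$theta_s),
              msr = if (is.null(msr_vals)) NA_real_ else msr_vals[[meth]],
              precision = sc$precision, recall = sc$recall, f1 = sc$f1,
              error = NA_character_)
          }
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(
    cbind(nrmse, msr, f1) ~ pattern + x_pct + outlier_level + method,
    data = results,
    FUN = function(z) c(mean = mean(z), sd = stats::sd(z)),
    na.action = stats::na.pass)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    agg <- lapply(seq_len(nrow(summary)), function(r) {
      s <- summary[r, ]
      list(pattern = s$pattern, x_pct = s$x_pct,
           outlier_level = s$outlier_level, method = s$method,
           nrmse_mean = unname(s$nrmse[1, "mean"]),
           nrmse_sd = unname(s$nrmse[1, "sd"]),
           msr_mean = unname(s$msr[1, "mean"]),
           f1_mean = unname(s$f1[1, "mean"]))
    })
    jsonlite::write_json(list(config = unclass(cfg)[setdiff(names(cfg), "fixture")],
                              aggregates = agg),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  list(results = results, summary = summary)
}

#' Paired method comparison on a benchmark result table
#'
#' Post-hoc significance annotation: for each grid cell, every method's
#' per-repeat NRMSE is compared with the reference method by a paired
#' t-test, and p-values are Benjamini-Hochberg adjusted across the whole
#' table. Reported for inspection only; no decision in the pipeline depends
#' on it.
#'
#' @param results the tidy `results` data frame from [run_benchmark()]
#' @param reference reference method name, default `"nmf"`
#' @return data frame with one row per (pattern, x_pct, outlier_level,
#'   method): mean NRMSE difference, raw and BH-adjusted p-values
#' @export
compare_methods <- function(results, reference = "nmf") {
  if (!reference %in% results$method)
    stop("reference method not present in results")
  cells <- unique(results[, c("pattern", "x_pct", "outlier_level")])
  out <- list()
  for (r in seq_len(nrow(cells))) {
    cell <- cells[r, ]
    sub <- merge(results, cell)
    ref <- sub[sub$method == reference, ]
    ref <- ref[order(ref$repeat_), ]
    for (meth in setdiff(unique(sub$method), reference)) {
      other <- sub[sub$method == meth, ]
      other <- other[order(other$repeat_), ]
      ok <- stats::complete.cases(ref$nrmse, other$nrmse)
      if (sum(ok) < 2L) next
      tt <- stats::t.test(other$nrmse[ok], ref$nrmse[ok], paired = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        cell, method = meth, mean_diff = unname(tt$estimate),
        p = tt$p.value)
    }
  }
  tab <- do.call(rbind, out)
  if (is.null(tab)) stop("not enough complete repeats for any comparison")
  tab$padj <- stats::p.adjust(tab$p, method = "BH")
  tab
}
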