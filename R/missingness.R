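#' Limit-of-detection surrogate from the abundance distribution
#'
#' MS instruments censor low-intensity compounds below a limit of detection
#' (LOD). The exact signal-to-noise rule behind a given dataset's LOD is
#' rarely recoverable, so the simulators use a quantile of the observed
#' log10-abundance distribution as a reproducible, dataset-adaptive
#' surrogate. The default q = 0.35 leaves the below-LOD stratum large enough
#' to absorb the heaviest MNAR/mixed scenarios (up to 30% total missingness
#' with 80% of it below the LOD).
#'
#' @param truth an `abundance_matrix`
#' @param q quantile in `[0, 1]`, default 0.35
#' @return the LOD on the log10-abundance scale
#' @export
determine_lod <- function(truth, q = 0.35) {
  if (q < 0 || q > 1) stop("`q` must be in [0, 1]")
  lv <- log10_values(truth)
  unname(stats::quantile(lv[!is.na(truth$values)], q))
}

new_simulated_dataset <- function(truth, masked, theta_s, scenario) {
  structure(list(truth = truth, masked = masked, theta_s = theta_s,
                 scenario = scenario),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: pattern %s, x = %g%%, r = %g%%, |Theta_s| = %d\n",
              x$scenario$pattern, x$scenario$x_pct, x$scenario$r_pct,
              nrow(x$theta_s)))
  invisible(x)
}

# number of artificial NAs implied by (x_pct, r_pct) on an I x J grid
artificial_count <- function(x_pct, r_pct, I, J) {
  if (r_pct < 0 || x_pct > 100 || r_pct > x_pct)
    stop("need 0 <= r_pct <= x_pct <= 100")
  round((x_pct - r_pct) / 100 * I * J)
}

# apply a set of artificial NA positions (2-column index matrix) to truth
mask_positions <- function(truth, theta, scenario) {
  v <- truth$values
  if (nrow(theta)) v[theta] <- NA_real_
  masked <- abundance_matrix(v, scale = truth$scale, offset = truth$offset)
  new_simulated_dataset(truth, masked, theta, scenario)
}

#' Simulate MCAR/MAR missingness
#'
#' Replaces uniformly chosen observed entries with NAs, the classic missing-
#' completely-at-random mechanism: artificial missingness carries no
#' information about abundance. The target total missingness is `x_pct`% of
#' the full grid, of which `r_pct`% is already missing in the input, so
#' round((x_pct - r_pct)/100 * I * J) artificial NAs are placed.
#'
#' @param truth an `abundance_matrix` (may already contain original NAs)
#' @param x_pct target total missing percentage of the grid
#' @param r_pct original missing percentage; defaults to the input's actual
#'   missing percentage
#' @param seed integer seed
#' @return a `simulated_dataset` with elements `truth`, `masked`, `theta_s`
#'   (2-column index matrix of the artificial NAs) and `scenario`
#' @export
simulate_mcar <- function(truth, x_pct, r_pct = 100 * mean(is.na(truth$values)),
                          seed = 1L) {
  I <- nrow(truth$values); J <- ncol(truth$values)
  n_art <- artificial_count(x_pct, r_pct, I, J)
  obs_idx <- which(!is.na(truth$values))
  if (n_art > length(obs_idx))
    stop(sprintf("requested %d artificial NAs but only %d observed cells",
                 n_art, length(obs_idx)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick <- if (n_art > 0L) sample(obs_idx, n_art) else integer(0)
  theta <- arrayInd(pick, dim(truth$values))
  scenario <- list(pattern = "MCAR", x_pct = x_pct, r_pct = r_pct,
                   lod = NA_real_, seed = seed)
  mask_positions(truth, theta, scenario)
}

# Allocate n draws over strata proportionally to `weights` by largest-
# remainder rounding, respecting per-stratum capacities. Falls back to
# uniform weights when all weights are zero.
allocate_proportional <- function(n, weights, capacity) {
  stopifnot(length(weights) == length(capacity))
  if (sum(capacity) < n)
    stop(sprintf("insufficient cells: need %d, attainable maximum %d",
                 n, sum(capacity)))
  w <- weights
  w[capacity == 0] <- 0
  # all-zero profile: fall back to uniform over eligible cells, i.e.
  # capacity-proportional over strata
  if (sum(w) == 0) w <- as.numeric(capacity)
  alloc <- integer(length(w))
  remaining <- n
  # iterate because capping one stratum redistributes its excess
  repeat {
    active <- which(capacity > alloc & w > 0)
    if (remaining == 0L || length(active) == 0L) break
    share <- remaining * w[active] / sum(w[active])
    add <- floor(share)
    rem <- share - add
    leftover <- remaining - sum(add)
    if (leftover > 0L) {
      top <- order(rem, decreasing = TRUE)[seq_len(leftover)]
      add[top] <- add[top] + 1L
    }
    add <- pmin(add, capacity[active] - alloc[active])
    alloc[active] <- alloc[active] + add
    if (sum(add) == 0L) {    # weighted strata saturated: spill by capacity
      w <- as.numeric(capacity - alloc)
    }
    remaining <- n - sum(alloc)
  }
  if (remaining > 0L) {      # spill into any stratum with room left
    room <- which(capacity > alloc)
    for (b in room) {
      take <- min(remaining, capacity[b] - alloc[b])
      alloc[b] <- alloc[b] + take
      remaining <- remaining - take
      if (remaining == 0L) break
    }
  }
  alloc
}

# sample `counts[b]` observed cells from each interval stratum; cells is a
# list of linear-index vectors per stratum
sample_strata <- function(cells, counts) {
  picked <- mapply(function(cel, k) {
    if (k == 0L) integer(0)
    else if (length(cel) == 1L && k == 1L) cel
    else sample(cel, k)
  }, cells, counts, SIMPLIFY = FALSE)
  unlist(picked, use.names = FALSE)
}

# linear indices of observed cells per profile interval, restricted to
# below-LOD (strictly) or above-LOD (>=) strata
stratum_cells <- function(truth, profile, lod, side = c("below", "above")) {
  side <- match.arg(side)
  lv <- log10_values(truth)
  obs <- !is.na(truth$values)
  edges <- profile$bin_edges
  nb <- profile$n_intervals
  sel <- if (side == "below") obs & lv < lod else obs & lv >= lod
  idx <- which(sel)
  if (nb == 1L) return(list(cells = list(idx), bins = 1L))
  b <- findInterval(lv[idx], edges, rightmost.closed = TRUE, all.inside = TRUE)
  b <- pmin(pmax(b, 1L), nb)
  list(cells = split(idx, factor(b, levels = seq_len(nb))),
       bins = seq_len(nb))
}

#' Simulate MNAR (below-LOD) missingness
#'
#' Places every artificial NA on an observed cell whose true log10 abundance
#' lies strictly below the LOD, emulating limit-of-detection censoring. The
#' artificial NAs are distributed across the below-LOD abundance intervals
#' proportionally to the interval profile's missing percentages, so the
#' simulated censoring follows the original dataset's low-abundance
#' missingness trend; intervals above the LOD are left untouched. When the
#' profile carries no missingness below the LOD (e.g. a complete synthetic
#' truth), the allocation falls back to uniform over the below-LOD cells.
#'
#' @param truth an `abundance_matrix`
#' @param x_pct,r_pct target total and original missing percentages of the
#'   grid, as in [simulate_mcar()]
#' @param lod log10-abundance threshold, e.g. from [determine_lod()]
#' @param profile an `interval_profile` of the original data; computed from
#'   `truth` when omitted
#' @param seed integer seed
#' @return a `simulated_dataset`
#' @export
simulate_mnar <- function(truth, x_pct,
                          r_pct = 100 * mean(is.na(truth$values)),
                          lod = determine_lod(truth),
                          profile = missingness_profile(truth), seed = 1L) {
  I <- nrow(truth$values); J <- ncol(truth$values)
  n_art <- artificial_count(x_pct, r_pct, I, J)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  theta <- arrayInd(draw_below_lod(truth, profile, lod, n_art),
                    dim(truth$values))
  scenario <- list(pattern = "MNAR", x_pct = x_pct, r_pct = r_pct,
                   lod = lod, seed = seed)
  mask_positions(truth, theta, scenario)
}

draw_below_lod <- function(truth, profile, lod, n_art) {
  if (n_art == 0L) return(integer(0))
  st <- stratum_cells(truth, profile, lod, "below")
  capacity <- lengths(st$cells)
  if (sum(capacity) == 0L) stop("no observed cells below the LOD")
  weights <- profile$missing_pct[st$bins]
  counts <- allocate_proportional(n_art, weights, capacity)
  sample_strata(st$cells, counts)
}

#' Simulate mixed missingness (MM)
#'
#' The mixed pattern allocates the artificial NAs as 20% MCAR/MAR among
#' observed cells at or above the LOD and 80% MNAR among cells below it:
#' exactly round(0.20 * n) cells uniformly above the LOD and the remaining
#' n - round(0.20 * n) below, distributed across the below-LOD intervals as
#' in [simulate_mnar()].
#'
#' @inheritParams simulate_mnar
#' @param mcar_share fraction of artificial NAs assigned to the above-LOD
#'   MCAR stratum, default 0.20
#' @return a `simulated_dataset`
#' @export
simulate_mm <- function(truth, x_pct,
                        r_pct = 100 * mean(is.na(truth$values)),
                        lod = determine_lod(truth),
                        profile = missingness_profile(truth), seed = 1L,
                        mcar_share = 0.20) {
  I <- nrow(truth$values); J <- ncol(truth$values)
  n_art <- artificial_count(x_pct, r_pct, I, J)
  n_above <- round(mcar_share * n_art)
  n_below <- n_art - n_above

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lv <- log10_values(truth)
  above_cells <- which(!is.na(truth$values) & lv >= lod)
  if (length(above_cells) < n_above)
    stop(sprintf("insufficient above-LOD cells: need %d, attainable maximum %d",
                 n_above, length(above_cells)))
  pick_above <- if (n_above > 0L) sample(above_cells, n_above) else integer(0)
  pick_below <- draw_below_lod(truth, profile, lod, n_below)
  theta <- arrayInd(c(pick_above, pick_below), dim(truth$values))
  scenario <- list(pattern = "MM", x_pct = x_pct, r_pct = r_pct,
                   lod = lod, seed = seed, n_above = n_above,
                   n_below = n_below)
  mask_positions(truth, theta, scenario)
}

#' Outlier replacement values for one metabolite
#'
#' The sampling routine behind [inject_outliers()]: draws from
#' Normal(mu, (sd_multiplier * sigma)^2), where mu and sigma are the
#' metabolite's observed mean and standard deviation on the raw scale.
#' By default non-positive draws are rejected and redrawn so the perturbed
#' matrix stays admissible for log-scale factorization.
#'
#' @param n number of draws
#' @param mu,sigma the metabolite's observed mean and SD
#' @param sd_multiplier inflation factor of the SD, default 5
#' @param positive_only reject-and-redraw non-positive values (default TRUE)
#' @return numeric vector of n replacement values
#' @export
outlier_values <- function(n, mu, sigma, sd_multiplier = 5,
                           positive_only = TRUE) {
  draws <- stats::rnorm(n, mu, sd_multiplier * sigma)
  if (positive_only) {
    bad <- which(draws <= 0)
    guard <- 0L
    while (length(bad) > 0L && guard < 1000L) {
      draws[bad] <- stats::rnorm(length(bad), mu, sd_multiplier * sigma)
      bad <- which(draws <= 0)
      guard <- guard + 1L
    }
    if (length(bad) > 0L)
      draws[bad] <- mu   # pathological mu/sigma; keep the matrix valid
  }
  draws
}

#' Inject artificial outliers
#'
#' Replaces a uniformly chosen fraction of the observed entries with draws
#' from Normal(mu_i, (sd_multiplier * sigma_i)^2), mu_i and sigma_i being the
#' row metabolite's observed mean and SD: large but plausible intensity
#' excursions of the kind ion suppression or integration errors produce.
#' Metabolites with fewer than two observed values are skipped with a warning
#' (their SD is undefined).
#'
#' @param truth raw-scale `abundance_matrix`
#' @param fraction proportion of observed entries to replace (0 < fraction < 1);
#'   the study levels are 0.01, 0.03, 0.05
#' @param sd_multiplier SD inflation, default 5
#' @param seed integer seed
#' @return list with `matrix` (the perturbed `abundance_matrix`) and `spec`
#'   (an `outlier_spec`: fraction, sd_multiplier, seed, and a data frame
#'   `replaced` of positions with their original and new values)
#' @export
inject_outliers <- function(truth, fraction, sd_multiplier = 5, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  v <- truth$values
  obs_idx <- which(!is.na(v))
  n_rep <- round(fraction * length(obs_idx))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  replaced <- data.frame(row = integer(0), col = integer(0),
                         original = numeric(0), outlier = numeric(0))
  if (n_rep > 0L) {
    pick <- sample(obs_idx, n_rep)
    pos <- arrayInd(pick, dim(v))
    n_obs_row <- rowSums(!is.na(v))
    ok <- n_obs_row[pos[, 1L]] >= 2L
    if (any(!ok)) {
      warning(sprintf("%d cell(s) skipped: metabolite has < 2 observed values",
                      sum(!ok)))
      pos <- pos[ok, , drop = FALSE]
    }
    if (nrow(pos)) {
      mu <- rowMeans(v, na.rm = TRUE)
      sdv <- apply(v, 1L, stats::sd, na.rm = TRUE)
      orig <- v[pos]
      new <- vapply(seq_len(nrow(pos)), function(t) {
        i <- pos[t, 1L]
        outlier_values(1L, mu[i], sdv[i], sd_multiplier)
      }, numeric(1))
      v[pos] <- new
      replaced <- data.frame(row = pos[, 1L], col = pos[, 2L],
                             original = orig, outlier = new)
    }
  }
  out <- abundance_matrix(v, scale = truth$scale, offset = truth$offset)
  spec <- structure(list(fraction = fraction, sd_multiplier = sd_multiplier,
                         seed = seed, replaced = replaced),
                    class = "outlier_spec")
  list(matrix = out, spec = spec)
}

#' @export
print.outlier_spec <- function(x, ...) {
  cat(sprintf("outlier_spec: fraction %g, SD multiplier %g, %d cell(s) replaced\n",
              x$fraction, x$sd_multiplier, nrow(x$replaced)))
  invisible(x)
}
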