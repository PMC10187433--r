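#' Autocorrelation of a single-cell p53 trajectory
#'
#' Sample autocorrelation of a (linearly detrended, mean-centred) p53 series,
#' normalized by the lag-0 autocovariance and computed over pairwise-complete
#' frames. Rising baselines otherwise masquerade as long-range correlation, so
#' linear detrending is the default; the choice is recorded in the result.
#' Series are truncated at death (missing frames are dropped from each lagged
#' product).
#'
#' @param x a `cell_trajectory` (its `p53` series is used) or a numeric
#'   series on a uniform grid.
#' @param max_lag largest lag, min (must be smaller than the observed span).
#' @param detrend `"linear"` or `"none"`.
#' @param frame_min frame spacing in min when `x` is a bare numeric vector.
#' @return object of class `acf_result`: list with `lags` (min), `acf`,
#'   `n_frames`, `detrend`.
#' @export
#' @examples
#' tt <- seq(0, 1440, 20)
#' r <- trajectory_acf(cos(2 * pi * tt / 330), max_lag = 600)
#' oscillation_score(r, c(260, 400))
trajectory_acf <- function(x, max_lag = 600, detrend = c("linear", "none"),
                           frame_min = 20) {
  detrend <- match.arg(detrend)
  if (inherits(x, "cell_trajectory")) {
    series <- x$p53
    frame_min <- x$t[2L] - x$t[1L]
  } else {
    series <- as.numeric(x)
  }
  obs <- which(!is.na(series))
  if (length(obs) < 12L) {
    stop("input error: need >= 12 non-missing frames")
  }
  # truncation at death gives a contiguous observed block
  y <- series[obs[1L]:obs[length(obs)]]
  n <- length(y)
  k_max <- as.integer(floor(max_lag / frame_min))
  if (k_max >= n) {
    stop("input error: 'max_lag' must be smaller than the observed span")
  }
  idx <- which(!is.na(y))
  scale0 <- stats::sd(y[idx])
  if (!is.finite(scale0) || scale0 == 0) {
    stop("degenerate-series error: constant series")
  }
  if (detrend == "linear") {
    fit <- stats::lm.fit(cbind(1, idx), y[idx])
    y[idx] <- fit$residuals
  }
  y <- y - mean(y, na.rm = TRUE)
  c0 <- sum(y[idx]^2) / n
  if (c0 <= (1e-10 * scale0)^2) {
    stop("degenerate-series error: constant series after detrend")
  }
  ac <- vapply(0:k_max, function(k) {
    a <- y[seq_len(n - k)]
    b <- y[seq_len(n - k) + k]
    sum(a * b, na.rm = TRUE) / n / c0
  }, numeric(1L))
  structure(list(lags = (0:k_max) * frame_min, acf = ac,
                 n_frames = length(idx), detrend = detrend),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("acf_result: %d lags (0..%g min), %d frames, detrend = %s\n",
              length(x$lags), max(x$lags), x$n_frames, x$detrend))
  invisible(x)
}

#' @export
plot.acf_result <- function(x, ...) {
  plot(x$lags, x$acf, type = "h", xlab = "lag (min)",
       ylab = "autocorrelation", ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Pooled autocorrelation over a group of cells
#'
#' Pointwise mean autocorrelation with a bootstrap percentile band (cells
#' resampled with replacement). Results must share the same lag spacing and
#' origin; shorter results (e.g. cells truncated by death) contribute to the
#' lags they cover, and the per-lag contributing count is reported.
#'
#' @param group non-empty list of [trajectory_acf()] results.
#' @param B bootstrap replicates.
#' @param conf band coverage.
#' @param seed integer seed for the bootstrap.
#' @return data frame with `lag_min`, `mean_acf`, `lo`, `hi`, `n_cells`.
#' @export
pooled_acf <- function(group, B = 1000, conf = 0.95, seed = 1) {
  if (length(group) == 0L) stop("input error: empty group")
  steps <- vapply(group, function(g) g$lags[2L] - g$lags[1L], numeric(1L))
  orig <- vapply(group, function(g) g$lags[1L], numeric(1L))
  if (length(unique(steps)) != 1L || any(orig != 0)) {
    stop("input error: mixed lag grids")
  }
  kmax <- max(vapply(group, function(g) length(g$lags), integer(1L)))
  mat <- t(vapply(group, function(g) {
    c(g$acf, rep(NA_real_, kmax - length(g$acf)))
  }, numeric(kmax)))
  lags <- seq(0, by = steps[1L], length.out = kmax)
  mean_acf <- colMeans(mat, na.rm = TRUE)
  n_cells <- colSums(!is.na(mat))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  boot <- matrix(NA_real_, B, kmax)
  for (b in seq_len(B)) {
    rs <- mat[sample.int(nrow(mat), replace = TRUE), , drop = FALSE]
    boot[b, ] <- colMeans(rs, na.rm = TRUE)
  }
  a <- (1 - conf) / 2
  data.frame(lag_min = lags, mean_acf = mean_acf,
             lo = apply(boot, 2L, stats::quantile, a, na.rm = TRUE),
             hi = apply(boot, 2L, stats::quantile, 1 - a, na.rm = TRUE),
             n_cells = n_cells)
}

#' Oscillation score of an autocorrelation result
#'
#' The acf value at the first positive local maximum whose lag falls inside
#' `period_window`; 0 when no local maximum exists there (monotone-decaying
#' acf). A pronounced side lobe near the pulse period marks an oscillatory
#' cell; sustained cells decay without recurrence.
#'
#' @param res [trajectory_acf()] result.
#' @param period_window `c(min, max)` lag window in min.
#' @return numeric score (0 when no positive local maximum in the window).
#' @export
oscillation_score <- function(res, period_window = c(260, 400)) {
  if (length(period_window) != 2L || period_window[2L] <= period_window[1L]) {
    stop("input error: empty period window")
  }
  if (period_window[1L] > max(res$lags)) {
    stop("input error: window outside the lag range")
  }
  a <- res$acf
  n <- length(a)
  if (n < 3L) return(0)
  for (k in 2:(n - 1L)) {
    if (res$lags[k] < period_window[1L]) next
    if (res$lags[k] > period_window[2L]) break
    if (!is.na(a[k]) && !is.na(a[k - 1L]) && !is.na(a[k + 1L]) &&
        a[k] > a[k - 1L] && a[k] >= a[k + 1L] && a[k] > 0) {
      return(a[k])
    }
  }
  0
}

#' Compare dying and surviving cells
#'
#' Per-fate summaries of the oscillation score, maximum p53 level and FOXO1
#' phase duration (the observed in-phase time, censored phases included at
#' their censoring time), with a two-sided Wilcoxon rank-sum statistic for
#' each.
#' Cells need at least 12 observed frames (and a span exceeding one period
#' window) to contribute an oscillation score; excluded counts are reported.
#'
#' @param pop `cell_trajectories` table (or list of trajectories).
#' @param features matching [phase_features()] table.
#' @param max_lag acf lag range, min.
#' @param period_window window passed to [oscillation_score()].
#' @return data frame of class `fate_comparison` with one row per metric:
#'   `metric`, `median_dying`, `median_surviving`, `n_dying`, `n_surviving`,
#'   `statistic`, `p_value`; the number of cells excluded from the acf is in
#'   attribute `n_excluded_acf`.
#' @export
compare_fates <- function(pop, features, max_lag = 600,
                          period_window = c(260, 400)) {
  cells <- if (is.data.frame(pop)) split_trajectories(pop) else pop
  died <- vapply(cells, function(cl) isTRUE(cl$died), logical(1L))
  if (!any(died) || all(died)) {
    stop("insufficient-data error: need both dying and surviving cells")
  }
  score <- rep(NA_real_, length(cells))
  excluded <- 0L
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    n_obs <- sum(!is.na(cl$p53))
    span <- (n_obs - 1L) * (cl$t[2L] - cl$t[1L])
    if (n_obs < 12L || span <= period_window[2L]) {
      excluded <- excluded + 1L
      next
    }
    r <- trajectory_acf(cl, max_lag = min(max_lag, span - (cl$t[2L] - cl$t[1L])))
    score[i] <- oscillation_score(r, period_window)
  }
  maxp <- vapply(cells, function(cl) {
    if (all(is.na(cl$p53))) NA_real_ else max(cl$p53, na.rm = TRUE)
  }, numeric(1L))
  # observed in-phase time: completed duration, or the phase time accrued
  # up to the censoring event (death or movie end) when the exit was never seen
  t_end <- max(cells[[1L]]$t)
  obs_dur <- ifelse(!is.na(features$duration), features$duration,
             ifelse(!is.na(features$t_entry),
                    pmin(ifelse(features$died, features$t_death, t_end),
                         t_end) - features$t_entry,
                    NA_real_))
  dur <- stats::setNames(obs_dur, features$cell_id)[
    vapply(cells, `[[`, character(1L), "cell_id")]
  one <- function(metric, v) {
    vd <- v[died & !is.na(v)]; vs <- v[!died & !is.na(v)]
    if (length(vd) == 0L || length(vs) == 0L) {
      return(data.frame(metric = metric, median_dying = NA_real_,
                        median_surviving = NA_real_, n_dying = length(vd),
                        n_surviving = length(vs), statistic = NA_real_,
                        p_value = NA_real_))
    }
    if (length(unique(c(vd, vs))) == 1L) {
      # completely tied groups carry no directional information
      return(data.frame(metric = metric, median_dying = vd[1L],
                        median_surviving = vs[1L], n_dying = length(vd),
                        n_surviving = length(vs), statistic = NA_real_,
                        p_value = 1))
    }
    w <- stats::wilcox.test(vd, vs, exact = FALSE)
    data.frame(metric = metric, median_dying = stats::median(vd),
               median_surviving = stats::median(vs), n_dying = length(vd),
               n_surviving = length(vs), statistic = unname(w$statistic),
               p_value = w$p.value)
  }
  out <- rbind(one("oscillation_score", score),
               one("max_p53", maxp),
               one("duration", dur))
  attr(out, "n_excluded_acf") <- excluded
  class(out) <- c("fate_comparison", "data.frame")
  out
}
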