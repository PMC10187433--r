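#' @title Two-phase trajectory feature extraction
#' @description Detection of the FOXO1 nuclear-residence window (phase entry,
#'   exit, duration), the p53 accumulation onset, the exit-to-onset lag, and
#'   the display helpers (exit-aligned population medians, duration-sorted
#'   heatmap ordering). Events are called with a run-length rule (`m`
#'   consecutive frames, default 2 at 20-min frames) so single noisy frames do
#'   not trigger or terminate a phase.
#' @name dynamics
NULL

# start index of the first run of >= m consecutive TRUEs in x (NA-safe:
# NAs break runs); 0 if none. Optionally only consider runs starting at or
# after index 'from'.
.first_run <- function(x, m, from = 1L) {
  x <- !is.na(x) & x
  n <- length(x)
  if (n < m) return(0L)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (x[i]) run + 1L else 0L
    if (run >= m && (i - m + 1L) >= from) return(i - m + 1L)
  }
  0L
}

#' Detect the FOXO1 phase of a single trajectory
#'
#' `t_entry` is the start of the first run of at least `m` consecutive frames
#' with FOXO1 nuclear fraction above the activation cutoff; `t_exit` is the
#' start of the first subsequent run of at least `m` frames at or below it.
#' A phase still open at the last observed frame is censored: by death when
#' the cell died, otherwise by the end of the movie.
#'
#' @param traj a `cell_trajectory` (see [generate_trajectory()]).
#' @param th [fit_thresholds()] object (its `foxo_nf_cut` is used).
#' @param m run length in frames (>= 1).
#' @return one-row data frame with `cell_id`, `t_entry`, `t_exit`, `duration`,
#'   `entry_censored`, `exit_censored` (times in min, `NA` when undefined).
#' @export
detect_phase <- function(traj, th, m = 2) {
  stopifnot(inherits(th, "activation_thresholds"), m >= 1)
  t <- traj$t
  if (length(t) > 1L) {
    steps <- diff(t)
    if (any(abs(steps - steps[1L]) > 1e-8)) {
      stop("input error: trajectory must be on a uniform time grid")
    }
  }
  nf <- traj$foxo1_nf
  obs <- which(!is.na(nf))
  last_obs <- if (length(obs)) obs[length(obs)] else 0L
  cut <- th$foxo_nf_cut
  i_entry <- .first_run(nf > cut, m)
  t_entry <- t_exit <- duration <- NA_real_
  entry_cens <- exit_cens <- FALSE
  if (i_entry > 0L) {
    t_entry <- t[i_entry]
    i_exit <- .first_run(nf <= cut, m, from = i_entry + 1L)
    if (i_exit > 0L) {
      t_exit <- t[i_exit]
      duration <- t_exit - t_entry
    } else {
      exit_cens <- TRUE  # phase open at death or end of movie
    }
  } else if (isTRUE(traj$died) && last_obs < length(t)) {
    # died without a detected entry: entry may have been missed
    entry_cens <- TRUE
  }
  data.frame(cell_id = traj$cell_id, t_entry = t_entry, t_exit = t_exit,
             duration = duration, entry_censored = entry_cens,
             exit_censored = exit_cens)
}

#' Detect the p53 accumulation onset of a single trajectory
#'
#' The baseline mean and sd are computed from the first `baseline_frames`
#' observed frames; the onset is the start of the first run of at least 2
#' frames with p53 above mean + `k` sd. A degenerate baseline (sd = 0) falls
#' back to a relative rule (20% above the baseline mean), recorded in the
#' output.
#'
#' @param traj a `cell_trajectory`.
#' @param k sd multiplier.
#' @param baseline_frames number of baseline frames (>= 2).
#' @return one-row data frame with `cell_id`, `t_onset`, `onset_censored`
#'   (death or movie end before any onset), `onset_rule` (`"sd"` or
#'   `"relative"`).
#' @export
detect_p53_onset <- function(traj, k = 3, baseline_frames = 3) {
  stopifnot(baseline_frames >= 2)
  t <- traj$t
  p <- traj$p53
  obs <- which(!is.na(p))
  if (length(obs) < baseline_frames) {
    return(data.frame(cell_id = traj$cell_id, t_onset = NA_real_,
                      onset_censored = TRUE, onset_rule = NA_character_))
  }
  base <- p[obs[seq_len(baseline_frames)]]
  mu <- mean(base); sdv <- stats::sd(base)
  rule <- "sd"
  if (!is.finite(sdv) || sdv == 0) {
    thr <- 1.2 * mu
    rule <- "relative"
  } else {
    thr <- mu + k * sdv
  }
  i_on <- .first_run(p > thr, 2L)
  t_onset <- if (i_on > 0L) t[i_on] else NA_real_
  cens <- is.na(t_onset) &&
    (isTRUE(traj$died) || length(obs) < length(t))
  data.frame(cell_id = traj$cell_id, t_onset = t_onset,
             onset_censored = cens, onset_rule = rule)
}

#' Phase and onset features for a whole population
#'
#' Runs [detect_phase()] and [detect_p53_onset()] on every cell and combines
#' them with the lag (`t_onset - t_exit`, defined only when both events are
#' detected and uncensored).
#'
#' @param pop a `cell_trajectories` data frame (or list of `cell_trajectory`).
#' @param th [fit_thresholds()] object.
#' @param m run length for phase detection.
#' @param k,baseline_frames onset-detection settings.
#' @return data frame of class `phase_features`: `cell_id`, `t_entry`,
#'   `t_exit`, `duration`, `t_onset`, `lag`, `entry_censored`,
#'   `exit_censored`, `onset_censored`, `died`, `t_death`.
#' @export
phase_features <- function(pop, th, m = 2, k = 3, baseline_frames = 3) {
  cells <- if (is.data.frame(pop)) split_trajectories(pop) else pop
  rows <- lapply(cells, function(cl) {
    ph <- detect_phase(cl, th, m = m)
    on <- detect_p53_onset(cl, k = k, baseline_frames = baseline_frames)
    lag <- if (!is.na(ph$t_exit) && !is.na(on$t_onset))
      on$t_onset - ph$t_exit else NA_real_
    cbind(ph, on[, c("t_onset", "onset_censored", "onset_rule")],
          data.frame(lag = lag, died = isTRUE(cl$died),
                     t_death = cl$t_death))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phase_features", "data.frame")
  out
}

#' Exit-aligned population median traces
#'
#' Re-indexes every cell with a detected (uncensored) FOXO1 exit on a relative
#' time grid centred at its exit and reports the per-offset median FOXO1
#' nuclear fraction and p53 level over the cells contributing an observation
#' at that offset.
#'
#' @param pop `cell_trajectories` table (or list of trajectories).
#' @param features matching [phase_features()] table.
#' @param window half-width of the relative grid, min.
#' @return data frame with `rel_t_min`, `foxo1_nf_median`, `p53_median`,
#'   `n_cells`.
#' @export
exit_align <- function(pop, features, window = 600) {
  cells <- if (is.data.frame(pop)) split_trajectories(pop) else pop
  names(cells) <- vapply(cells, `[[`, character(1L), "cell_id")
  ok <- features$cell_id[!is.na(features$t_exit)]
  if (length(ok) < 10L) {
    stop("insufficient-data error: fewer than 10 cells with a detected exit")
  }
  step <- cells[[1L]]$t[2L] - cells[[1L]]$t[1L]
  rel <- seq(-window, window, by = step)
  acc_nf <- vector("list", length(ok))
  acc_p <- vector("list", length(ok))
  exits <- stats::setNames(features$t_exit, features$cell_id)
  for (i in seq_along(ok)) {
    cl <- cells[[ok[i]]]
    r <- cl$t - exits[[ok[i]]]
    idx <- match(rel, r)
    acc_nf[[i]] <- cl$foxo1_nf[idx]
    acc_p[[i]] <- cl$p53[idx]
  }
  nf_m <- apply(do.call(rbind, acc_nf), 2L, stats::median, na.rm = TRUE)
  p_m <- apply(do.call(rbind, acc_p), 2L, stats::median, na.rm = TRUE)
  n_c <- colSums(!is.na(do.call(rbind, acc_p)))
  out <- data.frame(rel_t_min = rel, foxo1_nf_median = nf_m,
                    p53_median = p_m, n_cells = n_c)
  out[out$n_cells > 0L, , drop = FALSE]
}

#' Median exit-to-onset lag
#'
#' @param features [phase_features()] table.
#' @return list with `median_lag`, `iqr`, `n` (cells with a defined lag) and
#'   `n_censored` (cells whose exit or onset was censored).
#' @export
lag_summary <- function(features) {
  lags <- features$lag[!is.na(features$lag)]
  if (length(lags) == 0L) {
    stop("insufficient-data error: no cells with a defined lag")
  }
  list(median_lag = stats::median(lags),
       iqr = stats::IQR(lags),
       n = length(lags),
       n_censored = sum((features$exit_censored | features$onset_censored) &
                          is.na(features$lag)))
}

#' Duration-sorted heatmap ordering
#'
#' Ordering used for single-cell heatmaps: cells without a detected phase
#' first (duration 0, by cell id), then completed phases in ascending
#' duration (ties by cell id), then phases censored by the movie end (by
#' entry time), and last phases censored by death (by death time).
#'
#' @param features [phase_features()] table.
#' @return character vector of cell ids; a permutation of all cells.
#' @export
heatmap_order <- function(features) {
  f <- features
  grp <- ifelse(is.na(f$t_entry), 0L,
         ifelse(!is.na(f$duration), 1L,
         ifelse(f$exit_censored & !f$died, 2L, 3L)))
  key <- ifelse(grp == 0L, 0,
         ifelse(grp == 1L, f$duration,
         ifelse(grp == 2L, f$t_entry, f$t_death)))
  f$cell_id[order(grp, key, f$cell_id)]
}
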