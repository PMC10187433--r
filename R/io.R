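#' @title Table I/O with schema validation
#' @description CSV readers/writers for the package's table schemas
#'   (comma-separated, `.` decimal, UTF-8, `#`-prefixed metadata lines).
#'   Readers fail with the name of any missing required column and preserve
#'   unknown columns with a warning; write-then-read round-trips are lossless
#'   for all defined columns.
#' @name table-io
NULL

.schemas <- list(
  trajectories = c("cell_id", "t_min", "foxo1_nf", "p53", "died", "t_death",
                   "truth_t_entry", "truth_t_exit", "truth_t_onset",
                   "truth_mode", "truth_dose"),
  snapshot = c("cell_id", "dose_uM", "p53_nuc", "foxo1_nf", "gh2ax",
               "truth_foxo_active", "truth_p53_active"),
  redox = c("t_min", "r", "s", "d", "h", "H_uM"),
  quadrants = c("dose_uM", "n", "frac_both", "frac_foxo_only",
                "frac_p53_only", "frac_neither"),
  features = c("cell_id", "t_entry", "t_exit", "duration", "t_onset", "lag",
               "entry_censored", "exit_censored", "onset_censored"),
  measures = c("cell_id", "channel", "nuc_mean", "ring_mean",
               "nuclear_fraction"),
  aligned = c("rel_t_min", "foxo1_nf_median", "p53_median", "n_cells")
)

.read_schema <- function(path, schema, cls = NULL) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- .schemas[[schema]]
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop("schema error: required column(s) missing from ", basename(path),
         ": ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(d), req)
  if (length(extra)) {
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "))
  }
  if (!is.null(cls)) class(d) <- c(cls, "data.frame")
  d
}

.write_schema <- function(x, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' @rdname table-io
#' @param pop,cells,states,x table to write (see the generator and analysis
#'   functions for the schemas).
#' @param path file path.
#' @export
write_trajectories <- function(pop, path) .write_schema(pop, path)

#' @rdname table-io
#' @export
read_trajectories <- function(path) {
  .read_schema(path, "trajectories", "cell_trajectories")
}

#' @rdname table-io
#' @export
write_snapshot <- function(cells, path) .write_schema(cells, path)

#' @rdname table-io
#' @export
read_snapshot <- function(path) .read_schema(path, "snapshot", "snapshot_cells")

#' @rdname table-io
#' @export
write_redox_states <- function(states, path) .write_schema(states, path)

#' @rdname table-io
#' @export
read_redox_states <- function(path) .read_schema(path, "redox", "redox_states")

#' @rdname table-io
#' @param th thresholds echoed as `#` metadata lines.
#' @export
write_quadrants <- function(x, path, th = NULL) {
  meta <- NULL
  if (!is.null(th)) {
    meta <- c(sprintf("foxo_nf_cut=%.6g p53_log_cut=%.6g method=%s q=%g",
                      th$foxo_nf_cut, th$p53_log_cut, th$method$statistic,
                      th$method$parameter))
  }
  .write_schema(x, path, meta = meta)
}

#' @rdname table-io
#' @export
read_quadrants <- function(path) .read_schema(path, "quadrants", "quadrant_table")

#' @rdname table-io
#' @export
write_features <- function(x, path) .write_schema(x, path)

#' @rdname table-io
#' @export
write_measures <- function(x, path) .write_schema(x, path)

#' @rdname table-io
#' @export
write_aligned <- function(x, path) .write_schema(x, path)

#' Pipeline configuration
#'
#' @param doses snapshot dose grid, uM (calibrated presets).
#' @param traj_doses doses simulated as time-lapse populations.
#' @param n_snapshot snapshot cells per dose (and for the dose-0 control).
#' @param n_traj trajectory cells per dose.
#' @param seed master seed; every stage derives its own substream from it, so
#'   stage re-runs are independent of execution order.
#' @param preset perturbation preset name (see [perturb_params()]).
#' @param q control quantile for [fit_thresholds()].
#' @param t_fix snapshot fixation time, min.
#' @param render logical: include the render -> quantify image stage (on a
#'   small subfield) in the run.
#' @param n_render cells in the rendered field.
#' @param outdir output directory (`NULL`: nothing written).
#' @param params [switch_params()] overrides.
#' @param opts [sim_opts()] overrides.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(doses = c(20, 40, 50, 60, 80, 100, 150, 200, 300),
                            traj_doses = c(80, 100), n_snapshot = 1000,
                            n_traj = 150, seed = 1,
                            preset = "default", q = 0.99, t_fix = 300,
                            render = TRUE, n_render = 25, outdir = NULL,
                            params = switch_params(), opts = sim_opts()) {
  structure(list(doses = doses, traj_doses = traj_doses,
                 n_snapshot = n_snapshot, n_traj = n_traj, seed = seed,
                 preset = preset, q = q, t_fix = t_fix, render = render,
                 n_render = n_render, outdir = outdir, params = params,
                 opts = opts), class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> (render -> quantify) -> gate -> features -> acf ->
#' summary on seeded synthetic populations: snapshot populations over the dose
#' grid are gated against a dose-0 control, time-lapse populations at the
#' trajectory doses are run through phase/onset detection, exit alignment and
#' lag estimation, and p53 autocorrelations are compared between dying and
#' surviving cells. With an output directory set, every stage's tables, the
#' resolved configuration (seed and package version included) and a
#' machine-readable JSON summary are written.
#'
#' @param config [pipeline_config()].
#' @return the summary as a named list (invisibly the same list that is
#'   written as JSON): thresholds, per-dose quadrant fractions with
#'   `max_frac_both`, median detected entry time, median exit-to-onset lag,
#'   per-dose death fractions, oscillation scores and p53/duration medians by
#'   fate, and the render-recovery error when the image stage ran.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  params <- perturb_params(config$params, config$preset)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  sseed <- sample.int(2^30, 8)  # named substreams, order-independent
  names(sseed) <- c("control", "snapshot", "traj", "render", "acf",
                    "boot", "spare1", "spare2")
  out <- if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    function(x) file.path(config$outdir, x)
  } else NULL

  message("stage simulate: control + ", length(config$doses),
          " snapshot doses, n = ", config$n_snapshot, "/dose")
  control <- .stage("simulate", generate_snapshot(
    config$n_snapshot, dose_preset(0), t_fix = config$t_fix, params = params,
    seed = sseed[["control"]], opts = config$opts))
  snaps <- .stage("simulate", lapply(seq_along(config$doses), function(i) {
    generate_snapshot(config$n_snapshot, dose_preset(config$doses[i]),
                      t_fix = config$t_fix, params = params,
                      seed = sseed[["snapshot"]] + i, opts = config$opts)
  }))
  snap_all <- do.call(rbind, snaps)

  render_mae <- NULL
  if (isTRUE(config$render)) {
    message("stage render/quantify: ", config$n_render, " cells")
    render_mae <- .stage("quantify", {
      sub <- snaps[[1L]][seq_len(min(config$n_render, nrow(snaps[[1L]]))), ]
      side <- ceiling(sqrt(nrow(sub)))
      g <- field_geometry(width = 36 * side + 18, height = 36 * side + 18)
      set.seed(sseed[["render"]])
      fld <- render_field(sub, g, noise = "poisson")
      m <- measure_cells(fld$image, fld$mask)
      mf <- m[m$channel == "foxo1", ]
      mean(abs(mf$nuclear_fraction[order(mf$cell_id)] - sub$foxo1_nf))
    })
  }

  message("stage gate")
  th <- .stage("gate", fit_thresholds(control, q = config$q))
  labels <- .stage("gate", classify_cells(snap_all, th))
  quad <- .stage("gate", quadrant_table(labels, snap_all$dose_uM))

  message("stage features: trajectories at ",
          paste(config$traj_doses, collapse = "/"), " uM, n = ",
          config$n_traj, "/dose")
  pops <- .stage("simulate", lapply(seq_along(config$traj_doses), function(i) {
    generate_population(config$n_traj, dose_preset(config$traj_doses[i]),
                        params = params, seed = sseed[["traj"]] + i,
                        opts = config$opts)
  }))
  pop <- do.call(rbind, pops)
  pop$cell_id <- paste0(rep(paste0("d", config$traj_doses),
                            each = nrow(pops[[1L]])), "_", pop$cell_id)
  class(pop) <- c("cell_trajectories", "data.frame")
  feats <- .stage("features", phase_features(pop, th))
  # degrade gracefully when a condition has too few alignable cells
  # (e.g. a dose-0-only run has no phases at all)
  .maybe <- function(expr) {
    tryCatch(expr, error = function(e) {
      if (grepl("insufficient-data", conditionMessage(e))) NULL else stop(e)
    })
  }
  aligned <- .stage("features", .maybe(exit_align(pop, feats)))
  lag <- .stage("features", .maybe(lag_summary(feats)))
  if (is.null(lag)) lag <- list(median_lag = NA_real_, n = 0L)
  entries <- feats$t_entry[!is.na(feats$t_entry)]
  death_fracs <- vapply(split(feats$died, sub("_cell.*$", "", feats$cell_id)),
                        mean, numeric(1L))

  message("stage acf")
  fates <- .stage("acf", .maybe(compare_fates(pop, feats)))
  .fate <- function(metric, col) {
    if (is.null(fates)) NA_real_ else fates[[col]][fates$metric == metric]
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("prdxswitch")),
    seed = config$seed,
    preset = config$preset,
    thresholds = list(foxo_nf_cut = th$foxo_nf_cut,
                      p53_log_cut = th$p53_log_cut),
    max_frac_both = attr(quad, "max_frac_both"),
    median_entry_min = if (length(entries)) stats::median(entries) else NA,
    median_lag_min = lag$median_lag,
    n_lag = lag$n,
    death_fraction = as.list(death_fracs),
    n_phase_cells = sum(!is.na(feats$t_entry)),
    oscillation_score_dying = .fate("oscillation_score", "median_dying"),
    oscillation_score_surviving = .fate("oscillation_score",
                                        "median_surviving"),
    max_p53_dying = .fate("max_p53", "median_dying"),
    max_p53_surviving = .fate("max_p53", "median_surviving"),
    render_foxo1_nf_mae = render_mae
  )
  if (!is.null(out)) {
    .stage("summary", {
      write_snapshot(rbind(control, snap_all), out("snapshot_cells.csv"))
      write_quadrants(quad, out("quadrants.csv"), th = th)
      write_trajectories(pop, out("trajectories.csv"))
      write_features(feats, out("phase_features.csv"))
      if (!is.null(aligned)) write_aligned(aligned, out("exit_aligned.csv"))
      if (!is.null(fates)) {
        utils::write.csv(fates, out("fate_comparison.csv"), row.names = FALSE)
      }
      cfg <- unclass(config)
      cfg$params <- unclass(cfg$params)
      cfg$opts <- unclass(cfg$opts)
      cfg$outdir <- NULL
      jsonlite::write_json(list(config = cfg, substreams = as.list(sseed)),
                           out("resolved_config.json"), auto_unbox = TRUE,
                           digits = NA)
      jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                           digits = NA)
    })
  }
  invisible(summary)
}
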