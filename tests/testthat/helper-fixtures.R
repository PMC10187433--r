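# Shared fixtures, built once per test run. All synthetic, all seeded.

.fx <- new.env(parent = emptyenv())

fx_params <- function() switch_params()

# dose-0 control snapshot and thresholds fitted on it
fx_thresholds <- function() {
  if (is.null(.fx$th)) {
    .fx$control <- generate_snapshot(600, dose_preset(0), seed = 101)
    .fx$th <- fit_thresholds(.fx$control, q = 0.99)
  }
  .fx$th
}
fx_control <- function() {
  fx_thresholds()
  .fx$control
}

# a default-noise 100 uM trajectory population used by several suites
fx_pop100 <- function() {
  if (is.null(.fx$pop100)) {
    .fx$pop100 <- generate_population(300, dose_preset(100), fx_params(),
                                      seed = 202)
  }
  .fx$pop100
}

fx_features100 <- function() {
  if (is.null(.fx$fe100)) {
    .fx$fe100 <- phase_features(fx_pop100(), fx_thresholds())
  }
  .fx$fe100
}

# pooled 80 + 100 uM population, the condition used for the dying-vs-surviving
# comparisons
fx_pool <- function() {
  if (is.null(.fx$pool)) {
    p80 <- generate_population(200, dose_preset(80), fx_params(), seed = 203)
    p100 <- generate_population(200, dose_preset(100), fx_params(), seed = 204)
    p100$cell_id <- paste0("h_", p100$cell_id)
    pool <- rbind(p80, p100)
    class(pool) <- c("cell_trajectories", "data.frame")
    .fx$pool <- pool
    .fx$fe_pool <- phase_features(pool, fx_thresholds())
  }
  .fx$pool
}
fx_features_pool <- function() {
  fx_pool()
  .fx$fe_pool
}

# hand-built single-cell trajectory on the standard 20-min grid
make_traj <- function(foxo1_nf, p53 = NULL, frame_min = 20,
                      died = FALSE, t_death = NA_real_, cell_id = "c1") {
  n <- length(foxo1_nf)
  if (is.null(p53)) p53 <- rep(1, n)
  structure(list(cell_id = cell_id,
                 t = seq(0, by = frame_min, length.out = n),
                 foxo1_nf = foxo1_nf, p53 = p53, died = died,
                 t_death = t_death,
                 truth = list(t_entry = NA_real_, t_exit = NA_real_,
                              t_onset = NA_real_, mode = "oscillatory",
                              dose = 0)),
            class = "cell_trajectory")
}

# fixed thresholds for hand-built trajectories
make_th <- function(foxo_cut = 0.5, p53_cut = 0.3) {
  structure(list(foxo_nf_cut = foxo_cut, p53_log_cut = p53_cut,
                 method = list(statistic = "fixed", parameter = NA,
                               n_control = 0L)),
            class = "activation_thresholds")
}
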