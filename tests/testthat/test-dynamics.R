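test_that("flat sub-threshold trajectories yield no features and no censoring", {
  tr <- make_traj(rep(0.3, 73))
  ph <- detect_phase(tr, make_th())
  expect_true(is.na(ph$t_entry) && is.na(ph$t_exit) && is.na(ph$duration))
  expect_false(ph$entry_censored || ph$exit_censored)
  on <- detect_p53_onset(make_traj(rep(0.3, 73), p53 = rep(2, 73)))
  expect_true(is.na(on$t_onset))
})

test_that("noise-free step trajectories are detected exactly", {
  nf <- rep(0.3, 73)
  nf[(40 / 20 + 1):(400 / 20)] <- 0.8  # in nucleus [40, 400)
  ph <- detect_phase(make_traj(nf), make_th())
  expect_equal(ph$t_entry, 40)
  expect_equal(ph$t_exit, 400)
  expect_equal(ph$duration, 360)
  p53 <- rep(1, 73)
  p53[(460 / 20 + 1):73] <- 5
  on <- detect_p53_onset(make_traj(rep(0.3, 73), p53 = p53))
  expect_equal(on$t_onset, 460)
  expect_identical(on$onset_rule, "relative")  # constant baseline fallback
})

test_that("single noisy frames do not open or close a phase", {
  nf <- rep(0.3, 73)
  nf[10] <- 0.9  # one-frame spike
  ph <- detect_phase(make_traj(nf), make_th())
  expect_true(is.na(ph$t_entry))
  nf2 <- rep(0.8, 73)
  nf2[30] <- 0.2  # one-frame dip inside a long phase
  ph2 <- detect_phase(make_traj(nf2), make_th())
  expect_equal(ph2$t_entry, 0)
  expect_true(is.na(ph2$t_exit))
  expect_true(ph2$exit_censored)
})

test_that("non-uniform grids are rejected", {
  tr <- make_traj(rep(0.3, 10))
  tr$t[5] <- tr$t[5] + 3
  expect_error(detect_phase(tr, make_th()), "uniform time grid")
})

test_that("detection recovers simulator ground truth within one frame", {
  fe <- fx_features100()
  pop <- fx_pop100()
  one <- pop[!duplicated(pop$cell_id), ]
  truth_entry <- setNames(one$truth_t_entry, one$cell_id)[fe$cell_id]
  truth_exit <- setNames(one$truth_t_exit, one$cell_id)[fe$cell_id]
  truth_onset <- setNames(one$truth_t_onset, one$cell_id)[fe$cell_id]
  ok_e <- !is.na(fe$t_entry) & !is.na(truth_entry)
  expect_gt(sum(ok_e), 200)
  expect_lte(median(abs(fe$t_entry[ok_e] - truth_entry[ok_e])), 20)
  ok_x <- !is.na(fe$t_exit) & !is.na(truth_exit)
  expect_lte(median(abs(fe$t_exit[ok_x] - truth_exit[ok_x])), 20)
  ok_o <- !is.na(fe$t_onset) & !is.na(truth_onset)
  expect_lte(median(abs(fe$t_onset[ok_o] - truth_onset[ok_o])), 20)
})

test_that("lag summary recovers the programmed p53 delay", {
  fe3 <- data.frame(cell_id = c("a", "b", "c"), t_entry = 0, t_exit = 100,
                    duration = 100, t_onset = c(140, 160, 180),
                    lag = c(40, 60, 80), entry_censored = FALSE,
                    exit_censored = FALSE, onset_censored = FALSE)
  expect_equal(lag_summary(fe3)$median_lag, 60)
  # noise-free population: lag is tau_p53 up to frame quantization error
  opts0 <- sim_opts(noise_sd = 0, jitter_cv = 0.1)
  pop0 <- generate_population(50, dose_preset(100), fx_params(), seed = 81,
                              opts = opts0)
  fe0 <- phase_features(pop0, fx_thresholds())
  expect_lte(abs(lag_summary(fe0)$median_lag - 60), 20)
  # default noise, n = 200 pooled over 80+100 uM
  fe <- fx_features100()
  ls <- lag_summary(fe)
  expect_gte(ls$n, 100)
  expect_lte(abs(ls$median_lag - 60), 20)
  expect_error(lag_summary(fe3[0, ]), "insufficient-data")
})

test_that("exit alignment centres trajectories on the FOXO1 exit", {
  # identical cells: the aligned median reproduces any single trace
  nf <- rep(0.3, 73); nf[3:20] <- 0.8
  p53 <- rep(1, 73); p53[24:73] <- 4
  cells <- lapply(1:12, function(i) {
    tr <- make_traj(nf, p53 = p53); tr$cell_id <- paste0("c", i); tr
  })
  fe <- phase_features(cells, make_th())
  al <- exit_align(cells, fe, window = 200)
  expect_equal(al$p53_median[al$rel_t_min == 0], p53[fe$t_exit[1] / 20 + 1])
  expect_true(all(al$n_cells == 12))
  # permutation invariance
  al2 <- exit_align(rev(cells), phase_features(rev(cells), make_th()),
                    window = 200)
  expect_equal(al2$p53_median, al$p53_median)
  expect_error(exit_align(cells[1:3], fe[1:3, ]), "insufficient-data")
})

test_that("aligned median p53 turns on about an hour after FOXO1 exit", {
  pop80 <- generate_population(200, dose_preset(80), fx_params(), seed = 82)
  pop100 <- generate_population(200, dose_preset(100), fx_params(), seed = 83)
  pop100$cell_id <- paste0("h_", pop100$cell_id)
  pool <- rbind(pop80, pop100)
  class(pool) <- c("cell_trajectories", "data.frame")
  fe <- phase_features(pool, fx_thresholds())
  al <- exit_align(pool, fe, window = 400)
  base <- al$p53_median[al$rel_t_min < 0]
  crit <- mean(base) + 3 * sd(base)
  first_on <- al$rel_t_min[al$rel_t_min >= 0 & al$p53_median > crit][1]
  expect_gte(first_on, 40)
  expect_lte(first_on, 80)
})

test_that("heatmap ordering sorts by duration with the censoring rules", {
  fe <- data.frame(
    cell_id = c("a", "b", "c", "d", "e"),
    t_entry = c(NA, 40, 20, 100, 60), t_exit = c(NA, 140, 520, NA, NA),
    duration = c(NA, 100, 500, NA, NA), t_onset = NA, lag = NA,
    entry_censored = FALSE,
    exit_censored = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    onset_censored = FALSE, died = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    t_death = c(NA, NA, NA, NA, 700))
  # phase-less, completed ascending, movie-end censored, death censored
  expect_equal(heatmap_order(fe), c("a", "b", "c", "d", "e"))
  fe2 <- fe
  fe2$duration[2:3] <- 100  # tie broken by id
  expect_equal(heatmap_order(fe2)[2:3], c("b", "c"))
  expect_setequal(heatmap_order(fe), fe$cell_id)
})

test_that("recovered durations increase with dose and with death", {
  med_dur <- vapply(c(80, 100, 300), function(d) {
    pop <- generate_population(150, dose_preset(d), fx_params(),
                               seed = 84)
    fe <- phase_features(pop, fx_thresholds())
    median(fe$duration, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_dur) > 0))
  # dying cells hold FOXO1 in the nucleus longer than survivors
  fe <- fx_features_pool()
  w <- stats::wilcox.test(fe$duration[fe$died], fe$duration[!fe$died],
                          alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 0.05)
})
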