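test_that("population generation is seed-deterministic", {
  a <- generate_population(10, dose_preset(100), fx_params(), seed = 1)
  b <- generate_population(10, dose_preset(100), fx_params(), seed = 1)
  expect_identical(a, b)
  expect_equal(length(unique(a$cell_id)), 10L)
  expect_error(generate_population(0, dose_preset(100), fx_params(), seed = 1),
               "input error")
})

test_that("untreated cells never activate anything", {
  pop <- generate_population(50, dose_preset(0), fx_params(), seed = 2)
  expect_true(all(is.na(pop$truth_t_entry)))
  expect_true(all(is.na(pop$truth_t_onset)))
  expect_false(any(pop$died))
  # FOXO1 stays within measurement noise of its baseline
  expect_lt(max(abs(pop$foxo1_nf - 0.30)), 0.30 * exp(4 * 0.1) - 0.30 + 0.1)
  expect_lt(abs(mean(pop$foxo1_nf) - 0.30), 0.02)
  snap <- generate_snapshot(200, dose_preset(0), seed = 3)
  expect_false(any(snap$truth_foxo_active))
  expect_false(any(snap$truth_p53_active))
})

test_that("FOXO1 enters the nucleus within an hour at high dose", {
  pop <- generate_population(500, dose_preset(100), fx_params(), seed = 4)
  entries <- pop$truth_t_entry[!duplicated(pop$cell_id)]
  entries <- entries[!is.na(entries)]
  expect_gt(length(entries), 400)
  expect_lte(median(entries), 60)
})

test_that("without noise the p53 onset follows exit by exactly tau_p53", {
  opts0 <- sim_opts(noise_sd = 0, jitter_cv = 0)
  pop <- generate_population(5, dose_preset(80), fx_params(), seed = 5,
                             opts = opts0)
  one <- pop[!duplicated(pop$cell_id), ]
  expect_true(all(!is.na(one$truth_t_exit)))
  expect_equal(one$truth_t_onset - one$truth_t_exit, rep(60, 5))
})

test_that("at 50 uM essentially no cell shows a FOXO1 phase", {
  pop <- generate_population(196, dose_preset(50), fx_params(), seed = 6)
  frac_phase <- mean(!is.na(pop$truth_t_entry[!duplicated(pop$cell_id)]))
  expect_lte(frac_phase, 0.02)
})

test_that("FOXO1 phase and p53 activity are mutually exclusive by construction", {
  for (dose in c(50, 100, 300)) {
    pop <- generate_population(150, dose_preset(dose), fx_params(),
                               seed = 7 + dose)
    one <- pop[!duplicated(pop$cell_id), ]
    # p53 onset never falls inside the FOXO1 window
    both <- !is.na(one$truth_t_entry) & !is.na(one$truth_t_onset)
    if (any(both)) {
      expect_true(all(one$truth_t_onset[both] >= one$truth_t_exit[both]))
    }
    # phase-less activated cells switch on at the first frame, after t = 0
    lowroute <- is.na(one$truth_t_entry) & !is.na(one$truth_t_onset)
    if (any(lowroute)) {
      expect_true(all(one$truth_t_onset[lowroute] > 0))
    }
  }
})

test_that("dose ordering of phase fraction, duration and p53 activity holds", {
  doses <- c(50, 80, 100, 300)
  stats_by_dose <- lapply(doses, function(d) {
    pop <- generate_population(250, dose_preset(d), fx_params(),
                               seed = 900 + d)
    one <- pop[!duplicated(pop$cell_id), ]
    dur <- one$truth_t_exit - one$truth_t_entry
    list(frac_phase = mean(!is.na(one$truth_t_entry)),
         mean_dur = mean(dur, na.rm = TRUE),
         died = mean(one$died))
  })
  frac <- vapply(stats_by_dose, `[[`, numeric(1), "frac_phase")
  expect_true(all(diff(frac) >= 0))
  dur <- vapply(stats_by_dose, `[[`, numeric(1), "mean_dur")
  expect_true(all(diff(dur[-1]) > 0))  # durations over 80 -> 100 -> 300
  died <- vapply(stats_by_dose, `[[`, numeric(1), "died")
  expect_true(all(diff(died) > 0))
  # p53-active fraction at the 5-h snapshot peaks at intermediate doses
  p53_frac <- vapply(c(0, 50, 100, 300), function(d) {
    mean(generate_snapshot(400, dose_preset(d), seed = 77)$truth_p53_active)
  }, numeric(1))
  expect_equal(which.max(p53_frac), 2L)
})

test_that("snapshot gamma-H2AX rises with dose while p53 does not", {
  sn <- lapply(c(0, 50, 100, 200), function(d) {
    generate_snapshot(2000, dose_preset(d), seed = 11)
  })
  gh <- vapply(sn, function(s) mean(s$gh2ax), numeric(1))
  expect_true(all(diff(gh) > 0))
  p53 <- vapply(sn, function(s) mean(s$p53_nuc), numeric(1))
  # 200 uM is back within noise of untreated, and below the 50-100 uM peak
  expect_lt(abs(p53[4] - p53[1]) / p53[1], 0.1)
  expect_lt(p53[4], p53[2])
  expect_lt(p53[4], p53[3])
})

test_that("death calibration hits its target and is monotone", {
  expect_equal(as.numeric(calibrate_death(fx_params(), dose_preset(100), 0)), 0)
  m <- calibrate_death(fx_params(), dose_preset(100), 0.34, n_mc = 20000,
                       tol = 0.01, seed = 1)
  pr <- dose_preset(100, death_mult = as.numeric(m))
  pop <- generate_population(2000, pr, fx_params(), seed = 12)
  frac <- mean(pop$died[!duplicated(pop$cell_id)])
  expect_lt(abs(frac - 0.34), 0.01 + 2 * sqrt(0.34 * 0.66 / 2000))
  m98 <- calibrate_death(fx_params(), dose_preset(300), 0.98, n_mc = 20000,
                         tol = 0.01, seed = 1)
  pr98 <- dose_preset(300, death_mult = as.numeric(m98))
  pop98 <- generate_population(2000, pr98, fx_params(), seed = 13)
  frac98 <- mean(pop98$died[!duplicated(pop98$cell_id)])
  expect_lt(abs(frac98 - 0.98), 0.01 + 2 * sqrt(0.98 * 0.02 / 2000))
  expect_gt(as.numeric(m98), as.numeric(m))
  expect_error(calibrate_death(fx_params(), dose_preset(20), 0.9999,
                               n_mc = 500, mult_range = c(0, 0.01)),
               "calibration error")
})

test_that("perturbation presets shift populations in the printed directions", {
  frac_phase <- function(preset, dose, seed) {
    p <- perturb_params(fx_params(), preset)
    pop <- generate_population(200, dose_preset(dose), p, seed = seed)
    mean(!is.na(pop$truth_t_entry[!duplicated(pop$cell_id)]))
  }
  # SRXN1 overexpression suppresses the FOXO1 response at 80 uM
  expect_lt(frac_phase("srxn1oe", 80, 21), frac_phase("default", 80, 21) - 0.2)
  # PRDX1 knockout opens the window at 40-50 uM where controls show none
  expect_gt(frac_phase("prdx1ko", 50, 22), frac_phase("default", 50, 22) + 0.5)
  expect_gt(frac_phase("prdx1ko", 40, 23), 0.05)
  # near-zero repair prolongs phases and delays onsets
  pj <- perturb_params(fx_params(), "j14")
  popj <- generate_population(100, dose_preset(100), pj, seed = 24)
  popd <- generate_population(100, dose_preset(100), fx_params(), seed = 24)
  onej <- popj[!duplicated(popj$cell_id), ]
  oned <- popd[!duplicated(popd$cell_id), ]
  durj <- ifelse(is.na(onej$truth_t_exit), 1440 - onej$truth_t_entry,
                 onej$truth_t_exit - onej$truth_t_entry)
  durd <- ifelse(is.na(oned$truth_t_exit), 1440 - oned$truth_t_entry,
                 oned$truth_t_exit - oned$truth_t_entry)
  expect_gt(median(durj, na.rm = TRUE), median(durd, na.rm = TRUE))
  # onsets censored past the movie end count as infinitely delayed
  onset_or_inf <- function(x) ifelse(is.na(x$truth_t_onset) &
                                       !is.na(x$truth_t_entry), Inf,
                                     x$truth_t_onset)
  expect_gt(median(onset_or_inf(onej), na.rm = TRUE),
            median(onset_or_inf(oned), na.rm = TRUE))
})

test_that("trajectory tables round-trip losslessly and validate schemas", {
  pop <- generate_population(10, dose_preset(80), fx_params(), seed = 31)
  f <- tempfile(fileext = ".csv")
  write_trajectories(pop, f)
  rt <- read_trajectories(f)
  expect_equal(rt$foxo1_nf, pop$foxo1_nf, tolerance = 1e-12)
  expect_equal(rt$truth_t_exit, pop$truth_t_exit, tolerance = 1e-12)
  # missing required column is named in the error
  d <- utils::read.csv(f)
  d$foxo1_nf <- NULL
  utils::write.csv(d, f, row.names = FALSE)
  expect_error(read_trajectories(f), "foxo1_nf")
  # unknown columns survive with a warning
  pop2 <- generate_population(3, dose_preset(80), fx_params(), seed = 32)
  pop2$extra_col <- seq_len(nrow(pop2))
  write_trajectories(pop2, f)
  expect_warning(rt2 <- read_trajectories(f), "extra_col")
  expect_equal(rt2$extra_col, pop2$extra_col)
  unlink(f)
})
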