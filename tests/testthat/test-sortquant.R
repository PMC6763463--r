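test_that("segmentation recovers bright structures and handles edge cases", {
  set.seed(1)
  truth <- matrix(FALSE, 96, 96)
  xy <- expand.grid(x = 0:95, y = 0:95)
  for (c0 in list(c(20, 25), c(60, 40), c(40, 75)))
    truth <- truth | matrix((xy$x - c0[1])^2 + (xy$y - c0[2])^2 <= 36, 96)
  img <- matrix(rpois(96 * 96, 10), 96) + truth * 60
  mask <- segment_endosomes(img, analysis_config())
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.8)
  # constant image: Otsu undefined, fixed threshold fine
  expect_error(segment_endosomes(matrix(5, 16, 16), analysis_config()),
               "Otsu")
  cfg_fix <- analysis_config(threshold_method = "fixed", fixed_threshold = 1)
  expect_true(all(segment_endosomes(matrix(5, 16, 16), cfg_fix)))
  expect_false(any(segment_endosomes(matrix(0, 16, 16), cfg_fix)))
})

test_that("incorporation percentage obeys its limiting masks", {
  sim <- simulate_sorting_assay(
    sorting_sim_params(n_vesicles = 80L, n_frames = 25L), seed = 4)
  cfg <- analysis_config(threshold_method = "background")
  h <- sim$movie$height; w <- sim$movie$width
  # marker mask = entire image -> 100% everywhere defined
  tr_all <- endosomal_incorporation_trace(sim$movie, "cargo", "marker", cfg,
                                          marker_mask = matrix(TRUE, h, w))
  expect_true(all(abs(tr_all$values[is.finite(tr_all$values)] - 100) < 1e-9))
  # disjoint marker mask -> 0%
  tr_none <- endosomal_incorporation_trace(sim$movie, "cargo", "marker", cfg,
                                           marker_mask = matrix(FALSE, h, w))
  expect_true(all(tr_none$values[is.finite(tr_none$values)] == 0))
  # monotone under nested marker masks
  half <- matrix(FALSE, h, w); half[, seq_len(w %/% 2)] <- TRUE
  tr_half <- endosomal_incorporation_trace(sim$movie, "cargo", "marker", cfg,
                                           marker_mask = half)
  ok <- is.finite(tr_half$values) & is.finite(tr_all$values)
  expect_true(all(tr_all$values[ok] >= tr_half$values[ok] - 1e-9))
})

test_that("incorporation percentage is invariant to uniform PA rescaling", {
  sim <- simulate_sorting_assay(
    sorting_sim_params(n_vesicles = 60L, n_frames = 15L), seed = 8)
  cfg <- analysis_config(threshold_method = "background")
  tr1 <- endosomal_incorporation_trace(sim$movie, "cargo", "marker", cfg)
  mv2 <- sim$movie
  mv2$channels$cargo <- mv2$channels$cargo * 3.7
  tr2 <- endosomal_incorporation_trace(mv2, "cargo", "marker", cfg)
  expect_equal(tr1$values, tr2$values, tolerance = 1e-9)
})

test_that("incorporation curves order correctly across entry rates", {
  cfg <- analysis_config(threshold_method = "background")
  traces <- lapply(c(0.005, 0.01, 0.02), function(ke) {
    sim <- simulate_sorting_assay(
      sorting_sim_params(n_vesicles = 200L, n_frames = 80L,
                         k_entry_per_s = ke), seed = 21)
    endosomal_incorporation_trace(sim$movie, "cargo", "marker", cfg)$values
  })
  # compare smoothed level over the second half of the movie
  late <- 45:85
  m <- vapply(traces, function(v) mean(v[late], na.rm = TRUE), numeric(1))
  expect_true(m[1] < m[2] && m[2] < m[3])
})

test_that("exit slope equals closed-form least squares", {
  cfg <- analysis_config()
  t <- seq(50, 150, by = 2.5)
  tr <- intensity_trace(t, 80 - 0.2 * t, units = "percent")
  fit <- exit_slope(tr, cfg)
  expect_equal(fit$slope, -0.2, tolerance = 1e-12)
  expect_equal(fit$intercept, 80, tolerance = 1e-10)
  expect_equal(fit$slope_se, 0, tolerance = 1e-10)
  # constant trace
  tr0 <- intensity_trace(t, rep(42, length(t)))
  expect_equal(exit_slope(tr0, cfg)$slope, 0, tolerance = 1e-12)
  # noisy line vs normal equations
  set.seed(3)
  y <- 60 - 0.15 * t + rnorm(length(t))
  fit2 <- exit_slope(intensity_trace(t, y), cfg)
  ref <- normal_eq_slope(t, y)
  expect_equal(fit2$slope, unname(ref["slope"]), tolerance = 1e-12)
  expect_equal(fit2$intercept, unname(ref["intercept"]), tolerance = 1e-10)
  # regression window honours regression_start_s
  tr3 <- intensity_trace(seq(0, 150, 2.5),
                         c(rep(0, 20), 80 - 0.2 * seq(50, 150, 2.5)))
  expect_equal(exit_slope(tr3, cfg)$window[1], 50)
  expect_error(exit_slope(intensity_trace(c(51, 52), c(1, 2)), cfg),
               "at least 3")
})

test_that("half-maximal time interpolates the plateau crossing", {
  # linear ramp to a flat plateau of 100
  t <- seq(0, 130, by = 2.5)
  v <- pmin(t, 100)
  hm <- half_maximal_time(intensity_trace(t, v))
  expect_equal(hm$time_s, 50, tolerance = 1e-9)
  expect_equal(hm$plateau, 100)
  # step between frames at 10 and 12.5 s -> midpoint 11.25
  ts <- seq(0, 25, 2.5)
  vs <- ifelse(ts >= 12.5, 100, 0)
  expect_equal(half_maximal_time(intensity_trace(ts, vs))$time_s, 11.25)
  # exponential rise at k = 0.01/s -> ln2/k within one frame
  te <- seq(0, 600, 2.5)
  ve <- 100 * (1 - exp(-0.01 * te))
  hme <- half_maximal_time(intensity_trace(te, ve))
  expect_lt(abs(hme$time_s - log(2) / 0.01), 2.5)
  # too few finite points is an error, not a guess
  expect_error(half_maximal_time(intensity_trace(c(0, 1, 2), c(1, 2, 3))),
               "at least 4")
})

test_that("total recycling half-time sums and formats components", {
  tot <- total_recycling_halftime(186.6, 375)
  expect_equal(as.numeric(tot), 561.6)
  expect_equal(attr(tot, "formatted"), "9 min 21.6 s")
  expect_equal(as.numeric(total_recycling_halftime(0, 0)), 0)
  t2 <- total_recycling_halftime(60, 60)
  expect_equal(as.numeric(t2), 120)
  expect_equal(attr(t2, "formatted"), "2 min 0 s")
  expect_error(total_recycling_halftime(-1, 10), ">= 0")
})

test_that("window mean averages exactly the requested timepoints", {
  tr <- intensity_trace(c(0, 10, 20, 30), c(42, 42, 42, 42))
  expect_equal(window_mean(tr, 0, 30), 42)
  tr2 <- intensity_trace(c(5, 15, 25), c(10, 20, 99))
  expect_equal(window_mean(tr2, 0, 16), 15)
  set.seed(4)
  v <- rnorm(50); t <- sort(runif(50, 0, 100))
  tr3 <- intensity_trace(t, v)
  sel <- t >= 20 & t <= 70
  expect_equal(window_mean(tr3, 20, 70), sum(v[sel]) / sum(sel),
               tolerance = 1e-12)
  expect_error(window_mean(tr2, 90, 95), "no timepoints")
})

test_that("plasma-membrane trace is zero-mean at baseline and conserves", {
  cfg <- analysis_config()
  sim <- simulate_recycling_assay(recycling_sim_params(), seed = 6)
  tr <- plasma_membrane_recycling_trace(sim$movie, "cargo", cfg,
                                        cell_outline = sim$rois$cell_outline)
  nb <- sum(tr$times_s < -0.5)
  expect_equal(mean(tr$values[seq_len(nb)]), 0, tolerance = 1e-9)
  # noise-free delivery of 50%: raw band total equals the truth exactly
  simnf <- simulate_recycling_assay(
    recycling_sim_params(recycled_fraction = 0.5, noise = FALSE), seed = 7)
  trnf <- plasma_membrane_recycling_trace(
    simnf$movie, "cargo", cfg, pm_band = simnf$truth$pm_band_mask,
    normalization = "raw")
  expect_equal(tail(trnf$values, 1), tail(simnf$truth$cum_pm_intensity, 1),
               tolerance = 1e-9)
  # recycled_fraction = 0 stays at the noise floor
  sim0 <- simulate_recycling_assay(
    recycling_sim_params(recycled_fraction = 0), seed = 8)
  tr0 <- plasma_membrane_recycling_trace(sim0$movie, "cargo", cfg,
                                         cell_outline = sim0$rois$cell_outline)
  expect_lt(abs(mean(tr0$values)), 5)
  # a movie without baseline frames is rejected
  simb <- sim$movie
  simb$pa_frames <- 1L
  expect_error(plasma_membrane_recycling_trace(
    simb, "cargo", cfg, cell_outline = sim$rois$cell_outline), "baseline")
})
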