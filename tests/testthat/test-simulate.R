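# All simulator scales here are reduced relative to the full acquisition
# protocols to keep the suite fast; the full-scale runs live in
# test-acceptance.R.

test_that("sorting generator honours the rate-zero limit and determinism", {
  p <- sorting_sim_params(n_vesicles = 60L, n_frames = 30L,
                          k_entry_per_s = 0)
  sim <- simulate_sorting_assay(p, seed = 2)
  expect_true(all(sim$truth$occupancy_fraction == 0))
  s1 <- simulate_sorting_assay(p, seed = 9)
  s2 <- simulate_sorting_assay(p, seed = 9)
  expect_identical(s1$movie$channels, s2$movie$channels)
  expect_false(identical(
    s1$movie$channels$cargo,
    simulate_sorting_assay(p, seed = 10)$movie$channels$cargo))
  expect_error(simulate_sorting_assay(
    sorting_sim_params(n_vesicles = 5000L, height = 32L, width = 32L)),
    "too small")
  expect_error(sorting_sim_params(k_entry_per_s = -1), "non-negative")
})

test_that("irreversible-entry occupancy matches the closed-form CTMC", {
  ke <- 0.03
  p <- sorting_sim_params(n_vesicles = 400L, n_frames = 60L,
                          k_entry_per_s = ke, k_exit_per_s = 0,
                          noise = FALSE)
  sim <- simulate_sorting_assay(p, seed = 11)
  occ <- sim$truth$occupancy_fraction
  expect_true(all(diff(occ) >= -1e-12))   # monotone rise
  t_act <- (seq_len(p$pa_pulses) - 1) * p$frame_interval_s
  expected <- ctmc_occupancy(sim$truth$times_s, t_act, ke, 0)
  # binomial error over 400 vesicles
  se <- sqrt(pmax(expected * (1 - expected), 1e-4) / 400)
  expect_true(all(abs(occ - expected) < 4 * se + 0.02))
})

test_that("noise-free cargo intensity is conserved after the pulses", {
  p <- sorting_sim_params(n_vesicles = 100L, n_frames = 30L, noise = FALSE)
  sim <- simulate_sorting_assay(p, seed = 3)
  tot <- apply(sim$movie$channels$cargo, 3, sum)
  tot <- tot[(p$pa_pulses + 1):length(tot)]
  expect_lt((max(tot) - min(tot)) / max(tot), 0.005)
})

test_that("recycling generator conserves intensity and respects bounds", {
  expect_error(recycling_sim_params(recycled_fraction = 1.2), "\\[0, 1\\]")
  p <- recycling_sim_params(recycled_fraction = 0.5, noise = FALSE)
  sim <- simulate_recycling_assay(p, seed = 1)
  band <- sim$truth$pm_band_mask
  final <- sim$movie$channels$cargo[, , sim$movie$n_frames]
  # what arrived in the band is exactly what left the pool
  expect_equal(sum(final[band]), tail(sim$truth$cum_pm_intensity, 1),
               tolerance = 1e-12)
  k <- p$k_delivery_per_s
  t_end <- tail(sim$truth$times_s, 1) - sim$truth$t_delivery_start_s
  expect_equal(tail(sim$truth$cum_pm_fraction, 1),
               0.5 * (1 - exp(-k * t_end)), tolerance = 1e-9)
  # zero recycling: band never rises above the noise floor
  p0 <- recycling_sim_params(recycled_fraction = 0)
  sim0 <- simulate_recycling_assay(p0, seed = 4)
  band_tot <- apply(sim0$movie$channels$cargo, 3,
                    function(fr) sum(fr[band]))
  expect_lt(diff(range(band_tot)) / mean(band_tot), 0.05)
})

test_that("recycling half-maximal time follows the exponential oracle", {
  # fast delivery so the plateau is effectively complete within the movie
  k <- log(2) / 100
  hits <- vapply(1:8, function(sd) {
    sim <- simulate_recycling_assay(
      recycling_sim_params(k_delivery_per_s = k), seed = sd)
    tr <- plasma_membrane_recycling_trace(
      sim$movie, "cargo", analysis_config(),
      cell_outline = sim$rois$cell_outline)
    hm <- half_maximal_time(tr)
    abs(hm$time_s - (sim$truth$t_delivery_start_s + log(2) / k))
  }, numeric(1))
  # within one 30 s frame on average, never more than two
  expect_lt(mean(hits), 30)
  expect_lt(max(hits), 60)
})

test_that("TIRF generator produces Poisson event counts and flags", {
  sim0 <- simulate_tirf_fusion(
    tirf_sim_params(event_rate_per_min = 0, duration_s = 20), seed = 1)
  expect_equal(nrow(sim0$truth$events), 0L)
  # pure noise: intensities hover around the camera background
  expect_lt(abs(mean(sim0$movie$channels$event) - 10), 1)
  expect_error(tirf_sim_params(event_rate_per_min = -1), ">= 0")
  sim1 <- simulate_tirf_fusion(
    tirf_sim_params(cofusion_fraction = 1, duration_s = 60,
                    event_rate_per_min = 6), seed = 2)
  expect_true(all(sim1$truth$events$partner_present))
  # Poisson(4) mean over 40 one-minute movies at 4/min
  counts <- vapply(1:40, function(sd)
    nrow(simulate_tirf_fusion(
      tirf_sim_params(event_rate_per_min = 4, duration_s = 60,
                      height = 48L, width = 48L), seed = sd)$truth$events),
    numeric(1))
  se <- sqrt(4 / 40)
  expect_lt(abs(mean(counts) - 4), 3 * se)
})

test_that("grouped-trace generator is exchangeable under the null", {
  s1 <- simulate_group_traces(seed = 5)
  s2 <- simulate_group_traces(seed = 5)
  expect_identical(s1, s2)
  # large effect: complete separation after the divergence time
  big <- simulate_group_traces(effect_size_sd = 10, noise_sd = 1, seed = 6)
  post <- big$times_s >= 50
  expect_true(all(apply(big$a[, post], 2, min) >
                    apply(big$b[, post], 2, max)))
  # null: Wilcoxon p at a fixed timepoint is uniform across seeds (15
  # cells per group keeps the p distribution fine-grained)
  ps <- vapply(1:200, function(sd) {
    s <- simulate_group_traces(divergence_time_s = Inf, effect_size_sd = 0,
                               n_per_group = 15L, times_s = c(0, 10),
                               seed = sd)
    suppressWarnings(wilcox.test(s$a[, 2], s$b[, 2])$p.value)
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(simulate_group_traces(n_per_group = 1L), ">= 2")
})

test_that("aggregation merges conserve intensity", {
  p1 <- aggregation_sim_params(merge_factor = 1L, noise = FALSE)
  s1 <- simulate_aggregation(p1, seed = 1)
  expect_true(all(s1$truth$n_vesicles == 40L))
  expect_true(all(s1$truth$mean_intensity == s1$truth$mean_intensity[1]))
  p4 <- aggregation_sim_params(merge_factor = 4L, n_vesicles = 40L,
                               noise = FALSE)
  s4 <- simulate_aggregation(p4, seed = 2)
  sw <- s4$truth$switch_frame
  expect_equal(s4$truth$n_vesicles[sw], 10L)
  expect_equal(s4$truth$mean_intensity[sw] / s4$truth$mean_intensity[1], 4)
  # photon sums across the merge differ < 0.1%
  pre <- sum(s4$movie$channels$vesicles[, , sw - 1])
  post <- sum(s4$movie$channels$vesicles[, , sw])
  expect_lt(abs(pre - post) / pre, 0.001)
  expect_warning(simulate_aggregation(
    aggregation_sim_params(merge_factor = 3L, n_vesicles = 40L,
                           noise = FALSE), seed = 3), "unmerged")
})
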