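# Fixture: a recording whose ground truth is known exactly.
make_recording <- function(n_neurons, duration, rate_per_min = 3,
                           amplitude = 0.8, noise_sd = 2, drift = 0,
                           seed = 1, refractory = 2) {
  net <- generate_network(max(n_neurons, 2), 0.05, 1, seed = seed)
  ras <- simulate_spikes(net, spike_sim_params(
    duration = duration, dt = 1 / 33, baseline_rate = rate_per_min / 60,
    coupling_scale = 0, refractory = refractory, seed = seed + 500))
  ras$events <- ras$events[seq_len(n_neurons)]
  ras$n_neurons <- as.integer(n_neurons)
  rec <- render_fluorescence(ras, calcium_params(
    amplitude_per_spike = amplitude, noise_sd = noise_sd,
    drift_amplitude = drift, seed = seed + 900))
  list(raster = ras, rec = rec)
}

test_that("ROI grid reproduces the standard 900-ROI layout", {
  g <- build_roi_grid(c(1203, 1203), px_um = 5.9, roi_um = 14)
  expect_identical(nrow(g$rois), 900L)       # 30 x 30 grid
  expect_identical(g$roi_px, 2L)             # round(14 / 5.9)
  expect_identical(g$n_side, 30L)
  # ROIs are disjoint
  keys <- unlist(lapply(seq_len(nrow(g$rois)), function(i) {
    r <- g$rois[i, ]
    outer(r$r0:r$r1, r$c0:r$c1, function(a, b) a * 1e4 + b)
  }))
  expect_identical(anyDuplicated(keys), 0L)

  one <- build_roi_grid(c(2, 2), px_um = 5.9, roi_um = 14)
  expect_identical(nrow(one$rois), 1L)
  expect_identical(c(one$rois$r0, one$rois$r1, one$rois$c0, one$rois$c1),
                   c(1L, 2L, 1L, 2L))
  expect_error(build_roi_grid(c(1, 1), px_um = 5.9, roi_um = 14), "smaller")
})

test_that("trace extraction averages ROI pixels", {
  stack <- array(100L, c(8, 8, 5))
  g <- build_roi_grid(c(8, 8), px_um = 7, roi_um = 14)  # 2-px ROIs
  rec <- extract_roi_traces(stack, g, frame_rate = 10)
  expect_true(all(rec$F == 100))

  stack2 <- array(0L, c(2, 2, 3))
  stack2[1, 1, ] <- 255L
  g2 <- build_roi_grid(c(2, 2), px_um = 7, roi_um = 14)
  rec2 <- extract_roi_traces(stack2, g2)
  expect_equal(as.vector(rec2$F), rep(63.75, 3))  # mean of {255, 0, 0, 0}
})

test_that("rendered frames round-trip to the generating traces", {
  # neurons placed at ROI centers of a small field, noise-free
  ras <- spike_raster(list(2, 8, 14, 20), 4, duration = 30)
  rec <- render_fluorescence(ras, calcium_params(noise_sd = 0, seed = 2))
  px <- 7
  g <- build_roi_grid(c(40, 40), px_um = px, roi_um = 14, n_side = 2)
  net <- generate_network(4, 0.3, 1, seed = 2, radius_um = 100)
  net$positions <- cbind(g$rois$cx_um, g$rois$cy_um, 0)
  stack <- render_frames(rec, net, field_mm = 40 * px / 1000, px_um = px,
                         spot_sd_um = 5)
  rec2 <- extract_roi_traces(stack, g, frame_rate = rec$frame_rate)
  for (i in 1:4) {
    expect_gt(cor(rec2$F[i, ], rec$F[i, ]), 0.9)
  }
})

test_that("dF/F normalization satisfies its identities", {
  flat <- fluorescence_recording((0:99) / 33, matrix(80, 2, 100), 33)
  norm <- normalize_traces(flat)
  expect_true(all(norm$dff == 0))

  F <- matrix(50, 1, 200)
  F[1, 120] <- 100  # one frame at 2 * F0
  norm2 <- normalize_traces(fluorescence_recording((0:199) / 33, F, 33))
  expect_equal(norm2$dff[1, 120], 1, tolerance = 1e-12)
  expect_equal(norm2$F0, 50)

  expect_error(normalize_traces(
    fluorescence_recording((0:9) / 33, matrix(0, 1, 10), 33)), "F0")
})

test_that("known transient amplitudes are recovered after normalization", {
  fix <- make_recording(5, 120, amplitude = 0.8, noise_sd = 1, seed = 3)
  norm <- normalize_traces(fix$rec)
  peaks <- apply(norm$dff, 1, max)
  has_spike <- lengths(fix$raster$events) > 0
  expect_true(all(abs(peaks[has_spike] - 0.8) / 0.8 < 0.1))
  # median dF/F sits at zero after drift removal
  expect_lt(max(abs(apply(norm$dff, 1, median))), 0.02)
})

test_that("Schmitt trigger obeys hysteresis, duration and monotonicity", {
  fr <- 33
  t <- (0:(fr * 30 - 1)) / fr
  base <- matrix(0.01 * sin(2 * pi * t / 3), 1, length(t))
  norm <- structure(list(dff = base, F0 = 100, baseline = base * 0,
                         times = t, frame_rate = fr),
                    class = "normalized_traces")
  expect_identical(sum(lengths(schmitt_detect(norm, 0.5, 0.2)$events)), 0L)

  tr <- base
  tr[1, 200:260] <- 1.0  # one clean transient
  norm$dff <- tr
  ras <- schmitt_detect(norm, high = 0.5, low = 0.2, refine_onset = FALSE)
  expect_identical(lengths(ras$events), 1L)
  expect_equal(ras$events[[1]], (200 - 1) / fr)

  # a sub-minimum-duration blip is discarded
  tr2 <- base
  tr2[1, 300:301] <- 1.0
  norm$dff <- tr2
  expect_identical(sum(lengths(schmitt_detect(norm, 0.5, 0.2, min_frames = 3)$events)), 0L)

  expect_error(schmitt_detect(norm, high = 0.2, low = 0.5), "high > low")

  # raising the high threshold never creates events
  set.seed(42)
  for (rep in 1:10) {
    x <- matrix(stats::filter(rnorm(500), rep(0.4, 4), sides = 1), 1)
    x[is.na(x)] <- 0
    norm$dff <- x
    n1 <- sum(lengths(schmitt_detect(norm, 0.8, 0.3)$events))
    n2 <- sum(lengths(schmitt_detect(norm, 1.2, 0.3)$events))
    expect_lte(n2, n1)
  }
})

test_that("event detection recovers generator spike times", {
  # events spaced beyond the hysteresis closure time so each forms its own
  # cluster (at this SNR the low threshold sits deep in the decay tail)
  fix <- make_recording(10, 180, amplitude = 0.8, noise_sd = 2, seed = 6,
                        refractory = 4)
  ras <- schmitt_detect(normalize_traces(fix$rec))
  fr <- fix$rec$frame_rate
  fracs <- vapply(seq_len(10), function(i) {
    match_fraction(fix$raster$events[[i]], ras$events[[i]], tol = 2 / fr)
  }, numeric(1))
  expect_gt(mean(fracs, na.rm = TRUE), 0.9)
})

test_that("population activity counts window membership exactly", {
  ras <- spike_raster(list(0.0, 0.1, 0.2, 0.9), 4, duration = 2)
  pa <- population_activity(ras, window = 0.5, step = 0.1)
  expect_equal(pa$fraction_active[1], 0.75)  # window [0, 0.5): 3 of 4
  expect_length(pa$t_centers, floor((2 - 0.5) / 0.1) + 1)
  counts <- pa$fraction_active * 4
  expect_equal(counts, round(counts))  # integer neuron counts per window

  none <- spike_raster(rep(list(numeric(0)), 4), 4, duration = 2)
  expect_true(all(population_activity(none)$fraction_active == 0))
})

test_that("synchronization peaks require genuinely collective windows", {
  pa <- structure(list(t_centers = seq(0.25, 9.95, by = 0.1),
                       fraction_active = rep(0.05, 98),
                       window = 0.5, step = 0.1, n_neurons = 40),
                  class = "population_activity")
  expect_length(detect_sync_peaks(pa), 0)
  pa$fraction_active[50] <- 0.9
  expect_equal(detect_sync_peaks(pa), pa$t_centers[50])
})

test_that("firing rate is events per neuron per minute", {
  ev <- c(rep(list(seq_len(43) / 60), 50), rep(list(seq_len(44) / 60), 50))
  ras <- spike_raster(ev, 100, duration = 900)
  expect_equal(firing_rate(ras), 4350 / 100 / 15)  # = 2.9
  expect_equal(firing_rate(spike_raster(list(numeric(0)), 1, 60)), 0)
  expect_equal(firing_rate(spike_raster(list(30), 1, 60)), 1)
})

test_that("activity filter separates active from silent ROIs", {
  # pure noise: nothing kept
  silent <- spike_raster(rep(list(numeric(0)), 20), 20, duration = 60)
  rec0 <- render_fluorescence(silent, calcium_params(noise_sd = 2, seed = 8))
  expect_warning(out0 <- filter_active_rois(rec0), "passed the activity filter")
  expect_identical(attr(out0, "n_kept"), 0L)

  # every ROI with one clean transient: all kept
  ras1 <- spike_raster(as.list(seq(5, 24.5, by = 1)), 20, duration = 30)
  rec1 <- render_fluorescence(ras1, calcium_params(noise_sd = 1.5, seed = 9))
  out1 <- filter_active_rois(rec1)
  expect_identical(attr(out1, "n_kept"), 20L)
})

test_that("end-to-end detected rate tracks the generator rate", {
  for (s in 1:3) {
    fix <- make_recording(20, 240, rate_per_min = 3, noise_sd = 2, seed = s)
    det <- schmitt_detect(normalize_traces(fix$rec))
    r_true <- firing_rate(fix$raster)
    r_det <- firing_rate(det)
    expect_lt(abs(r_det - r_true) / r_true, 0.25)
  }
})
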