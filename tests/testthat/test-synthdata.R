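test_that("network generator hits the requested density and is deterministic", {
  net <- generate_network(100, density = 0.08, n_communities = 4, seed = 7)
  ne <- sum(net$adjacency)
  expect_gte(ne, 640)  # 792 expected edges +/- 20%
  expect_lte(ne, 960)
  expect_true(all(diag(net$adjacency) == 0))

  net2 <- generate_network(100, density = 0.08, n_communities = 4, seed = 7)
  expect_identical(net$adjacency, net2$adjacency)
  expect_identical(net$positions, net2$positions)

  net3 <- generate_network(100, density = 0.08, n_communities = 4, seed = 8)
  expect_false(identical(net$adjacency, net3$adjacency))
})

test_that("degenerate and invalid network requests are handled", {
  full <- generate_network(2, density = 1, n_communities = 1, seed = 1)
  expect_identical(full$adjacency, matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_error(generate_network(1, 0.5), "at least 2")
})

test_that("communities are non-empty, spatially boosted, and E/I split is 80/20", {
  net <- generate_network(90, density = 0.1, n_communities = 3, seed = 11)
  expect_setequal(unique(net$community_labels), 1:3)
  expect_true(all(table(net$community_labels) > 0))
  same <- outer(net$community_labels, net$community_labels, `==`)
  diag(same) <- NA
  p_in <- mean(net$adjacency[same & !is.na(same)])
  p_out <- mean(net$adjacency[!same & !is.na(same)])
  expect_gt(p_in, p_out)
  expect_equal(mean(net$excitatory_mask), 0.8, tolerance = 0.02)
})

test_that("ground truth round-trips through JSON", {
  net <- generate_network(25, 0.15, 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(net, path)
  back <- read_ground_truth(path)
  expect_identical(back$adjacency, net$adjacency)
  expect_equal(back$weights, net$weights)
  expect_equal(back$community_labels, net$community_labels)
})

test_that("spiking cascade respects drive, refractoriness and determinism", {
  net <- generate_network(10, 0.2, 1, seed = 1)
  silent <- simulate_spikes(net, spike_sim_params(
    duration = 60, dt = 0.03, baseline_rate = 0, coupling_scale = 0, seed = 1))
  expect_identical(sum(lengths(silent$events)), 0L)

  p <- spike_sim_params(duration = 300, dt = 0.03, baseline_rate = 2,
                        coupling_scale = 0.1, refractory = 0.24, seed = 5)
  ras <- simulate_spikes(net, p)
  gaps <- unlist(lapply(ras$events, diff))
  expect_gt(min(gaps), p$refractory - 1e-9)
  ras2 <- simulate_spikes(net, p)
  expect_identical(ras$events, ras2$events)

  expect_error(simulate_spikes(net, spike_sim_params(duration = 0.1, dt = 0.03)),
               "10 simulation steps")
})

test_that("a directed edge shifts the cross-correlogram to positive lag", {
  net <- generate_network(2, 0.5, 1, seed = 1)
  net$adjacency <- matrix(c(0L, 0L, 1L, 0L), 2, 2)  # edge 1 -> 2
  net$weights <- net$adjacency * 1.0
  p <- spike_sim_params(duration = 600, dt = 0.03, baseline_rate = 1,
                        coupling_scale = 0.6, transmission_delay = 0.03,
                        refractory = 0, seed = 9)
  ras <- simulate_spikes(net, p)
  b1 <- floor(ras$events[[1]] / p$dt)
  b2 <- floor(ras$events[[2]] / p$dt)
  # brute-force histogram of spike-time differences (target minus source)
  lag_count <- function(l) sum(outer(b2, b1, `-`) == l)
  expect_gt(lag_count(1), lag_count(0))
  expect_gt(lag_count(1), lag_count(-1))
})

test_that("uncoupled cascade reproduces the target Poisson event count", {
  # 2.9 activations/neuron/min over 15 min and 100 neurons -> 4350 events,
  # checked within 4 Poisson standard deviations (+/- 264)
  net <- generate_network(100, 0.05, 1, seed = 2)
  p <- spike_sim_params(duration = 900, dt = 0.03, baseline_rate = 2.9 / 60,
                        coupling_scale = 0, refractory = 0, seed = 21)
  ras <- simulate_spikes(net, p)
  total <- sum(lengths(ras$events))
  expect_gt(total, 4350 - 4 * sqrt(4350))
  expect_lt(total, 4350 + 4 * sqrt(4350))
  expect_equal(firing_rate(ras), total / 100 / 15)
})

test_that("fluorescence rendering follows the kernel contract", {
  empty <- spike_raster(rep(list(numeric(0)), 3), 3, duration = 10)
  cal0 <- calcium_params(noise_sd = 0, drift_amplitude = 0, baseline_F0 = 100)
  rec <- render_fluorescence(empty, cal0)
  expect_true(all(rec$F == 100))

  one <- spike_raster(list(2.0), 1, duration = 12)
  cal <- calcium_params(amplitude_per_spike = 0.8, noise_sd = 0,
                        drift_amplitude = 0, baseline_F0 = 100)
  tr <- render_fluorescence(one, cal)$F[1, ]
  expect_equal(max(tr), 100 * 1.8, tolerance = 0.02)  # kernel discretization
  expect_equal(tr[1], 100)

  # two spikes at the same frame phase, farther apart than the kernel
  # support, give exactly equal transients
  two <- spike_raster(list(c(2.0, 11.0)), 1, duration = 16)
  tr2 <- render_fluorescence(two, cal)$F[1, ]
  fr <- cal$frame_rate
  seg1 <- tr2[(2 * fr + 1):(2 * fr + 3 * fr)]
  seg2 <- tr2[(11 * fr + 1):(11 * fr + 3 * fr)]
  expect_equal(seg1, seg2, tolerance = 1e-12)
})

test_that("frame rendering has the documented geometry and round-trips TIFF", {
  # default field: 7.1 mm at 5.9 um/pixel -> floor() = 1203 px frames
  net1 <- generate_network(2, 0.5, 1, seed = 4, radius_um = 500)
  net1$positions <- matrix(c(-200, 200, 0, 0, 0, 0), 2, 3)
  rec1 <- fluorescence_recording(0, matrix(100, 2, 1), 33)
  stack <- render_frames(rec1, net1)
  expect_identical(dim(stack)[1:2], c(1203L, 1203L))
  expect_gt(max(stack), min(stack))  # spots over background

  # near-coincident neurons trigger the ROI-width warning
  net1$positions <- matrix(c(0, 5, 0, 0, 0, 0), 2, 3)
  expect_warning(render_frames(rec1, net1), "14 um")

  small <- array(sample(0:255, 20 * 20 * 4, replace = TRUE), c(20, 20, 4))
  path <- withr::local_tempfile(fileext = ".tif")
  write_frames_tiff(small, path)
  expect_identical(read_frames_tiff(path), small)
})

test_that("sweep generator matches its stated noise-free contracts", {
  tr <- rheo_truth(plateau_G1 = 200, loss_ratio = 0.1, noise_cv = 0)
  fs <- generate_sweeps(tr, "frequency", grid = list(omega = c(1, 5, 10), gamma0 = 5))
  expect_equal(fs$G1_Pa, c(200, 200, 200))       # plateau exact below onset
  expect_equal(fs$G2_Pa, c(20, 20, 20))          # G'' = loss_ratio * G'

  ts <- generate_sweeps(tr, "time")
  expect_equal(ts$G1_Pa[length(ts$G1_Pa)], 200, tolerance = 0.01)
  expect_lt(ts$G1_Pa[1], 200)                    # relaxes up to the plateau

  ss <- generate_sweeps(tr, "strain")
  expect_true(any(ss$torque_nNm < 2))            # sub-floor rows at low strain
  expect_true(all(ss$G1_Pa > ss$G2_Pa))

  expect_error(generate_sweeps(tr, "frequency", grid = list(omega = numeric(0))),
               "empty")
})

test_that("sweep and raster files round-trip through their readers", {
  tr <- rheo_truth(seed = 3)
  rec <- rbind(generate_sweeps(tr, "frequency", DIV = 1),
               generate_sweeps(tr, "time", DIV = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweeps(rec, path)
  back <- read_sweeps(path)
  expect_equal(back$G1_Pa, rec$G1_Pa)
  expect_identical(back$test_type, rec$test_type)

  ras <- spike_raster(list(c(0.1, 2 / 3), numeric(0), pi), 3, duration = 10)
  rpath <- withr::local_tempfile(fileext = ".csv")
  write_raster(ras, rpath)
  back <- read_raster(rpath)
  expect_identical(back$events, ras$events)  # exact round trip
  expect_identical(back$n_neurons, 3L)
})
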