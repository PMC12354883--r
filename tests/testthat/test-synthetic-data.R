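test_that("zero-force datasets reproduce the configured emission model", {
  ds <- generate_force_dataset(
    synthetic_scenario(n_tracks = 1000, phi_force = 0, phi_immobile = 0,
                       cell_present = FALSE, seed = 101))
  n <- nrow(ds)
  expect_gt(n, 5000)
  se <- 0.164 / sqrt(n)
  expect_lt(abs(mean(ds$efficiency) - 0.865), 3 * se)
  expect_false(any(ds$cell_contact))
  expect_true(all(ds$truth_force_pN == 0))
  expect_true(all(ds$truth_mobile))
})

test_that("force-bearing tracks emit at the calibration efficiency", {
  ds <- generate_force_dataset(
    synthetic_scenario(n_tracks = 500, phi_force = 1, force_pN = 9,
                       phi_immobile = 1, seed = 102))
  E9 <- efficiency_from_force(9, default_calib)
  expect_equal(E9, 0.1444, tolerance = 1e-3)
  se <- 0.164 / sqrt(nrow(ds))
  expect_lt(abs(mean(ds$efficiency) - E9), 3 * se)
  # forces require anchoring
  expect_true(all(!ds$truth_mobile))
})

test_that("generation is deterministic in the scenario seed", {
  sc <- synthetic_scenario(n_tracks = 50, phi_force = 0.2, force_pN = 5,
                           phi_immobile = 0.5, seed = 7)
  expect_identical(generate_force_dataset(sc), generate_force_dataset(sc))
  lt <- lifetime_scenario(n_events_per_interval = 100, seed = 7)
  expect_identical(generate_lifetime_dataset(lt),
                   generate_lifetime_dataset(lt))
  # and does not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_force_dataset(sc)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("mobile sensors cannot bear force", {
  expect_error(synthetic_scenario(phi_force = 0.5, phi_immobile = 0.2),
               "phi_force > phi_immobile")
})

test_that("mobile tracks diffuse with the configured coefficient", {
  D <- 0.7; dt <- 0.1
  ds <- generate_force_dataset(
    synthetic_scenario(n_tracks = 400, mean_track_length = 20,
                       min_track_length = 10, phi_immobile = 0, seed = 103),
    motion = motion_model(D_mobile = D, frame_interval = dt))
  # lag-1 MSD of Brownian steps: 4 D dt per step
  sq <- unlist(lapply(split(ds, ds$track_id), function(tr) {
    diff(tr$x_um)^2 + diff(tr$y_um)^2
  }))
  expect_equal(mean(sq), 4 * D * dt,
               tolerance = 3 * stats::sd(sq) / sqrt(length(sq)) / (4 * D * dt))
})

test_that("intensities are consistent with the drawn efficiency", {
  ds <- generate_force_dataset(
    synthetic_scenario(n_tracks = 300, phi_immobile = 0, seed = 104),
    emission = emission_model(total_intensity = 5000, intensity_noise = 0.1))
  prox <- ds$i_acceptor / (ds$i_acceptor + ds$i_donor)
  eff_clamped <- pmin(pmax(ds$efficiency, 0.001), 0.999)
  # binomial split: proximity ratio tracks the clamped efficiency
  expect_lt(mean(abs(prox - eff_clamped)), 0.02)
})

test_that("lifetime generator obeys its closed-form limits", {
  # no bleaching: mean duration recovers tau_bond
  lt <- generate_lifetime_dataset(
    lifetime_scenario(tau_bond = 10, p_bleach_per_frame = 0,
                      recording_intervals = 1, n_events_per_interval = 2000,
                      seed = 105))
  d <- lt$duration_frames * 1
  expect_lt(abs(mean(d) - 0.5 - 10), 3 * stats::sd(d) / sqrt(length(d)) + 0.5)
  # bleach-only limit: geometric with the bleaching parameter
  lt2 <- generate_lifetime_dataset(
    lifetime_scenario(tau_bond = 1e6, p_bleach_per_frame = 0.2,
                      recording_intervals = 1, n_events_per_interval = 2000,
                      seed = 106))
  k <- lt2$duration_frames
  expect_lt(abs(mean(k) - 1 / 0.2), 3 * stats::sd(k) / sqrt(length(k)))
  # competing risks: apparent per-time rate 1/tau + (-log(1-p))/dt
  lt3 <- generate_lifetime_dataset(
    lifetime_scenario(tau_bond = 10, p_bleach_per_frame = 0.2,
                      recording_intervals = 1, n_events_per_interval = 5000,
                      seed = 107))
  rate <- 0.1 - log(0.8)
  k3 <- lt3$duration_frames
  expect_equal(mean(k3), 1 / (1 - exp(-rate)), tolerance = 0.05)
})

test_that("trajectory tables round-trip through the text format", {
  ds <- generate_force_dataset(synthetic_scenario(n_tracks = 20, seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectories(ds, path)
  back <- read_trajectories(path)
  expect_equal(back$efficiency, ds$efficiency, tolerance = 1e-12)
  expect_equal(back$track_id, ds$track_id)
  expect_equal(attr(back, "scenario")$seed, 9)
})
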