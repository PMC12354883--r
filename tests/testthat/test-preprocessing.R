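test_that("FRET efficiency reduces to the proximity ratio at identity corrections", {
  ds <- data.frame(track_id = 1, frame = 1:3, time_s = 0:2 / 10,
                   x_um = 0, y_um = 0,
                   i_donor = c(100, 30, 50), i_acceptor = c(100, 70, 150))
  out <- compute_fret(ds)
  expect_equal(out$efficiency, c(0.5, 0.7, 0.75))
})

test_that("bleed-through correction follows the stated formula", {
  ds <- data.frame(track_id = 1, frame = 1, time_s = 0, x_um = 0, y_um = 0,
                   i_donor = 100, i_acceptor = 60)
  out <- compute_fret(ds, bleedthrough = 0.1)
  # corrected acceptor = 60 - 0.1*100 = 50; E = 50/(100+50)
  expect_equal(out$efficiency, 50 / 150, tolerance = 1e-9)
})

test_that("stoichiometry uses the acceptor-excitation channel", {
  ds <- data.frame(track_id = 1, frame = 1, time_s = 0, x_um = 0, y_um = 0,
                   i_donor = 100, i_acceptor = 100, i_acceptor_aex = 200)
  out <- compute_fret(ds)
  expect_equal(out$stoichiometry, 200 / 400)
  # zero-total observations are dropped and logged
  ds2 <- rbind(ds, data.frame(track_id = 1, frame = 2, time_s = 0.1,
                              x_um = 0, y_um = 0, i_donor = 0,
                              i_acceptor = 0, i_acceptor_aex = 5))
  out2 <- compute_fret(ds2)
  expect_equal(nrow(out2), 1)
  prov <- provenance_log(out2)
  expect_equal(prov$removed[prov$rule == "zero_total_intensity"], 1)
})

test_that("same-frame neighbors within the radius are both removed", {
  ds <- make_trajectory_df(list(
    cbind(c(0, 0, 0, 0, 0, 0), c(0, 0, 0, 0, 0, 0)),
    cbind(c(0.2, 5, 5, 5, 5, 5), c(0, 5, 5, 5, 5, 5))))
  out <- filter_tracks(ds, min_length = 1, efficiency_range = NULL,
                       neighbor_radius = 0.5)
  # frame 1 of both tracks is an overlap; later frames are far apart
  expect_false(any(out$frame == 1))
  expect_equal(sum(out$track_id == 1), 5)
  prov <- provenance_log(out)
  expect_equal(prov$removed[prov$rule == "overlapping_signal"], 2)
  # radius 0 disables the rule
  out0 <- filter_tracks(ds, min_length = 1, efficiency_range = NULL,
                        neighbor_radius = 0)
  expect_equal(nrow(out0), nrow(ds))
})

test_that("tracks shorter than the minimum length are discarded", {
  ds <- make_trajectory_df(list(
    matrix(0, nrow = 4, ncol = 2),    # 4 observations: out
    matrix(1, nrow = 5, ncol = 2)))   # 5 observations: kept
  out <- filter_tracks(ds, min_length = 5, efficiency_range = NULL)
  expect_equal(unique(out$track_id), 2)
  expect_equal(provenance_log(out)$removed[
    provenance_log(out)$rule == "min_track_length"], 4)
})

test_that("length and proximity filters commute on non-interacting fixtures", {
  set.seed(20)
  ds <- make_trajectory_df(lapply(1:8, function(i)
    matrix(runif(2 * sample(3:8, 1), 0, 50), ncol = 2)))
  a <- filter_tracks(filter_tracks(ds, min_length = 1,
                                   efficiency_range = NULL,
                                   neighbor_radius = 0.5),
                     min_length = 5, efficiency_range = NULL)
  b <- filter_tracks(filter_tracks(ds, min_length = 5,
                                   efficiency_range = NULL),
                     min_length = 1, efficiency_range = NULL,
                     neighbor_radius = 0.5)
  expect_equal(a[names(a) != "row.names"], b[names(b) != "row.names"],
               ignore_attr = TRUE)
})

test_that("single-emitter filter keeps one-step bleaching, drops two steps", {
  one_step <- data.frame(track_id = 1, frame = 1:12, time_s = (0:11) / 10,
                         x_um = 0, y_um = 0,
                         i_donor = c(rep(500, 6), rep(5, 6)),
                         i_acceptor = c(rep(500, 6), rep(5, 6)))
  two_step <- data.frame(track_id = 2, frame = 1:12, time_s = (0:11) / 10,
                         x_um = 0, y_um = 0,
                         i_donor = c(rep(1000, 4), rep(500, 4), rep(5, 4)),
                         i_acceptor = c(rep(1000, 4), rep(500, 4), rep(5, 4)))
  set.seed(30)
  stepless <- data.frame(track_id = 3, frame = 1:12, time_s = (0:11) / 10,
                         x_um = 0, y_um = 0,
                         i_donor = 500 + rnorm(12, 0, 10),
                         i_acceptor = 500 + rnorm(12, 0, 10))
  ds <- rbind(one_step, two_step, stepless)
  out <- single_emitter_filter(ds)
  expect_setequal(unique(out$track_id), c(1, 3))
  prov <- provenance_log(out)
  expect_equal(prov$removed[prov$rule == "multi_emitter"], 12)
})

test_that("tracks too short for changepoint analysis pass unfiltered", {
  short <- data.frame(track_id = 1, frame = 1:3, time_s = (0:2) / 10,
                      x_um = 0, y_um = 0,
                      i_donor = c(900, 400, 20), i_acceptor = c(900, 400, 20))
  out <- single_emitter_filter(short)
  expect_equal(nrow(out), 3)
  prov <- provenance_log(out)
  expect_equal(prov$removed[prov$rule == "too_short_for_changepoint"], 3)
})
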