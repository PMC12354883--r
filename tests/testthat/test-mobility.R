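test_that("smallest enclosing circle handles degenerate inputs", {
  expect_error(smallest_enclosing_circle(matrix(numeric(0), ncol = 2)),
               "empty")
  one <- smallest_enclosing_circle(matrix(c(1, 2), ncol = 2))
  expect_equal(one$radius, 0)
  # two points: diameter circle
  two <- smallest_enclosing_circle(rbind(c(0, 0), c(3, 4)))
  expect_equal(two$radius, 2.5)
  expect_equal(two$center, c(1.5, 2))
  # unit equilateral triangle: circumradius 1/sqrt(3)
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(smallest_enclosing_circle(tri)$radius, 1 / sqrt(3),
               tolerance = 1e-12)
  # collinear points: farthest-pair diameter
  col <- rbind(c(0, 0), c(1, 0), c(2, 0), c(5, 0))
  expect_equal(smallest_enclosing_circle(col)$radius, 2.5)
})

test_that("smallest enclosing circle matches the brute-force oracle", {
  set.seed(40)
  for (i in 1:1000) {
    pts <- matrix(runif(2 * sample(2:12, 1), 0, 10), ncol = 2)
    fast <- smallest_enclosing_circle(pts)
    slow <- brute_force_sec(pts)
    expect_equal(fast$radius, slow$radius, tolerance = 1e-9)
    # and it really contains every point
    d <- sqrt((pts[, 1] - fast$center[1])^2 + (pts[, 2] - fast$center[2])^2)
    expect_true(all(d <= fast$radius + 1e-9))
  }
})

test_that("classification separates static, Brownian and short tracks", {
  set.seed(41)
  static <- cbind(5 + rnorm(100, 0, 0.01), 5 + rnorm(100, 0, 0.01))
  brownian <- cbind(cumsum(c(0, rnorm(19, 0, sqrt(2 * 0.7 * 0.1)))),
                    cumsum(c(0, rnorm(19, 0, sqrt(2 * 0.7 * 0.1)))))
  short <- matrix(0, nrow = 4, ncol = 2)
  ds <- make_trajectory_df(list(static, brownian, short), dt = 0.1)
  lab <- classify_mobility(ds)
  expect_equal(lab$label, c("immobilized", "mobile", "too_short"))
  expect_equal(lab$reduced_radius[1],
               lab$radius_um[1] / sqrt(lab$duration_s[1]))
})

test_that("Brownian tracks at D = 0.7 are classified mobile almost surely", {
  set.seed(42)
  n_sim <- 500
  sd_step <- sqrt(2 * 0.7 * 0.1)
  labels <- vapply(seq_len(n_sim), function(i) {
    xy <- cbind(cumsum(c(0, rnorm(19, 0, sd_step))),
                cumsum(c(0, rnorm(19, 0, sd_step))))
    ds <- make_trajectory_df(list(xy), dt = 0.1)
    classify_mobility(ds)$label
  }, character(1))
  expect_gt(mean(labels == "mobile"), 0.95)
})

test_that("reduced radius is invariant under diffusion rescaling in expectation", {
  set.seed(43)
  rr <- function(time_scale, space_scale) {
    mean(replicate(300, {
      sd_step <- sqrt(2 * 0.7 * 0.1) * space_scale
      xy <- cbind(cumsum(c(0, rnorm(19, 0, sd_step))),
                  cumsum(c(0, rnorm(19, 0, sd_step))))
      circ <- smallest_enclosing_circle(xy)
      circ$radius / sqrt(19 * 0.1 * time_scale)
    }))
  }
  # t -> 4t, x -> 2x leaves the reduced radius unchanged
  expect_equal(rr(1, 1), rr(4, 2), tolerance = 0.05)
})

test_that("bound fraction recovers the immobilized share with bootstrap", {
  ds <- generate_force_dataset(
    synthetic_scenario(n_tracks = 300, mean_track_length = 12,
                       min_track_length = 5, phi_immobile = 0.3, seed = 44))
  lab <- classify_mobility(ds)
  bf <- bound_fraction(lab, n_boot = 400, seed = 45)
  expect_lt(abs(bf$fraction - 0.3), 3 * bf$bootstrap$se + 0.02)
  # degenerate case: everything immobilized
  all_imm <- data.frame(label = rep("immobilized", 10))
  expect_equal(bound_fraction(all_imm, n_boot = 10)$fraction, 1)
  # label swap maps p to 1 - p
  mixed <- data.frame(label = c(rep("immobilized", 3), rep("mobile", 7)))
  swapped <- data.frame(label = c(rep("mobile", 3), rep("immobilized", 7)))
  expect_equal(bound_fraction(mixed, n_boot = 10)$fraction,
               1 - bound_fraction(swapped, n_boot = 10)$fraction)
  expect_error(bound_fraction(data.frame(label = "too_short")), "too short")
})

test_that("force statistics conditioned on immobilized tracks match truth labels", {
  ds <- generate_force_dataset(
    synthetic_scenario(n_tracks = 400, mean_track_length = 12,
                       min_track_length = 5, phi_force = 0.15, force_pN = 9,
                       phi_immobile = 0.4, seed = 46))
  nocell <- generate_force_dataset(
    synthetic_scenario(n_tracks = 400, mean_track_length = 12,
                       min_track_length = 5, cell_present = FALSE, seed = 47))
  th <- compute_threshold(nocell$efficiency)
  lab <- classify_mobility(ds)
  imm_ids <- lab$track_id[lab$label == "immobilized"]
  est_imm <- high_force_fraction(
    ds$efficiency[ds$track_id %in% imm_ids], th)$fraction_point
  truth_ids <- unique(ds$track_id[!ds$truth_mobile])
  est_truth <- high_force_fraction(
    ds$efficiency[ds$track_id %in% truth_ids], th)$fraction_point
  # classifier-conditioned and truth-conditioned fractions agree closely
  expect_equal(est_imm, est_truth, tolerance = 0.03)
  # and both are enriched relative to the full dataset
  expect_gt(est_imm, high_force_fraction(ds$efficiency, th)$fraction_point)
})
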