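test_that("threshold is the interpolated empirical quantile", {
  th <- compute_threshold(1:100, f = 0.05)
  # type-7 interpolation between the 5th and 6th order statistics
  expect_equal(th$q_f, unname(quantile(1:100, 0.05, type = 7)))
  expect_gte(th$q_f, 5); expect_lte(th$q_f, 6)
  # degenerate distribution
  expect_equal(compute_threshold(rep(0.9, 50))$q_f, 0.9)
  # large uniform sample: q_f near f
  set.seed(1)
  expect_lt(abs(compute_threshold(runif(2e4), f = 0.05)$q_f - 0.05), 0.01)
  expect_error(compute_threshold(1:10), "at least 20")
  expect_error(compute_threshold(1:100, f = 1), "'f'")
})

test_that("corrected fraction is n_low/n_total - f, unclamped", {
  th <- compute_threshold(rnorm(1000, 0.865, 0.164))
  # saturated case: everything below threshold
  hf <- high_force_fraction(rep(th$q_f - 1, 100), th)
  expect_equal(hf$fraction_point, 1 - 0.05)
  expect_equal(hf$n_low, 100)
  # null case: same distribution, expectation 0
  set.seed(2)
  x <- rnorm(5e4, 0.865, 0.164)
  th2 <- compute_threshold(rnorm(5e4, 0.865, 0.164))
  se <- sqrt(0.05 * 0.95 / 5e4) * 2  # threshold noise roughly doubles it
  expect_lt(abs(high_force_fraction(x, th2)$fraction_point), 3 * se + 0.005)
  # negative values are reported, not clamped
  hf0 <- high_force_fraction(rep(th$q_f + 1, 100), th)
  expect_equal(hf0$fraction_point, -0.05)
  expect_error(high_force_fraction(numeric(0), th), "no cell")
})

test_that("synthetic mixtures recover 0.95 * phi", {
  set.seed(3)
  calib <- default_calib
  E9 <- efficiency_from_force(9, calib)
  th <- compute_threshold(rnorm(5e4, 0.865, 0.164))
  for (phi in c(0.05, 0.1, 0.2)) {
    n <- 4e4
    nf <- round(phi * n)
    x <- c(rnorm(n - nf, 0.865, 0.164), rnorm(nf, E9, 0.164))
    est <- high_force_fraction(x, th)$fraction_point
    # essentially all force observations fall below q_f, so the corrected
    # fraction estimates 0.95 * phi (binomial error + threshold noise)
    expect_lt(abs(est - 0.95 * phi), 0.012)
  }
})

test_that("track bootstrap is deterministic and degenerates correctly", {
  th <- structure(list(q_f = 0.5, f = 0.05, n = 100),
                  class = "threshold_result")
  # identical tracks: degenerate bootstrap distribution
  eff <- rep(c(0.4, 0.6), 10)
  ids <- rep(1:10, each = 2)
  bf <- bootstrap_fraction(eff, ids, th, n_boot = 100, seed = 5)
  expect_equal(bf$bootstrap$se, 0)
  expect_equal(bf$bootstrap$median, bf$fraction_point)
  # fixed seed reproduces summaries
  set.seed(6)
  eff2 <- rnorm(200, 0.6, 0.1); ids2 <- rep(1:40, each = 5)
  b1 <- bootstrap_fraction(eff2, ids2, th, n_boot = 200, seed = 11)
  b2 <- bootstrap_fraction(eff2, ids2, th, n_boot = 200, seed = 11)
  expect_identical(b1$bootstrap, b2$bootstrap)
  expect_error(bootstrap_fraction(eff2, ids2, th, n_boot = 1), "n_boot")
})

test_that("bootstrap mean tracks the point estimate on mixtures", {
  set.seed(7)
  E9 <- efficiency_from_force(9, default_calib)
  th <- compute_threshold(rnorm(2e4, 0.865, 0.164))
  n_tracks <- 200
  force_track <- runif(n_tracks) < 0.10
  eff <- unlist(lapply(seq_len(n_tracks), function(i)
    rnorm(8, if (force_track[i]) E9 else 0.865, 0.164)))
  ids <- rep(seq_len(n_tracks), each = 8)
  bf <- bootstrap_fraction(eff, ids, th, n_boot = 400, seed = 8)
  expect_lt(abs(bf$bootstrap$mean - 0.95 * mean(force_track)),
            3 * bf$bootstrap$se)
})

test_that("ASH bin count follows Sturges's rule and the density normalizes", {
  expect_equal(ash_pdf(rnorm(100), n_points_for_bins = 1000)$n_bins, 11)
  expect_equal(ash_pdf(c(0.1, 0.2), n_points_for_bins = 2)$n_bins, 2)
  set.seed(9)
  pdf <- ash_pdf(rnorm(5000, 0.5, 0.2))
  expect_equal(sum(pdf$y) * pdf$fine_width, 1, tolerance = 1e-6)
  expect_true(all(pdf$y >= 0))
  # out-of-range values are excluded, not binned
  pdf2 <- ash_pdf(c(rnorm(1000, 0.5, 0.1), 7, -7))
  expect_equal(pdf2$n_excluded, 2)
})

test_that("force PDF recovers the injected force and its mixture weight", {
  set.seed(10)
  calib <- default_calib
  n <- 2e4; nf <- round(0.2 * n)
  cell <- c(rnorm(n - nf, 0.865, 0.164),
            rnorm(nf, efficiency_from_force(5, calib), 0.164))
  nocell <- rnorm(n, 0.865, 0.164)
  fp <- estimate_force_pdf(cell, nocell, calib)
  expect_true(fp$detected)
  expect_equal(unname(fp$quartiles[["median"]]), 5, tolerance = 0.1)
  # unchanged no-force component: width ~1, height ~ force-free mass
  expect_equal(fp$s_width, 1, tolerance = 0.05)
  expect_equal(fp$s_height, 0.8, tolerance = 0.05)
  expect_true(all(fp$density >= 0))
  expect_true(all(fp$force > 0))
})

test_that("self-subtraction yields a no-detectable-force result", {
  set.seed(11)
  x <- rnorm(1e4, 0.865, 0.164)
  fp <- estimate_force_pdf(x, x, default_calib)
  expect_false(fp$detected)
  expect_null(fp$quartiles)
  expect_lt(fp$residual_mass, 1e-3)
})

test_that("null high-force fraction has mean zero over repeated simulations", {
  set.seed(12)
  n_sim <- 500
  fracs <- vapply(seq_len(n_sim), function(i) {
    th <- compute_threshold(rnorm(800, 0.865, 0.164))
    high_force_fraction(rnorm(800, 0.865, 0.164), th)$fraction_point
  }, numeric(1))
  expect_lt(abs(mean(fracs)), 3 * stats::sd(fracs) / sqrt(n_sim))
})
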