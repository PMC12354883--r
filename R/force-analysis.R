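# High-force fraction estimation and force-PDF reconstruction by scaled
# subtraction of average shifted FRET efficiency histograms.

#' Efficiency threshold from cell-free data
#'
#' The threshold \code{q_f} is the empirical \code{f}-quantile (linear
#' interpolation between order statistics, \code{stats::quantile} type 7)
#' of FRET efficiencies recorded without cells. Observations below
#' \code{q_f} in cell-derived data are counted as high-force events with a
#' nominal false-positive rate \code{f}.
#'
#' @param no_cell_efficiencies Numeric vector of cell-free efficiencies
#'   (at least 20 values).
#' @param f Nominal false-positive rate in (0, 1); default 0.05.
#' @param quantile_type Quantile algorithm passed to
#'   \code{\link[stats]{quantile}} (default 7, linear interpolation).
#' @return A \code{threshold_result} list with fields \code{q_f}, \code{f}
#'   and \code{n} (sample size used).
#' @export
compute_threshold <- function(no_cell_efficiencies, f = 0.05,
                              quantile_type = 7) {
  x <- no_cell_efficiencies[is.finite(no_cell_efficiencies)]
  if (length(x) < 20)
    stop("at least 20 cell-free datapoints are required to set a threshold; ",
         "got ", length(x))
  if (!(f > 0 && f < 1)) stop("'f' must lie in (0, 1)")
  q <- unname(stats::quantile(x, probs = f, type = quantile_type))
  structure(list(q_f = q, f = f, n = length(x)), class = "threshold_result")
}

#' Corrected high-force fraction (point estimate)
#'
#' Counts cell-derived observations with efficiency strictly below the
#' threshold and subtracts the nominal false-positive rate:
#' \code{n_low / n_total - f}. The result may be negative through sampling
#' noise and is deliberately not clamped.
#'
#' @param efficiencies Numeric vector of cell-derived efficiencies.
#' @param threshold A \code{\link{compute_threshold}} result.
#' @return A \code{high_force_result} list with \code{fraction_point},
#'   \code{n_low}, \code{n_total} and the threshold used.
#' @export
high_force_fraction <- function(efficiencies, threshold) {
  stopifnot(inherits(threshold, "threshold_result"))
  x <- efficiencies[is.finite(efficiencies)]
  if (length(x) == 0) stop("no cell-derived efficiencies supplied")
  n_low <- sum(x < threshold$q_f)
  structure(list(fraction_point = n_low / length(x) - threshold$f,
                 n_low = n_low, n_total = length(x),
                 threshold = threshold),
            class = "high_force_result")
}

# Box-and-whisker style summary used for all bootstrap distributions:
# quartiles, whiskers at the most extreme points within 1.5 IQR of the box,
# mean and standard deviation (reported as the standard error of the
# estimate, since each resample re-estimates the statistic).
bootstrap_summary <- function(values) {
  qs <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- qs[3] - qs[1]
  lo_lim <- qs[1] - 1.5 * iqr
  hi_lim <- qs[3] + 1.5 * iqr
  inside <- values[values >= lo_lim & values <= hi_lim]
  list(q1 = qs[1], median = qs[2], q3 = qs[3],
       whisker_lo = if (length(inside)) min(inside) else qs[1],
       whisker_hi = if (length(inside)) max(inside) else qs[3],
       mean = mean(values), se = stats::sd(values),
       n_resamples = length(values))
}

#' Track-preserving bootstrap of the high-force fraction
#'
#' Resamples whole tracks with replacement (observations within a track may
#' be correlated, so tracks are the exchangeable unit), recomputes the
#' corrected fraction for each resample, and summarizes the resulting
#' distribution with quartiles, 1.5-IQR whiskers, mean and standard error.
#'
#' @param efficiencies Numeric vector of cell-derived efficiencies.
#' @param track_ids Track identifier per observation (same length).
#' @param threshold A \code{\link{compute_threshold}} result.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the resampling stream.
#' @return A \code{high_force_result} with the point estimate plus a
#'   \code{bootstrap} summary list and the vector of resampled fractions.
#' @export
bootstrap_fraction <- function(efficiencies, track_ids, threshold,
                               n_boot = 1000, seed = 1L) {
  stopifnot(length(efficiencies) == length(track_ids),
            inherits(threshold, "threshold_result"))
  if (n_boot < 2) stop("'n_boot' must be >= 2")
  tracks <- split(efficiencies, track_ids)
  if (length(tracks) < 2)
    stop("track-preserving bootstrap needs at least 2 tracks")
  point <- high_force_fraction(efficiencies, threshold)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 3))
  nt <- length(tracks)
  fracs <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(nt, nt, replace = TRUE)
    x <- unlist(tracks[idx], use.names = FALSE)
    sum(x < threshold$q_f) / length(x) - threshold$f
  }, numeric(1))
  point$bootstrap <- bootstrap_summary(fracs)
  point$bootstrap_values <- fracs
  point$seed <- seed
  point
}

#' Average shifted histogram density estimate
#'
#' Averages \code{n_shifts} histograms whose bin origins are uniformly
#' offset across one bin width, on a fixed range. The number of (coarse)
#' bins follows Sturges's rule, \code{1 + ceiling(log2(n))}, where \code{n}
#' is \code{n_points_for_bins} (by default the sample size). The result is
#' a piecewise-constant density on a fine grid of \code{bins * n_shifts}
#' cells, normalized to integrate to 1 over the range. Values outside the
#' range are excluded and counted in the \code{n_excluded} field.
#'
#' @param values Numeric sample.
#' @param range_lo,range_hi Histogram range (defaults -0.5 and 1.5, the
#'   admissible FRET-efficiency window).
#' @param n_shifts Number of shifted histograms (default 40).
#' @param n_points_for_bins Sample size driving Sturges's rule; defaults to
#'   \code{length(values)}. Supplying it explicitly lets two samples share
#'   one grid.
#' @return An \code{ash_pdf} list with \code{x} (fine-grid cell centers),
#'   \code{y} (density), \code{breaks}, \code{bin_width}, \code{n_bins},
#'   \code{n_used}, \code{n_excluded}.
#' @export
ash_pdf <- function(values, range_lo = -0.5, range_hi = 1.5, n_shifts = 40,
                    n_points_for_bins = length(values)) {
  stopifnot(range_hi > range_lo, n_shifts >= 1, n_points_for_bins >= 2)
  x <- values[is.finite(values)]
  inside <- x >= range_lo & x <= range_hi
  n_excluded <- sum(!inside) + (length(values) - length(x))
  x <- x[inside]
  if (length(x) == 0) stop("no values inside the histogram range")
  n_bins <- 1 + ceiling(log2(n_points_for_bins))
  h <- (range_hi - range_lo) / n_bins          # coarse bin width
  delta <- h / n_shifts                        # fine cell width
  n_fine <- n_bins * n_shifts
  # fine-cell counts; clamp the right edge into the last cell
  idx <- pmin(floor((x - range_lo) / delta) + 1L, n_fine)
  counts <- tabulate(idx, nbins = n_fine)
  # ASH weights: triangular kernel over 2*n_shifts - 1 fine cells
  w <- 1 - abs(seq(-(n_shifts - 1), n_shifts - 1)) / n_shifts
  dens <- numeric(n_fine)
  for (j in seq_along(w)) {
    off <- j - n_shifts
    src <- seq_len(n_fine) + off
    ok <- src >= 1 & src <= n_fine
    dens[ok] <- dens[ok] + w[j] * counts[src[ok]]
  }
  dens <- dens / (length(x) * h)
  # renormalize: boundary truncation of the kernel loses a little mass
  mass <- sum(dens) * delta
  if (mass > 0) dens <- dens / mass
  structure(list(x = range_lo + (seq_len(n_fine) - 0.5) * delta,
                 y = dens,
                 bin_width = h, fine_width = delta, n_bins = n_bins,
                 n_used = length(x), n_excluded = n_excluded),
            class = "ash_pdf")
}

# Evaluate an ash_pdf at arbitrary points by linear interpolation
# (0 outside the range).
ash_eval <- function(pdf, x) {
  y <- stats::approx(pdf$x, pdf$y, xout = x, yleft = 0, yright = 0)$y
  y[is.na(y)] <- 0
  y
}

#' Reconstruct the force probability density
#'
#' Builds average shifted histograms of the cell-derived and cell-free
#' efficiency samples on a common grid, fits two scale parameters
#' (\code{s_width}, \code{s_height}) so that the cell-free PDF, x-scaled
#' about \code{anchor_E} via \code{anchor_E + s_width * (x - anchor_E)} and
#' y-scaled by \code{s_height}, best matches the cell PDF on the low-force
#' window (\code{efficiency > fit_window_lo}), subtracts the scaled
#' cell-free PDF, clips negative residual density to zero, and converts the
#' surviving low-efficiency density to a force PDF through the sensor
#' calibration with the analytic change-of-variables Jacobian. Residual
#' mass at negative force (efficiencies above the zero-force efficiency) is
#' dropped before renormalization. Quartiles are read off the inverse CDF
#' by linear interpolation.
#'
#' @param cell_efficiencies,no_cell_efficiencies Numeric samples.
#' @param calib A \code{\link{sensor_calibration}}.
#' @param anchor_E Efficiency about which the width scaling pivots
#'   (default 0.87, the zero-force reference of the subtraction procedure —
#'   kept distinct from the calibration's own zero-force efficiency).
#' @param fit_window_lo Lower efficiency bound of the fit window
#'   (default 0.75).
#' @param range_lo,range_hi,n_shifts ASH parameters, see
#'   \code{\link{ash_pdf}}. Sturges's rule uses the cell sample size for
#'   both histograms so the grids match.
#' @param mass_floor Minimum residual probability mass (of the whole
#'   efficiency residual) below which a "no detectable force" result is
#'   returned instead of quartiles (default 1e-3).
#' @return A \code{force_pdf} list: \code{force} grid (pN), \code{density},
#'   \code{quartiles} (Q1/median/Q3, pN, or \code{NULL}), \code{s_width},
#'   \code{s_height}, \code{residual_mass}, \code{detected} flag, and the
#'   efficiency-space grids for inspection.
#' @export
estimate_force_pdf <- function(cell_efficiencies, no_cell_efficiencies,
                               calib = sensor_calibration(),
                               anchor_E = 0.87, fit_window_lo = 0.75,
                               range_lo = -0.5, range_hi = 1.5,
                               n_shifts = 40, mass_floor = 1e-3) {
  stopifnot(length(cell_efficiencies) > 0, length(no_cell_efficiencies) > 0,
            inherits(calib, "sensor_calibration"))
  n_ref <- sum(is.finite(cell_efficiencies))
  pdf_cell <- ash_pdf(cell_efficiencies, range_lo, range_hi, n_shifts,
                      n_points_for_bins = n_ref)
  pdf_free <- ash_pdf(no_cell_efficiencies, range_lo, range_hi, n_shifts,
                      n_points_for_bins = n_ref)

  fit_idx <- pdf_cell$x > fit_window_lo
  x_fit <- pdf_cell$x[fit_idx]
  y_cell_fit <- pdf_cell$y[fit_idx]
  scaled_at <- function(x, s_width, s_height) {
    # value at x of the cell-free PDF whose x axis was stretched by s_width
    # about the anchor and whose height was multiplied by s_height
    s_height * ash_eval(pdf_free, anchor_E + (x - anchor_E) / s_width)
  }
  obj <- function(par) {
    sum((y_cell_fit - scaled_at(x_fit, par[1], par[2]))^2)
  }
  fit <- stats::optim(c(1, 1), obj, method = "L-BFGS-B",
                      lower = c(1e-3, 1e-3), upper = c(5, 5))
  s_width <- fit$par[1]; s_height <- fit$par[2]

  resid <- pdf_cell$y - scaled_at(pdf_cell$x, s_width, s_height)
  resid[resid < 0] <- 0
  dx <- pdf_cell$fine_width
  residual_mass <- sum(resid) * dx
  base <- list(efficiency = pdf_cell$x, residual_density = resid,
               s_width = s_width, s_height = s_height,
               residual_mass = residual_mass,
               cell_pdf = pdf_cell, no_cell_pdf = pdf_free)
  if (residual_mass < mass_floor) {
    return(structure(c(base, list(detected = FALSE, force = numeric(0),
                                  density = numeric(0), quartiles = NULL)),
                     class = "force_pdf"))
  }

  # change of variables E -> F on the grid points with a defined force;
  # efficiencies at or above the zero-force efficiency map to F <= 0 and
  # are dropped before renormalization
  ok <- pdf_cell$x > 0 & pdf_cell$x < 1
  E_grid <- pdf_cell$x[ok]
  F_grid <- force_from_efficiency(E_grid, calib)
  dens_F <- resid[ok] * abs(efficiency_force_jacobian(F_grid, calib))
  pos <- F_grid > 0
  F_grid <- F_grid[pos]; dens_F <- dens_F[pos]
  ord <- order(F_grid)
  F_grid <- F_grid[ord]; dens_F <- dens_F[ord]
  # trapezoidal renormalization on the (non-uniform) force grid
  mass <- sum(diff(F_grid) * (utils::head(dens_F, -1) + utils::tail(dens_F, -1)) / 2)
  if (mass <= 0) {
    return(structure(c(base, list(detected = FALSE, force = F_grid,
                                  density = dens_F, quartiles = NULL)),
                     class = "force_pdf"))
  }
  dens_F <- dens_F / mass
  cdf <- c(0, cumsum(diff(F_grid) *
                       (utils::head(dens_F, -1) + utils::tail(dens_F, -1)) / 2))
  cdf <- cdf / cdf[length(cdf)]
  qfun <- function(p) stats::approx(cdf, F_grid, xout = p, ties = "ordered")$y
  quart <- c(q1 = qfun(0.25), median = qfun(0.5), q3 = qfun(0.75))
  structure(c(base, list(detected = TRUE, force = F_grid, density = dens_F,
                         quartiles = quart)),
            class = "force_pdf")
}

#' @export
print.force_pdf <- function(x, ...) {
  cat("Force PDF by scaled PDF subtraction\n")
  cat(sprintf("  fit: s_width = %.3f, s_height = %.3f; residual mass %.4f\n",
              x$s_width, x$s_height, x$residual_mass))
  if (isTRUE(x$detected)) {
    cat(sprintf("  force quartiles [pN]: Q1 = %.2f, median = %.2f, Q3 = %.2f\n",
                x$quartiles[["q1"]], x$quartiles[["median"]],
                x$quartiles[["q3"]]))
  } else {
    cat("  no detectable force (residual mass below floor)\n")
  }
  invisible(x)
}
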