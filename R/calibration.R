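# Sensor calibration: entropic-spring force law and Foerster relation.
# All lengths in nm, all forces in pN throughout the package.

#' Molecular force sensor calibration
#'
#' Construct the calibration object that links dye separation, FRET
#' efficiency and force for a peptide-based molecular force sensor. The
#' spring element behaves as an entropic spring with a linear
#' force-extension relation \eqn{F(r) = (r - b n - c) / (a n)}, and the
#' FRET efficiency follows the Foerster relation
#' \eqn{E(r) = 1 / (1 + (r/R_0)^6)}.
#'
#' @param a Spring compliance slope, nm/pN. Must be positive.
#' @param b Per-residue extension offset, nm. Must be non-negative.
#' @param c Spring-specific constant, nm. Must be non-negative.
#' @param n Number of amino acids in the spring element (positive integer).
#' @param R0 Foerster radius of the dye pair, nm. Must be positive.
#'
#' @return An object of class \code{sensor_calibration}: a list with fields
#'   \code{a}, \code{b}, \code{c}, \code{n}, \code{R0} plus the derived
#'   zero-force separation \code{r0 = b*n + c} (nm) and zero-force
#'   efficiency \code{E0 = efficiency_from_separation(r0, R0)}.
#'
#' @examples
#' calib <- sensor_calibration()
#' force_from_efficiency(0.5, calib)   # about 4.02 pN
#' @export
sensor_calibration <- function(a = 0.0122, b = 0.044, c = 2.4, n = 29,
                               R0 = 5.1) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(c), length(c) == 1L, is.finite(c),
            is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(R0), length(R0) == 1L, is.finite(R0))
  if (a <= 0) stop("spring compliance 'a' must be > 0 nm/pN")
  if (b < 0) stop("per-residue offset 'b' must be >= 0 nm")
  if (c < 0) stop("constant 'c' must be >= 0 nm")
  if (n < 1 || n != round(n)) stop("'n' must be a positive integer")
  if (R0 <= 0) stop("Foerster radius 'R0' must be > 0 nm")
  r0 <- b * n + c
  if (r0 <= 0) stop("zero-force separation b*n + c must be > 0 nm")
  structure(
    list(a = a, b = b, c = c, n = as.integer(n), R0 = R0,
         r0 = r0, E0 = 1 / (1 + (r0 / R0)^6)),
    class = "sensor_calibration"
  )
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat("Molecular force sensor calibration\n")
  cat(sprintf("  a  = %.4f nm/pN (compliance slope)\n", x$a))
  cat(sprintf("  b  = %.3f nm (per-residue offset), n = %d residues\n",
              x$b, x$n))
  cat(sprintf("  c  = %.2f nm, R0 = %.2f nm\n", x$c, x$R0))
  cat(sprintf("  zero-force separation r0 = %.4f nm (E0 = %.4f)\n",
              x$r0, x$E0))
  invisible(x)
}

#' Force from dye separation
#'
#' Linear entropic-spring force law \eqn{F(r) = (r - b n - c)/(a n)}.
#' Values of \code{r} below the zero-force separation give negative forces;
#' they are returned as-is so that callers decide whether to clamp.
#'
#' @param r Dye separation, nm (positive).
#' @param calib A \code{\link{sensor_calibration}}.
#' @return Force in pN, same length as \code{r}.
#' @export
force_from_separation <- function(r, calib = sensor_calibration()) {
  stopifnot(inherits(calib, "sensor_calibration"), is.numeric(r))
  if (any(!is.finite(r)) || any(r <= 0))
    stop("dye separation 'r' must be positive and finite")
  (r - calib$b * calib$n - calib$c) / (calib$a * calib$n)
}

#' FRET efficiency from dye separation
#'
#' Foerster relation \eqn{E(r) = (1 + (r/R_0)^6)^{-1}}; strictly decreasing
#' in \code{r} with values in (0, 1).
#'
#' @param r Dye separation, nm (positive).
#' @param R0 Foerster radius, nm (positive).
#' @return FRET efficiency in (0, 1).
#' @export
efficiency_from_separation <- function(r, R0 = 5.1) {
  stopifnot(is.numeric(r), is.numeric(R0), length(R0) == 1L)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("dye separation 'r' must be positive and finite")
  if (!is.finite(R0) || R0 <= 0) stop("Foerster radius 'R0' must be positive")
  1 / (1 + (r / R0)^6)
}

#' Dye separation from FRET efficiency
#'
#' Closed-form inverse of the Foerster relation,
#' \eqn{r(E) = R_0 (1/E - 1)^{1/6}}.
#'
#' @param E FRET efficiency, strictly inside (0, 1).
#' @param R0 Foerster radius, nm.
#' @return Dye separation in nm.
#' @export
separation_from_efficiency <- function(E, R0 = 5.1) {
  stopifnot(is.numeric(E), is.numeric(R0), length(R0) == 1L)
  if (any(!is.finite(E)) || any(E <= 0) || any(E >= 1))
    stop("FRET efficiency must lie strictly inside (0, 1)")
  if (!is.finite(R0) || R0 <= 0) stop("Foerster radius 'R0' must be positive")
  R0 * (1 / E - 1)^(1 / 6)
}

#' Force from FRET efficiency
#'
#' The sensor readout map \eqn{F(E)}: invert the Foerster relation in closed
#' form and apply the linear spring law. Strictly decreasing in \code{E};
#' efficiencies above the zero-force efficiency yield negative forces
#' (returned unclamped).
#'
#' @inheritParams separation_from_efficiency
#' @param calib A \code{\link{sensor_calibration}}.
#' @return Force in pN.
#' @export
force_from_efficiency <- function(E, calib = sensor_calibration()) {
  stopifnot(inherits(calib, "sensor_calibration"))
  force_from_separation(separation_from_efficiency(E, calib$R0), calib)
}

#' FRET efficiency from force
#'
#' Forward map \eqn{E(F)}: spring extension \eqn{r = a n F + b n + c}
#' followed by the Foerster relation. Inverse of
#' \code{\link{force_from_efficiency}}.
#'
#' @param F Force, pN. May be negative as long as the implied separation
#'   stays positive.
#' @param calib A \code{\link{sensor_calibration}}.
#' @return FRET efficiency in (0, 1).
#' @export
efficiency_from_force <- function(F, calib = sensor_calibration()) {
  stopifnot(inherits(calib, "sensor_calibration"), is.numeric(F))
  r <- calib$a * calib$n * F + calib$r0
  if (any(!is.finite(r)) || any(r <= 0))
    stop("force implies a non-positive dye separation")
  efficiency_from_separation(r, calib$R0)
}

# dE/dF of the efficiency-from-force map, analytic. Used as change-of-
# variables Jacobian when converting efficiency densities to force densities.
efficiency_force_jacobian <- function(F, calib = sensor_calibration()) {
  r <- calib$a * calib$n * F + calib$r0
  u <- (r / calib$R0)^6
  # dE/dr = -6 u / (r (1 + u)^2); dr/dF = a n
  -(6 * u / (r * (1 + u)^2)) * calib$a * calib$n
}

#' Propagate efficiency uncertainty into force uncertainty
#'
#' Maps \code{n_grid} forces evenly spaced on \code{[0, F_max]} to their
#' FRET efficiencies, shifts each efficiency down by \code{delta_E},
#' re-inverts to force and reports the largest resulting force error
#' \eqn{\Delta F_i = F(E_i - \Delta E) - F_i}. Because \eqn{F(E)} is
#' decreasing and convex in this regime, the error grows with force, so the
#' maximum sits at the high-force end of the grid.
#'
#' @param calib A \code{\link{sensor_calibration}}.
#' @param delta_E Efficiency uncertainty (non-negative), typically the
#'   standard error of the fitted zero-force mean efficiency.
#' @param F_max Upper end of the force grid, pN.
#' @param n_grid Number of grid points (>= 2).
#' @return Maximum force uncertainty over the grid, pN.
#' @export
propagate_uncertainty <- function(calib = sensor_calibration(),
                                  delta_E = 0.005, F_max = 9, n_grid = 100) {
  stopifnot(inherits(calib, "sensor_calibration"),
            is.numeric(delta_E), length(delta_E) == 1L,
            is.numeric(F_max), length(F_max) == 1L,
            is.numeric(n_grid), length(n_grid) == 1L)
  if (delta_E < 0) stop("'delta_E' must be >= 0")
  if (F_max <= 0) stop("'F_max' must be > 0")
  if (n_grid < 2) stop("'n_grid' must be >= 2")
  F_i <- seq(0, F_max, length.out = n_grid)
  E_i <- efficiency_from_force(F_i, calib)
  E_shift <- E_i - delta_E
  if (any(E_shift <= 0))
    stop("delta_E pushes a grid efficiency to or below 0; reduce F_max or delta_E")
  max(force_from_efficiency(E_shift, calib) - F_i)
}
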