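# Shared fixtures and independent oracles used across the test files.

default_calib <- sensor_calibration()

# list-of-tracks sample: nt tracks of given length from one normal
make_tracks <- function(nt, len, mu = 0.865, sigma = 0.164) {
  lapply(seq_len(nt), function(i) stats::rnorm(len, mu, sigma))
}

# independent numeric inversion of the efficiency->force map via uniroot,
# used as oracle against the closed-form inverse
force_from_efficiency_numeric <- function(E, calib = default_calib) {
  vapply(E, function(e) {
    # forces below -r0/(a n) imply a non-positive separation; stay inside
    f_lo <- -0.99 * calib$r0 / (calib$a * calib$n)
    stats::uniroot(function(F) efficiency_from_force(F, calib) - e,
                   interval = c(f_lo, 200), tol = 1e-12)$root
  }, numeric(1))
}

# brute-force smallest enclosing circle: try every 2-point diameter circle
# and every 3-point circumcircle, keep the smallest that contains all points
brute_force_sec <- function(pts) {
  n <- nrow(pts)
  best <- NULL
  contains_all <- function(center, radius) {
    all(sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2) <=
          radius + 1e-9)
  }
  consider <- function(center, radius) {
    if (contains_all(center, radius) &&
        (is.null(best) || radius < best$radius))
      best <<- list(center = center, radius = radius)
  }
  if (n == 1) return(list(center = pts[1, ], radius = 0))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    consider((pts[i, ] + pts[j, ]) / 2,
             sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2)
  }
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    p <- pts[i, ]; q <- pts[j, ]; r <- pts[k, ]
    d <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) +
                r[1] * (p[2] - q[2]))
    if (abs(d) < 1e-12) next
    ux <- (sum(p^2) * (q[2] - r[2]) + sum(q^2) * (r[2] - p[2]) +
             sum(r^2) * (p[2] - q[2])) / d
    uy <- (sum(p^2) * (r[1] - q[1]) + sum(q^2) * (p[1] - r[1]) +
             sum(r^2) * (q[1] - p[1])) / d
    consider(c(ux, uy), sqrt((ux - p[1])^2 + (uy - p[2])^2))
  }
  best
}

# build a minimal trajectory data.frame from per-track position lists
make_trajectory_df <- function(tracks_xy, dt = 0.1) {
  rows <- lapply(seq_along(tracks_xy), function(i) {
    xy <- tracks_xy[[i]]
    data.frame(track_id = i, frame = seq_len(nrow(xy)),
               time_s = (seq_len(nrow(xy)) - 1) * dt,
               x_um = xy[, 1], y_um = xy[, 2])
  })
  do.call(rbind, rows)
}
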