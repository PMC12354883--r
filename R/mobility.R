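# Mobile vs. immobilized classification of single-molecule tracks via the
# smallest enclosing circle. On fluid bilayers an immobilized sensor is the
# proxy for a receptor-bound (anchored) sensor.

# circle through two points (diameter) and through three points
# (circumcircle; falls back to the widest diameter circle when collinear)
circle2 <- function(p, q) {
  list(center = (p + q) / 2, radius = sqrt(sum((p - q)^2)) / 2)
}
circle3 <- function(p, q, r) {
  ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14 * max(1, abs(ax), abs(ay), abs(bx), abs(by))) {
    # collinear: smallest circle is the diameter circle of the farthest pair
    cands <- list(circle2(p, q), circle2(p, r), circle2(q, r))
    return(cands[[which.max(vapply(cands, `[[`, numeric(1), "radius"))]])
  }
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  center <- c(ux, uy)
  list(center = center, radius = sqrt(sum((center - p)^2)))
}
in_circle <- function(circ, p, eps) {
  sqrt(sum((p - circ$center)^2)) <= circ$radius + eps
}

#' Smallest enclosing circle of a 2-D point set
#'
#' Deterministic incremental (Welzl-style) construction without random
#' shuffling, so repeated calls on the same input give identical output.
#' The returned circle contains every input point (within a small numeric
#' tolerance) and no smaller circle does.
#'
#' @param points Two-column numeric matrix (or data.frame) of x/y
#'   positions, um.
#' @return A list with \code{center} (length-2 numeric) and \code{radius}.
#' @export
smallest_enclosing_circle <- function(points) {
  pts <- as.matrix(points)
  if (length(pts) == 0 || nrow(pts) == 0) stop("empty point set")
  stopifnot(ncol(pts) == 2, all(is.finite(pts)))
  n <- nrow(pts)
  scale <- max(1, max(abs(pts)))
  eps <- 1e-10 * scale
  P <- lapply(seq_len(n), function(i) pts[i, ])

  circ <- list(center = P[[1]], radius = 0)
  if (n == 1) return(circ)
  for (i in 2:n) {
    if (in_circle(circ, P[[i]], eps)) next
    # P[[i]] lies on the boundary of the circle of P[1..i]
    circ <- circle2(P[[1]], P[[i]])
    if (i > 2) for (j in 2:(i - 1)) {
      if (in_circle(circ, P[[j]], eps)) next
      # P[[i]] and P[[j]] on the boundary
      circ <- circle2(P[[i]], P[[j]])
      if (j > 1) for (k in seq_len(j - 1)) {
        if (in_circle(circ, P[[k]], eps)) next
        circ <- circle3(P[[i]], P[[j]], P[[k]])
      }
    }
  }
  circ
}

#' Classify tracks as mobile or immobilized
#'
#' Computes the smallest enclosing circle of each track and its reduced
#' radius, \code{radius / sqrt(duration)}: under free diffusion the squared
#' radius grows linearly with time, so the reduced radius is a
#' diffusion-scale-free statistic. Tracks with a reduced radius below the
#' threshold (default 0.35 um s^-0.5) are labeled immobilized; tracks with
#' fewer than \code{min_observations} observations are labeled
#' \code{too_short} and excluded from fraction denominators. Duration is
#' measured from timestamps (last minus first), matching the s^-0.5 unit
#' of the threshold; a zero-duration track with enough observations is
#' immobilized by convention.
#'
#' @param ds Trajectory \code{data.frame} with \code{track_id},
#'   \code{time_s}, \code{x_um}, \code{y_um}.
#' @param reduced_radius_threshold Immobilization threshold, um s^-0.5
#'   (default 0.35).
#' @param min_observations Minimum observations per track (default 5).
#' @return A \code{data.frame} with one row per track: \code{track_id},
#'   \code{center_x_um}, \code{center_y_um}, \code{radius_um},
#'   \code{duration_s}, \code{reduced_radius}, \code{label} (one of
#'   \code{"mobile"}, \code{"immobilized"}, \code{"too_short"}).
#' @export
classify_mobility <- function(ds, reduced_radius_threshold = 0.35,
                              min_observations = 5) {
  stopifnot(is.data.frame(ds),
            all(c("track_id", "time_s", "x_um", "y_um") %in% names(ds)))
  rows <- lapply(split(ds, ds$track_id), function(tr) {
    n <- nrow(tr)
    circ <- smallest_enclosing_circle(cbind(tr$x_um, tr$y_um))
    dur <- max(tr$time_s) - min(tr$time_s)
    if (n < min_observations) {
      label <- "too_short"
      rr <- if (dur > 0) circ$radius / sqrt(dur) else NA_real_
    } else if (dur <= 0) {
      label <- "immobilized"  # no elapsed time: cannot have moved
      rr <- NA_real_
    } else {
      rr <- circ$radius / sqrt(dur)
      label <- if (rr < reduced_radius_threshold) "immobilized" else "mobile"
    }
    data.frame(track_id = tr$track_id[1],
               center_x_um = circ$center[1], center_y_um = circ$center[2],
               radius_um = circ$radius, duration_s = dur,
               reduced_radius = rr, label = label)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Immobilized (bound) fraction with track bootstrap
#'
#' Fraction of tracks labeled immobilized among all tracks that are not
#' \code{too_short}, with a track-resampling bootstrap summarized as in
#' \code{\link{bootstrap_fraction}}.
#'
#' @param labels Output of \code{\link{classify_mobility}}.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return A list with \code{fraction}, \code{n_immobilized},
#'   \code{n_classified}, \code{n_too_short} and a \code{bootstrap}
#'   summary.
#' @export
bound_fraction <- function(labels, n_boot = 1000, seed = 1L) {
  stopifnot(is.data.frame(labels), "label" %in% names(labels))
  lab <- labels$label[labels$label != "too_short"]
  if (length(lab) == 0)
    stop("all tracks are too short to classify")
  imm <- lab == "immobilized"
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 4))
  n <- length(imm)
  fracs <- vapply(seq_len(n_boot), function(i)
    mean(imm[sample.int(n, n, replace = TRUE)]), numeric(1))
  list(fraction = mean(imm), n_immobilized = sum(imm), n_classified = n,
       n_too_short = sum(labels$label == "too_short"),
       bootstrap = bootstrap_summary(fracs))
}
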