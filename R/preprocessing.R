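# Preprocessing of single-molecule trajectory tables: corrected FRET
# efficiency / stoichiometry, overlap and length filters, and a stepwise-
# bleaching (single-emitter) filter.

#' Compute corrected FRET efficiency and stoichiometry
#'
#' Applies the community-standard ALEX-style correction scheme. The
#' sensitized acceptor emission is corrected for donor bleed-through and
#' direct acceptor excitation,
#' \code{F_A = i_acceptor - bleedthrough * i_donor - direct * i_acceptor_aex},
#' and combined with the detection-efficiency factor \code{gamma} and
#' excitation factor \code{beta}:
#' efficiency \code{= F_A / (gamma * i_donor + F_A)} and stoichiometry
#' \code{= (gamma * i_donor + F_A) / (gamma * i_donor + F_A +
#' i_acceptor_aex / beta)}. With identity corrections (the defaults) the
#' efficiency reduces to the proximity ratio
#' \code{i_acceptor / (i_acceptor + i_donor)}.
#'
#' @param ds Trajectory \code{data.frame} with \code{i_donor} and
#'   \code{i_acceptor} columns; an \code{i_acceptor_aex} column (acceptor
#'   emission under direct acceptor excitation) is used when present.
#' @param bleedthrough Donor bleed-through factor (default 0).
#' @param direct Direct acceptor-excitation factor (default 0).
#' @param gamma Detection-efficiency correction factor (default 1).
#' @param beta Excitation correction factor (default 1).
#' @return The input with \code{efficiency} (and, when
#'   \code{i_acceptor_aex} is available, \code{stoichiometry}) columns
#'   filled. Observations with zero corrected total intensity are dropped.
#'   Negative corrected intensities are kept but flagged in the logical
#'   column \code{neg_corrected}. Removal counts are appended to the
#'   \code{"provenance"} attribute.
#' @export
compute_fret <- function(ds, bleedthrough = 0, direct = 0,
                         gamma = 1, beta = 1) {
  stopifnot(is.data.frame(ds),
            all(c("i_donor", "i_acceptor") %in% names(ds)),
            bleedthrough >= 0, direct >= 0, gamma > 0, beta > 0)
  aex <- if ("i_acceptor_aex" %in% names(ds)) ds$i_acceptor_aex else 0
  f_a <- ds$i_acceptor - bleedthrough * ds$i_donor - direct * aex
  total <- gamma * ds$i_donor + f_a
  keep <- total != 0
  dropped <- sum(!keep)
  out <- ds[keep, , drop = FALSE]
  f_a <- f_a[keep]
  total <- total[keep]
  out$efficiency <- f_a / total
  out$neg_corrected <- f_a < 0
  if ("i_acceptor_aex" %in% names(ds)) {
    aex <- out$i_acceptor_aex
    out$stoichiometry <- total / (total + aex / beta)
  }
  prov <- attr(ds, "provenance")
  prov <- rbind(prov, data.frame(rule = "zero_total_intensity",
                                 removed = dropped))
  attr(out, "provenance") <- prov
  attr(out, "scenario") <- attr(ds, "scenario")
  out
}

#' Filter trajectory tables
#'
#' Applies, in order: (1) overlap removal — observations with a same-frame
#' neighbor from another track closer than \code{neighbor_radius} are
#' discarded (both partners, since neither intensity is trustworthy); (2)
#' efficiency / stoichiometry window filters; (3) minimum track length.
#' Per-rule removal counts are recorded in the \code{"provenance"}
#' attribute.
#'
#' @param ds Trajectory \code{data.frame}.
#' @param min_length Minimum observations per track (default 5).
#' @param efficiency_range Two-element numeric window for \code{efficiency}
#'   (default \code{c(-0.5, 1.5)}); \code{NULL} disables the rule.
#' @param stoichiometry_range Window for \code{stoichiometry} when that
#'   column exists; \code{NULL} (default) disables the rule.
#' @param neighbor_radius Same-frame proximity radius, um; 0 disables.
#' @return Filtered \code{data.frame} with updated provenance.
#' @export
filter_tracks <- function(ds, min_length = 5,
                          efficiency_range = c(-0.5, 1.5),
                          stoichiometry_range = NULL,
                          neighbor_radius = 0) {
  stopifnot(is.data.frame(ds), min_length >= 1, neighbor_radius >= 0)
  prov <- attr(ds, "provenance")
  log_rule <- function(rule, removed) {
    prov <<- rbind(prov, data.frame(rule = rule, removed = removed))
  }

  if (neighbor_radius > 0 && nrow(ds) > 0) {
    drop <- rep(FALSE, nrow(ds))
    for (fr in split(seq_len(nrow(ds)), ds$frame)) {
      if (length(fr) < 2) next
      d <- as.matrix(stats::dist(cbind(ds$x_um[fr], ds$y_um[fr])))
      diag(d) <- Inf
      # only neighbors from a different track count as overlap
      same <- outer(ds$track_id[fr], ds$track_id[fr], "==")
      d[same] <- Inf
      drop[fr[apply(d < neighbor_radius, 1, any)]] <- TRUE
    }
    log_rule("overlapping_signal", sum(drop))
    ds <- ds[!drop, , drop = FALSE]
  } else {
    log_rule("overlapping_signal", 0L)
  }

  if (!is.null(efficiency_range) && "efficiency" %in% names(ds)) {
    keep <- ds$efficiency >= efficiency_range[1] &
      ds$efficiency <= efficiency_range[2]
    keep[is.na(keep)] <- FALSE
    log_rule("efficiency_window", sum(!keep))
    ds <- ds[keep, , drop = FALSE]
  }
  if (!is.null(stoichiometry_range) && "stoichiometry" %in% names(ds)) {
    keep <- ds$stoichiometry >= stoichiometry_range[1] &
      ds$stoichiometry <= stoichiometry_range[2]
    keep[is.na(keep)] <- FALSE
    log_rule("stoichiometry_window", sum(!keep))
    ds <- ds[keep, , drop = FALSE]
  }

  len <- table(ds$track_id)
  short_ids <- names(len)[len < min_length]
  keep <- !(as.character(ds$track_id) %in% short_ids)
  log_rule("min_track_length", sum(!keep))
  out <- ds[keep, , drop = FALSE]
  attr(out, "provenance") <- prov
  attr(out, "scenario") <- attr(ds, "scenario")
  out
}

# Binary segmentation for downward mean shifts in a 1-D intensity trace.
# Returns the number of accepted downward changepoints. Noise scale is
# estimated robustly from first differences; a split is accepted when it
# reduces the residual sum of squares by more than pen * sigma^2 * log(n).
count_down_changepoints <- function(x, pen = 6, min_seg = 2) {
  n <- length(x)
  if (n < 2 * min_seg) return(NA_integer_)
  sigma <- stats::mad(diff(x)) / sqrt(2)
  sigma <- max(sigma, 1e-8 * max(abs(x), 1))
  penalty <- pen * sigma^2 * log(n)
  cps <- integer(0)
  segments <- list(c(1L, n))
  while (length(segments) > 0) {
    seg <- segments[[1]]
    segments <- segments[-1]
    lo <- seg[1]; hi <- seg[2]
    m <- hi - lo + 1
    if (m < 2 * min_seg) next
    xs <- x[lo:hi]
    best_gain <- -Inf; best_k <- NA_integer_
    sse0 <- sum((xs - mean(xs))^2)
    sumsq <- sum(xs^2)
    csum <- cumsum(xs); tot <- csum[m]
    for (k in min_seg:(m - min_seg)) {
      m1 <- csum[k] / k
      m2 <- (tot - csum[k]) / (m - k)
      sse_after <- sumsq - k * m1^2 - (m - k) * m2^2
      gain <- sse0 - sse_after
      if (gain > best_gain) { best_gain <- gain; best_k <- k }
    }
    if (!is.na(best_k) && best_gain > penalty) {
      k_abs <- lo + best_k - 1L
      left_mean <- mean(x[lo:k_abs])
      right_mean <- mean(x[(k_abs + 1L):hi])
      if (right_mean < left_mean) cps <- c(cps, k_abs)
      segments <- c(segments, list(c(lo, k_abs)), list(c(k_abs + 1L, hi)))
    }
  }
  length(cps)
}

#' Remove multi-emitter tracks by stepwise-bleaching analysis
#'
#' A single emitter bleaches in at most one downward intensity step. Tracks
#' whose summed donor+acceptor intensity trace shows more than one downward
#' changepoint (binary segmentation on mean shifts) are removed as likely
#' multi-emitter signals. Tracks too short for changepoint analysis pass
#' unfiltered and are counted in the provenance log.
#'
#' @param ds Trajectory \code{data.frame} with intensity columns.
#' @param penalty Changepoint acceptance penalty multiplier (on the squared
#'   robust noise scale times \code{log(n)}).
#' @return Filtered \code{data.frame} with provenance entries
#'   \code{multi_emitter} (observations removed) and
#'   \code{too_short_for_changepoint} (observations passed unchecked).
#' @export
single_emitter_filter <- function(ds, penalty = 6) {
  stopifnot(is.data.frame(ds),
            all(c("i_donor", "i_acceptor") %in% names(ds)))
  prov <- attr(ds, "provenance")
  total <- ds$i_donor + ds$i_acceptor
  n_down <- vapply(split(total, ds$track_id), count_down_changepoints,
                   integer(1), pen = penalty)
  too_short_ids <- names(n_down)[is.na(n_down)]
  bad_ids <- names(n_down)[!is.na(n_down) & n_down > 1]
  is_bad <- as.character(ds$track_id) %in% bad_ids
  prov <- rbind(prov,
                data.frame(rule = "multi_emitter", removed = sum(is_bad)),
                data.frame(rule = "too_short_for_changepoint",
                           removed = sum(as.character(ds$track_id) %in%
                                           too_short_ids)))
  out <- ds[!is_bad, , drop = FALSE]
  attr(out, "provenance") <- prov
  attr(out, "scenario") <- attr(ds, "scenario")
  out
}

#' Per-rule removal counts of a filtered dataset
#'
#' @param ds A trajectory \code{data.frame} that has passed through one or
#'   more filters.
#' @return A \code{data.frame} with columns \code{rule} and \code{removed},
#'   or \code{NULL} if no filter has run.
#' @export
provenance_log <- function(ds) attr(ds, "provenance")
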