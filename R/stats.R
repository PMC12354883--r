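# Track-preserving permutation hypothesis tests. Observations within a
# single-molecule track may be correlated, so permutations reassign whole
# tracks between groups, never individual observations.

# One-sided KS statistic D+ = max_x (CDF_A(x) - CDF_B(x)), evaluated at the
# pooled sorted values. 'values' is the pooled sample sorted once; 'weights'
# carries +1/nA for group-A observations and -1/nB for group-B observations
# in that sorted order; 'last_of_tie' marks the last position of each tie
# group (the CDF difference is only well-defined there).
dplus_from_weights <- function(weights, last_of_tie) {
  max(cumsum(weights)[last_of_tie])
}

#' Track-preserving one-sided permutation KS test
#'
#' Tests whether sample A is stochastically smaller than sample B (the
#' default alternative: efficiencies of cell-engaged sensors are shifted
#' down relative to cell-free sensors) using the maximum signed difference
#' of empirical CDFs, \eqn{D^+ = \max_x (F_A(x) - F_B(x))}, as test
#' statistic. The null distribution is obtained by reassigning whole tracks
#' between the two groups, preserving the original group track counts. When
#' the number of distinct assignments \code{choose(nA + nB, nA)} is at most
#' \code{exact_limit}, the permutation distribution is enumerated exactly;
#' otherwise \code{n_resamples} random reassignments are drawn and the
#' add-one (Phipson-Smyth) p-value estimator is used, so Monte-Carlo
#' p-values are never zero.
#'
#' @param tracks_a,tracks_b Lists of numeric vectors, one vector per track.
#' @param n_resamples Number of random permutations when enumeration is not
#'   feasible (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param alternative \code{"less"} (default; A stochastically smaller,
#'   i.e. CDF_A above CDF_B) or \code{"greater"} (the reverse, computed by
#'   swapping the roles of A and B).
#' @param exact_limit Enumerate the null exactly when the number of
#'   distinct track assignments does not exceed this (default 20000).
#' @return A \code{permutation_test} list with \code{statistic} (observed
#'   D+), \code{p_value}, \code{n_resamples} (resamples drawn, or the
#'   number of enumerated assignments), \code{exact} flag, \code{seed},
#'   \code{alternative}.
#' @export
track_permutation_ks <- function(tracks_a, tracks_b, n_resamples = 9999,
                                 seed = 1L, alternative = c("less", "greater"),
                                 exact_limit = 20000) {
  alternative <- match.arg(alternative)
  if (alternative == "greater") {
    res <- track_permutation_ks(tracks_b, tracks_a, n_resamples, seed,
                                "less", exact_limit)
    res$alternative <- "greater"
    return(res)
  }
  stopifnot(is.list(tracks_a), is.list(tracks_b))
  if (length(tracks_a) < 2 || length(tracks_b) < 2)
    stop("each sample needs at least 2 tracks")
  if (n_resamples < 99) stop("'n_resamples' must be >= 99")

  all_tracks <- c(tracks_a, tracks_b)
  nA <- length(tracks_a); nt <- length(all_tracks)
  track_of <- rep(seq_len(nt), lengths(all_tracks))
  pooled <- unlist(all_tracks, use.names = FALSE)
  ord <- order(pooled)
  pooled_s <- pooled[ord]
  track_s <- track_of[ord]
  n <- length(pooled_s)
  last_of_tie <- c(pooled_s[-n] != pooled_s[-1], TRUE)
  n_a_obs <- sum(lengths(tracks_a))
  n_b_obs <- n - n_a_obs
  if (n_a_obs == 0 || n_b_obs == 0) stop("both samples need observations")

  stat_for <- function(a_track_ids) {
    in_a <- track_s %in% a_track_ids
    na_o <- sum(in_a)
    nb_o <- n - na_o
    if (na_o == 0 || nb_o == 0) return(NA_real_)
    w <- ifelse(in_a, 1 / na_o, -1 / nb_o)
    dplus_from_weights(w, last_of_tie)
  }
  observed <- stat_for(seq_len(nA))

  n_assign <- choose(nt, nA)
  if (n_assign <= exact_limit) {
    combos <- utils::combn(nt, nA)
    stats_null <- apply(combos, 2, stat_for)
    stats_null <- stats_null[!is.na(stats_null)]
    p <- mean(stats_null >= observed - 1e-12)
    return(structure(list(statistic = observed, p_value = p,
                          n_resamples = length(stats_null), exact = TRUE,
                          seed = seed, alternative = alternative),
                     class = "permutation_test"))
  }
  if (nt < 3) stop("too few tracks for distinct permutations")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 5))
  count <- 0L
  for (i in seq_len(n_resamples)) {
    s <- stat_for(sample.int(nt, nA))
    if (!is.na(s) && s >= observed - 1e-12) count <- count + 1L
  }
  p <- (1 + count) / (1 + n_resamples)
  structure(list(statistic = observed, p_value = p,
                 n_resamples = n_resamples, exact = FALSE,
                 seed = seed, alternative = alternative),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("Track-preserving one-sided permutation KS test\n")
  cat(sprintf("  D+ = %.4f, p = %.4g (%s, %d %s)\n", x$statistic, x$p_value,
              if (x$exact) "exact enumeration" else "Monte Carlo",
              x$n_resamples,
              if (x$exact) "assignments" else "resamples"))
  cat(sprintf("  alternative: sample A stochastically %s; stars: %s\n",
              if (x$alternative == "less") "smaller" else "greater",
              significance_stars(x$p_value)))
  invisible(x)
}

#' Significance stars
#'
#' Maps a p-value to the conventional star annotation: \code{***} below
#' 0.001, \code{**} below 0.01, \code{*} below 0.05, otherwise \code{ns}.
#'
#' @param p P-value.
#' @return Character annotation.
#' @export
significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Difference of empirical CDFs on a shared grid
#'
#' Evaluates \code{CDF_A - CDF_B} at the supplied grid (default: pooled
#' sorted unique values). The maximum of the curve equals the D+ statistic
#' of \code{\link{track_permutation_ks}} on the same data.
#'
#' @param sample_a,sample_b Numeric samples (pooled observations).
#' @param grid Evaluation points; default pooled sorted unique values.
#' @return A \code{data.frame} with columns \code{x} and \code{cdf_diff},
#'   the latter bounded in [-1, 1].
#' @export
cdf_difference_curve <- function(sample_a, sample_b, grid = NULL) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  if (is.null(grid)) grid <- sort(unique(c(sample_a, sample_b)))
  fa <- stats::ecdf(sample_a)
  fb <- stats::ecdf(sample_b)
  data.frame(x = grid, cdf_diff = fa(grid) - fb(grid))
}
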