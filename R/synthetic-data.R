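# Synthetic single-molecule trajectory generator. Emulates the statistical
# structure the downstream analysis assumes: a Gaussian zero-force FRET
# efficiency peak, a force-bearing (immobilized) subpopulation shifted by the
# calibration map, Brownian vs. static motion, geometric track lengths, and
# binding events terminated by either unbinding or photobleaching.

#' Zero-force FRET emission model
#'
#' @param mu0 Mean FRET efficiency of force-free (collapsed) sensors.
#'   Default 0.865.
#' @param sigma0 Standard deviation of the per-observation efficiency noise.
#'   Default 0.164. The noise is Gaussian and force-independent: sensors
#'   under load emit from a normal with the same width centred on the
#'   calibration efficiency of the applied force.
#' @param total_intensity Mean summed donor+acceptor photon count per
#'   observation (log-normal across observations).
#' @param intensity_noise Relative standard deviation of the total intensity.
#' @return An \code{emission_model} list.
#' @export
emission_model <- function(mu0 = 0.865, sigma0 = 0.164,
                           total_intensity = 2000, intensity_noise = 0.2) {
  stopifnot(mu0 > 0, mu0 < 1, sigma0 > 0, total_intensity > 0,
            intensity_noise >= 0)
  structure(list(mu0 = mu0, sigma0 = sigma0,
                 total_intensity = total_intensity,
                 intensity_noise = intensity_noise),
            class = "emission_model")
}

#' Lateral motion model for synthetic tracks
#'
#' @param D_mobile Diffusion coefficient of freely diffusing sensors on a
#'   fluid bilayer, um^2/s. Default 0.7.
#' @param immobile_jitter Localization noise of immobilized sensors, um
#'   (standard deviation per coordinate). Default 0.02.
#' @param frame_interval Time between frames, s. Default 0.1.
#' @return A \code{motion_model} list.
#' @export
motion_model <- function(D_mobile = 0.7, immobile_jitter = 0.02,
                         frame_interval = 0.1) {
  stopifnot(D_mobile > 0, immobile_jitter >= 0, frame_interval > 0)
  structure(list(D_mobile = D_mobile, immobile_jitter = immobile_jitter,
                 frame_interval = frame_interval),
            class = "motion_model")
}

#' Scenario for a synthetic force dataset
#'
#' Describes one experimental condition: how many tracks, how long they
#' live, which fraction is immobilized (anchored, e.g. TCR-bound) and which
#' fraction of those bears force. Mobile sensors cannot bear force, so
#' \code{phi_force <= phi_immobile} is required.
#'
#' @param n_tracks Number of tracks to simulate.
#' @param mean_track_length Mean of the geometric track-length law
#'   (lengths are geometric conditioned on >= \code{min_track_length}),
#'   in observations.
#' @param min_track_length Minimum track length, observations.
#' @param phi_force Fraction of tracks under force (in [0, 1]).
#' @param force_pN Force applied to the force-bearing subpopulation, pN.
#' @param phi_immobile Fraction of immobilized tracks (in [0, 1]).
#' @param cell_present Logical flag recorded in the \code{cell_contact}
#'   column; cell-free ("no-cell") scenarios use \code{FALSE}.
#' @param seed Integer random seed recorded in the output metadata.
#' @return A \code{synthetic_scenario} list.
#' @export
synthetic_scenario <- function(n_tracks = 300, mean_track_length = 8,
                               min_track_length = 1,
                               phi_force = 0, force_pN = 0,
                               phi_immobile = 0, cell_present = TRUE,
                               seed = 1L) {
  stopifnot(n_tracks >= 1, mean_track_length >= min_track_length,
            min_track_length >= 1,
            phi_force >= 0, phi_force <= 1,
            phi_immobile >= 0, phi_immobile <= 1)
  if (phi_force > phi_immobile)
    stop("invalid scenario: phi_force > phi_immobile ",
         "(mobile sensors cannot bear force)")
  structure(list(n_tracks = as.integer(n_tracks),
                 mean_track_length = mean_track_length,
                 min_track_length = as.integer(min_track_length),
                 phi_force = phi_force, force_pN = force_pN,
                 phi_immobile = phi_immobile,
                 cell_present = isTRUE(cell_present),
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Scenario for synthetic binding-event lifetimes
#'
#' @param tau_bond Characteristic bond lifetime, s (exponential unbinding).
#' @param p_bleach_per_frame Per-frame photobleaching probability in [0, 1).
#' @param recording_intervals Strictly positive, distinct frame intervals, s.
#' @param n_events_per_interval Events to simulate for each interval.
#' @param seed Integer random seed.
#' @return A \code{lifetime_scenario} list.
#' @export
lifetime_scenario <- function(tau_bond = 10,
                              p_bleach_per_frame = 0.2,
                              recording_intervals = c(0.5, 1, 2, 4, 8),
                              n_events_per_interval = 1000,
                              seed = 1L) {
  stopifnot(tau_bond > 0, p_bleach_per_frame >= 0, p_bleach_per_frame < 1,
            length(recording_intervals) >= 1,
            all(recording_intervals > 0),
            !anyDuplicated(recording_intervals),
            n_events_per_interval >= 1)
  structure(list(tau_bond = tau_bond,
                 p_bleach_per_frame = p_bleach_per_frame,
                 recording_intervals = as.numeric(recording_intervals),
                 n_events_per_interval = as.integer(n_events_per_interval),
                 seed = as.integer(seed)),
            class = "lifetime_scenario")
}

# Deterministically derive independent stream seeds from a scenario seed.
# Kept below 2^31 - 1 so they remain valid R integers.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 9973) %% 2147483629
}

# Geometric track lengths conditioned on >= min_len. The geometric choice is
# a stand-in for the (unpublished) photobleaching-limited length law.
sample_track_lengths <- function(n, mean_len, min_len) {
  if (mean_len <= min_len) return(rep(min_len, n))
  p <- 1 / (mean_len - min_len + 1)
  min_len + stats::rgeom(n, p)
}

#' Generate a synthetic single-molecule force dataset
#'
#' Simulates trajectory tables with the structure the analysis pipeline
#' consumes. Mobile tracks perform free Brownian motion with diffusion
#' coefficient \code{motion$D_mobile}; immobilized tracks sit at a fixed
#' position plus localization jitter. Force-free tracks draw efficiencies
#' from \code{Normal(mu0, sigma0)}; force-bearing tracks (always
#' immobilized) draw from \code{Normal(E(force_pN), sigma0)} where
#' \code{E(.)} is the calibration map. Donor/acceptor intensities are a
#' binomial split of a log-normal total consistent with the efficiency.
#' Ground-truth force and mobility labels are carried per observation.
#'
#' @param scenario A \code{\link{synthetic_scenario}}.
#' @param emission An \code{\link{emission_model}}.
#' @param motion A \code{\link{motion_model}}.
#' @param calib A \code{\link{sensor_calibration}}.
#' @return A \code{data.frame} with columns \code{track_id}, \code{frame},
#'   \code{time_s}, \code{x_um}, \code{y_um}, \code{i_donor},
#'   \code{i_acceptor}, \code{efficiency}, \code{cell_contact},
#'   \code{truth_force_pN}, \code{truth_mobile}; the scenario is attached
#'   as attribute \code{"scenario"}.
#' @export
generate_force_dataset <- function(scenario = synthetic_scenario(),
                                   emission = emission_model(),
                                   motion = motion_model(),
                                   calib = sensor_calibration()) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(emission, "emission_model"),
            inherits(motion, "motion_model"),
            inherits(calib, "sensor_calibration"))
  withr_seed <- derive_seed(scenario$seed, 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)

  nt <- scenario$n_tracks
  lengths <- sample_track_lengths(nt, scenario$mean_track_length,
                                  scenario$min_track_length)
  # label assignment: first draw immobilized, then force among immobilized
  immobile <- stats::runif(nt) < scenario$phi_immobile
  force <- rep(FALSE, nt)
  idx_imm <- which(immobile)
  if (scenario$phi_force > 0 && length(idx_imm) > 0) {
    p_force_given_imm <- min(1, scenario$phi_force / scenario$phi_immobile)
    force[idx_imm] <- stats::runif(length(idx_imm)) < p_force_given_imm
  }
  E_force <- if (scenario$force_pN > 0)
    efficiency_from_force(scenario$force_pN, calib) else emission$mu0

  dt <- motion$frame_interval
  sd_step <- sqrt(2 * motion$D_mobile * dt)
  per_track <- vector("list", nt)
  for (i in seq_len(nt)) {
    len <- lengths[i]
    origin <- stats::runif(2, 0, 20)  # field of view 20 x 20 um
    if (immobile[i]) {
      x <- origin[1] + stats::rnorm(len, 0, motion$immobile_jitter)
      y <- origin[2] + stats::rnorm(len, 0, motion$immobile_jitter)
    } else {
      x <- origin[1] + c(0, cumsum(stats::rnorm(len - 1, 0, sd_step)))
      y <- origin[2] + c(0, cumsum(stats::rnorm(len - 1, 0, sd_step)))
    }
    mu <- if (force[i]) E_force else emission$mu0
    eff <- stats::rnorm(len, mu, emission$sigma0)
    total <- stats::rlnorm(len,
                           log(emission$total_intensity) -
                             0.5 * log(1 + emission$intensity_noise^2),
                           sqrt(log(1 + emission$intensity_noise^2)))
    p_acc <- pmin(pmax(eff, 0.001), 0.999)
    i_acc <- stats::rbinom(len, round(total), p_acc)
    per_track[[i]] <- data.frame(
      track_id = i,
      frame = seq_len(len),
      time_s = (seq_len(len) - 1) * dt,
      x_um = x, y_um = y,
      i_donor = round(total) - i_acc,
      i_acceptor = i_acc,
      efficiency = eff,
      cell_contact = scenario$cell_present,
      truth_force_pN = if (force[i]) scenario$force_pN else 0,
      truth_mobile = !immobile[i]
    )
  }
  out <- do.call(rbind, per_track)
  rownames(out) <- NULL
  attr(out, "scenario") <- scenario
  out
}

#' Generate synthetic binding-event durations
#'
#' Each binding event lives until the earlier of unbinding (exponential with
#' mean \code{tau_bond}, discretized upward to whole frames) and
#' photobleaching (geometric over frames with per-frame probability
#' \code{p_bleach_per_frame}). The observed duration in frames is the
#' minimum of the two, with a floor of one frame.
#'
#' @param scenario A \code{\link{lifetime_scenario}}.
#' @return A \code{data.frame} with columns \code{interval_s} and
#'   \code{duration_frames}; the scenario is attached as attribute
#'   \code{"scenario"}.
#' @export
generate_lifetime_dataset <- function(scenario = lifetime_scenario()) {
  stopifnot(inherits(scenario, "lifetime_scenario"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(scenario$seed, 2))
  out <- lapply(scenario$recording_intervals, function(dt) {
    n <- scenario$n_events_per_interval
    frames_bond <- pmax(1L, ceiling(stats::rexp(n, 1 / scenario$tau_bond) / dt))
    if (scenario$p_bleach_per_frame > 0) {
      frames_bleach <- stats::rgeom(n, scenario$p_bleach_per_frame) + 1L
      frames <- pmin(frames_bond, frames_bleach)
    } else {
      frames <- frames_bond
    }
    data.frame(interval_s = dt, duration_frames = as.integer(frames))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "scenario") <- scenario
  out
}

#' Write / read trajectory tables
#'
#' Trajectory tables are stored as plain tab-separated text with a JSON
#' sidecar (\code{<path>.json}) holding the generating scenario, if one is
#' attached.
#'
#' @param ds Trajectory \code{data.frame} as produced by
#'   \code{\link{generate_force_dataset}}.
#' @param path Output file path.
#' @return \code{write_trajectories} returns \code{path} invisibly;
#'   \code{read_trajectories} returns the \code{data.frame}.
#' @export
write_trajectories <- function(ds, path) {
  utils::write.table(ds, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sc <- attr(ds, "scenario")
  if (!is.null(sc)) {
    jsonlite::write_json(unclass(sc), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  ds <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(ds, "scenario") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ds
}

# Save/restore the global RNG state so generators are pure functions of
# their scenario seed and never perturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
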