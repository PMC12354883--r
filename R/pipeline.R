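# Pipeline orchestration: a declarative run configuration with every
# analysis parameter visible, staged execution with serialized
# intermediates, and numeric QC gates mirroring the evaluation criteria a
# force-sensor experiment must pass before entering a pooled database.

#' Default run configuration
#'
#' All tunable parameters of the pipeline in one nested list, pre-filled
#' with the standard values: false-positive rate \code{f = 0.05}, ASH range
#' -0.5..1.5 with 40 shifts, fit window above 0.75, scaling anchor 0.87,
#' reduced-radius threshold 0.35 um s^-0.5, minimum track length 5, 1000
#' bootstrap resamples, 9999 permutation resamples. The configuration can
#' be written to and read from YAML and is embedded verbatim in every
#' result bundle.
#'
#' @param seed Master seed; all random streams derive from it.
#' @return A nested list of class \code{run_config}.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    calibration = list(a = 0.0122, b = 0.044, c = 2.4, n = 29, R0 = 5.1),
    emission = list(mu0 = 0.865, sigma0 = 0.164,
                    total_intensity = 2000, intensity_noise = 0.2),
    motion = list(D_mobile = 0.7, immobile_jitter = 0.02,
                  frame_interval = 0.1),
    scenario = list(n_tracks = 300, mean_track_length = 8,
                    min_track_length = 1, phi_force = 0.1, force_pN = 9,
                    phi_immobile = 0.3, cell_present = TRUE),
    no_cell_scenario = list(n_tracks = 300, mean_track_length = 8,
                            min_track_length = 1, phi_force = 0,
                            force_pN = 0, phi_immobile = 0,
                            cell_present = FALSE),
    filters = list(min_length = 5, efficiency_lo = -0.5,
                   efficiency_hi = 1.5, neighbor_radius = 0.8),
    analysis = list(f = 0.05, ash_range_lo = -0.5, ash_range_hi = 1.5,
                    ash_shifts = 40, fit_window_lo = 0.75, anchor_E = 0.87,
                    mass_floor = 1e-3, n_boot = 1000, n_resamples = 9999,
                    reduced_radius_threshold = 0.35, min_observations = 5),
    lifetime = list(tau_bond = 10, p_bleach_per_frame = 0.2,
                    recording_intervals = c(0.5, 1, 2, 4, 8),
                    n_events_per_interval = 1000),
    qc = list(no_cell_fraction_abs_max = 0.03,
              positive_control_fraction_min = 0.03,
              mobile_fraction_min = 0.5)
  ), class = "run_config")
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @param config A \code{run_config} list.
#' @return \code{load_config} returns a \code{run_config} (missing keys are
#'   filled from \code{\link{default_config}}); \code{save_config} returns
#'   \code{path} invisibly.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- unclass(default_config())
  merge_lists <- function(base, user) {
    for (k in names(user)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
        merge_lists(base[[k]], user[[k]]) else user[[k]]
    }
    base
  }
  structure(merge_lists(base, user), class = "run_config")
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_calibration <- function(config) {
  do.call(sensor_calibration, config$calibration)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, force, mobility, test and lifetime stages
#' in order on synthetic data described by the configuration, writing each
#' stage's output under \code{out_dir} (trajectory tables as TSV, results
#' as JSON). Identical config and seed give identical outputs. With
#' \code{resume = TRUE}, stages whose outputs already exist are reloaded
#' instead of recomputed.
#'
#' @param config A \code{run_config}; see \code{\link{default_config}}.
#' @param out_dir Output directory (created if missing).
#' @param resume Reuse existing stage outputs (default \code{FALSE}).
#' @return Invisibly, the result bundle list (also written to
#'   \code{results.json}): threshold, high-force fraction with bootstrap,
#'   force PDF summary, mobility fractions, permutation-test result,
#'   lifetime fit, per-stage provenance, and the embedded config.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("smforce_run_"),
                         resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_file <- function(name) file.path(out_dir, name)
  calib <- config_calibration(config)
  emission <- do.call(emission_model, config$emission)
  motion <- do.call(motion_model, config$motion)

  run_stage <- function(name, fun) {
    path <- stage_file(paste0(name, ".tsv"))
    if (resume && file.exists(path)) return(read_trajectories(path))
    ds <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    write_trajectories(ds, path)
    ds
  }

  # --- simulate -------------------------------------------------------
  cell_raw <- run_stage("simulated_cell", function() {
    sc <- do.call(synthetic_scenario,
                  c(config$scenario, list(seed = derive_seed(config$seed, 11))))
    generate_force_dataset(sc, emission, motion, calib)
  })
  nocell_raw <- run_stage("simulated_no_cell", function() {
    sc <- do.call(synthetic_scenario,
                  c(config$no_cell_scenario,
                    list(seed = derive_seed(config$seed, 12))))
    generate_force_dataset(sc, emission, motion, calib)
  })

  # --- preprocess -----------------------------------------------------
  fl <- config$filters
  prep <- function(ds) {
    filter_tracks(ds, min_length = fl$min_length,
                  efficiency_range = c(fl$efficiency_lo, fl$efficiency_hi),
                  neighbor_radius = fl$neighbor_radius)
  }
  cell <- run_stage("filtered_cell", function() prep(cell_raw))
  nocell <- run_stage("filtered_no_cell", function() prep(nocell_raw))
  if (nrow(cell) == 0 || nrow(nocell) == 0)
    stop("stage 'preprocess' failed: filtering removed all observations",
         call. = FALSE)

  an <- config$analysis
  # --- force analysis -------------------------------------------------
  threshold <- compute_threshold(nocell$efficiency, f = an$f)
  frac <- bootstrap_fraction(cell$efficiency, cell$track_id, threshold,
                             n_boot = an$n_boot,
                             seed = derive_seed(config$seed, 13))
  fpdf <- estimate_force_pdf(cell$efficiency, nocell$efficiency, calib,
                             anchor_E = an$anchor_E,
                             fit_window_lo = an$fit_window_lo,
                             range_lo = an$ash_range_lo,
                             range_hi = an$ash_range_hi,
                             n_shifts = an$ash_shifts,
                             mass_floor = an$mass_floor)

  # --- mobility -------------------------------------------------------
  labels <- classify_mobility(cell,
                              reduced_radius_threshold =
                                an$reduced_radius_threshold,
                              min_observations = an$min_observations)
  utils::write.table(labels, stage_file("mobility_labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  bound <- bound_fraction(labels, n_boot = an$n_boot,
                          seed = derive_seed(config$seed, 14))
  nocell_labels <- classify_mobility(nocell,
                                     reduced_radius_threshold =
                                       an$reduced_radius_threshold,
                                     min_observations = an$min_observations)
  nocell_mobile <- {
    cl <- nocell_labels$label[nocell_labels$label != "too_short"]
    if (length(cl)) mean(cl == "mobile") else NA_real_
  }

  # --- hypothesis test ------------------------------------------------
  ks <- track_permutation_ks(split(cell$efficiency, cell$track_id),
                             split(nocell$efficiency, nocell$track_id),
                             n_resamples = an$n_resamples,
                             seed = derive_seed(config$seed, 15))

  # --- lifetime -------------------------------------------------------
  lt_sc <- do.call(lifetime_scenario,
                   c(config$lifetime, list(seed = derive_seed(config$seed, 16))))
  lt_events <- generate_lifetime_dataset(lt_sc)
  utils::write.table(lt_events, stage_file("lifetime_events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  lt_fit <- fit_lifetimes(lt_events)

  results <- list(
    config = unclass(config),
    threshold = list(q_f = threshold$q_f, f = threshold$f, n = threshold$n),
    high_force = list(fraction_point = frac$fraction_point,
                      n_low = frac$n_low, n_total = frac$n_total,
                      bootstrap = frac$bootstrap),
    force_pdf = list(detected = fpdf$detected,
                     s_width = fpdf$s_width, s_height = fpdf$s_height,
                     residual_mass = fpdf$residual_mass,
                     quartiles_pN = if (fpdf$detected)
                       as.list(fpdf$quartiles) else NULL,
                     force_grid = fpdf$force, density = fpdf$density),
    mobility = list(bound_fraction = bound$fraction,
                    n_immobilized = bound$n_immobilized,
                    n_classified = bound$n_classified,
                    n_too_short = bound$n_too_short,
                    bootstrap = bound$bootstrap,
                    no_cell_mobile_fraction = nocell_mobile),
    ks_test = list(statistic = ks$statistic, p_value = ks$p_value,
                   exact = ks$exact, n_resamples = ks$n_resamples,
                   stars = significance_stars(ks$p_value)),
    lifetime = list(tau_bond_s = lt_fit$tau_bond,
                    tau_bond_se = lt_fit$tau_bond_se,
                    k_bleach_per_frame = lt_fit$k_bleach,
                    identifiable = lt_fit$identifiable,
                    curve = lt_fit$curve),
    provenance = list(cell = provenance_log(cell),
                      no_cell = provenance_log(nocell))
  )
  jsonlite::write_json(results, stage_file("results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null")
  invisible(results)
}

#' Evaluate QC gates on a result bundle
#'
#' Applies the configured numeric gates: the no-cell control must show no
#' high-force excess, a positive control must respond, and fluid-bilayer
#' (mobile) datasets must show the expected mobility. A gate whose metric
#' is missing from the bundle is reported as not evaluable and flags the
#' run.
#'
#' @param results Result bundle from \code{\link{run_pipeline}}, or a
#'   named list of metrics (\code{no_cell_fraction},
#'   \code{positive_control_fraction}, \code{mobile_fraction}).
#' @param gates Named list of gate values (defaults from
#'   \code{default_config()$qc}).
#' @return A \code{qc_report} data.frame with one row per gate: \code{gate},
#'   \code{metric}, \code{threshold}, \code{verdict} (\code{"pass"},
#'   \code{"fail"} or \code{"not_evaluable"}); attribute \code{"ok"} is
#'   TRUE only if every gate passed.
#' @export
qc_evaluate <- function(results, gates = default_config()$qc) {
  metric <- function(name) {
    if (!is.null(results[[name]])) return(results[[name]])
    switch(name,
           no_cell_fraction = NULL,
           positive_control_fraction =
             if (!is.null(results$high_force))
               results$high_force$fraction_point else NULL,
           mobile_fraction =
             if (!is.null(results$mobility))
               results$mobility$no_cell_mobile_fraction else NULL)
  }
  rows <- list()
  add <- function(gate, value, threshold, pass) {
    verdict <- if (is.null(value) || is.na(value)) "not_evaluable"
      else if (pass) "pass" else "fail"
    rows[[length(rows) + 1]] <<- data.frame(
      gate = gate, metric = if (is.null(value)) NA_real_ else value,
      threshold = threshold, verdict = verdict)
  }
  v <- metric("no_cell_fraction")
  add("no_cell_force_absence", v, gates$no_cell_fraction_abs_max,
      !is.null(v) && !is.na(v) && abs(v) < gates$no_cell_fraction_abs_max)
  v <- metric("positive_control_fraction")
  add("positive_control_responds", v, gates$positive_control_fraction_min,
      !is.null(v) && !is.na(v) && v > gates$positive_control_fraction_min)
  v <- metric("mobile_fraction")
  add("mobile_bilayer_mobility", v, gates$mobile_fraction_min,
      !is.null(v) && !is.na(v) && v > gates$mobile_fraction_min)
  rep <- do.call(rbind, rows)
  attr(rep, "ok") <- all(rep$verdict == "pass")
  class(rep) <- c("qc_report", class(rep))
  rep
}
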