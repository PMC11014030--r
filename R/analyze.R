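#' Default pipeline configuration
#'
#' All tunable parameters of the recording-to-metrics pipeline with their
#' defaults: 3-50 Hz Hamming FIR acquisition band (60 dB target, Harris tap
#' rule), kappa = 100 artifact threshold with 1000 ms expansion, 0.65-3.5 Hz
#' heart-rate band with unit combination weights, 600 ms RMS envelope,
#' trough association window -350 to -100 ms, 450 ms pruning distance,
#' -200/+300 ms motif windows with 400 ms motifs, and the three
#' cardiac-phase integration windows. Override any entry by passing a
#' modified copy to [scg_analyze()].
#'
#' @return Nested named list of parameters, classed `scg_config`.
#' @export
scg_config <- function() {
  structure(list(
    filter = list(f_lo = 3, f_hi = 50, attenuation_db = 60,
                  transition_width = 1),
    artifact = list(kappa = 100, expand_ms = 1000),
    beats = list(lambda_lin = 1, lambda_rot = 1, f_lo = 0.65, f_hi = 3.5,
                 transition_width = 0.3, envelope_ms = 600,
                 trough_window_ms = c(-350, -100), min_dist_ms = 450,
                 min_prominence = 0, window_ms = c(-200, 300),
                 motif_len_ms = 400, motif_threshold_k = 3),
    metrics = list(windows = phase_windows()),
    quality = list(max_gap_ms = 250, min_clean_fraction = 0.5)),
    class = "scg_config")
}

#' Full recording-to-metrics analysis
#'
#' Runs the complete ECG-free pipeline on one recording: resampling to a
#' uniform grid, band-pass filtering of all six channels, velocity
#' integration, linear and rotational kinetic energy, movement-artifact
#' masking (union of both channels), low-frequency profile and candidate
#' scoring, matrix-profile motif confirmation, and per-record median
#' kinetic-energy metrics.
#'
#' @param rec An [inertial_recording()].
#' @param config Pipeline parameters, see [scg_config()].
#' @return Object of class `scg_analysis` bundling the intermediate signals
#'   (`ke`, `profile`), the `beats`, the per-beat table (`per_beat`), the
#'   record metrics (`metrics`), quality flags and the resolved `config`.
#' @examples
#' \donttest{
#' sim <- simulate_recording(sim_config(duration = 60, seed = 1))
#' fit <- scg_analyze(sim$recording)
#' fit
#' }
#' @export
scg_analyze <- function(rec, config = scg_config()) {
  stopifnot(inherits(rec, "inertial_recording"))
  rec <- regularize(rec, max_gap_ms = config$quality$max_gap_ms)
  fs <- rec$nominal_fs
  spec <- design_bandpass(fs, config$filter$f_lo, config$filter$f_hi,
                          config$filter$attenuation_db,
                          config$filter$transition_width)
  acc_f <- apply_bandpass(rec$acc, spec)
  gyr_f <- apply_bandpass(rec$gyr, spec)
  v <- integrate_velocity(acc_f, fs, spec)
  ke <- kinetic_energy(v, gyr_f, rec$device, fs)
  mask <- combine_masks(
    detect_artifacts(ke$ke_lin, fs, config$artifact$kappa,
                     config$artifact$expand_ms),
    detect_artifacts(ke$ke_rot, fs, config$artifact$kappa,
                     config$artifact$expand_ms))
  ke <- set_artifact_mask(ke, mask)
  profile <- lowfreq_profile(ke, config$beats$lambda_lin,
                             config$beats$lambda_rot, config$beats$f_lo,
                             config$beats$f_hi,
                             config$beats$transition_width,
                             envelope_ms = config$beats$envelope_ms)
  cands <- find_candidates(profile, config$beats$min_prominence)
  scored <- score_candidates(cands, profile, config$beats$trough_window_ms)
  pruned <- prune_peaks(scored, config$beats$min_dist_ms)
  beats <- confirm_beats(pruned, profile, config$beats$window_ms,
                         config$beats$motif_len_ms,
                         config$beats$motif_threshold_k)
  per_beat <- beat_metrics(ke, beats)
  metrics <- record_metrics(per_beat, beats, ke)
  structure(
    list(record_id = rec$record_id, subject_id = rec$subject_id,
         usable = isTRUE(attr(rec, "usable")),
         low_quality = ke$clean_fraction < config$quality$min_clean_fraction,
         fs = fs, ke = ke, profile = profile, beats = beats,
         per_beat = per_beat, metrics = metrics, config = config,
         version = as.character(utils::packageVersion("scgkinetics"))),
    class = "scg_analysis")
}

#' @export
print.scg_analysis <- function(x, ...) {
  cat(sprintf("<scg_analysis> %s/%s\n", x$subject_id, x$record_id))
  print(x$metrics)
  if (!x$usable) cat("  WARNING: record flagged unusable (timestamp gap)\n")
  if (x$low_quality) cat("  WARNING: clean fraction below threshold\n")
  invisible(x)
}

#' @export
summary.scg_analysis <- function(object, ...) {
  cat(sprintf("Record %s/%s at %g Hz\n", object$subject_id,
              object$record_id, object$fs))
  cat(sprintf("  clean fraction      %.3f\n", object$ke$clean_fraction))
  cat(sprintf("  candidates/rejected %d/%d\n", object$beats$n_candidates,
              object$beats$n_rejected))
  cat(sprintf("  beats (valid)       %d (%d)\n",
              length(object$beats$reference_points),
              object$metrics$n_valid_beats))
  cat(sprintf("  HR                  %.1f bpm\n", object$beats$hr_bpm))
  cat(sprintf("  iK_Sys              %.4g nJ s\n", object$metrics$ik_sys))
  cat(sprintf("  iK_Late dia         %.4g nJ s\n",
              object$metrics$ik_late_dia))
  cat(sprintf("  iK_Early dia        %.4g nJ s\n",
              object$metrics$ik_early_dia))
  invisible(object)
}

#' Diagnostic plot of an analysed recording
#'
#' Two panels: linear kinetic energy with artifact spans shaded and beat
#' reference points marked, and the low-frequency profile with its RMS
#' envelope.
#'
#' @param x An `scg_analysis`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.scg_analysis <- function(x, ...) {
  t <- (seq_along(x$ke$ke_lin) - 1) / x$fs
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  graphics::plot(t, x$ke$ke_lin * 1e9, type = "l", xlab = "time (s)",
                 ylab = "KE lin (nJ)", main = x$record_id, ...)
  if (any(x$ke$artifact_mask)) {
    r <- rle(x$ke$artifact_mask)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values))
      graphics::rect(t[starts[k]], graphics::par("usr")[3L], t[ends[k]],
                     graphics::par("usr")[4L],
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
  }
  graphics::abline(v = x$beats$reference_points, col = "steelblue",
                   lty = 3)
  graphics::plot(t, x$profile$slf, type = "l", xlab = "time (s)",
                 ylab = "S_lf (IQR units)")
  graphics::lines(t, x$profile$elf, col = "darkorange")
  graphics::abline(v = x$beats$reference_points, col = "steelblue",
                   lty = 3)
  invisible(x)
}
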