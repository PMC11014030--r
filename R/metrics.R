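#' Time integral of kinetic energy over a cardiac-phase window
#'
#' Trapezoidal integral of the linear kinetic energy over
#' `[ref + a, ref + b)` seconds, with the half-open window mapped to the
#' sample grid as `floor((ref + a) * fs) .. floor((ref + b) * fs)` (the
#' trapezoid runs over the `floor((b - a) * fs)` sample intervals between
#' those indices, so a constant signal integrates to exactly
#' `value * (b - a)`). Reported in nJ s.
#'
#' @param ke_lin Numeric vector of linear kinetic energy in joules.
#' @param fs Sampling rate, Hz.
#' @param ref Reference time, s.
#' @param window Length-2 numeric, window in ms relative to `ref`
#'   (e.g. `c(-100, 100)`).
#' @return Integral in nJ s, or `NA` when the window leaves the record.
#' @examples
#' integrate_phase(rep(1e-8, 100), 100, 0.5, c(-100, 100))  # 2 nJ s
#' @export
integrate_phase <- function(ke_lin, fs, ref, window) {
  i0 <- floor((ref + window[1L] / 1000) * fs)
  i1 <- floor((ref + window[2L] / 1000) * fs)
  if (i0 < 0 || i1 > length(ke_lin) - 1L || i1 <= i0) return(NA_real_)
  idx <- (i0:i1) + 1L
  trapz_reg(ke_lin[idx], 1 / fs) * 1e9
}

phase_windows <- function() {
  list(ik_sys = c(-100, 100), ik_late_dia = c(-300, -100),
       ik_early_dia = c(100, 300))
}

#' Per-beat kinetic-energy phase integrals
#'
#' For each reference point, integrates the linear kinetic energy over the
#' three cardiac-phase windows: systolic `(-100, +100)` ms, late-diastolic
#' `(-300, -100)` ms and early-diastolic `(+100, +300)` ms. A beat is valid
#' only when all three windows lie wholly inside the record and contain no
#' artifact-masked sample.
#'
#' @param ke A `ke_signals` object.
#' @param beats A `beat_set`.
#' @return Data frame with columns `ref_time`, `ik_sys`, `ik_late_dia`,
#'   `ik_early_dia` (nJ s) and `valid`.
#' @export
beat_metrics <- function(ke, beats) {
  stopifnot(inherits(ke, "ke_signals"), inherits(beats, "beat_set"))
  if (!length(beats$reference_points))
    stop("empty beat set", call. = FALSE)
  wins <- phase_windows()
  fs <- ke$fs
  n <- length(ke$ke_lin)
  out <- data.frame(ref_time = beats$reference_points,
                    ik_sys = NA_real_, ik_late_dia = NA_real_,
                    ik_early_dia = NA_real_, valid = FALSE)
  for (r in seq_len(nrow(out))) {
    ref <- out$ref_time[r]
    ok <- TRUE
    for (w in wins) {
      i0 <- floor((ref + w[1L] / 1000) * fs)
      i1 <- floor((ref + w[2L] / 1000) * fs)
      if (i0 < 0 || i1 > n - 1L ||
          any(ke$artifact_mask[(i0:i1) + 1L])) { ok <- FALSE; break }
    }
    for (nm in names(wins))
      out[[nm]][r] <- integrate_phase(ke$ke_lin, fs, ref, wins[[nm]])
    out$valid[r] <- ok && !anyNA(out[r, names(wins)])
  }
  out
}

#' Reduce per-beat metrics to per-record medians
#'
#' The record-level iK_Sys, iK_Late dia and iK_Early dia are the medians of
#' the corresponding per-beat integrals over valid beats only, which makes
#' them robust to the occasional mis-segmented beat. Heart rate is carried
#' over from the beat set.
#'
#' @param per_beat Data frame from [beat_metrics()].
#' @param beats The `beat_set`.
#' @param ke The `ke_signals` (for the clean fraction).
#' @return Object of class `record_metrics`: `ik_sys`, `ik_late_dia`,
#'   `ik_early_dia` (nJ s), `hr_bpm`, `n_valid_beats`, `clean_fraction`.
#' @export
record_metrics <- function(per_beat, beats, ke) {
  v <- per_beat[per_beat$valid, , drop = FALSE]
  if (!nrow(v))
    stop("no valid beats: record metrics undefined", call. = FALSE)
  structure(
    list(ik_sys = stats::median(v$ik_sys),
         ik_late_dia = stats::median(v$ik_late_dia),
         ik_early_dia = stats::median(v$ik_early_dia),
         hr_bpm = beats$hr_bpm,
         n_valid_beats = nrow(v),
         clean_fraction = ke$clean_fraction),
    class = "record_metrics")
}

#' @export
print.record_metrics <- function(x, ...) {
  cat(sprintf(paste0("<record_metrics> iK_Sys %.3g, iK_Late dia %.3g, ",
                     "iK_Early dia %.3g nJ s; HR %.1f bpm ",
                     "(%d valid beats, clean %.2f)\n"),
              x$ik_sys, x$ik_late_dia, x$ik_early_dia, x$hr_bpm,
              x$n_valid_beats, x$clean_fraction))
  invisible(x)
}
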