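#' Default beat template: Gaussian-windowed sinusoid atoms
#'
#' Each heartbeat injects, per axis, a sum of Gabor atoms. An atom is
#' parameterized in velocity space as
#' \eqn{v(t) = (A/\omega)\, e^{-t^2 / 2\sigma^2} \sin(\omega t)} so that the
#' emitted acceleration is its exact analytic derivative and the true
#' sensor velocity — hence the true kinetic energy and its phase
#' integrals — is known in closed form. `amp` (m/s^2) is the approximate
#' peak acceleration, `freq` (Hz) the carrier and `sigma` (s) the Gaussian
#' half-width. Defaults place the dominant atom on the dorsoventral z axis
#' at 16 Hz, well inside the 3-50 Hz acquisition band.
#'
#' @return Data frame with columns `axis` (1 = x, 2 = y, 3 = z), `amp`,
#'   `freq`, `sigma`.
#' @export
beat_template <- function() {
  data.frame(axis = c(1L, 2L, 3L),
             amp = c(0.03, 0.04, 0.10),
             freq = c(12, 14, 16),
             sigma = c(0.050, 0.045, 0.040))
}

# Velocity (m/s) of one atom at times t (relative to the beat centre).
atom_velocity <- function(t, amp, freq, sigma) {
  w <- 2 * pi * freq
  (amp / w) * exp(-t^2 / (2 * sigma^2)) * sin(w * t)
}

# Exact acceleration (m/s^2): time-derivative of atom_velocity.
atom_acceleration <- function(t, amp, freq, sigma) {
  w <- 2 * pi * freq
  (amp / w) * exp(-t^2 / (2 * sigma^2)) *
    (w * cos(w * t) - (t / sigma^2) * sin(w * t))
}

#' Simulation configuration
#'
#' Parameters of the synthetic 6-DOF chest-vibration generator, defaulting
#' to the acquisition conditions of the telemonitoring protocol it
#' emulates: 100 Hz sampling, 3-minute supine records, normal breathing
#' (amplitude modulation at 0.25 Hz), resting heart rate with mild
#' beat-to-beat variability, accelerometer-grade white noise, and
#' occasional high-amplitude movement bursts.
#'
#' @param fs Sampling rate, Hz (default 100; must exceed twice the highest
#'   template frequency).
#' @param duration Record length, s (default 180).
#' @param hr_bpm Mean heart rate, bpm, in \[30, 220\] (default 60).
#' @param hrv_cv Coefficient of variation of the interbeat intervals
#'   (lognormal jitter; default 0.03).
#' @param template Beat template data frame (default [beat_template()]).
#' @param noise_rms White-noise RMS per acceleration axis, m/s^2
#'   (default 0.005).
#' @param artifact_rate Movement bursts per minute (default 0).
#' @param artifact_gain Burst amplitude as a multiple of the dominant
#'   template amplitude (default 50).
#' @param respiration_mod Fractional beat-amplitude modulation at 0.25 Hz
#'   (default 0.1).
#' @param gyr_scale Angular-velocity template scale, rad/s per m/s of the
#'   velocity template (default 50, giving gyrocardiography-typical peak
#'   angular rates of a few hundredths of rad/s).
#' @param gyr_noise_rms Gyroscope white-noise RMS, rad/s; default
#'   `0.1 * noise_rms`, matching the noise-density ratio of MEMS
#'   accelerometer/gyroscope pairs.
#' @param baseline_amp Per-axis amplitude (m/s) of the continuous
#'   micro-vibration floor: three fixed tones at `baseline_freqs`
#'   emulating the in-band physiological background (muscle activity,
#'   residual motion) that real chest recordings always carry between
#'   beats. Default 1.5e-4, roughly 18 dB below the cardiac velocity peak.
#'   Set to 0 for a strictly beat-only record.
#' @param baseline_freqs Tone frequencies per axis, Hz (default 18, 20,
#'   22 — chosen so no rectification product of floor and template falls
#'   into the heart-rate band).
#' @param seed Mandatory RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(fs = 100, duration = 180, hr_bpm = 60,
                       hrv_cv = 0.03, template = beat_template(),
                       noise_rms = 0.005, artifact_rate = 0,
                       artifact_gain = 50, respiration_mod = 0.1,
                       gyr_scale = 50, gyr_noise_rms = NULL,
                       baseline_amp = 1.5e-4,
                       baseline_freqs = c(18, 20, 22), seed = 1) {
  if (fs <= 2 * max(template$freq))
    stop("`fs` must exceed twice the highest template frequency",
         call. = FALSE)
  if (hr_bpm < 30 || hr_bpm > 220)
    stop("`hr_bpm` must lie in [30, 220]", call. = FALSE)
  if (hrv_cv < 0 || noise_rms < 0 || artifact_rate < 0)
    stop("rates and noise levels must be non-negative", call. = FALSE)
  if (is.null(gyr_noise_rms)) gyr_noise_rms <- 0.1 * noise_rms
  structure(list(fs = fs, duration = duration, hr_bpm = hr_bpm,
                 hrv_cv = hrv_cv, template = template,
                 noise_rms = noise_rms, artifact_rate = artifact_rate,
                 artifact_gain = artifact_gain,
                 respiration_mod = respiration_mod, gyr_scale = gyr_scale,
                 gyr_noise_rms = gyr_noise_rms,
                 baseline_amp = baseline_amp,
                 baseline_freqs = baseline_freqs, seed = seed),
            class = "sim_config")
}

# Analytic per-beat phase integrals of the linear KE of the template
# (numerical quadrature of the closed-form velocity, independent of any
# sampled signal). Returns nJ s per window for a unit-amplitude beat.
template_phase_integrals <- function(template, device,
                                     windows = phase_windows(),
                                     gyr_scale = 2) {
  vel2 <- function(t) {
    tot <- 0
    for (ax in 1:3) {
      at <- template[template$axis == ax, , drop = FALSE]
      if (!nrow(at)) next
      v <- 0
      for (r in seq_len(nrow(at)))
        v <- v + atom_velocity(t, at$amp[r], at$freq[r], at$sigma[r])
      tot <- tot + v^2
    }
    tot
  }
  vapply(windows, function(w) {
    f <- stats::integrate(function(t) 0.5 * device$mass * vel2(t),
                          w[1L] / 1000, w[2L] / 1000,
                          subdivisions = 2000L, rel.tol = 1e-10)
    f$value * 1e9
  }, 0)
}

# RMS of the clean template acceleration over one mean beat period,
# pooled over axes; used to set noise levels for a requested SNR.
template_acc_rms <- function(cfg) {
  ibi <- 60 / cfg$hr_bpm
  tt <- seq(-ibi / 2, ibi / 2, by = 1e-4)
  p <- 0
  for (ax in 1:3) {
    at <- cfg$template[cfg$template$axis == ax, , drop = FALSE]
    if (!nrow(at)) next
    a <- 0
    for (r in seq_len(nrow(at)))
      a <- a + atom_acceleration(tt, at$amp[r], at$freq[r], at$sigma[r])
    p <- p + mean(a^2)
  }
  sqrt(p / 3)
}

#' Noise level for a target in-band signal-to-noise ratio
#'
#' Returns the per-axis white-noise RMS that puts the clean template
#' acceleration at `snr_db` decibels above the noise,
#' `noise_rms = rms_clean / 10^(snr_db / 20)`.
#'
#' @param cfg A `sim_config`.
#' @param snr_db Target SNR in dB.
#' @return Noise RMS in m/s^2.
#' @export
noise_for_snr <- function(cfg, snr_db) {
  template_acc_rms(cfg) / 10^(snr_db / 20)
}

#' Simulate a 6-DOF chest-vibration recording with ground truth
#'
#' Beats are laid down at lognormally jittered interbeat intervals (CV =
#' `hrv_cv`); each beat adds the multi-axis template to the acceleration
#' channels and a scaled copy of the template velocity to the gyroscope
#' channels, with its amplitude modulated by respiration at 0.25 Hz. White
#' noise is added per channel, and movement artifacts are injected as
#' high-amplitude 0.5 s bursts at Poisson-distributed times. The RNG draw
#' order is fixed (interbeat intervals, then acceleration noise, then
#' gyroscope noise, then artifact count, times and phases), so any draw can
#' be reproduced independently from the same seed. The returned ground
#' truth carries the beat times, true heart rate, artifact spans and the
#' analytic per-beat phase integrals.
#'
#' @param cfg A [sim_config()].
#' @param device A [sensor_model()] (default smartphone preset).
#' @return List with `recording` (an [inertial_recording()]) and
#'   `ground_truth` (fields `beat_times`, `true_hr_bpm`, `artifact_spans`,
#'   `beat_integrals`, `amp_scale`).
#' @export
simulate_recording <- function(cfg, device = sensor_preset("smartphone")) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$fs; dur <- cfg$duration
  n <- as.integer(round(dur * fs))
  tgrid <- (seq_len(n) - 1L) / fs
  mean_ibi <- 60 / cfg$hr_bpm
  n_max <- as.integer(ceiling(dur / mean_ibi * 1.5)) + 10L
  out <- with_seed(cfg$seed, {
    ibis <- if (cfg$hrv_cv > 0) {
      s2 <- log(1 + cfg$hrv_cv^2)
      stats::rlnorm(n_max, log(mean_ibi) - s2 / 2, sqrt(s2))
    } else rep(mean_ibi, n_max)
    acc_noise <- matrix(stats::rnorm(3L * n, 0, cfg$noise_rms), n, 3L)
    gyr_noise <- matrix(stats::rnorm(3L * n, 0, cfg$gyr_noise_rms), n, 3L)
    n_art <- stats::rpois(1L, cfg$artifact_rate * dur / 60)
    art_t <- if (n_art > 0) sort(stats::runif(n_art, 0.5, dur - 1)) else numeric(0)
    art_ph <- if (n_art > 0) stats::runif(n_art, 0, 2 * pi) else numeric(0)
    list(ibis = ibis, acc_noise = acc_noise, gyr_noise = gyr_noise,
         art_t = art_t, art_ph = art_ph)
  })
  beat_times <- cumsum(c(0.5 * out$ibis[1L], out$ibis[-1L]))
  beat_times <- beat_times[beat_times <= dur - 0.5]
  amp_scale <- 1 + cfg$respiration_mod * sin(2 * pi * 0.25 * beat_times)
  acc <- out$acc_noise
  gyr <- out$gyr_noise
  # continuous micro-vibration floor: fixed-phase velocity tones per axis
  if (cfg$baseline_amp > 0) {
    for (ax in 1:3) {
      wt <- 2 * pi * cfg$baseline_freqs[ax]
      acc[, ax] <- acc[, ax] + cfg$baseline_amp * wt * cos(wt * tgrid)
      gyr[, ax] <- gyr[, ax] + cfg$gyr_scale * cfg$baseline_amp *
        sin(wt * tgrid)
    }
  }
  tpl <- cfg$template
  support <- 5 * max(tpl$sigma)
  for (bi in seq_along(beat_times)) {
    tb <- beat_times[bi]
    k0 <- max(1L, as.integer(floor((tb - support) * fs)) + 1L)
    k1 <- min(n, as.integer(ceiling((tb + support) * fs)) + 1L)
    trel <- tgrid[k0:k1] - tb
    for (r in seq_len(nrow(tpl))) {
      ax <- tpl$axis[r]
      acc[k0:k1, ax] <- acc[k0:k1, ax] + amp_scale[bi] *
        atom_acceleration(trel, tpl$amp[r], tpl$freq[r], tpl$sigma[r])
      gyr[k0:k1, ax] <- gyr[k0:k1, ax] + amp_scale[bi] * cfg$gyr_scale *
        atom_velocity(trel, tpl$amp[r], tpl$freq[r], tpl$sigma[r])
    }
  }
  art_spans <- NULL
  amp_burst <- cfg$artifact_gain * max(tpl$amp)
  for (ai in seq_along(out$art_t)) {
    ta <- out$art_t[ai]
    k0 <- as.integer(floor(ta * fs)) + 1L
    k1 <- min(n, k0 + as.integer(0.5 * fs))
    tb <- tgrid[k0:k1] - ta
    burst <- amp_burst * sin(pi * tb / 0.5)^2 *
      sin(2 * pi * 7 * tb + out$art_ph[ai])
    for (ax in 1:3) {
      acc[k0:k1, ax] <- acc[k0:k1, ax] + burst
      gyr[k0:k1, ax] <- gyr[k0:k1, ax] + cfg$gyr_scale * burst / (2 * pi * 7)
    }
    art_spans <- rbind(art_spans, c(ta, ta + 0.5))
  }
  base_int <- template_phase_integrals(tpl, device, gyr_scale = cfg$gyr_scale)
  beat_integrals <- outer(amp_scale^2, base_int)
  colnames(beat_integrals) <- names(phase_windows())
  rec <- inertial_recording(tgrid, acc, gyr, fs, device,
                            subject_id = "sim",
                            record_id = sprintf("sim-seed%d", cfg$seed))
  list(recording = rec,
       ground_truth = list(beat_times = beat_times,
                           true_hr_bpm = 60 / mean(diff(beat_times)),
                           artifact_spans = art_spans,
                           beat_integrals = beat_integrals,
                           amp_scale = amp_scale))
}

#' Simulate paired session measurements with a target ICC
#'
#' Draws `y_ij = mu + p_i + e_ij` with subject effects
#' `var(p) = target_icc * var_total` and residuals
#' `var(e) = (1 - target_icc) * var_total`, so the population
#' absolute-agreement ICC equals `target_icc` exactly.
#'
#' @param n Subjects (>= 2).
#' @param k Sessions.
#' @param target_icc Target ICC in \[0, 1).
#' @param grand_mean Grand mean (default 10).
#' @param var_total Total variance (default 1).
#' @param seed RNG seed.
#' @return n x k matrix with attributes `var_subject` and `var_error`.
#' @export
simulate_paired_metrics <- function(n, k = 2, target_icc = 0.8,
                                    grand_mean = 10, var_total = 1,
                                    seed = 1) {
  if (target_icc < 0 || target_icc >= 1)
    stop("`target_icc` must lie in [0, 1)", call. = FALSE)
  if (n < 2L) stop("need n >= 2 subjects", call. = FALSE)
  vp <- target_icc * var_total
  ve <- (1 - target_icc) * var_total
  M <- with_seed(seed, {
    p <- stats::rnorm(n, 0, sqrt(vp))
    e <- matrix(stats::rnorm(n * k, 0, sqrt(ve)), n, k)
    grand_mean + p + e
  })
  attr(M, "var_subject") <- vp
  attr(M, "var_error") <- ve
  M
}

#' Simulate an at-home compliance table
#'
#' One row per patient: an age sampled uniformly within its band and a
#' completed-recording count drawn from a truncated normal (rejection
#' sampling on \[0, 100\] percent) around the band's mean compliance and
#' rounded. Defaults emulate the telemonitoring study design: 138 patients
#' asked to record three times a week for three months (36 expected
#' recordings each, 4968 in total), with band means chosen so the expected
#' pooled compliance is about 41%.
#'
#' @param n_per_band Patients per age band `<46`, `46-75`, `>75`
#'   (default `c(34, 90, 14)`).
#' @param mean_pct_per_band Mean compliance percentage per band
#'   (default `c(29.3, 48.3, 26.3)`).
#' @param sd_pct Compliance standard deviation, percentage points
#'   (default 15).
#' @param expected_per_patient Expected recordings per patient
#'   (default 36).
#' @param seed RNG seed.
#' @return A `compliance_table` data frame.
#' @export
simulate_compliance <- function(n_per_band = c(34, 90, 14),
                                mean_pct_per_band = c(29.3, 48.3, 26.3),
                                sd_pct = 15, expected_per_patient = 36,
                                seed = 1) {
  if (any(mean_pct_per_band < 0 | mean_pct_per_band > 100))
    stop("band means must lie in [0, 100] percent", call. = FALSE)
  age_lo <- c(18, 46, 76); age_hi <- c(45, 75, 92)
  with_seed(seed, {
    rows <- lapply(1:3, function(b) {
      nb <- n_per_band[b]
      if (nb == 0L) return(NULL)
      age <- floor(stats::runif(nb, age_lo[b], age_hi[b] + 1))
      pct <- numeric(nb)
      for (i in seq_len(nb)) {
        repeat {
          v <- stats::rnorm(1L, mean_pct_per_band[b], sd_pct)
          if (sd_pct == 0 || (v >= 0 && v <= 100)) { pct[i] <- v; break }
        }
      }
      data.frame(age = age, expected_count = expected_per_patient,
                 completed_count = round(expected_per_patient * pct / 100))
    })
    read_compliance(do.call(rbind, rows))
  })
}
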