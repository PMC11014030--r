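#' Integrate band-limited acceleration to velocity
#'
#' Cumulative trapezoidal integration per axis with zero initial condition,
#' followed by re-application of the same band-pass to remove the slow drift
#' that numerical integration introduces. Because the acceleration is
#' already band-limited, any drift is out of band by construction and the
#' second filtering pass leaves the cardiac content untouched.
#'
#' @param acc_filtered N x 3 matrix of band-passed acceleration (m/s^2).
#' @param fs Sampling rate, Hz.
#' @param spec The `fir_spec` used to band-pass the acceleration.
#' @return N x 3 matrix of velocity (m/s).
#' @export
integrate_velocity <- function(acc_filtered, fs, spec) {
  acc_filtered <- as.matrix(acc_filtered)
  v <- acc_filtered
  h <- 1 / fs
  for (j in seq_len(ncol(v)))
    v[, j] <- pracma::cumtrapz(acc_filtered[, j]) * h
  apply_bandpass(v, spec)
}

#' Linear and rotational kinetic-energy signals
#'
#' Per-sample Newtonian kinetic energy of the sensor:
#' \deqn{KE_{lin} = \tfrac{1}{2} m (v_x^2 + v_y^2 + v_z^2), \quad
#'       KE_{rot} = \tfrac{1}{2} (I_{xx}\omega_x^2 + I_{yy}\omega_y^2 +
#'       I_{zz}\omega_z^2)}
#' both in joules and non-negative by construction. The artifact mask starts
#' empty; see [detect_artifacts()].
#'
#' @param v N x 3 velocity matrix (m/s).
#' @param gyr_filtered N x 3 band-passed angular velocity (rad/s).
#' @param device A [sensor_model()].
#' @param fs Sampling rate, Hz.
#' @return An object of class `ke_signals` with fields `ke_lin`, `ke_rot`
#'   (J), `fs`, `artifact_mask`, `clean_fraction`.
#' @export
kinetic_energy <- function(v, gyr_filtered, device, fs) {
  v <- as.matrix(v); gyr_filtered <- as.matrix(gyr_filtered)
  stopifnot(inherits(device, "sensor_model"))
  if (nrow(v) != nrow(gyr_filtered))
    stop("velocity and angular velocity must have equal length",
         call. = FALSE)
  ke_lin <- 0.5 * device$mass * rowSums(v^2)
  Id <- device$inertia_diag
  ke_rot <- 0.5 * (Id[1L] * gyr_filtered[, 1L]^2 +
                   Id[2L] * gyr_filtered[, 2L]^2 +
                   Id[3L] * gyr_filtered[, 3L]^2)
  structure(
    list(ke_lin = as.numeric(ke_lin), ke_rot = as.numeric(ke_rot), fs = fs,
         artifact_mask = rep(FALSE, nrow(v)), clean_fraction = 1),
    class = "ke_signals")
}

#' @export
print.ke_signals <- function(x, ...) {
  cat(sprintf("<ke_signals> %d samples at %g Hz, clean fraction %.3f\n",
              length(x$ke_lin), x$fs, x$clean_fraction))
  invisible(x)
}

#' Movement-artifact detection on a kinetic-energy signal
#'
#' Samples are flagged where the energy exceeds the robust threshold
#' \eqn{\tau = \mathrm{median}(KE) + \kappa \cdot \mathrm{IQR}(KE)} with
#' \eqn{\kappa = 100} by default; every flagged run is then dilated by
#' `expand_ms` on both sides so that filter ringing around a movement burst
#' is excluded as well. For a strictly constant signal the IQR is zero and
#' no sample is strictly above the median, so the mask is empty.
#'
#' @param ke Non-negative numeric vector (J).
#' @param fs Sampling rate, Hz.
#' @param kappa Threshold multiplier (default 100).
#' @param expand_ms Dilation half-width in ms (default 1000).
#' @return Logical mask, `TRUE` = contaminated.
#' @export
detect_artifacts <- function(ke, fs, kappa = 100, expand_ms = 1000) {
  if (any(ke < 0)) stop("kinetic energy must be non-negative", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  tau <- stats::median(ke) + kappa * iqr7(ke)
  dilate_mask(ke > tau, as.integer(round(expand_ms / 1000 * fs)))
}

#' Combine artifact masks from linear and rotational energy
#'
#' Element-wise union: a sample is contaminated if either energy channel
#' flags it.
#'
#' @param mask_lin,mask_rot Logical vectors of equal length.
#' @return Logical vector.
#' @export
combine_masks <- function(mask_lin, mask_rot) {
  if (length(mask_lin) != length(mask_rot))
    stop("mask length mismatch", call. = FALSE)
  mask_lin | mask_rot
}

# Attach a combined artifact mask to a ke_signals object.
set_artifact_mask <- function(ke, mask) {
  stopifnot(inherits(ke, "ke_signals"), length(mask) == length(ke$ke_lin))
  ke$artifact_mask <- mask
  ke$clean_fraction <- 1 - mean(mask)
  ke
}
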