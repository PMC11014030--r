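#' Inertial sensor model
#'
#' Mass and principal moments of inertia of the recording device. These enter
#' the kinetic-energy equations \eqn{KE_{lin} = \frac{1}{2} m (v_x^2 + v_y^2
#' + v_z^2)} and \eqn{KE_{rot} = \frac{1}{2}(I_{xx}\omega_x^2 +
#' I_{yy}\omega_y^2 + I_{zz}\omega_z^2)} as multiplicative constants, so they
#' rescale the reported metrics but do not affect beat detection.
#'
#' @param mass Device mass in kg (> 0).
#' @param inertia_diag Length-3 numeric, principal moments of inertia
#'   (Ixx, Iyy, Izz) in kg m^2, all > 0.
#' @param label Free-text device label.
#' @return An object of class `sensor_model`.
#' @examples
#' sensor_model(0.1, c(1e-4, 1e-4, 2e-4), "demo")
#' @export
sensor_model <- function(mass, inertia_diag, label = "custom") {
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("`mass` must be a single positive number (kg)", call. = FALSE)
  if (!is.numeric(inertia_diag) || length(inertia_diag) != 3L ||
      any(!is.finite(inertia_diag)) || any(inertia_diag <= 0))
    stop("`inertia_diag` must be three positive numbers (kg m^2)",
         call. = FALSE)
  structure(
    list(mass = mass,
         inertia_diag = c(Ixx = inertia_diag[1L], Iyy = inertia_diag[2L],
                          Izz = inertia_diag[3L]),
         label = as.character(label)[1L]),
    class = "sensor_model")
}

# Inertia of a uniform cuboid of mass m and edge lengths (a, b, c) in metres,
# about its principal axes.
cuboid_inertia <- function(mass, dims) {
  a <- dims[1L]; b <- dims[2L]; d <- dims[3L]
  mass / 12 * c(b^2 + d^2, a^2 + d^2, a^2 + b^2)
}

#' Built-in sensor profiles
#'
#' Two configurable device profiles: `"smartphone"` (148 g handset modelled
#' as a uniform 138.4 x 67.3 x 7.3 mm cuboid) and `"wearable"` (20 g chest
#' sensor, scaled cuboid). These are conveniences only; any
#' [sensor_model()] can be supplied wherever a device is needed.
#'
#' @param profile `"smartphone"` or `"wearable"`.
#' @return A `sensor_model`.
#' @examples
#' sensor_preset("smartphone")
#' @export
sensor_preset <- function(profile = c("smartphone", "wearable")) {
  profile <- match.arg(profile)
  if (profile == "smartphone") {
    dims <- c(0.1384, 0.0673, 0.0073)
    sensor_model(0.148, cuboid_inertia(0.148, dims), "smartphone")
  } else {
    dims <- c(0.040, 0.030, 0.010)
    sensor_model(0.020, cuboid_inertia(0.020, dims), "wearable")
  }
}

#' @export
print.sensor_model <- function(x, ...) {
  cat(sprintf("<sensor_model> %s: mass %.4g kg, I = (%.3g, %.3g, %.3g) kg m^2\n",
              x$label, x$mass, x$inertia_diag[1L], x$inertia_diag[2L],
              x$inertia_diag[3L]))
  invisible(x)
}
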