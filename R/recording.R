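#' Construct and validate an inertial recording
#'
#' A 6-degree-of-freedom chest-vibration record: per-sample timestamps,
#' 3-axis linear acceleration and 3-axis angular velocity. Axis convention
#' follows the standard seismocardiography nomenclature: x mediolateral,
#' y head-foot, z dorsoventral.
#'
#' @param timestamps Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param acc N x 3 numeric matrix of linear acceleration (m/s^2), columns
#'   x, y, z.
#' @param gyr N x 3 numeric matrix of angular velocity (rad/s), columns
#'   x, y, z.
#' @param nominal_fs Nominal sampling rate in Hz.
#' @param device A [sensor_model()].
#' @param subject_id,record_id Opaque labels.
#' @return An object of class `inertial_recording`.
#' @examples
#' t <- seq(0, 11.99, by = 0.01)
#' rec <- inertial_recording(t, matrix(0, length(t), 3),
#'                           matrix(0, length(t), 3), 100)
#' rec
#' @export
inertial_recording <- function(timestamps, acc, gyr, nominal_fs,
                               device = sensor_preset("smartphone"),
                               subject_id = "anon", record_id = "rec") {
  timestamps <- as.numeric(timestamps)
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  n <- length(timestamps)
  if (ncol(acc) != 3L || ncol(gyr) != 3L)
    stop("`acc` and `gyr` must have 3 columns (x, y, z)", call. = FALSE)
  if (nrow(acc) != n || nrow(gyr) != n)
    stop("`acc` and `gyr` must have one row per timestamp", call. = FALSE)
  if (!is.numeric(nominal_fs) || length(nominal_fs) != 1L || nominal_fs <= 0)
    stop("`nominal_fs` must be a single positive number (Hz)", call. = FALSE)
  stopifnot_finite(timestamps, "timestamps")
  stopifnot_finite(acc, "acc")
  stopifnot_finite(gyr, "gyr")
  dt <- diff(timestamps)
  bad <- which(dt <= 0)
  if (length(bad))
    stop(sprintf("timestamps not strictly increasing: first violation at index %d",
                 bad[1L] + 1L), call. = FALSE)
  if (n >= 3L) {
    med_dt <- stats::median(dt)
    if (abs(med_dt - 1 / nominal_fs) > 0.2 / nominal_fs)
      stop(sprintf(paste0("median sampling interval %.5f s is more than 20%% away ",
                          "from nominal 1/%g s"), med_dt, nominal_fs),
           call. = FALSE)
  }
  colnames(acc) <- colnames(gyr) <- c("x", "y", "z")
  structure(
    list(timestamps = timestamps, acc = acc, gyr = gyr,
         nominal_fs = nominal_fs, device = device,
         subject_id = as.character(subject_id)[1L],
         record_id = as.character(record_id)[1L]),
    class = "inertial_recording")
}

#' @export
print.inertial_recording <- function(x, ...) {
  cat(sprintf("<inertial_recording> %s/%s: %d samples, %.3g s at nominal %g Hz (%s)\n",
              x$subject_id, x$record_id, length(x$timestamps),
              diff(range(x$timestamps)), x$nominal_fs, x$device$label))
  invisible(x)
}

rec_cols <- c("t", "ax", "ay", "az", "gx", "gy", "gz")

# Unit conversion factors to SI. Accepted acceleration units: "m/s^2", "g";
# angular-velocity units: "rad/s", "deg/s".
acc_unit_factor <- function(unit) {
  switch(unit, "m/s^2" = 1, "g" = 9.80665,
         stop(sprintf("unknown acceleration unit '%s'", unit), call. = FALSE))
}
gyr_unit_factor <- function(unit) {
  switch(unit, "rad/s" = 1, "deg/s" = pi / 180,
         stop(sprintf("unknown angular-velocity unit '%s'", unit),
              call. = FALSE))
}

#' Read an inertial recording from disk
#'
#' The canonical on-disk dialect is a CSV with columns
#' `t, ax, ay, az, gx, gy, gz` plus a JSON sidecar (`<path>.json`) holding
#' device metadata, units and identifiers; `schema = "json"` reads a single
#' self-contained JSON document as written by [write_recording()]. Units are
#' taken from the sidecar/header and converted to SI; they are never guessed.
#'
#' @param path File path.
#' @param schema `"csv"` or `"json"`.
#' @return A validated [inertial_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, schema = c("csv", "json")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (schema == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    missing <- setdiff(rec_cols, names(df))
    if (length(missing))
      stop(sprintf("format error: missing column(s) %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    meta_path <- paste0(path, ".json")
    meta <- if (file.exists(meta_path))
      jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
    build_recording_from_parts(df, meta)
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    missing <- setdiff(rec_cols, names(doc$samples))
    if (length(missing))
      stop(sprintf("format error: missing key(s) %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    build_recording_from_parts(as.data.frame(doc$samples), doc$meta)
  }
}

build_recording_from_parts <- function(df, meta) {
  fa <- acc_unit_factor(meta$acc_unit %||% "m/s^2")
  fg <- gyr_unit_factor(meta$gyr_unit %||% "rad/s")
  dev <- if (!is.null(meta$device)) {
    sensor_model(meta$device$mass, unlist(meta$device$inertia_diag),
                 meta$device$label %||% "custom")
  } else sensor_preset("smartphone")
  inertial_recording(
    timestamps = df$t,
    acc = fa * as.matrix(df[, c("ax", "ay", "az")]),
    gyr = fg * as.matrix(df[, c("gx", "gy", "gz")]),
    nominal_fs = meta$nominal_fs %||% round(1 / stats::median(diff(df$t))),
    device = dev,
    subject_id = meta$subject_id %||% "anon",
    record_id = meta$record_id %||% "rec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an inertial recording to disk
#'
#' Writes SI units. `schema = "csv"` produces the canonical CSV plus a
#' `<path>.json` metadata sidecar; `schema = "json"` produces one
#' self-contained JSON document that [read_recording()] round-trips exactly
#' (values serialized at full double precision).
#'
#' @param rec An [inertial_recording()].
#' @param path Output path.
#' @param schema `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, schema = c("csv", "json")) {
  schema <- match.arg(schema)
  stopifnot(inherits(rec, "inertial_recording"))
  df <- data.frame(t = rec$timestamps,
                   ax = rec$acc[, 1L], ay = rec$acc[, 2L], az = rec$acc[, 3L],
                   gx = rec$gyr[, 1L], gy = rec$gyr[, 2L], gz = rec$gyr[, 3L])
  meta <- list(nominal_fs = rec$nominal_fs,
               acc_unit = "m/s^2", gyr_unit = "rad/s",
               subject_id = rec$subject_id, record_id = rec$record_id,
               device = list(mass = rec$device$mass,
                             inertia_diag = as.list(rec$device$inertia_diag),
                             label = rec$device$label))
  if (schema == "csv") {
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    jsonlite::write_json(list(meta = meta, samples = as.list(df)), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Resample a recording onto a uniform grid
#'
#' Smartphone sampling is only nominally uniform; per-sample timestamps
#' carry jitter and occasional gaps. This maps the record onto the regular
#' grid `t0 + k / fs_target` by linear interpolation. Records containing any
#' inter-sample gap above `max_gap_ms` are flagged unusable
#' (interpolating across more than a heartbeat period would fabricate
#' beats); they are still returned for inspection.
#'
#' @param rec An [inertial_recording()].
#' @param fs_target Target sampling rate in Hz; defaults to the record's
#'   nominal rate.
#' @param max_gap_ms Largest tolerated timestamp gap, in ms (default 250).
#' @return An `inertial_recording` with attributes `max_gap_s` (largest gap
#'   seen, seconds) and `usable` (logical).
#' @export
regularize <- function(rec, fs_target = rec$nominal_fs, max_gap_ms = 250) {
  stopifnot(inherits(rec, "inertial_recording"))
  if (fs_target <= 0) stop("`fs_target` must be positive", call. = FALSE)
  span <- rec$timestamps[length(rec$timestamps)] - rec$timestamps[1L]
  if (span < 10)
    stop(sprintf("record too short: %.2f s (need >= 10 s)", span),
         call. = FALSE)
  max_gap <- max(diff(rec$timestamps))
  grid <- rec$timestamps[1L] + seq(0, span, by = 1 / fs_target)
  interp <- function(m) {
    out <- matrix(0, length(grid), 3L)
    for (j in 1:3)
      out[, j] <- stats::approx(rec$timestamps, m[, j], xout = grid,
                                rule = 2)$y
    out
  }
  out <- inertial_recording(grid, interp(rec$acc), interp(rec$gyr),
                            nominal_fs = fs_target, device = rec$device,
                            subject_id = rec$subject_id,
                            record_id = rec$record_id)
  attr(out, "max_gap_s") <- max_gap
  attr(out, "usable") <- max_gap <= max_gap_ms / 1000
  out
}
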