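#' Design a Hamming-window FIR band-pass filter
#'
#' Linear-phase windowed-sinc band-pass. The tap count follows the
#' Fred Harris rule of thumb, `N = ceil((fs / delta_f) * (A / 22))` for a
#' target stop-band attenuation of `A` dB and transition width `delta_f`,
#' incremented to the next odd integer so the group delay is a whole number
#' of samples. With the defaults used for raw seismocardiograms
#' (fs = 100 Hz, 3-50 Hz, 60 dB, 1 Hz transition) this gives 273 taps.
#'
#' @param fs Sampling rate, Hz.
#' @param f_lo,f_hi Pass-band corner frequencies, Hz; must satisfy
#'   `0 < f_lo < f_hi < fs/2`.
#' @param attenuation_db Target stop-band attenuation, dB (default 60).
#' @param transition_width Transition band width, Hz (default 1).
#' @return An object of class `fir_spec` with fields `coefficients`,
#'   `n_taps`, `fs`, `f_lo`, `f_hi`, `attenuation_db`, `transition_width`.
#' @examples
#' spec <- design_bandpass(100, 3, 50)
#' spec$n_taps  # 273
#' @export
design_bandpass <- function(fs, f_lo, f_hi, attenuation_db = 60,
                            transition_width = 1) {
  # the upper cutoff may sit exactly at the Nyquist limit (the usual choice
  # for 100 Hz acquisition), but never beyond it
  if (f_hi > fs / 2)
    stop(sprintf("upper cutoff %g Hz is beyond the Nyquist frequency %g Hz",
                 f_hi, fs / 2), call. = FALSE)
  if (!(f_lo > 0 && f_lo < f_hi)) stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (transition_width <= 0) stop("`transition_width` must be positive",
                                  call. = FALSE)
  n_taps <- as.integer(ceiling((fs / transition_width) *
                                 (attenuation_db / 22)))
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  b <- signal::fir1(n_taps - 1L, c(f_lo, f_hi) / (fs / 2), type = "pass",
                    window = signal::hamming(n_taps), scale = TRUE)
  structure(
    list(coefficients = as.numeric(b), n_taps = n_taps, fs = fs,
         f_lo = f_lo, f_hi = f_hi, attenuation_db = attenuation_db,
         transition_width = transition_width),
    class = "fir_spec")
}

#' @export
print.fir_spec <- function(x, ...) {
  cat(sprintf("<fir_spec> %g-%g Hz band-pass at fs=%g Hz, %d taps (Hamming, %g dB target)\n",
              x$f_lo, x$f_hi, x$fs, x$n_taps, x$attenuation_db))
  invisible(x)
}

# Magnitude response of an FIR at frequencies f (Hz).
fir_response <- function(spec, f) {
  k <- seq_len(spec$n_taps) - 1L
  vapply(f, function(ff)
    Mod(sum(spec$coefficients * exp(-2i * pi * ff * k / spec$fs))), 0)
}

#' Apply an FIR filter with zero net delay
#'
#' Convolves the signal with the linear-phase FIR and compensates the
#' constant group delay of `(n_taps - 1) / 2` samples, so in-band features
#' keep their timing. Edges are reflection-padded before convolution and the
#' output has the same length as the input.
#'
#' @param x Numeric vector (or N x k matrix, filtered column-wise).
#' @param spec A `fir_spec` from [design_bandpass()].
#' @return Filtered signal, same shape as `x`.
#' @export
apply_bandpass <- function(x, spec) {
  stopifnot(inherits(spec, "fir_spec"))
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- apply_bandpass(x[, j], spec)
    return(out)
  }
  n <- length(x)
  if (n <= spec$n_taps)
    stop(sprintf("signal too short for the filter: %d samples <= %d taps",
                 n, spec$n_taps), call. = FALSE)
  gd <- (spec$n_taps - 1L) %/% 2L
  xp <- c(x[(gd + 1L):2L], x, x[(n - 1L):(n - gd)])
  cf <- stats::convolve(xp, rev(spec$coefficients), type = "open")
  cf[(2L * gd + 1L):(2L * gd + n)]
}
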