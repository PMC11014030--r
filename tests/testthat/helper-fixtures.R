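# Shared fixture builders: everything is generated in code at test time.

# A minimal valid recording of `dur` seconds of near-zero signal plus an
# in-band wiggle so nothing degenerates.
make_flat_recording <- function(dur = 12, fs = 100, seed = 1) {
  n <- dur * fs
  t <- (seq_len(n) - 1) / fs
  set.seed(seed)
  acc <- matrix(1e-3 * sin(2 * pi * 5 * t) + 1e-4 * rnorm(n), n, 3)
  gyr <- matrix(1e-3 * cos(2 * pi * 7 * t) + 1e-4 * rnorm(n), n, 3)
  inertial_recording(t, acc, gyr, fs)
}

# Hand-built lf_profile wrapper around an arbitrary signal.
make_profile <- function(slf, fs = 100, mask = rep(FALSE, length(slf)),
                         ske = slf) {
  structure(list(slf = slf, slf_lin = slf, slf_rot = slf, ske = ske,
                 elf = rms_envelope(slf, fs, 600), fs = fs, mask = mask,
                 lambda_lin = 1, lambda_rot = 1),
            class = "lf_profile")
}

# Brute-force z-normalized nearest-neighbour distances between windows:
# literal double loop, independent of the package implementation.
brute_min_dists <- function(W, m) {
  zn <- function(s) {
    sg <- stats::sd(s)
    if (sg > 1e-12) (s - mean(s)) / sg else rep(0, length(s))
  }
  L <- ncol(W); nW <- nrow(W); ns <- L - m + 1
  subs <- list()
  for (i in seq_len(nW))
    subs[[i]] <- lapply(seq_len(ns), function(j) zn(W[i, j:(j + m - 1)]))
  vapply(seq_len(nW), function(i) {
    best <- Inf
    for (oi in seq_len(ns)) for (j in seq_len(nW)) {
      if (j == i) next
      for (oj in seq_len(ns)) {
        d <- sqrt(sum((subs[[i]][[oi]] - subs[[j]][[oj]])^2))
        if (d < best) best <- d
      }
    }
    best
  }, 0)
}
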