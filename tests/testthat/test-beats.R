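make_ke <- function(lin, rot = lin, fs = 100,
                    mask = rep(FALSE, length(lin))) {
  ke <- kinetic_energy(cbind(sqrt(2 * lin / 0.1), 0, 0) / 1,
                       matrix(0, length(lin), 3),
                       sensor_model(0.1, rep(1e-4, 3)), fs)
  ke$ke_lin <- lin; ke$ke_rot <- rot
  ke$artifact_mask <- mask
  ke$clean_fraction <- 1 - mean(mask)
  ke
}

test_that("low-frequency profile combines standardized channels by weight", {
  fs <- 100
  t <- (0:1499) / fs
  lin <- 1e-8 * (1 + sin(2 * pi * 1.2 * t))
  rot <- 2e-9 * (1 + cos(2 * pi * 1.1 * t))
  ke <- make_ke(lin, rot, fs)
  p_lin <- lowfreq_profile(ke, lambda_lin = 1, lambda_rot = 0)
  expect_equal(p_lin$slf, p_lin$slf_lin)
  p <- lowfreq_profile(ke, 1, 1)
  expect_equal(p$slf, (p$slf_lin + p$slf_rot) / 2)
  # standardized components have median 0 and unit IQR on clean samples
  expect_equal(stats::median(p$slf_lin), 0, tolerance = 1e-9)
  expect_equal(stats::quantile(p$slf_lin, 0.75, names = FALSE) -
                 stats::quantile(p$slf_lin, 0.25, names = FALSE), 1,
               tolerance = 1e-9)
  expect_error(lowfreq_profile(make_ke(rep(1e-8, 1500))), "degenerate")
})

test_that("RMS envelope reproduces closed forms", {
  fs <- 100
  expect_equal(rms_envelope(rep(3, 500), fs), rep(3, 500))
  expect_equal(rms_envelope(rep(-2, 500), fs), rep(2, 500))
  expect_equal(rms_envelope(rep(0, 500), fs), rep(0, 500))
  t <- (0:999) / fs
  x <- 2 * sin(2 * pi * 20 * t)   # period 50 ms << 600 ms window
  env <- rms_envelope(x, fs, 600)
  expect_equal(env[100:900], rep(2 / sqrt(2), 801), tolerance = 0.02)
})

test_that("candidate extrema and prominences match analytic expectations", {
  fs <- 100
  t <- (0:999) / fs
  prof <- make_profile(sin(2 * pi * 1.2 * t), fs)
  cands <- find_candidates(prof)
  expect_identical(nrow(cands$peaks), 12L)
  expect_identical(nrow(cands$troughs), 12L)
  # monotone ramp: no interior extrema
  ramp <- make_profile(seq(0, 1, length.out = 500), fs)
  expect_identical(nrow(find_candidates(ramp)$peaks), 0L)
  # unimodal signal: prominence of the global maximum equals its range
  uni <- make_profile(dnorm(t, 5, 1), fs)
  pk <- find_candidates(uni)$peaks
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$prominence, max(uni$slf) - min(uni$slf), tolerance = 1e-6)
  # candidates inside the artifact mask are discarded
  mask <- t >= 2 & t < 4
  masked <- make_profile(sin(2 * pi * 1.2 * t), fs, mask = mask)
  expect_false(any(find_candidates(masked)$peaks$time >= 2 &
                   find_candidates(masked)$peaks$time < 4))
})

test_that("trough association and score combination follow the stated rules", {
  fs <- 100
  n <- 1200
  slf <- rep(0, n)
  # peak at t = 6 s, troughs at -200 ms (in window) and -50 ms (outside)
  slf[601] <- 2
  slf[581] <- -1.5
  slf[596] <- -0.4
  prof <- make_profile(slf, fs)
  prof$elf <- rep(1, n)  # unit envelope -> scores are raw slf values
  cands <- find_candidates(prof)
  sc <- score_candidates(cands, prof)
  main <- sc[sc$index == 601L, ]
  expect_identical(main$trough_index, 581L)
  # sigma = slf/elf + |slf_trough|/elf = 2 + 1.5, times prominence
  expect_equal(main$score, (2 + 1.5) * main$prominence)

  # trough at -50 ms only: not associated
  slf2 <- rep(0, n); slf2[601] <- 2; slf2[596] <- -0.4
  prof2 <- make_profile(slf2, fs); prof2$elf <- rep(1, n)
  sc2 <- score_candidates(find_candidates(prof2), prof2)
  main2 <- sc2[sc2$index == 601L, ]
  expect_true(is.na(main2$trough_index))
  expect_equal(main2$score, 2 * main2$prominence)

  # among several qualifying troughs the deepest normalized one wins
  slf3 <- rep(0, n); slf3[601] <- 2; slf3[581] <- -1; slf3[571] <- -3
  prof3 <- make_profile(slf3, fs); prof3$elf <- rep(1, n)
  sc3 <- score_candidates(find_candidates(prof3), prof3)
  expect_identical(sc3[sc3$index == 601L, ]$trough_index, 571L)
})

test_that("greedy pruning keeps the forced subsets", {
  mk <- function(times_ms, scores)
    data.frame(index = as.integer(times_ms / 10) + 1L,
               time = times_ms / 1000, prominence = 1,
               trough_index = NA_integer_, score = scores)
  # two peaks 300 ms apart: only the higher score survives
  out <- prune_peaks(mk(c(0, 300), c(5, 3)))
  expect_equal(out$time, 0)
  # 500 ms apart: both survive
  expect_identical(nrow(prune_peaks(mk(c(0, 500), c(5, 3)))), 2L)
  # 0/400/800 ms with scores 1/5/1: only the middle survives
  out3 <- prune_peaks(mk(c(0, 400, 800), c(1, 5, 1)))
  expect_equal(out3$time, 0.4)
  # result is invariant to input ordering
  perm <- mk(c(800, 0, 400), c(1, 1, 5))
  expect_equal(prune_peaks(perm)$time, 0.4)
  # all pairwise gaps respect the minimum distance
  set.seed(2)
  rnd <- mk(sort(sample(0:5000, 40)) , runif(40))
  pruned <- prune_peaks(rnd)
  expect_true(all(diff(pruned$time) >= 0.45 - 1e-12))
})

test_that("motif confirmation separates template windows from noise", {
  fs <- 100
  # 22 windows 1 s apart; 20 carry an identical morphology-rich pattern
  n <- 2500
  set.seed(7)
  x <- rnorm(n, 0, 0.02)
  shape <- function(tt) exp(-tt^2 / (2 * 0.05^2)) * sin(2 * pi * 9 * tt) +
    0.6 * exp(-(tt - 0.12)^2 / (2 * 0.03^2))
  centers <- 2:23
  noise_wins <- c(5, 17)
  for (ci in seq_along(centers)) {
    idx <- (centers[ci] * fs - 30):(centers[ci] * fs + 30)
    tt <- (idx - centers[ci] * fs) / fs
    if (ci %in% noise_wins) x[idx + 1] <- rnorm(length(idx), 0, 1)
    else x[idx + 1] <- x[idx + 1] + shape(tt)
  }
  prof <- make_profile(x, fs)
  pruned <- data.frame(index = centers * fs + 1L, time = centers,
                       prominence = 1, trough_index = NA_integer_,
                       score = 1)
  beats <- confirm_beats(pruned, prof, motif_source = "slf")
  expect_identical(length(beats$reference_points), 20L)
  expect_identical(beats$n_rejected, 2L)
  expect_false(any(round(beats$reference_points) %in%
                     centers[noise_wins]))
  # brute-force oracle: the same windows are flagged by a literal
  # double-loop z-normalized distance computation
  a <- -20L; b <- 30L; m <- 41L
  W <- t(vapply(pruned$index + a, function(s) x[s:(s + 50L)], numeric(51)))
  d_or <- brute_min_dists(W, m)
  expect_equal(sort(beats$motif_distance),
               sort(d_or[d_or <= stats::median(d_or) + 3 *
                           (stats::quantile(d_or, .75) -
                              stats::quantile(d_or, .25))]),
               tolerance = 1e-10)
})

test_that("identical windows confirm everywhere with zero motif distance", {
  fs <- 100
  n <- 2000
  x <- rep(0, n)
  shape <- function(tt) sin(2 * pi * 6 * tt) * exp(-tt^2 / (2 * 0.06^2))
  centers <- seq(2, 18, by = 1)
  for (cc in centers) {
    idx <- (cc * fs - 30):(cc * fs + 30)
    x[idx + 1] <- shape((idx - cc * fs) / fs)
  }
  prof <- make_profile(x, fs)
  pruned <- data.frame(index = centers * fs + 1L, time = centers,
                       prominence = 1, trough_index = NA_integer_, score = 1)
  beats <- confirm_beats(pruned, prof, motif_source = "slf")
  expect_identical(length(beats$reference_points), length(centers))
  expect_equal(max(beats$motif_distance), 0, tolerance = 1e-10)
  # reference points sit on the candidate peaks (the motif middles)
  expect_equal(beats$reference_points, centers, tolerance = 1e-9)
  # exactly 1 s spacing -> 60 bpm
  expect_equal(beats$hr_bpm, 60)
  expect_error(confirm_beats(pruned[1:3, ], prof), "insufficient")
})

test_that("pure-noise windows raise a no-motif error", {
  fs <- 100
  set.seed(31)
  x <- rnorm(3000)
  pruned <- data.frame(index = seq(200, 2800, by = 100), time = NA,
                       prominence = 1, trough_index = NA_integer_, score = 1)
  pruned$time <- (pruned$index - 1) / fs
  expect_error(confirm_beats(pruned, make_profile(x, fs)),
               "no repeating heartbeat motif")
})

test_that("heart rate uses the mean-of-intervals convention", {
  bs <- structure(list(reference_points = c(0, 0.9, 2.0),
                       ibis = c(0.9, 1.1), hr_bpm = 60, fs = 100),
                  class = "beat_set")
  est <- estimate_hr(bs)
  expect_equal(est$mean_hr, 60)  # 60 / mean(0.9, 1.1), not mean of rates
  expect_equal(est$ibis, c(0.9, 1.1))
  bs$reference_points <- seq(0, 10, by = 0.5)
  expect_equal(estimate_hr(bs)$mean_hr, 120)
  bs$reference_points <- 1
  expect_error(estimate_hr(bs), "at least 2")
})

test_that("the detector recovers simulated beats and their heart rate", {
  cfg_base <- sim_config(hr_bpm = 75)
  cfg <- sim_config(duration = 120, hr_bpm = 75, hrv_cv = 0.03, seed = 42,
                    noise_rms = noise_for_snr(cfg_base, 10))
  sim <- simulate_recording(cfg)
  fit <- scg_analyze(sim$recording)
  gt <- sim$ground_truth
  ref <- fit$beats$reference_points
  d <- vapply(gt$beat_times, function(b) min(abs(ref - b)), 0)
  fd <- vapply(ref, function(r) min(abs(gt$beat_times - r)), 0)
  expect_gte(mean(d <= 0.05), 0.95)
  expect_lte(mean(fd > 0.05), 0.05)
  expect_lte(abs(fit$beats$hr_bpm - gt$true_hr_bpm), 2)
})

test_that("the pipeline is deterministic and time-shift equivariant", {
  cfg <- sim_config(duration = 60, hr_bpm = 70, hrv_cv = 0.02, seed = 5,
                    noise_rms = 0.002)
  sim <- simulate_recording(cfg)
  f1 <- scg_analyze(sim$recording)
  f2 <- scg_analyze(sim$recording)
  expect_identical(f1$beats$reference_points, f2$beats$reference_points)
  expect_identical(f1$metrics$ik_sys, f2$metrics$ik_sys)

  # shift the record by 2 s: interior reference points shift with it
  rec <- sim$recording
  k <- 200L
  n <- length(rec$timestamps)
  shifted <- inertial_recording(rec$timestamps[1:(n - k)],
                                rec$acc[(k + 1):n, ],
                                rec$gyr[(k + 1):n, ],
                                rec$nominal_fs, rec$device)
  fs_ <- scg_analyze(shifted)
  a <- f1$beats$reference_points - k / 100
  b <- fs_$beats$reference_points
  interior <- a[a > 5 & a < 47]
  matched <- vapply(interior, function(t0) min(abs(b - t0)), 0)
  expect_lt(max(matched), 0.011)
})
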