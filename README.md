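# scgkinetics

Cardiac kinetic-energy metrics from smartphone seismocardiography, without
an ECG.

Seismocardiography (SCG) records the micro-vibrations of the chest wall
caused by the beating heart with an accelerometer; adding a gyroscope gives
the rotational counterpart (gyrocardiography). From a 6-degree-of-freedom
chest recording — 3-axis linear acceleration and 3-axis angular velocity at
a nominal 100 Hz, as produced by a smartphone lying on the sternum or a
chest-worn inertial sensor — this package computes per-record cardiac
kinetic-energy metrics and heart rate with no ECG channel, and provides the
statistical machinery used to validate such metrics in telemonitoring
studies (device agreement and at-home compliance). The intended users are
researchers in cardiac mechanography and biomedical-signal engineers
evaluating smartphone-based cardiac monitoring.

## The method

1. **Filtering.** Raw signals are band-passed 3–50 Hz with a Hamming-window
   linear-phase FIR; the tap count follows the Fred Harris rule
   `N = ceil((fs/Δf)·(A/22))` (273 taps for a 60 dB target with a 1 Hz
   transition at 100 Hz). Group delay is compensated, so filtering has zero
   net delay.
2. **Kinetic energy.** Velocity is obtained by cumulative trapezoidal
   integration of the filtered acceleration (with the same band-pass
   re-applied to suppress integration drift), then

   KE_lin = ½ m (v_x² + v_y² + v_z²),  KE_rot = ½ (I_xx ω_x² + I_yy ω_y² + I_zz ω_z²)

   using the sensor's mass and principal moments of inertia.
3. **Artifact rejection.** Samples where KE exceeds
   τ = median(KE) + κ·IQR(KE) (κ = 100) are flagged, the flags dilated by
   1000 ms, and the union over both energy channels masks movement
   artifacts.
4. **Beat detection.** Each KE channel is band-passed to the heart-rate
   band (0.65–3.5 Hz), standardized by median/IQR and combined with weights
   λ_lin = λ_rot = 1 into the low-frequency profile S_lf. Peaks are scored
   by their height relative to a 600 ms RMS envelope, boosted by an
   associated trough 350–100 ms earlier, weighted by topographic
   prominence, and greedily pruned at a 450 ms minimum spacing. Windows of
   −200…+300 ms around the surviving peaks are then cross-matched with a
   matrix-profile join of 400 ms z-normalized subsequences; windows whose
   best cross-window motif distance is an outlier (median + 3·IQR rule)
   are rejected, and the confirmed motif middles become the beat reference
   points. HR = 60 / mean(inter-beat interval).
5. **Metrics.** The linear KE is integrated over three phase windows around
   each reference point — systolic iK_Sys (−100…+100 ms), late-diastolic
   iK_Late dia (−300…−100 ms), early-diastolic iK_Early dia
   (+100…+300 ms) — and each metric is reported as the median over valid
   beats, in nJ·s.
6. **Validation statistics.** Bland–Altman agreement with ±1.96 SD limits,
   exact CIs, Monte Carlo Lilliefors normality, bias tests and clinically
   motivated agreement intervals (±67 / 35 / 7 % for the three metrics);
   two-way mixed-model intraclass correlation for absolute agreement
   (single measure) with F-based CIs; and at-home compliance analysis by
   age band (<46, 46–75, >75) with ANOVA and Bonferroni-corrected pairwise
   tests (p < 0.017).

A synthetic-data module generates 6-DOF recordings with analytic ground
truth (beat times, artifact spans, closed-form phase integrals), paired
metric tables at a target ICC, and compliance tables, so that every stage
can be verified without access to clinical data.

## Worked example

```r
library(scgkinetics)

# a simulated 3-minute recording at 72 bpm, 10 dB in-band SNR
cfg <- sim_config(duration = 180, hr_bpm = 72, hrv_cv = 0.03,
                  noise_rms = noise_for_snr(sim_config(hr_bpm = 72), 10),
                  seed = 42)
sim <- simulate_recording(cfg)
fit <- scg_analyze(sim$recording)
summary(fit)
#> Record sim/sim-seed42 at 100 Hz
#>   clean fraction      1.000
#>   candidates/rejected 216/0
#>   beats (valid)       216 (216)
#>   HR                  72.1 bpm
#>   iK_Sys              3.601 nJ s
#>   iK_Late dia         0.4918 nJ s
#>   iK_Early dia        0.4937 nJ s
```

The 216 detected beats and their HR agree with the simulator's ground
truth (72.0 bpm); the three iK values are the per-record medians of the
per-beat phase integrals. Comparing two devices measuring the same
subjects:

```r
M <- simulate_paired_metrics(150, 2, target_icc = 0.85, grand_mean = 20, seed = 5)
tab_a <- data.frame(subject_id = sprintf("s%03d", 1:150), session = "kcg",
                    ik_sys = M[, 1], ik_late_dia = 1, ik_early_dia = 1, hr = 60)
tab_b <- transform(tab_a, session = "phone", ik_sys = M[, 2])
cmd_compare(tab_a, tab_b, "ik_sys")
#> Comparison of 'ik_sys' over 150 shared subjects
#> <Bland-Altman> n=150  bias 0.001912 [-0.08759, 0.09141]
#>   LoA [-1.085, 1.089], 96.0% of differences within
#>   normality p 0.555; bias test (t) p 0.966; trend p 0.726
#>   clinical interval +/-67%: PASS
#> <ICC(A,1)> 0.843 [0.789, 0.883] (excellent; n=150, k=2)
```

The estimated ICC (0.843) recovers the generating value (0.85), the bias is
indistinguishable from zero, and the limits of agreement sit well inside
the ±67 % clinical interval for iK_Sys, so the two "devices" are declared
comparable. A command-line front end wraps the same functions:

```sh
scgk simulate --seed 7 --out rec.csv
scgk analyze rec.csv --out metrics.csv
scgk compare a.csv b.csv --metric ik_sys --out cmp.json
scgk compliance counts.csv --out comp.json
```

(`scgk` is installed under `<library>/scgkinetics/exec/scgk`.)

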