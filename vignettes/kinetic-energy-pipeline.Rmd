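---
title: "ECG-free cardiac kinetic-energy metrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG-free cardiac kinetic-energy metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgkinetics)
```

## The measurement model

A chest-mounted inertial sensor (a smartphone resting on the sternum, or a
small wearable unit) experiences the recoil of the beating heart as linear
accelerations $\vec a$ and angular rates $\vec\omega$. Treating the sensor
as a rigid body of mass $m$ and principal moments of inertia
$(I_{xx}, I_{yy}, I_{zz})$, its instantaneous kinetic energy splits into

$$KE_{lin} = \tfrac12 m\,(v_x^2 + v_y^2 + v_z^2), \qquad
  KE_{rot} = \tfrac12\,(I_{xx}\omega_x^2 + I_{yy}\omega_y^2 +
  I_{zz}\omega_z^2),$$

where $\vec v$ is the band-limited velocity obtained by integrating the
filtered acceleration. The per-beat time integrals of $KE_{lin}$ over three
fixed windows around a beat reference point — systolic ($-100\ldots100$ ms),
late-diastolic ($-300\ldots-100$ ms) and early-diastolic
($100\ldots300$ ms) — summarize the mechanical activity of the
corresponding cardiac phases and are reported as per-record medians in
nJ·s (`ik_sys`, `ik_late_dia`, `ik_early_dia`).

The central assumption of the whole pipeline is that the heartbeat leaves a
*repeating* vibration pattern: beats are localized from the signal itself
(no ECG), first coarsely through the low-frequency energy envelope, then
confirmed by motif discovery across beat windows.

## Pipeline parameters

All defaults live in `scg_config()` and are logged into every results
sidecar. The ones that matter:

| parameter | default | role |
|---|---|---|
| `filter.f_lo`, `f_hi` | 3, 50 Hz | acquisition band; the upper edge sits at the Nyquist limit of 100 Hz sampling |
| `filter.attenuation_db`, `transition_width` | 60 dB, 1 Hz | Harris tap rule `ceil((fs/Δf)(A/22))` → 273 taps at 100 Hz |
| `artifact.kappa`, `expand_ms` | 100, 1000 ms | movement threshold τ = median + κ·IQR and mask dilation |
| `beats.f_lo`, `f_hi`, `transition_width` | 0.65, 3.5, 0.3 Hz | heart-rate band of the low-frequency profile (911 taps at 100 Hz) |
| `beats.lambda_lin`, `lambda_rot` | 1, 1 | channel weights in the combined profile |
| `beats.envelope_ms` | 600 ms | RMS envelope used for scoring |
| `beats.trough_window_ms` | −350…−100 ms | trough-to-peak association interval |
| `beats.min_dist_ms` | 450 ms | greedy pruning distance (≈ the shortest plausible inter-beat interval) |
| `beats.window_ms`, `motif_len_ms` | −200…+300 ms, 400 ms | motif windows and motif length |
| `beats.motif_threshold_k` | 3 | motif outlier rule median + k·IQR |
| `metrics.windows` | ±100 / −300…−100 / +100…+300 ms | cardiac-phase integration windows |

Transition widths are not implied by the band edges and the attenuation
alone; 1 Hz (acquisition) and 0.3 Hz (heart band) keep the 3 Hz and
0.65 Hz edges meaningful while holding tap counts tractable at 100 Hz.

## Numerical choices

**Zero-phase filtering.** The linear-phase FIR is applied once and its
constant group delay $(N-1)/2$ samples compensated, with reflection padding
at the edges. Unlike forward–backward filtering this preserves the designed
magnitude response exactly.

**Velocity integration.** Cumulative trapezoidal integration with zero
initial condition, followed by re-application of the acquisition band-pass:
the acceleration is band-limited, so genuine cardiac content is untouched
while integration drift (which lives near DC) is removed. The trapezoid
rule attenuates a component at frequency $f$ by the factor
$(\pi f h)/\tan(\pi f h)$ relative to ideal integration ($h$ the sampling
interval); at 100 Hz this is a 5–10 % energy deficit for content at
12–16 Hz. It is a *common-mode* bias — identical for any two devices
sampled at the same rate — so it does not affect agreement analyses, but
absolute nJ·s values at 100 Hz are systematically conservative. The
metric-oracle checks therefore run the simulator at 500 Hz, where the
discretization error of the full chain stays below 2 % and the comparison
isolates the pipeline's integration fidelity rather than the sampling
grid.

**Quantiles.** All IQRs (artifact threshold, standardization) use linear
interpolation (type-7) quantiles, computed over artifact-free samples only.
A strictly constant energy signal has IQR 0 and τ = median, so no sample is
strictly above threshold and the artifact mask is empty — the correct
degenerate behaviour. A flat signal reaching the profile stage (IQR 0
after filtering) raises an explicit degenerate-signal error.

**Phase-window sampling.** Windows $[ref+a, ref+b)$ map to sample indices
$\lfloor(ref+a)f_s\rfloor \ldots \lfloor(ref+b)f_s\rfloor$ and the
trapezoid runs over the enclosed sample intervals, so a constant signal
integrates to exactly value × (b−a) and results are bit-reproducible.

**Greedy pruning.** Candidates are visited in descending score order with
ties broken by time, which makes the output independent of input ordering.

## Beat confirmation: design rationale

Two decisions here were genuinely open and deserve justification.

**What signal do the motifs live on?** The candidate stage runs on the
heart-band profile $S_{lf}$, but after 0.65–3.5 Hz filtering every beat
window reduces to nearly the same single lobe; once z-normalized, motif
distances between such windows measure little but noise. Motif matching
therefore runs on the *wide-band* standardized kinetic-energy combination
(same λ weights), which retains per-beat morphology: genuine beats match
each other tightly while unrelated windows do not. The heart-band variant
remains available (`motif_source = "slf"`).

**Where is the reference point?** z-normalized matching between windows
that are already aligned on their peaks cannot determine absolute phase:
for identical beats every common subsequence offset ties, and under noise
the arg-min offset is essentially uniform over its ±100 ms slack. The only
phase anchor in the construction is the detected peak itself, so the
reference point is the middle of each window's peak-centred motif
representative — i.e. the peak — while confirmation uses the full
symmetric cross-window join (both windows' subsequences slide, so peak
jitter in either direction can be absorbed before the outlier rule is
applied). The motif middles are then consistent across beats and the phase
windows stay mutually comparable.

**Rejecting signal-free records.** The median + 3·IQR rule is relative; on
a record containing *no* repeating pattern it would still confirm most
windows. Since z-normalized distances have an absolute meaning
($d^2 = 2m(1-\hat\rho)$ for subsequence correlation $\hat\rho$), a record
is rejected outright when the median best-match correlation falls below
0.8: the best spurious match among the few thousand unrelated 41-sample
subsequences of a 3-minute record only reaches $\hat\rho \approx 0.6$–0.7
(extreme-value scaling $\sqrt{2\ln N}/\sqrt{m}$), while genuine repeated
beats exceed 0.95.

Unassociated troughs are discarded (they never form candidates on their
own), and candidate windows crossing the record boundary or the artifact
mask are dropped before the join.

## The statistics layer

**Bland–Altman.** Bias = mean difference; limits of agreement
bias ± 1.96·SD with t-based CIs for the bias and the standard-error formula
$s\sqrt{1/n + z^2/(2(n-1))}$ for each limit; a least-squares trend of
difference on pairwise mean; percentage differences use the pairwise mean
as denominator. The clinical verdict requires both limits, expressed as a
percentage of the grand mean, to lie within the metric's agreement
interval (±67 % for `ik_sys`, ±35 % for `ik_late_dia`, ±7 % for
`ik_early_dia`) *and* at least 90 % of differences inside the limits.

**Normality.** The Lilliefors statistic (KS against a normal with
estimated parameters) has no closed-form null; the p-value is a seeded
Monte Carlo estimate, $p = (1 + \#\{D^\ast \ge D\})/(n_{mc}+1)$, with
$10^4$ replicates by default (fewer inside Bland–Altman for very large
samples, where the p-value only routes the bias test).

**ICC.** The reliability index is the single-measure, absolute-agreement
intraclass correlation of a two-way model without interaction
(McGraw–Wong ICC(A,1)): with subjects as rows and the $k$ sessions/devices
as fixed columns,

$$ICC = \frac{MS_S - MS_E}{MS_S + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)},$$

where $MS_S$, $MS_C$, $MS_E$ are the between-subject, between-session and
residual mean squares. Some descriptions of this coefficient swap the
labels of the subject and session mean squares; the implementation pins
the algebra to the absolute-agreement form (a duplicated column yields
ICC = 1) and verifies it in the tests against an independent
`aov()`-based sums-of-squares oracle to $10^{-10}$. Confidence intervals
use the McGraw–Wong F-distribution method. Labels are strict:
ICC > 0.8 "excellent", > 0.7 "satisfactory", otherwise "poor".

**Compliance.** Per-patient compliance is completed/expected; the overall
rate pools the counts (equivalently, an expected-count-weighted mean of
per-patient percentages — the pooled convention reproduces the worked
arithmetic 100·2058/4968 = 41.4 %). Age bands default to [0, 45],
[46, 75], [76, ∞) with integer ages; descriptions of such bands are often
ambiguous between "under 45" and "<46", so the breaks are configurable.
Pairwise tests (after a significant ANOVA) use Welch t-tests when both
groups pass the Lilliefors check and Mann–Whitney U otherwise, at the
Bonferroni threshold 0.017 for three comparisons.

## What the simulator emulates — and what it does not

`simulate_recording()` builds a 6-DOF record from:

* beats at lognormally jittered inter-beat intervals (lognormal keeps
  intervals positive; CV = `hrv_cv`, default 0.03 — resting sinus
  variability);
* a fixed multi-axis beat template of Gabor atoms *defined in velocity
  space* ($v(t) = (A/\omega)e^{-t^2/2\sigma^2}\sin\omega t$ at 12/14/16 Hz,
  dominant on the dorsoventral axis) whose emitted acceleration is the
  exact analytic derivative — so true velocity, kinetic energy and the
  phase integrals are known in closed form (the ground-truth integrals are
  high-precision quadratures of the analytic energy, independent of any
  sampled signal);
* angular-rate channels as a scaled copy of the template velocity
  (50 rad/s per m/s, giving gyrocardiography-typical peaks of a few
  hundredths of rad/s);
* respiration as pure amplitude modulation of the beats at 0.25 Hz
  (±10 %), which scales each beat's true integrals by the squared
  envelope;
* a deterministic in-band micro-vibration floor (velocity tones at
  18/20/22 Hz per axis, ~18 dB below the cardiac velocity peak). Real
  chest recordings are never silent between beats; without this floor the
  κ = 100 artifact threshold collapses onto the sensor-noise IQR and
  flags the beats themselves on clean records. The tone frequencies are
  chosen so that no rectification product of floor and template falls
  into the 0.65–3.5 Hz heart band;
* white sensor noise per channel (`noise_rms` on the accelerometer,
  one tenth of it in rad/s on the gyroscope, matching MEMS noise-density
  ratios; `noise_for_snr()` converts a target record-level SNR in dB —
  clean pooled acceleration RMS over noise RMS — into a noise level);
* movement artifacts as 0.5 s high-amplitude bursts at Poisson times.

The generator is a pure function of (configuration, seed) with a fixed
RNG draw order, so any draw can be reproduced independently.

What it does **not** emulate: pathology-specific morphology (atrial
fibrillation irregularity, valvular signatures), respiration-induced
*frequency* modulation or baseline wander, sensor clipping and coupling
changes, 1/f and narrow-band hardware noise, or inter-subject template
variability. Detection results on simulated records therefore demonstrate
the pipeline's correctness and its noise robustness under the stated
model — not clinical performance on patient data, which requires real
recordings.

Problem sizes used by the test-suite and acceptance checks — twenty
3-minute records at 100 Hz for detection, one 40 s record at 500 Hz for
the metric oracle, $10^5$ differences for agreement calibration, 100
replicates of 200×2 matrices for ICC recovery — were chosen as the
smallest sizes at which the Monte Carlo noise of each check is clearly
below its acceptance margin.

## Known limitations

* Absolute nJ·s values at 100 Hz carry the trapezoid integration deficit
  described above (common-mode across devices at equal rates).
* The fixed −200…+300 ms / 400 ms motif geometry assumes resting heart
  rates; at rates well above 130 bpm neighbouring beats enter the window.
* HR is 60/mean(IBI) over confirmed beats; a missed beat lengthens one
  interval and biases HR low by roughly the miss fraction.
* The beat-level detector is validated against simulated ground truth
  only; beat-by-beat agreement with ECG R-peaks is out of scope.
* Records shorter than ~10 s cannot be processed at all (the heart-band
  FIR needs more samples than taps), and gaps above 250 ms flag a record
  unusable rather than interpolating across a potential beat.
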