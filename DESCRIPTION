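Package: scgkinetics
Title: Cardiac Kinetic-Energy Metrics from Smartphone Seismocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: ECG-free processing of 6-degree-of-freedom chest-vibration
    recordings (3-axis linear acceleration, 3-axis angular velocity) from
    smartphones or wearable inertial sensors into per-record cardiac
    kinetic-energy metrics and heart rate. Implements FIR band-pass
    filtering, velocity integration, linear and rotational kinetic-energy
    computation, robust movement-artifact masking, heartbeat localization by
    low-frequency profile scoring and matrix-profile motif confirmation, and
    time integrals of kinetic energy over systolic and diastolic phase
    windows (iK_Sys, iK_Late dia, iK_Early dia). Also provides the
    statistical validation layer used for telemonitoring studies:
    Bland-Altman agreement with clinically motivated limits, two-way mixed
    intraclass correlation for absolute agreement, Monte Carlo Lilliefors
    normality testing, and at-home compliance analysis by age group, plus
    synthetic-data generators with analytic ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    pracma,
    jsonlite
Suggests:
    nortest,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
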