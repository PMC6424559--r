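Package: runfree
Title: Running Stability Analysis from Step-to-Step Variability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how runners keep from falling. Implements a
    three-dimensional point-mass biped running model with massless telescoping
    legs (a direct leg-force variant and a Hill-type muscle variant), periodic
    gait synthesis, a feedback controller acting at flight apex through foot
    placement, landing leg length and within-stance force or activation
    modulation, and motor-noise injection. A companion inference pipeline mines
    step-to-step variability in ground reaction force and kinematic time
    series: it estimates center-of-mass state at flight apex, segments steps,
    extracts per-step control features (impulses, half-stance vertical
    impulses, foot placement, landing leg length, phase-binned forces), fits
    the linear control regressions and apex-to-apex return maps, and quantifies
    estimator uncertainty by bootstrap. A synthetic-data generator emulating a
    dual-rate force-plate plus motion-capture treadmill experiment closes the
    loop for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    signal,
    jsonlite,
    data.table,
    yaml,
    stats,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
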