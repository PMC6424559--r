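# Shared fixtures, built once per test run. The nominal-gait solves and
# controller fits are deterministic, so caching them across test files only
# saves time, not coverage.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

ref_force_model <- function() {
  memo("force_model", function() fit_model_controller("force"))
}

ref_muscle_model <- function() {
  memo("muscle_model", function() fit_model_controller("muscle"))
}

# moderate-size noisy dataset from the muscle model (the variant that
# survives calibrated noise), reused by the inference and recovery tests
ref_dataset <- function() {
  memo("dataset", function()
    generate_gait_data(ref_muscle_model(), n_steps = 2000, seed = 42))
}

ref_fit <- function() {
  memo("fit", function() fit_gait_controller(ref_dataset()))
}

# cached COM kinematics and event table of the reference dataset
ref_ck <- function() {
  memo("ck", function() com_kinematics_from_grf(ref_dataset()))
}

ref_ev <- function() {
  memo("ev", function() segment_events(ref_dataset(), com_kin = ref_ck()))
}

ref_implied <- function() {
  memo("implied", function() model_implied_gains(ref_muscle_model()))
}

# oracle regressions on the generator's exact step quantities: the values a
# faithful measurement pipeline should reproduce
ref_truth <- function() {
  memo("truth", function() truth_gains(ref_dataset()$truth$steps))
}

# noiseless twin of the reference dataset: identical motor-noise
# realization (same seed), zero measurement noise. Its pipeline output is
# the reference for statistics that are ill-posed against an independent
# oracle (the half-stance impulse split hinges on a takeoff detection that
# dwells at the force threshold).
ref_oracle <- function() {
  memo("oracle", function() {
    ds0 <- generate_gait_data(ref_muscle_model(), n_steps = 2000, seed = 42,
                              meas_sd_force = 0, meas_sd_pos = 0)
    fit_control_regressions(extract_step_features(ds0, segment_events(ds0)))
  })
}

# Simpson integration on a uniform grid (exact for piecewise quadratics);
# the independent quadrature oracle used by the closed-form tests.
simpson <- function(f, a, b, n = 2000L) {
  if (n %% 2L == 1L) n <- n + 1L
  x <- seq(a, b, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f(x)) * (b - a) / (3 * n)
}
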