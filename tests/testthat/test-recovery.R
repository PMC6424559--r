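# closing the loop: simulate with a known controller, infer it back

test_that("headline control gains are recovered within 3 standard errors", {
  fit <- ref_fit()
  implied <- ref_truth()
  reg <- fit$regressions[fit$regressions$term != "(Intercept)", ]
  primary <- list(
    c("impulse_x", "d_vxa"), c("impulse_y", "d_vya"),
    c("landing", "d_za"), c("fp_x", "d_vxa"),
    c("fp_y", "d_vya"), c("fp_y", "d_za"))
  for (sd_ in c("left", "right")) {
    for (p in primary) {
      est <- reg[reg$family == p[1] & reg$side == sd_ & reg$term == p[2], ]
      tru <- implied$value[implied$family == p[1] & implied$side == sd_ &
                             implied$term == p[2]]
      expect_lt(abs(est$estimate - tru), 3 * est$se,
                label = sprintf("%s %s %s: est %.3f vs programmed %.3f (se %.3f)",
                                p[1], sd_, p[2], est$estimate, tru, est$se))
    }
  }
})

test_that("half-stance impulse slopes have the human sign structure and are
           measurement-robust", {
  fit <- ref_fit()
  reg <- fit$regressions[fit$regressions$term == "d_za", ]
  oracle <- ref_oracle()
  for (sd_ in c("left", "right")) {
    first <- reg[reg$family == "half_impulse_z_first" & reg$side == sd_, ]
    second <- reg[reg$family == "half_impulse_z_second" & reg$side == sd_, ]
    # a high apex is answered by less first-half and more second-half
    # vertical impulse (the triangular-model prediction)
    expect_lt(first$estimate, 0)
    expect_gt(second$estimate, 0)
    # the split point rides on a takeoff detection that is ill-posed for
    # this plant (the muscle's force tail dwells at the threshold), so the
    # quantitative reference is the same pipeline on the noiseless twin
    for (fam in c("half_impulse_z_first", "half_impulse_z_second")) {
      a <- reg[reg$family == fam & reg$side == sd_, ]
      b <- oracle[oracle$family == fam & oracle$side == sd_ &
                    oracle$term == "d_za", ]
      expect_lt(abs(a$estimate - b$estimate), 3 * a$se)
    }
  }
})

test_that("impulse slopes and apex-map diagonals tell one story", {
  fit <- ref_fit()
  reg <- fit$regressions
  for (sd_ in c("left", "right")) {
    sl <- reg[reg$family == "impulse_x" & reg$side == sd_ &
                reg$term == "d_vxa", ]
    K11 <- fit$apex_map$K[[sd_]][1, 1]
    seK <- fit$apex_map$se[[sd_]][1, 1]
    # impulse = momentum change over the stance: 1 + slope ~ map diagonal
    expect_lt(abs((1 + sl$estimate) - K11), 3 * (sl$se + seK))
  }
})

test_that("adding apex positions barely improves impulse regressions", {
  fit <- ref_fit()
  r1 <- fit_control_regressions(fit$features, predictors = "apex")
  r2 <- fit_control_regressions(fit$features, predictors = "apex+position")
  for (fam in c("impulse_x", "impulse_y")) {
    for (sd_ in c("left", "right")) {
      a <- unique(r1$r_squared[r1$family == fam & r1$side == sd_])
      b <- unique(r2$r_squared[r2$family == fam & r2$side == sd_])
      expect_gte(b, a)            # nesting never lowers R-squared
      expect_lt(b - a, 0.015)     # the controller is position-blind
    }
  }
})

test_that("mirror symmetry of the generator shows up in the fitted gains", {
  fit <- ref_fit()
  sym <- symmetry_check(fit$regressions)
  # the generator is mirror-symmetric up to the small estimated left/right
  # gain differences; expect the large majority of pairs consistent
  expect_gte(mean(sym$consistent), 0.75)
})

test_that("the deterministic model's own placement gains are the programmed ones", {
  implied <- ref_implied()
  g <- function(f, s, t) implied$value[implied$family == f &
                                         implied$side == s &
                                         implied$term == t]
  expect_equal(g("fp_x", "left", "d_vxa"), 0.95, tolerance = 0.01)
  expect_equal(g("fp_x", "right", "d_vxa"), 1.00, tolerance = 0.01)
  expect_equal(g("landing", "left", "d_za"), 0.3, tolerance = 1e-6)
  expect_equal(g("landing", "right", "d_za"), 0.3, tolerance = 1e-6)
  # placement responds negligibly to the other apex states
  expect_lt(abs(g("fp_x", "left", "d_vya")), 0.05)
})

test_that("recovery experiments are deterministic given the seed", {
  m <- ref_muscle_model()
  r1 <- run_recovery_experiment(m, n_steps = 150, seed = 5)
  r2 <- run_recovery_experiment(m, n_steps = 150, seed = 5)
  expect_identical(r1$table, r2$table)
  expect_false(r1$fell)
  expect_s3_class(r1, "recovery_report")
  expect_true(all(c("programmed", "estimate", "se", "recovered")
                  %in% names(r1$table)))
})

test_that("experiment wrappers write complete artifact sets", {
  m <- ref_muscle_model()
  d1 <- tempfile(); d2 <- tempfile()
  ds <- run_simulation_experiment(m, d1, n_steps = 80, seed = 3)
  expect_true(all(file.exists(file.path(d1,
    c("forces.tsv", "kin.tsv", "meta.json", "ground_truth.tsv",
      "summary.json")))))
  summ <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_equal(summ$steps_completed, 80)
  expect_false(summ$fell)
  fit <- run_inference_experiment(d1, d2)
  expect_true(all(file.exists(file.path(d2,
    c("regressions.tsv", "phase_sensitivities.tsv", "summary.json")))))
  s2 <- jsonlite::read_json(file.path(d2, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(dim(s2$K_right), c(3, 3))
  expect_true(all(abs(s2$eigenvalue_moduli) >= 0))
})
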