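test_that("a noiseless generator reproduces the true CDF exactly", {
  truth <- scaled_t(4, 30, 20)
  spec <- panel_generator_spec(truth, truth, n_experts = 3,
                               probit_noise_sd = 0, rounding_grid = 0,
                               seed = 1)
  panel <- generate_expert_panel(spec)
  want <- 100 * pt((c(60, 30, 20, 10, 5) - 30) / 20, 4)
  for (e in panel$experts) {
    expect_equal(e$answers$probability_pct[1:5], want, tolerance = 1e-12)
    expect_equal(e$answers$probability_pct[6:10], want, tolerance = 1e-12)
  }
})

test_that("rounded answers respect the percent grid and stay monotone", {
  spec <- panel_generator_spec(scaled_t(4, 30, 20), scaled_t(4, 35, 25),
                               n_experts = 40, probit_noise_sd = 0.5,
                               rounding_grid = 5, seed = 21)
  panel <- generate_expert_panel(spec)   # answer_set() re-validates monotonicity
  probs <- unlist(lapply(panel$experts, function(e) e$answers$probability_pct))
  expect_true(all(probs %% 5 == 0))
  expect_true(all(probs >= 0 & probs <= 100))
})

test_that("generated panels are reproducible and expert-wise independent", {
  spec <- panel_generator_spec(scaled_t(4, 30, 20), scaled_t(4, 35, 25),
                               n_experts = 4, seed = 9)
  p1 <- generate_expert_panel(spec)
  p2 <- generate_expert_panel(spec)
  expect_identical(p1$experts[[3]]$answers, p2$experts[[3]]$answers)
})

test_that("a large low-noise panel concentrates on the true answers", {
  truth <- scaled_t(4, 30, 20)
  spec <- panel_generator_spec(truth, truth, n_experts = 200,
                               probit_noise_sd = 0.05, seed = 13)
  cons <- consensus_answers(generate_expert_panel(spec))
  want <- 100 * pt((c(60, 30, 20, 10, 5) - 30) / 20, 4)
  expect_lt(max(abs(cons$answers$probability_pct - rep(want, 2))), 1)
})

test_that("patient-level generation matches its moments", {
  zero <- generate_patient_data(model_parameters(-30, -20, 0), 5, seed = 2)
  expect_equal(zero$change_mm, rep(c(-30, -20), each = 5))
  expect_identical(generate_patient_data(model_parameters(-30, -20, 8), 5, 3),
                   generate_patient_data(model_parameters(-30, -20, 8), 5, 3))
  big <- generate_patient_data(model_parameters(-30, -20, 8), 5000, seed = 6)
  s2 <- summarize_patients(big)$s2
  expect_lt(abs(s2 - 64) / 64, 0.05)
})

test_that("summaries match the hand-computed pooled statistics", {
  recs <- data.frame(arm = rep(c("pamidronate", "adalimumab"), each = 2),
                     change_mm = c(-30, -20, -10, 0))
  s <- summarize_patients(recs)
  expect_equal(s$xbar_P, -25)
  expect_equal(s$xbar_A, -5)
  expect_equal(s$s2, 50)   # pooled: (50 + 50) / (4 - 2), each arm SS = 2 * 5^2
  same <- data.frame(arm = rep("pamidronate", 3), change_mm = c(-7, -7, -7))
  expect_equal(summarize_patients(same)$s2, 0)
  expect_error(summarize_patients(recs[0, ]), "no patient records")
})

test_that("IPD and direct summaries drive identical updates", {
  prior <- consensus_prior()
  recs <- generate_patient_data(model_parameters(-30, -28, 7), 8, seed = 11)
  s <- summarize_patients(recs)
  direct <- trial_summary(s$n_P, s$n_A, s$xbar_P, s$xbar_A, s$s2)
  expect_equal(ng_update(prior, s), ng_update(prior, direct))
})

test_that("generator specs validate their inputs", {
  expect_error(panel_generator_spec(scaled_t(4), scaled_t(4),
                                    thresholds = c(10, 20)), "decreasing")
  expect_error(panel_generator_spec(scaled_t(4), scaled_t(4),
                                    rounding_grid = 7), "divide 100")
})
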