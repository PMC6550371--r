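test_that("conjugate updating reproduces the known posterior intervals", {
  prior <- consensus_prior()
  post1 <- ng_update(prior, trial_summary(20, 20, -30, -30, 4.6))
  ciA <- credible_interval(post1, "mu_A", 0.90)
  expect_equal(round(ciA, 1), c(-30.8, -29.2))
  expect_equal(post1$a0, prior$a0 + 20)
  # symmetric interval
  m <- ng_marginal(post1, "mu_A")
  expect_equal(mean(ciA), m$location)
})

test_that("updating with no data returns the belief unchanged", {
  prior <- consensus_prior()
  expect_identical(ng_update(prior, trial_summary(0, 0, NA, NA, NA)), prior)
})

test_that("summary updating matches a patient-level oracle", {
  # oracle: Bayesian linear model computed directly from the design
  # matrix and outcome vector, never through the sufficient statistics
  prior <- consensus_prior()
  recs <- generate_patient_data(model_parameters(-32, -28, 8), 12, seed = 4)
  y <- recs$change_mm
  X <- cbind(1, as.numeric(recs$arm == "adalimumab"))
  P0 <- solve(prior$R)
  Pn <- P0 + crossprod(X)
  theta0 <- c(prior$mu_P0, prior$delta0)
  theta_n <- solve(Pn, P0 %*% theta0 + crossprod(X, y))
  a_n <- prior$a0 + length(y) / 2
  b_n <- prior$b0 + 0.5 * (sum(y^2) + t(theta0) %*% P0 %*% theta0 -
                             t(theta_n) %*% Pn %*% theta_n)[1]
  post <- ng_update(prior, summarize_patients(recs))
  expect_equal(post$mu_P0, theta_n[1], tolerance = 1e-9)
  expect_equal(post$delta0, theta_n[2], tolerance = 1e-9)
  expect_equal(post$a0, a_n, tolerance = 1e-9)
  expect_equal(post$b0, b_n, tolerance = 1e-9)
  expect_equal(post$R, solve(Pn), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("sequential updating is coherent with pooled updating", {
  prior <- consensus_prior()
  recs <- generate_patient_data(model_parameters(-30, -25, 9), 10, seed = 7)
  idx <- c(1:5, 11:15)   # first half of each arm
  seq2 <- ng_update(ng_update(prior, summarize_patients(recs[idx, ])),
                    summarize_patients(recs[-idx, ]))
  pooled <- ng_update(prior, summarize_patients(recs))
  expect_equal(seq2$a0, pooled$a0, tolerance = 1e-9)
  expect_equal(seq2$b0, pooled$b0, tolerance = 1e-9)
  expect_equal(seq2$mu_P0, pooled$mu_P0, tolerance = 1e-9)
  expect_equal(seq2$delta0, pooled$delta0, tolerance = 1e-9)
  expect_equal(seq2$R, pooled$R, tolerance = 1e-9)
})

test_that("the flat-prior limit recovers ordinary least squares", {
  vague <- ng_belief(1e-9, 1e-9, 0, 0, diag(2) * 1e9)
  d <- trial_summary(15, 25, -22.5, -31.25, 18.4)
  post <- ng_update(vague, d)
  expect_equal(post$mu_P0, -22.5, tolerance = 1e-5)
  expect_equal(post$delta0, -31.25 - (-22.5), tolerance = 1e-5)
  expect_equal(post$b0, 0.5 * (15 + 25 - 2) * 18.4, tolerance = 1e-4)
})

test_that("posterior effect uncertainty contracts with sample size", {
  prior <- consensus_prior()
  scales <- vapply(c(10, 40, 160), function(n) {
    set.seed(123)
    d <- simulate_trial_summary(model_parameters(-32, -30, 9), n)
    ng_marginal(ng_update(prior, d), "delta")$scale
  }, numeric(1))
  expect_true(all(diff(scales) < 0))
})

test_that("decision probabilities match a marginal oracle at margin 0", {
  # when both arms are almost surely beneficial, the margin-0 events
  # reduce to the sign of delta, so p_P and p_A are computable from the
  # closed-form delta marginal alone (up to the arm-sign tail mass)
  b <- ng_belief(2, 8, -40, 1, diag(2))
  pr <- prob_clinically_relevant(b, decision_rule(margin = 0),
                                 n_draws = 1e6, seed = 31)
  p_delta_le_0 <- prob_below(ng_marginal(b, "delta"), 0)
  tail <- 1 - prob_below(ng_marginal(b, "mu_P"), 0) +
    1 - prob_below(ng_marginal(b, "mu_A"), 0)
  se <- 3 * sqrt(0.25 / 1e6) + tail
  expect_lt(abs(pr$p_P - (1 - p_delta_le_0)), se)
  expect_lt(abs(pr$p_A - p_delta_le_0), se)
  expect_equal(pr$p_union, pr$p_P + pr$p_A, tolerance = 2 * tail)
})

test_that("a strongly superior arm is declared with near certainty", {
  prior <- consensus_prior()
  post2 <- ng_update(prior, trial_summary(20, 20, -20, -30, 21.3))
  pr <- prob_clinically_relevant(post2, decision_rule(margin = 0.3),
                                 n_draws = 1e5, seed = 17)
  # the winning event is {mu_A < 0 and delta <= 0.3 mu_P}; with
  # P(mu_A < 0) = 1 to machine precision the second condition's
  # (-0.3, 1)-contrast t marginal gives the probability in closed form
  exact <- prob_below(ng_marginal(post2, c(-0.3, 1)), 0)
  expect_lt(abs(pr$p_A - exact), 3 * sqrt(exact * (1 - exact) / 1e5))
  expect_gt(pr$p_A, 0.985)
  expect_lt(pr$p_P, 0.001)
})

test_that("a belief concentrated on harm never declares benefit", {
  b <- ng_belief(5, 5, 5, 0, matrix(0, 2, 2), degenerate = TRUE)
  pr <- prob_clinically_relevant(b, decision_rule(margin = 0.3),
                                 n_draws = 1000, seed = 1)
  expect_equal(pr$p_P, 0)
  expect_equal(pr$p_A, 0)
})

test_that("the union probability is within [0,1] and decreases in margin", {
  prior <- consensus_prior()
  post <- ng_update(prior, trial_summary(20, 20, -25, -30, 10))
  ps <- vapply(c(0, 0.3, 0.6, 1), function(m)
    prob_clinically_relevant(post, decision_rule(margin = m),
                             n_draws = 5e4, seed = 8)$p_union,
    numeric(1))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_true(all(diff(ps) <= 0))
  # events stay disjoint for margin > 0
  pr <- prob_clinically_relevant(post, decision_rule(margin = 0.3),
                                 n_draws = 5e4, seed = 8)
  expect_equal(pr$p_union, pr$p_P + pr$p_A)
})

test_that("decision probabilities are reproducible given a seed", {
  prior <- consensus_prior()
  a <- prob_clinically_relevant(prior, n_draws = 1000, seed = 5)
  b <- prob_clinically_relevant(prior, n_draws = 1000, seed = 5)
  expect_identical(a, b)
})
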