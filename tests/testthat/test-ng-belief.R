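test_that("parameter marginals have the Normal-Gamma t form", {
  b <- ng_belief(1, 1, 0, 0, diag(2))
  m <- ng_marginal(b, "delta")
  expect_equal(m$df, 2)
  expect_equal(m$location, 0)
  expect_equal(m$scale, 1)
  # treatment-effect interval from its published scale components
  b2 <- ng_belief(2, 4.42, -32.3, 2.3, diag(c(1, 8.41)))
  ci <- st_interval(ng_marginal(b2, "delta"), 0.90)
  expect_equal(ci, c(-6.9, 11.5), tolerance = 0.05)
  # general contrast arithmetic: mu_A = mu_P + delta
  b3 <- ng_belief(3, 2, -10, 4, matrix(c(2, 0.5, 0.5, 1), 2))
  mA <- ng_marginal(b3, "mu_A")
  expect_equal(mA$location, -6)
  expect_equal(mA$scale^2, (2 / 3) * (2 + 2 * 0.5 + 1))
})

test_that("predictive distributions add sampling variance", {
  b <- ng_belief(1, 1, 0, 0, diag(2))
  p <- ng_predictive(b, "pamidronate")
  expect_equal(p$df, 2)
  expect_equal(p$scale, sqrt(2))
  # parameter certainty leaves only sampling variance
  b0 <- ng_belief(2, 3, -30, 1, matrix(0, 2, 2), degenerate = TRUE)
  expect_equal(ng_predictive(b0, "adalimumab")$scale^2, 3 / 2)
})

test_that("predictive scale dominates the marginal scale", {
  set.seed(11)
  for (i in 1:20) {
    A <- matrix(rnorm(4), 2)
    R <- crossprod(A) + diag(2) * 0.01
    b <- ng_belief(runif(1, 0.5, 5), runif(1, 0.5, 10),
                   rnorm(1), rnorm(1), R)
    for (arm in c("pamidronate", "adalimumab")) {
      cvec <- if (arm == "pamidronate") c(1, 0) else c(1, 1)
      expect_gt(ng_predictive(b, arm)$scale, ng_marginal(b, cvec)$scale)
    }
  }
})

test_that("variance quantiles follow the inverse-gamma law", {
  b <- ng_belief(2, 4.42, 0, 0, diag(2))
  expect_equal(variance_quantile(b, 0.75), 4.6, tolerance = 0.01)
  b1 <- ng_belief(1, 1, 0, 0, diag(2))
  expect_equal(variance_quantile(b1, 0.5), 1 / log(2), tolerance = 1e-12)
  qs <- vapply(c(0.1, 0.25, 0.5, 0.75, 0.9), variance_quantile,
               numeric(1), belief = b)
  expect_true(all(diff(qs) > 0))
  expect_error(variance_quantile(b, 1), "0, 1")
})

test_that("variance quantile agrees with Monte-Carlo draws of 1/tau", {
  b <- ng_belief(2, 4.42, 0, 0, diag(2))
  # exact identity: P(1/tau <= v_q) = q under the gamma law
  for (q in c(0.1, 0.25, 0.5, 0.75, 0.9))
    expect_equal(1 - pgamma(1 / variance_quantile(b, q),
                            shape = b$a0, rate = b$b0), q,
                 tolerance = 1e-12)
  set.seed(20260922)
  v <- 1 / rgamma(1e6, shape = b$a0, rate = b$b0)
  for (q in c(0.25, 0.75)) {
    # empirical CDF at the computed quantile should equal q within 3 MC SEs
    p_hat <- mean(v <= variance_quantile(b, q))
    expect_lt(abs(p_hat - q), 3 * sqrt(q * (1 - q) / 1e6))
  }
})

test_that("belief validation catches bad hyperparameters", {
  expect_error(ng_belief(0, 1, 0, 0, diag(2)), "a0")
  expect_error(ng_belief(1, -1, 0, 0, diag(2)), "b0")
  expect_error(ng_belief(1, 1, 0, 0, matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_error(ng_belief(1, 1, 0, 0, diag(c(1, -1))), "positive definite")
  # PSD only allowed behind the degenerate flag
  psd <- matrix(c(1, 1, 1, 1), 2)
  expect_error(ng_belief(1, 1, 0, 0, psd), "positive definite")
  expect_s3_class(ng_belief(1, 1, 0, 0, psd, degenerate = TRUE), "ng_belief")
  expect_error(ng_marginal(ng_belief(1, 1, 0, 0, diag(2)), c(1, NA)),
               "contrast")
})
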