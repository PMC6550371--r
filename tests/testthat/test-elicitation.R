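test_that("consensus aggregation averages on the answer scale", {
  # single expert: consensus is that expert
  e1 <- make_answers("a", c(80, 40, 30, 20, 10), c(70, 50, 40, 30, 20))
  p1 <- expert_panel(e1)
  expect_equal(consensus_answers(p1)$answers$probability_pct,
               e1$answers$probability_pct)
  # two experts answering 40 and 60 average to 50
  e2 <- make_answers("b", c(90, 60, 40, 30, 20), c(80, 60, 40, 30, 20),
                     thr = c(60, 30, 20, 10, 5))
  ea <- make_answers("a", c(80, 40, 30, 20, 10), c(70, 40, 40, 30, 20))
  cons <- consensus_answers(expert_panel(ea, e2))
  expect_equal(cons$answers$probability_pct[1:5],
               c(85, 50, 35, 25, 15))
  expect_equal(cons$expert_id, "consensus")
  # median method
  e3 <- make_answers("c", c(70, 30, 20, 10, 5), c(60, 30, 20, 10, 5))
  med <- consensus_answers(expert_panel(ea, e2, e3), "median")
  expect_equal(med$answers$probability_pct[1], 80)
})

test_that("consensus of a panel concatenated with itself is unchanged", {
  panel <- fixture_panel()
  doubled <- expert_panel(c(panel$experts, panel$experts))
  expect_equal(consensus_answers(doubled)$answers$probability_pct,
               consensus_answers(panel)$answers$probability_pct)
})

test_that("structurally mismatched panels are rejected", {
  e1 <- make_answers("a", c(80, 40, 30, 20, 10), c(70, 50, 40, 30, 20))
  e2 <- make_answers("b", c(80, 40, 30), c(70, 50, 40), thr = c(60, 30, 20))
  expect_error(expert_panel(e1, e2), "question structure")
  expect_error(expert_panel(list()), "at least one")
})

test_that("quantile-transform fit is exact on self-consistent answers", {
  thr <- c(60, 40, 20, 10, 5)
  p <- 100 * pt((thr - 30) / 20, df = 4)  # exact t(4, 30, 20) CDF, score scale
  fit <- fit_predictive_from_answers(
    data.frame(threshold_mm = thr, probability_pct = p), df = 4,
    baseline = 60)
  expect_equal(fit$location, -30, tolerance = 1e-6)
  expect_equal(fit$scale, 20, tolerance = 1e-6)
})

test_that("two answers interpolate the t quantiles exactly", {
  fit <- fit_predictive_from_answers(
    data.frame(threshold_mm = c(40, 20), probability_pct = c(80, 20)),
    df = 4, baseline = 60)
  s <- 20 / (2 * qt(0.8, 4))
  expect_equal(fit$location, 30 - 60, tolerance = 1e-9)
  expect_equal(fit$scale, s, tolerance = 1e-9)
  expect_equal(fit$scale, 10.63, tolerance = 1e-2)
})

test_that("fit rejects invalid answers and drops boundary probabilities", {
  expect_error(fit_predictive_from_answers(
    data.frame(threshold_mm = c(40, 20), probability_pct = c(50, 60)),
    df = 4), "non-increasing")
  expect_message(fit_predictive_from_answers(
    data.frame(threshold_mm = c(60, 40, 20), probability_pct = c(100, 80, 20)),
    df = 4), "dropping 1")
  expect_error(suppressMessages(fit_predictive_from_answers(
    data.frame(threshold_mm = c(60, 20), probability_pct = c(100, 0)),
    df = 4)), "at least two")
  expect_error(fit_predictive_from_answers(
    data.frame(threshold_mm = c(60, 40, 20),
               probability_pct = c(50, 50, 50)), df = 4),
    "degenerate")
})

test_that("the fit attains the least-squares minimum", {
  # noisy (not self-consistent) answers: compare the fitted residual sum
  # of squares against a grid search over (location, scale)
  thr <- c(60, 40, 20, 10, 5)
  p <- c(85, 60, 35, 20, 10)
  fit <- fit_predictive_from_answers(
    data.frame(threshold_mm = thr, probability_pct = p), df = 4,
    baseline = 60)
  z <- qt(p / 100, 4)
  rss <- function(m, s) sum((thr - (m + s * z))^2)
  rss_fit <- rss(fit$location + 60, fit$scale)
  grid <- expand.grid(m = seq(20, 45, by = 0.25), s = seq(5, 40, by = 0.25))
  rss_grid <- min(mapply(rss, grid$m, grid$s))
  expect_lte(rss_fit, rss_grid + 1e-9)
})
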