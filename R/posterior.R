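#' Sufficient statistics of a two-arm trial
#'
#' Under the common-variance Gaussian outcome model, a two-arm trial is
#' fully summarised by the per-arm sample sizes and mean changes from
#' baseline together with the pooled variance estimate: any two
#' individual-patient datasets sharing these values yield identical
#' posteriors.
#'
#' @param n_P,n_A Patients randomised to pamidronate / adalimumab
#'   (non-negative integers).
#' @param xbar_P,xbar_A Observed mean change from baseline per arm (mm).
#' @param s2 Pooled variance estimate (mm^2), with denominator
#'   `n_P + n_A - 2`. May be `NA` when fewer than 3 patients were observed
#'   (no residual degrees of freedom).
#' @return An object of class `"trial_summary"`.
#' @export
trial_summary <- function(n_P, n_A, xbar_P, xbar_A, s2) {
  stopifnot(length(n_P) == 1L, length(n_A) == 1L,
            is.numeric(n_P), is.numeric(n_A))
  if (n_P < 0 || n_A < 0 || n_P != round(n_P) || n_A != round(n_A))
    stop("'n_P' and 'n_A' must be non-negative integers")
  n <- n_P + n_A
  if (n_P > 0 && (!is.numeric(xbar_P) || !is.finite(xbar_P)))
    stop("'xbar_P' must be finite when n_P > 0")
  if (n_A > 0 && (!is.numeric(xbar_A) || !is.finite(xbar_A)))
    stop("'xbar_A' must be finite when n_A > 0")
  if (n >= 3) {
    if (!is.numeric(s2) || !is.finite(s2) || s2 < 0)
      stop("'s2' must be a finite non-negative variance (mm^2)")
  } else {
    s2 <- NA_real_  # no residual degrees of freedom
  }
  structure(list(n_P = as.integer(n_P), n_A = as.integer(n_A),
                 xbar_P = if (n_P > 0) as.numeric(xbar_P) else NA_real_,
                 xbar_A = if (n_A > 0) as.numeric(xbar_A) else NA_real_,
                 s2 = as.numeric(s2)),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf(paste0("Two-arm trial summary: n = %d/%d, ",
                     "xbar_P = %.2f mm, xbar_A = %.2f mm, s2 = %.2f mm^2\n"),
              x$n_P, x$n_A, x$xbar_P, x$xbar_A, x$s2))
  invisible(x)
}

#' Posterior-probability decision rule
#'
#' The trial declares evidence of a clinically relevant difference when
#' the posterior probability that one arm is beneficial on average *and*
#' superior to the other by the relative margin exceeds `prob_threshold`.
#' The margin is multiplicative on the change scale: with benefit defined
#' as a negative change, arm X is clinically superior to arm Y when
#' `mu_X <= (1 + margin) * mu_Y` (and `mu_X < 0`).
#'
#' @param margin Relative superiority margin; default 0.30.
#' @param prob_threshold Posterior-probability cutoff; default 0.2.
#' @param combine `"union"` (default) thresholds the probability that
#'   either arm is clinically superior (the two events are disjoint for
#'   `margin > 0`); `"max"` thresholds the larger of the two per-arm
#'   probabilities.
#' @return An object of class `"decision_rule"`.
#' @export
decision_rule <- function(margin = 0.30, prob_threshold = 0.2,
                          combine = c("union", "max")) {
  combine <- match.arg(combine)
  stopifnot(is.numeric(margin), length(margin) == 1L, is.finite(margin),
            is.numeric(prob_threshold), length(prob_threshold) == 1L)
  if (margin < 0) stop("'margin' must be >= 0")
  if (prob_threshold < 0 || prob_threshold > 1)
    stop("'prob_threshold' must be in [0, 1]")
  structure(list(margin = margin, prob_threshold = prob_threshold,
                 combine = combine),
            class = "decision_rule")
}

#' Conjugate update of a Normal-Gamma belief with trial summary data
#'
#' Exact Bayesian updating under the two-arm Gaussian linear model
#' `y = mu_P + delta * [arm == adalimumab] + e`, `e ~ N(0, 1/tau)`. The
#' sufficient statistics are converted to design cross-products and the
#' standard Normal-Gamma recursions applied, so the result is again an
#' [ng_belief()]:
#' `R_n = (R^-1 + X'X)^-1`, `theta_n = R_n (R^-1 theta_0 + X'y)`,
#' `a_n = a_0 + n / 2`,
#' `b_n = b_0 + (y'y + theta_0' R^-1 theta_0 - theta_n' R_n^-1 theta_n)/2`.
#' All solves use the symmetric Cholesky factorisation; `b_n` uses the
#' residual form above rather than explicit residual sums, avoiding
#' catastrophic cancellation.
#'
#' @param belief An [ng_belief()] (prior).
#' @param data A [trial_summary()].
#' @return The posterior [ng_belief()]. With `n_P = n_A = 0` the belief is
#'   returned unchanged.
#' @examples
#' prior <- calibrate_from_summaries(consensus_constraints())
#' post <- ng_update(prior, trial_summary(20, 20, -30, -30, 4.6))
#' credible_interval(post, "mu_A", 0.90)
#' @export
ng_update <- function(belief, data) {
  stopifnot(inherits(belief, "ng_belief"), inherits(data, "trial_summary"))
  n <- data$n_P + data$n_A
  if (n == 0L) return(belief)
  if (belief$degenerate)
    stop("cannot update a degenerate belief: 'R' is singular")
  xP <- if (data$n_P > 0) data$xbar_P else 0
  xA <- if (data$n_A > 0) data$xbar_A else 0
  rss <- if (n >= 3) (n - 2) * data$s2 else 0
  XtX <- matrix(c(n, data$n_A, data$n_A, data$n_A), 2L, 2L)
  Xty <- c(data$n_P * xP + data$n_A * xA, data$n_A * xA)
  yty <- rss + data$n_P * xP^2 + data$n_A * xA^2

  theta0 <- c(belief$mu_P0, belief$delta0)
  P0 <- chol2inv(chol(belief$R))
  Pn <- P0 + XtX
  Un <- chol(Pn)
  Rn <- chol2inv(Un)
  rhs <- P0 %*% theta0 + Xty
  theta_n <- backsolve(Un, backsolve(Un, rhs, transpose = TRUE))
  a_n <- belief$a0 + n / 2
  b_n <- belief$b0 + 0.5 * (yty +
    as.numeric(crossprod(theta0, P0 %*% theta0)) -
    as.numeric(crossprod(theta_n, Pn %*% theta_n)))
  if (!is.finite(b_n) || b_n <= 0)
    stop("computed posterior rate b_n is not positive: numerical failure")
  ng_belief(a0 = a_n, b0 = b_n, mu_P0 = theta_n[1], delta0 = theta_n[2],
            R = Rn)
}

#' Equal-tailed credible interval for a mean contrast
#'
#' @param belief An [ng_belief()] (typically a posterior).
#' @param contrast As in [ng_marginal()].
#' @param level Coverage in (0, 1); default 0.90.
#' @return `c(lower, upper)` in mm.
#' @export
credible_interval <- function(belief, contrast, level = 0.90) {
  st_interval(ng_marginal(belief, contrast), level)
}

#' Posterior probability of a clinically relevant difference
#'
#' Monte-Carlo evaluation of the decision rule's target probabilities
#' under the joint law of a belief: draw `tau ~ Gamma(a0, b0)`, then
#' `(mu_P, delta) ~ N((mu_P0, delta0), R / tau)` and set
#' `mu_A = mu_P + delta`. Reports
#' `p_P = P(mu_P < 0 and mu_P <= (1 + margin) mu_A)` (pamidronate
#' beneficial and clinically superior), `p_A` symmetrically, and their
#' union. For `margin > 0` the two events are disjoint (asserted on the
#' draws), so `p_union = p_P + p_A`.
#'
#' @param belief An [ng_belief()].
#' @param rule A [decision_rule()].
#' @param n_draws Number of Monte-Carlo draws; default 10000.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `p_P`, `p_A`, `p_union`, the Monte-Carlo standard
#'   error `mc_se` of `p_union`, and `n_draws`.
#' @export
prob_clinically_relevant <- function(belief, rule = decision_rule(),
                                     n_draws = 10000, seed = NULL) {
  stopifnot(inherits(belief, "ng_belief"), inherits(rule, "decision_rule"))
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 1)
    stop("'n_draws' must be a positive integer")
  n_draws <- as.integer(n_draws)
  if (!is.null(seed)) set.seed(seed)
  tau <- stats::rgamma(n_draws, shape = belief$a0, rate = belief$b0)
  L <- if (belief$degenerate) {
    # eigen square root: valid for positive semi-definite R
    e <- eigen(belief$R, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2L)
  } else t(chol(belief$R))
  z <- matrix(stats::rnorm(2L * n_draws), nrow = 2L)
  theta <- c(belief$mu_P0, belief$delta0) +
    (L %*% z) * rep(1 / sqrt(tau), each = 2L)
  mu_P <- theta[1L, ]
  mu_A <- theta[1L, ] + theta[2L, ]
  m <- rule$margin
  win_P <- mu_P < 0 & mu_P <= (1 + m) * mu_A
  win_A <- mu_A < 0 & mu_A <= (1 + m) * mu_P
  if (m > 0 && any(win_P & win_A))
    stop("internal error: superiority events overlapped at margin > 0")
  p_union <- mean(win_P | win_A)
  list(p_P = mean(win_P), p_A = mean(win_A), p_union = p_union,
       mc_se = sqrt(p_union * (1 - p_union) / n_draws), n_draws = n_draws)
}

#' Apply a decision rule to computed posterior probabilities
#'
#' @param probs Result of [prob_clinically_relevant()].
#' @param rule The [decision_rule()] used.
#' @return Logical: declare a clinically relevant difference?
#' @export
declare_difference <- function(probs, rule) {
  p <- if (rule$combine == "union") probs$p_union else max(probs$p_P, probs$p_A)
  p > rule$prob_threshold
}
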