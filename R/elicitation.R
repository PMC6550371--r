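#' One expert's elicitation answers
#'
#' Holds an expert's answers to the threshold-probability questions: for
#' each arm, the stated chance (in percent) that a typical patient --
#' presenting at baseline with a 60 mm pain score -- records a 26-week
#' score below each threshold on the 0-100 mm visual analogue scale.
#' Thresholds are asked in strictly decreasing order, so stated
#' probabilities must be non-increasing down the list. Optionally carries
#' interval weights: a histogram of belief over score intervals used to
#' cross-check the threshold answers.
#'
#' @param expert_id Label for the expert.
#' @param answers `data.frame` with columns `arm`
#'   (`"pamidronate"`/`"adalimumab"`), `question_id`, `threshold_mm`,
#'   `probability_pct` (in \[0, 100\]).
#' @param baseline_score Baseline pain score of the typical patient (mm);
#'   default 60.
#' @param interval_weights Optional `data.frame` with columns `arm`,
#'   `interval_lo_mm`, `interval_hi_mm`, `weight`; per arm the intervals
#'   must be disjoint and ordered and the weights non-negative, summing
#'   to 1.
#' @return An object of class `"answer_set"`.
#' @export
answer_set <- function(expert_id, answers, baseline_score = 60,
                       interval_weights = NULL) {
  stopifnot(length(expert_id) == 1L, is.data.frame(answers))
  need <- c("arm", "question_id", "threshold_mm", "probability_pct")
  miss <- setdiff(need, names(answers))
  if (length(miss)) stop("answers are missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(answers$arm %in% c("pamidronate", "adalimumab")))
    stop("'arm' must be \"pamidronate\" or \"adalimumab\"")
  if (any(!is.finite(answers$probability_pct)) ||
      any(answers$probability_pct < 0) || any(answers$probability_pct > 100))
    stop("probabilities must lie in [0, 100] percent")
  for (a in unique(answers$arm)) {
    sub <- answers[answers$arm == a, ]
    if (any(diff(sub$threshold_mm) >= 0))
      stop(sprintf("thresholds must be strictly decreasing in question order (arm %s)", a))
    if (any(diff(sub$probability_pct) > 0))
      stop(sprintf("probabilities must be non-increasing as thresholds decrease (arm %s)", a))
  }
  if (!is.null(interval_weights)) {
    wneed <- c("arm", "interval_lo_mm", "interval_hi_mm", "weight")
    if (!all(wneed %in% names(interval_weights)))
      stop("interval_weights are missing column(s): ",
           paste(setdiff(wneed, names(interval_weights)), collapse = ", "))
    for (a in unique(interval_weights$arm)) {
      w <- interval_weights[interval_weights$arm == a, ]
      if (any(w$weight < 0)) stop("interval weights must be non-negative")
      if (abs(sum(w$weight) - 1) > 1e-6)
        stop("interval weights must sum to 1 (arm ", a, ")")
      if (any(w$interval_hi_mm <= w$interval_lo_mm))
        stop("intervals must satisfy lo < hi")
      if (nrow(w) > 1 && any(w$interval_lo_mm[-1] < w$interval_hi_mm[-nrow(w)]))
        stop("intervals must be disjoint and ordered (arm ", a, ")")
    }
  }
  structure(list(expert_id = as.character(expert_id),
                 answers = answers[, need],
                 baseline_score = as.numeric(baseline_score),
                 interval_weights = interval_weights),
            class = "answer_set")
}

#' A panel of experts with a common question structure
#'
#' @param ... [answer_set()] objects, or a single list of them.
#' @return An object of class `"expert_panel"`.
#' @export
expert_panel <- function(...) {
  experts <- list(...)
  if (length(experts) == 1L && !inherits(experts[[1]], "answer_set"))
    experts <- experts[[1]]
  if (!length(experts)) stop("panel must contain at least one expert")
  if (!all(vapply(experts, inherits, logical(1), "answer_set")))
    stop("all panel members must be answer_set objects")
  ref <- experts[[1]]$answers[, c("arm", "question_id", "threshold_mm")]
  for (e in experts[-1]) {
    cur <- e$answers[, c("arm", "question_id", "threshold_mm")]
    if (!identical(dim(cur), dim(ref)) ||
        !all(cur$arm == ref$arm) ||
        !all(cur$question_id == ref$question_id) ||
        !all(cur$threshold_mm == ref$threshold_mm))
      stop("expert '", e$expert_id,
           "' does not share the panel's question structure")
  }
  structure(list(experts = experts), class = "expert_panel")
}

#' @export
print.expert_panel <- function(x, ...) {
  cat(sprintf("Expert panel: %d experts, %d questions each\n",
              length(x$experts), nrow(x$experts[[1]]$answers)))
  invisible(x)
}

#' Consensus answers of an expert panel
#'
#' Aggregates a panel to a single answer set, question by question, on the
#' answer scale: the consensus probability for each question is the
#' arithmetic mean (default) or median of the experts' stated
#' probabilities. Aggregating answers rather than fitted distributions is
#' the behavioural-aggregation convention: a moderated group adopts the
#' mean answers as its consensus position.
#'
#' @param panel An [expert_panel()].
#' @param method `"mean"` (default) or `"median"`.
#' @return An [answer_set()] with `expert_id = "consensus"`. Monotonicity
#'   of the aggregated probabilities is re-validated (the mean of
#'   monotone sequences is monotone).
#' @examples
#' p <- parse_answers_csv(system.file("extdata", "expert_answers.csv",
#'                                    package = "crmobayes"))
#' consensus_answers(p)$answers
#' @export
consensus_answers <- function(panel, method = c("mean", "median")) {
  stopifnot(inherits(panel, "expert_panel"))
  method <- match.arg(method)
  agg <- if (method == "mean") mean else stats::median
  probs <- vapply(panel$experts, function(e) e$answers$probability_pct,
                  numeric(nrow(panel$experts[[1]]$answers)))
  probs <- if (is.matrix(probs)) apply(probs, 1L, agg) else agg(probs)
  out <- panel$experts[[1]]$answers
  out$probability_pct <- probs
  answer_set("consensus", out,
             baseline_score = panel$experts[[1]]$baseline_score)
}

#' Fit a predictive distribution to one arm's threshold answers
#'
#' Quantile-transform regression: each answer states
#' `P(score < t_k) = p_k`, so under a Student-t predictive with `df`
#' degrees of freedom `t_k = m + s * qt(p_k / 100, df)`. Ordinary least
#' squares of the thresholds on the standard-t quantiles yields the
#' predictive location `m` (score scale) and scale `s`; the fit is exact
#' whenever the answers lie on a t CDF with the fitting `df`. Answers of
#' exactly 0% or 100% have infinite quantiles and are dropped (with a
#' message).
#'
#' @param answers `data.frame` with columns `threshold_mm` and
#'   `probability_pct` for a single arm, thresholds strictly decreasing.
#' @param df Degrees of freedom of the fitted predictive (use `2 * a0`).
#' @param baseline Baseline score (mm) subtracted to move the fit onto the
#'   change-from-baseline scale; default 60.
#' @return A [scaled_t()] on the change scale.
#' @export
fit_predictive_from_answers <- function(answers, df, baseline = 60) {
  stopifnot(is.data.frame(answers),
            all(c("threshold_mm", "probability_pct") %in% names(answers)))
  t_k <- answers$threshold_mm
  p_k <- answers$probability_pct
  if (any(diff(t_k) >= 0)) stop("thresholds must be strictly decreasing")
  if (any(diff(p_k) > 0))
    stop("probabilities must be non-increasing as thresholds decrease")
  keep <- p_k > 0 & p_k < 100
  if (any(!keep))
    message(sprintf("dropping %d answer(s) of exactly 0%% or 100%% from the fit",
                    sum(!keep)))
  t_k <- t_k[keep]; p_k <- p_k[keep]
  if (length(t_k) < 2L)
    stop("need at least two answers strictly inside (0, 100)%")
  z <- stats::qt(p_k / 100, df = df)
  fit <- stats::lm.fit(cbind(1, z), t_k)
  m <- fit$coefficients[[1]]
  s <- fit$coefficients[[2]]
  if (!is.finite(s) || s <= 0)
    stop("fitted scale is not positive: answers carry no spread ",
         "(degenerate fit)")
  scaled_t(df = df, location = m - baseline, scale = s)
}

#' Configuration for fitting a Normal-Gamma belief to a panel
#'
#' Controls the decomposition of fitted predictive variances into
#' sampling variance and parameter uncertainty. Total predictive variance
#' scale per arm is `(b0 / a0) * (1 + r_arm)`; the `sampling_variance`
#' (the `b0 / a0` part, mm^2) must therefore be smaller than both fitted
#' squared scales. The between-arm correlation `rho` of opinion about the
#' two arm means controls how much of the per-arm uncertainty cancels in
#' the treatment effect; the default 0.99 reflects a panel whose opinions
#' about the two arms move almost in lockstep, giving a treatment-effect
#' prior much narrower than either arm marginal.
#'
#' @param a0 Gamma shape (default 2); the fitting df is `2 * a0`.
#' @param sampling_variance Sampling variance `b0 / a0` (mm^2). Default
#'   `NULL`: taken from `reference_belief` when supplied, else from the
#'   shipped consensus calibration [consensus_constraints()].
#' @param rho Correlation in \[-1, 1\] between opinions on the two arm
#'   means; default 0.99.
#' @param reference_belief Optional [ng_belief()] supplying
#'   `sampling_variance = b0 / a0`.
#' @return An object of class `"panel_fit_config"`.
#' @export
panel_fit_config <- function(a0 = 2, sampling_variance = NULL, rho = 0.99,
                             reference_belief = NULL) {
  stopifnot(is.numeric(a0), length(a0) == 1L, a0 > 0,
            is.numeric(rho), length(rho) == 1L, rho >= -1, rho <= 1)
  if (is.null(sampling_variance)) {
    ref <- if (!is.null(reference_belief)) reference_belief
           else calibrate_from_summaries(consensus_constraints(a0 = a0))
    sampling_variance <- ref$b0 / ref$a0
  }
  stopifnot(is.numeric(sampling_variance), length(sampling_variance) == 1L,
            sampling_variance > 0)
  structure(list(a0 = a0, sampling_variance = sampling_variance, rho = rho),
            class = "panel_fit_config")
}

#' Fit a Normal-Gamma belief to an expert panel
#'
#' Full elicitation fit: form the panel's consensus answers, fit one
#' predictive Student-t per arm by [fit_predictive_from_answers()], then
#' decompose the fitted predictive spreads into hyperparameters. With
#' fitted per-arm locations `m_P, m_A` and scales `v_P, v_A` (change
#' scale):
#' `a0` and `b0 = a0 * sampling_variance` come from the configuration;
#' `mu_P0 = m_P`, `delta0 = m_A - m_P`;
#' `r_PP = v_P^2 / sampling_variance - 1` (floored at 0), `r_AA`
#' analogously; and the belief matrix in `(mu_P, delta)` coordinates is
#' assembled with `var(delta) = r_PP + r_AA - 2 rho sqrt(r_PP r_AA)` and
#' `cov(mu_P, delta) = rho sqrt(r_PP r_AA) - r_PP`.
#'
#' @param panel An [expert_panel()].
#' @param config A [panel_fit_config()].
#' @param method Consensus method passed to [consensus_answers()].
#' @return An [ng_belief()].
#' @export
fit_belief_from_panel <- function(panel, config = panel_fit_config(),
                                  method = "mean") {
  stopifnot(inherits(panel, "expert_panel"),
            inherits(config, "panel_fit_config"))
  cons <- consensus_answers(panel, method)
  df <- 2 * config$a0
  base <- cons$baseline_score
  fitP <- fit_predictive_from_answers(
    cons$answers[cons$answers$arm == "pamidronate", ], df, base)
  fitA <- fit_predictive_from_answers(
    cons$answers[cons$answers$arm == "adalimumab", ], df, base)
  sv <- config$sampling_variance
  if (sv >= min(fitP$scale^2, fitA$scale^2))
    stop("'sampling_variance' is at least one arm's fitted predictive ",
         "variance: no non-negative parameter-uncertainty solution")
  r_PP <- max(fitP$scale^2 / sv - 1, 0)
  r_AA <- max(fitA$scale^2 / sv - 1, 0)
  rho <- config$rho
  cross <- rho * sqrt(r_PP * r_AA)
  R <- matrix(c(r_PP, cross - r_PP,
                cross - r_PP, r_PP + r_AA - 2 * cross), 2L, 2L)
  ng_belief(a0 = config$a0, b0 = config$a0 * sv,
            mu_P0 = fitP$location, delta0 = fitA$location - fitP$location,
            R = R)
}

#' Descriptive feedback on a fitted or calibrated belief
#'
#' Emulates the summaries a facilitator feeds back to experts during
#' elicitation: per arm, predictive percentiles on both the change and
#' score scales, the chance of any improvement and of reaching milestone
#' scores; plus the treatment-effect summary (mode, 90% equal-tailed
#' interval, probability that pamidronate is superior by any margin,
#' i.e. `P(delta > 0)`).
#'
#' @param belief An [ng_belief()].
#' @param baseline Baseline score (mm); default 60.
#' @param milestones Score milestones (mm) at which `P(score <= milestone)`
#'   is reported; default `c(30, 20, 10)`.
#' @param percentiles Predictive percentiles reported; default
#'   `c(5, 25, 50, 75, 95) / 100`.
#' @return An object of class `"elicitation_report"`: a list with one
#'   element per arm (`percentiles` data.frame, `p_improvement`,
#'   `p_milestones`) and a `delta` element (`mode`, `interval_90`,
#'   `p_delta_gt_0`).
#' @export
feedback_report <- function(belief, baseline = 60, milestones = c(30, 20, 10),
                            percentiles = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  stopifnot(inherits(belief, "ng_belief"))
  arms <- c("pamidronate", "adalimumab")
  out <- lapply(arms, function(a) {
    pred <- ng_predictive(belief, a)
    qs <- st_quantile(pred, percentiles)
    stopifnot(all(diff(qs) > 0) || pred$scale == 0)
    pm <- prob_below(pred, milestones - baseline)
    names(pm) <- paste0("score_le_", milestones, "mm")
    list(predictive = pred,
         percentiles = data.frame(percentile = 100 * percentiles,
                                  change_mm = qs,
                                  score_mm = baseline + qs),
         p_improvement = prob_below(pred, 0),
         p_milestones = pm)
  })
  names(out) <- arms
  dmarg <- ng_marginal(belief, "delta")
  out$delta <- list(mode = dmarg$location,
                    interval_90 = st_interval(dmarg, 0.90),
                    p_delta_gt_0 = 1 - prob_below(dmarg, 0))
  structure(out, class = "elicitation_report")
}

#' @export
print.elicitation_report <- function(x, ...) {
  for (a in c("pamidronate", "adalimumab")) {
    cat(sprintf("\n%s (predictive for one new patient)\n", a))
    tab <- x[[a]]$percentiles
    tab$change_mm <- round(tab$change_mm, 1)
    tab$score_mm <- round(tab$score_mm, 1)
    print(tab, row.names = FALSE)
    cat(sprintf("  P(any improvement) = %.1f%%\n", 100 * x[[a]]$p_improvement))
    for (nm in names(x[[a]]$p_milestones))
      cat(sprintf("  P(%s) = %.1f%%\n", nm, 100 * x[[a]]$p_milestones[[nm]]))
  }
  cat(sprintf(paste0("\ntreatment effect delta: mode %.1f mm, ",
                     "90%% interval (%.1f, %.1f) mm, P(delta > 0) = %.1f%%\n"),
              x$delta$mode, x$delta$interval_90[1], x$delta$interval_90[2],
              100 * x$delta$p_delta_gt_0))
  invisible(x)
}

#' Consistency check of interval weights against a fitted belief
#'
#' Compares an expert's elicited histogram of belief (interval weights on
#' the 26-week score) with the bin probabilities implied by the belief's
#' predictive distribution, per arm. Agreement is measured by the total
#' variation distance over the stated bins,
#' `TV = sum(|elicited - fitted|) / 2`.
#'
#' @param answers An [answer_set()] carrying `interval_weights`.
#' @param belief An [ng_belief()].
#' @return A list per arm, each with a `bins` data.frame
#'   (`interval_lo_mm`, `interval_hi_mm`, `elicited`, `fitted`) and `tv`.
#' @export
histogram_check <- function(answers, belief) {
  stopifnot(inherits(answers, "answer_set"), inherits(belief, "ng_belief"))
  if (is.null(answers$interval_weights))
    stop("answer set carries no interval weights")
  base <- answers$baseline_score
  out <- list()
  for (a in unique(answers$interval_weights$arm)) {
    w <- answers$interval_weights[answers$interval_weights$arm == a, ]
    pred <- ng_predictive(belief, a)
    fitted <- prob_below(pred, w$interval_hi_mm - base) -
      prob_below(pred, w$interval_lo_mm - base)
    out[[a]] <- list(
      bins = data.frame(interval_lo_mm = w$interval_lo_mm,
                        interval_hi_mm = w$interval_hi_mm,
                        elicited = w$weight, fitted = fitted),
      tv = sum(abs(w$weight - fitted)) / 2)
  }
  out
}
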