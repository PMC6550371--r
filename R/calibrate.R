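#' Published prior summaries as calibration constraints
#'
#' Bundle of printed summaries of a consensus prior from which the
#' Normal-Gamma hyperparameters can be reconstructed when the fitted
#' hyperparameters themselves were not published: the per-arm prior modes,
#' an equal-tailed interval for the treatment effect, one quantile of the
#' outcome variance, and the predictive probability that a pamidronate
#' patient improves at all.
#'
#' @param mode_P Prior modal average pamidronate change (mm).
#' @param mode_A Prior modal average adalimumab change (mm).
#' @param delta_interval Equal-tailed interval `c(lo, hi)` (mm) for the
#'   treatment effect delta.
#' @param level Coverage of `delta_interval`; default 0.90.
#' @param variance_percentile `c(q, value)`: the `q`-quantile of the
#'   outcome variance equals `value` (mm^2, or mm if
#'   `variance_units = "sd"`).
#' @param improvement_prob_P Predictive probability, in (0, 1), that a new
#'   pamidronate patient's change from baseline is negative.
#' @param a0 Gamma shape held fixed during calibration (the t marginals
#'   then have `2 * a0` degrees of freedom); default 2.
#' @param variance_units `"mm2"` (default) reads the variance summary on
#'   the variance scale; `"sd"` reads it as a standard deviation in mm and
#'   squares it.
#' @return An object of class `"summary_constraints"`.
#' @seealso [calibrate_from_summaries()], [consensus_constraints()]
#' @export
summary_constraints <- function(mode_P, mode_A, delta_interval, level = 0.90,
                                variance_percentile, improvement_prob_P,
                                a0 = 2, variance_units = c("mm2", "sd")) {
  variance_units <- match.arg(variance_units)
  stopifnot(is.numeric(mode_P), length(mode_P) == 1L, is.finite(mode_P),
            is.numeric(mode_A), length(mode_A) == 1L, is.finite(mode_A),
            is.numeric(delta_interval), length(delta_interval) == 2L,
            all(is.finite(delta_interval)),
            is.numeric(level), length(level) == 1L, level > 0, level < 1,
            is.numeric(variance_percentile), length(variance_percentile) == 2L,
            is.numeric(improvement_prob_P), length(improvement_prob_P) == 1L,
            is.numeric(a0), length(a0) == 1L, a0 > 0)
  if (delta_interval[1] >= delta_interval[2])
    stop("'delta_interval' must satisfy lo < hi")
  q <- variance_percentile[1]
  if (q <= 0 || q >= 1) stop("variance percentile level must be in (0, 1)")
  if (variance_percentile[2] <= 0) stop("variance percentile value must be > 0")
  if (improvement_prob_P <= 0 || improvement_prob_P >= 1)
    stop("'improvement_prob_P' must be in (0, 1)")
  structure(list(mode_P = mode_P, mode_A = mode_A,
                 delta_interval = as.numeric(delta_interval), level = level,
                 variance_percentile = as.numeric(variance_percentile),
                 improvement_prob_P = improvement_prob_P, a0 = a0,
                 variance_units = variance_units),
            class = "summary_constraints")
}

#' Constraints describing the reported consensus prior
#'
#' The summaries fed back to (and accepted by) the expert panel: prior
#' modes of -32.3 mm (pamidronate) and -30 mm (adalimumab); a 90% chance
#' that the treatment effect lies between -6.9 and 11.5 mm; 4.6 mm^2 as
#' the 75th percentile of the outcome-variance prior; and an 84.2%
#' consensus chance that a typical pamidronate patient improves at all.
#'
#' @inheritParams summary_constraints
#' @return A [summary_constraints()] object.
#' @export
consensus_constraints <- function(a0 = 2, variance_units = "mm2") {
  summary_constraints(mode_P = -32.3, mode_A = -30,
                      delta_interval = c(-6.9, 11.5), level = 0.90,
                      variance_percentile = c(0.75, 4.6),
                      improvement_prob_P = 0.842,
                      a0 = a0, variance_units = variance_units)
}

#' Reconstruct Normal-Gamma hyperparameters from published summaries
#'
#' Inverts the printed summaries of a consensus prior into the
#' hyperparameters of an [ng_belief()]:
#'
#' * `a0` is held at its configured value;
#' * `b0 = value * qgamma(1 - q, a0, rate = 1)` from the variance quantile;
#' * `mu_P0` and `delta0` come from the per-arm modes (t marginals are
#'   symmetric, so mode = location);
#' * the delta diagonal of `R` matches the half-width of the equal-tailed
#'   delta interval;
#' * the `mu_P` diagonal is solved so the pamidronate predictive
#'   distribution assigns the stated probability to any improvement.
#'
#' `R` is diagonal: nothing in the published summaries identifies the
#' prior correlation between `mu_P` and `delta`.
#'
#' @param constraints A [summary_constraints()] object.
#' @return An [ng_belief()] satisfying the constraints; the prior
#'   probability `P(delta > 0)` is *not* used and serves as a held-out
#'   check.
#' @examples
#' prior <- calibrate_from_summaries(consensus_constraints())
#' variance_quantile(prior, 0.75)           # 4.6 mm^2 by construction
#' st_interval(ng_marginal(prior, "delta")) # (-6.9, 11.5) mm
#' 1 - prob_below(ng_marginal(prior, "delta"), 0) # held-out: ~0.684
#' @export
calibrate_from_summaries <- function(constraints) {
  stopifnot(inherits(constraints, "summary_constraints"))
  cs <- constraints
  a0 <- cs$a0
  df <- 2 * a0
  vval <- cs$variance_percentile[2]
  if (cs$variance_units == "sd") vval <- vval^2
  b0 <- vval * stats::qgamma(1 - cs$variance_percentile[1],
                             shape = a0, rate = 1)
  mu_P0 <- cs$mode_P
  delta0 <- cs$mode_A - cs$mode_P

  half <- diff(cs$delta_interval) / 2
  if (half <= 0) stop("'delta_interval' has zero width: R would be degenerate")
  mid <- mean(cs$delta_interval)
  if (abs(mid - delta0) > 0.05 + 1e-9)
    warning(sprintf(paste0("delta interval midpoint (%.3f) differs from ",
                           "mode_A - mode_P (%.3f); the interval half-width ",
                           "is used as stated"), mid, delta0))
  tq <- stats::qt(1 - (1 - cs$level) / 2, df = df)
  r_dd <- (half / tq)^2 / (b0 / a0)

  # Pamidronate predictive: P(change < 0) = p  <=>  -mu_P0 / s = qt(p, df),
  # with s^2 = (b0 / a0) (1 + r11). Solvable iff sign(mu_P0) != sign(qt(p)).
  zp <- stats::qt(cs$improvement_prob_P, df = df)
  s_pred <- -mu_P0 / zp
  if (!is.finite(s_pred) || s_pred <= 0)
    stop("'improvement_prob_P' is inconsistent with the sign of 'mode_P': ",
         "no positive predictive scale exists")
  r11 <- s_pred^2 / (b0 / a0) - 1
  if (r11 <= 0)
    stop("'improvement_prob_P' implies a predictive scale no larger than ",
         "the sampling scale: no positive r11 solution")
  ng_belief(a0 = a0, b0 = b0, mu_P0 = mu_P0, delta0 = delta0,
            R = diag(c(r11, r_dd)))
}

#' Extract calibration summaries from a belief
#'
#' Inverse companion to [calibrate_from_summaries()]: reads the summary
#' constraints back off a belief, so that calibrating the result returns
#' the same hyperparameters (used as a self-consistency check).
#'
#' @param belief An [ng_belief()].
#' @param level Coverage of the reported delta interval; default 0.90.
#' @param q Variance percentile level; default 0.75.
#' @return A [summary_constraints()] object.
#' @export
extract_constraints <- function(belief, level = 0.90, q = 0.75) {
  stopifnot(inherits(belief, "ng_belief"))
  summary_constraints(
    mode_P = belief$mu_P0,
    mode_A = belief$mu_P0 + belief$delta0,
    delta_interval = st_interval(ng_marginal(belief, "delta"), level),
    level = level,
    variance_percentile = c(q, variance_quantile(belief, q)),
    improvement_prob_P = prob_below(ng_predictive(belief, "pamidronate"), 0),
    a0 = belief$a0)
}
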