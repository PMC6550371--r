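#' Normal-Gamma opinion model for a two-arm trial
#'
#' Represents prior (or posterior) opinion about the three unknowns of the
#' trial's Gaussian outcome model: the average pamidronate change from
#' baseline `mu_P` (mm), the treatment effect `delta = mu_A - mu_P` (mm,
#' negative favouring adalimumab), and the outcome precision `tau`
#' (reciprocal of the common variance across arms). The model is conjugate:
#'
#' * `tau ~ Gamma(a0, b0)` (shape/rate), and
#' * given `tau`, `(mu_P, delta) ~ N((mu_P0, delta0), R / tau)`,
#'
#' so updating with trial data returns a belief of the same form. The same
#' class therefore represents opinion both before and after a trial.
#'
#' @param a0 Gamma shape (> 0, dimensionless). The implied t marginals
#'   have `2 * a0` degrees of freedom.
#' @param b0 Gamma rate (> 0, mm^2).
#' @param mu_P0 Location of the average pamidronate change (mm).
#' @param delta0 Location of the treatment effect (mm).
#' @param R Symmetric positive-definite 2x2 matrix (dimensionless) scaling
#'   the conditional covariance `R / tau` of `(mu_P, delta)`.
#' @param degenerate If `TRUE`, accept a positive semi-definite `R`
#'   (representing certainty about some linear combination of the means).
#'   Default `FALSE`: a non-positive-definite `R` is an error.
#'
#' @return An object of class `"ng_belief"`.
#' @examples
#' b <- ng_belief(a0 = 1, b0 = 1, mu_P0 = 0, delta0 = 0, R = diag(2))
#' ng_marginal(b, "delta")
#' @export
ng_belief <- function(a0, b0, mu_P0, delta0, R, degenerate = FALSE) {
  stopifnot(is.numeric(a0), length(a0) == 1L, is.finite(a0),
            is.numeric(b0), length(b0) == 1L, is.finite(b0),
            is.numeric(mu_P0), length(mu_P0) == 1L, is.finite(mu_P0),
            is.numeric(delta0), length(delta0) == 1L, is.finite(delta0),
            is.matrix(R), all(dim(R) == c(2L, 2L)), all(is.finite(R)))
  if (a0 <= 0) stop("'a0' must be > 0")
  if (b0 <= 0) stop("'b0' must be > 0")
  if (max(abs(R - t(R))) > 1e-8 * max(1, max(abs(R))))
    stop("'R' must be symmetric")
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-12 * max(1, max(abs(R)))
  if (min(ev) < -tol || (!degenerate && min(ev) <= tol))
    stop("'R' must be positive definite (set degenerate = TRUE to allow ",
         "a positive semi-definite matrix)")
  structure(list(a0 = as.numeric(a0), b0 = as.numeric(b0),
                 mu_P0 = as.numeric(mu_P0), delta0 = as.numeric(delta0),
                 R = unname(R), degenerate = isTRUE(degenerate)),
            class = "ng_belief")
}

#' @export
print.ng_belief <- function(x, ...) {
  cat("Normal-Gamma belief about (mu_P, delta, tau)\n")
  cat(sprintf("  tau ~ Gamma(a0 = %.6g, b0 = %.6g mm^2)\n", x$a0, x$b0))
  cat(sprintf("  (mu_P, delta) | tau ~ N((%.6g, %.6g) mm, R / tau)\n",
              x$mu_P0, x$delta0))
  cat(sprintf("  R = [%.6g %.6g; %.6g %.6g]\n",
              x$R[1, 1], x$R[1, 2], x$R[2, 1], x$R[2, 2]))
  invisible(x)
}

# Resolve "mu_P" / "delta" / "mu_A" or a numeric 2-vector into a contrast.
resolve_contrast <- function(contrast) {
  if (is.character(contrast)) {
    contrast <- match.arg(contrast, c("mu_P", "delta", "mu_A"))
    return(switch(contrast, mu_P = c(1, 0), delta = c(0, 1), mu_A = c(1, 1)))
  }
  if (!is.numeric(contrast) || length(contrast) != 2L ||
      any(!is.finite(contrast)))
    stop("'contrast' must be a finite numeric 2-vector or one of ",
         "\"mu_P\", \"delta\", \"mu_A\"")
  as.numeric(contrast)
}

#' Marginal distribution of a linear combination of the mean parameters
#'
#' Integrating the precision `tau` out of a Normal-Gamma belief makes any
#' linear combination `c' (mu_P, delta)` a location-scale Student-t with
#' `2 * a0` degrees of freedom, location `c' (mu_P0, delta0)` and scale
#' `sqrt((b0 / a0) * c' R c)`.
#'
#' @param belief An [ng_belief()].
#' @param contrast Numeric 2-vector, or one of `"mu_P"` (`c(1, 0)`),
#'   `"delta"` (`c(0, 1)`), `"mu_A"` (`c(1, 1)`).
#' @return A [scaled_t()].
#' @export
ng_marginal <- function(belief, contrast) {
  stopifnot(inherits(belief, "ng_belief"))
  cvec <- resolve_contrast(contrast)
  q <- as.numeric(crossprod(cvec, belief$R %*% cvec))
  if (q < -1e-12 * max(1, max(abs(belief$R))))
    stop("contrast' R contrast < 0: 'R' is not a valid covariance scale")
  scaled_t(df = 2 * belief$a0,
           location = sum(cvec * c(belief$mu_P0, belief$delta0)),
           scale = sqrt((belief$b0 / belief$a0) * max(q, 0)))
}

#' Predictive distribution for a single future patient
#'
#' The change from baseline of one new patient randomised to an arm mixes
#' sampling variability (variance `1 / tau`) with parameter uncertainty,
#' yielding a Student-t with `2 * a0` degrees of freedom and scale
#' `sqrt((b0 / a0) * (1 + c' R c))`, where the contrast `c` is `(1, 0)` for
#' pamidronate and `(1, 1)` for adalimumab. Negative values mean
#' improvement.
#'
#' @param belief An [ng_belief()].
#' @param arm `"pamidronate"` or `"adalimumab"`.
#' @return A [scaled_t()] on the change-from-baseline scale (mm).
#' @export
ng_predictive <- function(belief, arm = c("pamidronate", "adalimumab")) {
  stopifnot(inherits(belief, "ng_belief"))
  arm <- match.arg(arm)
  cvec <- if (arm == "pamidronate") c(1, 0) else c(1, 1)
  q <- as.numeric(crossprod(cvec, belief$R %*% cvec))
  scaled_t(df = 2 * belief$a0,
           location = sum(cvec * c(belief$mu_P0, belief$delta0)),
           scale = sqrt((belief$b0 / belief$a0) * (1 + max(q, 0))))
}

#' Quantile of the outcome variance
#'
#' The belief puts `tau ~ Gamma(a0, b0)` on the outcome precision, so the
#' outcome variance `1 / tau` has q-quantile
#' `b0 / qgamma(1 - q, shape = a0, rate = 1)`.
#'
#' @param belief An [ng_belief()].
#' @param q Probability in (0, 1).
#' @return Variance quantile in mm^2.
#' @export
variance_quantile <- function(belief, q) {
  stopifnot(inherits(belief, "ng_belief"), is.numeric(q), length(q) == 1L)
  if (!is.finite(q) || q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
  belief$b0 / stats::qgamma(1 - q, shape = belief$a0, rate = 1)
}
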