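#' Location-scale Student-t distribution
#'
#' Light-weight container for a location-scale Student-t law, the
#' distribution family of every parameter marginal and patient predictive
#' distribution implied by a Normal-Gamma belief. A zero scale is permitted
#' and denotes a degenerate point mass at the location.
#'
#' @param df Degrees of freedom; a single positive number.
#' @param location Location in mm (on either the score or the
#'   change-from-baseline scale, depending on context).
#' @param scale Scale in mm; non-negative.
#'
#' @return An object of class `"scaled_t"` with elements `df`, `location`
#'   and `scale`.
#' @examples
#' d <- scaled_t(df = 4, location = 2.3, scale = 4.3)
#' prob_below(d, 0)
#' st_interval(d, 0.90)
#' @export
scaled_t <- function(df, location = 0, scale = 1) {
  stopifnot(is.numeric(df), length(df) == 1L, is.finite(df), df > 0,
            is.numeric(location), length(location) == 1L, is.finite(location),
            is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (scale < 0) stop("'scale' must be >= 0")
  structure(list(df = as.numeric(df), location = as.numeric(location),
                 scale = as.numeric(scale)),
            class = "scaled_t")
}

#' @export
print.scaled_t <- function(x, ...) {
  cat(sprintf("Student-t(df = %g, location = %.4g mm, scale = %.4g mm)\n",
              x$df, x$location, x$scale))
  invisible(x)
}

#' Cumulative probability of a location-scale t
#'
#' Evaluates P(X <= x) for a [scaled_t()] distribution. For a degenerate
#' (zero-scale) distribution the CDF is the step function at the location.
#'
#' @param dist A [scaled_t()] object.
#' @param x Numeric vector of evaluation points (mm); must be finite.
#' @return Probabilities in \[0, 1\], same length as `x`.
#' @export
prob_below <- function(dist, x) {
  stopifnot(inherits(dist, "scaled_t"), is.numeric(x))
  if (any(!is.finite(x))) stop("'x' must be finite")
  if (dist$scale == 0) return(as.numeric(x >= dist$location))
  stats::pt((x - dist$location) / dist$scale, df = dist$df)
}

#' Quantiles of a location-scale t
#'
#' @param dist A [scaled_t()] object.
#' @param p Probabilities in (0, 1).
#' @return Quantiles in mm.
#' @export
st_quantile <- function(dist, p) {
  stopifnot(inherits(dist, "scaled_t"), is.numeric(p), all(p > 0), all(p < 1))
  dist$location + dist$scale * stats::qt(p, df = dist$df)
}

#' Equal-tailed interval of a location-scale t
#'
#' Returns the central interval leaving probability `(1 - level) / 2` in
#' each tail. For a degenerate distribution both endpoints equal the
#' location.
#'
#' @param dist A [scaled_t()] object.
#' @param level Coverage level in (0, 1); default 0.90.
#' @return Numeric vector `c(lower, upper)` in mm.
#' @export
st_interval <- function(dist, level = 0.90) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  if (dist$scale == 0) return(c(dist$location, dist$location))
  alpha <- (1 - level) / 2
  st_quantile(dist, c(alpha, 1 - alpha))
}
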