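#' Deterministic RNG substream seeds
#'
#' Derives a reproducible 31-bit seed for a named substream (e.g. one
#' expert, one simulated trial) from a master seed, so each component of
#' a simulation can be regenerated independently.
#'
#' @param master Master seed (integer).
#' @param stream Substream name, e.g. `"experts"`, `"patients"`.
#' @param k Index or vector of indices within the substream.
#' @return Integer seed(s) in `[1, 2^31 - 1)`.
#' @keywords internal
#' @export
substream_seed <- function(master, stream, k) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  # exact in double arithmetic: all terms < 2^53
  val <- ((abs(master) %% 2147483647) * 48271 + h * 69621 + k * 16807) %%
    2147483562
  as.integer(val) + 1L
}

#' Specification of a synthetic expert panel
#'
#' Describes how to generate an expert panel whose answers are noisy,
#' rounded evaluations of a known Student-t predictive CDF per arm --
#' the structure the elicitation fit assumes. Each expert perturbs the
#' true predictive location (additive Gaussian noise scaled by the
#' predictive scale) and log-scale, evaluates the perturbed CDF at the
#' question thresholds, rounds to a percent grid (real panels answer
#' predominantly in multiples of 5), and restores monotonicity.
#'
#' @param pred_P,pred_A True predictive distributions per arm as
#'   [scaled_t()] objects on the *score* scale (mm).
#' @param n_experts Number of experts; >= 1.
#' @param probit_noise_sd Standard deviation of the location/log-scale
#'   perturbations (location noise is `probit_noise_sd * scale` mm);
#'   >= 0.
#' @param rounding_grid Percent grid to round answers to (must divide
#'   100); 0 disables rounding. Default 5.
#' @param thresholds Question thresholds (mm), strictly decreasing;
#'   default `c(60, 30, 20, 10, 5)`.
#' @param baseline Baseline score (mm); default 60.
#' @param seed Master seed.
#' @return An object of class `"panel_generator_spec"`.
#' @export
panel_generator_spec <- function(pred_P, pred_A, n_experts = 13,
                                 probit_noise_sd = 0.1, rounding_grid = 5,
                                 thresholds = c(60, 30, 20, 10, 5),
                                 baseline = 60, seed = 1) {
  stopifnot(inherits(pred_P, "scaled_t"), inherits(pred_A, "scaled_t"),
            is.numeric(n_experts), n_experts >= 1,
            is.numeric(probit_noise_sd), probit_noise_sd >= 0,
            is.numeric(rounding_grid), rounding_grid >= 0,
            is.numeric(thresholds), length(thresholds) >= 2L)
  if (any(diff(thresholds) >= 0))
    stop("'thresholds' must be strictly decreasing")
  if (rounding_grid > 0 && (100 %% rounding_grid) != 0)
    stop("'rounding_grid' must divide 100")
  structure(list(pred_P = pred_P, pred_A = pred_A,
                 n_experts = as.integer(n_experts),
                 probit_noise_sd = probit_noise_sd,
                 rounding_grid = rounding_grid,
                 thresholds = as.numeric(thresholds),
                 baseline = as.numeric(baseline), seed = seed),
            class = "panel_generator_spec")
}

# Round to the percent grid, clamp, and restore monotonicity by a
# pool-adjacent-violators (isotonic) adjustment.
tidy_answers <- function(p, grid) {
  if (grid > 0) p <- round(p / grid) * grid
  p <- pmin(pmax(p, 0), 100)
  if (any(diff(p) > 0)) {           # thresholds decrease, so p must too
    iso <- stats::isoreg(rev(p))$yf # PAVA on the reversed (increasing) order
    p <- rev(iso)
    if (grid > 0) p <- round(p / grid) * grid
    p <- rev(cummax(rev(p)))        # rounding cannot be allowed to re-break it
  }
  p
}

#' Generate a synthetic expert panel
#'
#' @param spec A [panel_generator_spec()].
#' @return An [expert_panel()], deterministic given `spec$seed`.
#' @examples
#' truthP <- scaled_t(4, 30, 20)  # score scale
#' truthA <- scaled_t(4, 32, 22)
#' spec <- panel_generator_spec(truthP, truthA, n_experts = 5, seed = 7)
#' generate_expert_panel(spec)
#' @export
generate_expert_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_generator_spec"))
  arms <- list(pamidronate = spec$pred_P, adalimumab = spec$pred_A)
  qids <- list(pamidronate = paste0("QP", seq_along(spec$thresholds)),
               adalimumab = paste0("QA", seq_along(spec$thresholds)))
  experts <- vector("list", spec$n_experts)
  for (e in seq_len(spec$n_experts)) {
    set.seed(substream_seed(spec$seed, "experts", e))
    rows <- lapply(names(arms), function(a) {
      truth <- arms[[a]]
      loc <- truth$location +
        stats::rnorm(1, 0, spec$probit_noise_sd * truth$scale)
      scl <- truth$scale * exp(stats::rnorm(1, 0, spec$probit_noise_sd))
      p <- 100 * stats::pt((spec$thresholds - loc) / scl, df = truth$df)
      data.frame(arm = a, question_id = qids[[a]],
                 threshold_mm = spec$thresholds,
                 probability_pct = tidy_answers(p, spec$rounding_grid))
    })
    experts[[e]] <- answer_set(sprintf("synthetic_%02d", e),
                               do.call(rbind, rows),
                               baseline_score = spec$baseline)
  }
  expert_panel(experts)
}

#' Generate individual patient changes from baseline
#'
#' Draws Gaussian change-from-baseline outcomes per arm under the
#' common-variance outcome model.
#'
#' @param params A [model_parameters()] object.
#' @param n_per_arm Patients per arm (integer >= 1).
#' @param seed Master seed.
#' @return A `data.frame` with columns `patient_id`, `arm`, `change_mm`;
#'   deterministic given `seed`.
#' @export
generate_patient_data <- function(params, n_per_arm, seed = 1) {
  stopifnot(inherits(params, "model_parameters"))
  if (!is.numeric(n_per_arm) || length(n_per_arm) != 1L || n_per_arm < 1 ||
      n_per_arm != round(n_per_arm))
    stop("'n_per_arm' must be an integer >= 1")
  set.seed(substream_seed(seed, "patients", 1L))
  data.frame(
    patient_id = sprintf("pt%03d", seq_len(2 * n_per_arm)),
    arm = rep(c("pamidronate", "adalimumab"), each = n_per_arm),
    change_mm = c(stats::rnorm(n_per_arm, params$mu_P, params$sigma),
                  stats::rnorm(n_per_arm, params$mu_A, params$sigma)))
}

#' Summarise patient records into trial sufficient statistics
#'
#' @param records `data.frame` with columns `arm` and `change_mm` (as
#'   produced by [generate_patient_data()]).
#' @return A [trial_summary()] with pooled variance denominator
#'   `n_P + n_A - 2`.
#' @examples
#' recs <- data.frame(arm = rep(c("pamidronate", "adalimumab"), each = 2),
#'                    change_mm = c(-30, -20, -10, 0))
#' summarize_patients(recs)  # xbar_P = -25, xbar_A = -5, s2 = 25
#' @export
summarize_patients <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("arm", "change_mm") %in% names(records)))
  if (!nrow(records)) stop("no patient records")
  yP <- records$change_mm[records$arm == "pamidronate"]
  yA <- records$change_mm[records$arm == "adalimumab"]
  n <- length(yP) + length(yA)
  s2 <- if (n >= 3) {
    (sum((yP - mean(yP))^2) + sum((yA - mean(yA))^2)) / (n - 2)
  } else NA_real_
  trial_summary(length(yP), length(yA),
                if (length(yP)) mean(yP) else NA_real_,
                if (length(yA)) mean(yA) else NA_real_, s2)
}
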