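#' Read an expert panel from an answers CSV
#'
#' The answers CSV has one row per answer with header columns
#' `expert_id`, `arm` (`pamidronate`/`adalimumab`), `question_id`,
#' `threshold_mm`, `probability_pct`. Row order is irrelevant; duplicate
#' `(expert, arm, question)` rows are rejected; validation errors name
#' the offending column, row or expert.
#'
#' @param path Path to the CSV file.
#' @param baseline_score Baseline score attached to every expert (mm);
#'   default 60.
#' @return An [expert_panel()].
#' @examples
#' path <- system.file("extdata", "expert_answers.csv", package = "crmobayes")
#' panel <- parse_answers_csv(path)
#' length(panel$experts)
#' @export
parse_answers_csv <- function(path, baseline_score = 60) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "arm", "question_id", "threshold_mm",
            "probability_pct")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("answers CSV is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(raw$probability_pct) | raw$probability_pct < 0 |
                 raw$probability_pct > 100)
  if (length(bad))
    stop("probability outside [0, 100] at row(s): ",
         paste(bad, collapse = ", "))
  key <- paste(raw$expert_id, raw$arm, raw$question_id)
  if (anyDuplicated(key))
    stop("duplicate (expert, arm, question) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  experts <- lapply(split(raw, factor(raw$expert_id,
                                      levels = unique(raw$expert_id))),
                    function(d) {
    # restore question order: within arm, thresholds strictly decreasing
    d <- d[order(match(d$arm, c("pamidronate", "adalimumab")),
                 -d$threshold_mm), ]
    tryCatch(
      answer_set(d$expert_id[1],
                 d[, c("arm", "question_id", "threshold_mm",
                       "probability_pct")],
                 baseline_score = baseline_score),
      error = function(e) stop("expert '", d$expert_id[1], "': ",
                               conditionMessage(e), call. = FALSE))
  })
  expert_panel(unname(experts))
}

#' Write an expert panel (or single answer set) to CSV
#'
#' @param x An [expert_panel()] or [answer_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_answers_csv <- function(x, path) {
  sets <- if (inherits(x, "expert_panel")) x$experts
          else if (inherits(x, "answer_set")) list(x)
          else stop("'x' must be an expert_panel or answer_set")
  rows <- do.call(rbind, lapply(sets, function(e)
    cbind(expert_id = e$expert_id, e$answers)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a Normal-Gamma belief to JSON
#'
#' Writes the hyperparameters at full double precision, so that a
#' write/read round trip is lossless.
#'
#' @param belief An [ng_belief()].
#' @param path Output path.
#' @param source Free-text provenance stored in the metadata.
#' @return `path`, invisibly.
#' @export
write_belief_json <- function(belief, path, source = "crmobayes") {
  stopifnot(inherits(belief, "ng_belief"))
  obj <- list(a0 = belief$a0, b0 = belief$b0, mu_P0 = belief$mu_P0,
              delta0 = belief$delta0,
              R = lapply(1:2, function(i) belief$R[i, ]),
              meta = list(source = source,
                          created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                          units = "mm"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a Normal-Gamma belief from JSON
#'
#' @param path Path written by [write_belief_json()].
#' @return An [ng_belief()].
#' @export
read_belief_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- if (is.matrix(obj$R)) obj$R else do.call(rbind, obj$R)
  ng_belief(a0 = obj$a0, b0 = obj$b0, mu_P0 = obj$mu_P0,
            delta0 = obj$delta0, R = R)
}

#' Read named trial summaries from JSON
#'
#' The file holds an object of named entries, each with fields `n_P`,
#' `n_A`, `xbar_P_mm`, `xbar_A_mm`, `s2_mm2`.
#'
#' @param path Path to the JSON file.
#' @return Named list of [trial_summary()] objects.
#' @examples
#' path <- system.file("extdata", "hypothetical_datasets.json",
#'                     package = "crmobayes")
#' read_trial_summaries_json(path)
#' @export
read_trial_summaries_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(d)
    trial_summary(d$n_P, d$n_A, d$xbar_P_mm, d$xbar_A_mm, d$s2_mm2))
}

#' Write named trial summaries to JSON
#'
#' @param summaries Named list of [trial_summary()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_summaries_json <- function(summaries, path) {
  obj <- lapply(summaries, function(d)
    list(n_P = d$n_P, n_A = d$n_A, xbar_P_mm = d$xbar_P,
         xbar_A_mm = d$xbar_A, s2_mm2 = d$s2))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read simulation scenarios from YAML
#'
#' Each YAML entry carries `label`, `mu_P_mm`, `mu_A_mm`, `sigma_mm` and
#' optionally `n_per_arm` (default 20).
#'
#' @param path Path to the YAML file.
#' @param n_per_arm Default patients per arm for entries that omit it.
#' @return List of [scenario()] objects.
#' @examples
#' path <- system.file("extdata", "trial_scenarios.yaml",
#'                     package = "crmobayes")
#' length(read_scenarios_yaml(path))
#' @export
read_scenarios_yaml <- function(path, n_per_arm = 20) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) {
    need <- c("label", "mu_P_mm", "mu_A_mm", "sigma_mm")
    miss <- setdiff(need, names(s))
    if (length(miss))
      stop("scenario entry missing field(s): ", paste(miss, collapse = ", "))
    scenario(s$label, model_parameters(s$mu_P_mm, s$mu_A_mm, s$sigma_mm),
             n_per_arm = if (!is.null(s$n_per_arm)) s$n_per_arm else n_per_arm)
  })
}
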