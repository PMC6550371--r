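# shared fixtures built in code

consensus_prior <- function() calibrate_from_summaries(consensus_constraints())

fixture_path <- function(f) system.file("extdata", f, package = "crmobayes")

hypo_datasets <- function()
  read_trial_summaries_json(fixture_path("hypothetical_datasets.json"))

fixture_panel <- function() parse_answers_csv(fixture_path("expert_answers.csv"))

# build a one-expert answer set from two probability vectors (percent),
# ordered along strictly decreasing thresholds
make_answers <- function(id, pP, pA, thr = c(60, 30, 20, 10, 5),
                         baseline = 60) {
  answer_set(id, data.frame(
    arm = rep(c("pamidronate", "adalimumab"), each = length(thr)),
    question_id = c(paste0("QP", seq_along(thr)), paste0("QA", seq_along(thr))),
    threshold_mm = rep(thr, 2),
    probability_pct = c(pP, pA)), baseline_score = baseline)
}
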