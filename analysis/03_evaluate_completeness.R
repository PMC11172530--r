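#!/usr/bin/env Rscript
# Step 3 — survey-based data-completeness and concordance evaluation.
#
# Uses the shipped machine-readable transcription of the point-of-care
# survey (10 dermatooncologists; 9 after one drop-out): per-parameter
# relevance percentages are banded (less / moderate / high), matched
# against the algorithm's explicit and implicit parameter usage, and turned
# into per-decision-point completeness rates; the simulation's next-step
# choices are scored against the clinicians' per-option response counts.

suppressPackageStartupMessages(library(melpathsim))

survey <- make_survey_fixture()
report <- completeness_report(survey)
conc <- concordance(survey)
dir.create("results", showWarnings = FALSE)
write_evaluation_report(report, conc, "results")

message("completeness per decision point (excl. / incl. implicit usage):")
for (i in seq_len(nrow(report)))
  message(sprintf("  %-5s %5.1f%% / %5.1f%%  (%d highly relevant, %d mismatched)",
                  report$dp[i], report$rate_excluding_implicit[i],
                  report$rate_including_implicit[i],
                  report$n_highly_relevant[i], report$n_mismatched[i]))
message("discrepancies (highly relevant at point of care, unused in the algorithm):")
for (dp in report$dp) {
  mm <- mismatch_set(survey, dp)
  message(sprintf("  %-5s %s", dp,
                  if (length(mm)) paste(mm, collapse = ", ") else "-"))
}
cs <- concordance_summary(conc)
message("next-step concordance:")
for (i in seq_len(nrow(cs)))
  message(sprintf("  %-5s %d/%d options agree%s", cs$dp[i],
                  cs$n_options[i] - cs$n_mismatched[i], cs$n_options[i],
                  if (cs$n_mismatched[i])
                    paste0(" (flagged: ", cs$mismatched_options[i], ")") else ""))
message("reports written to results/evaluation.json and results/evaluation.md")
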