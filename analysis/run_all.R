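#!/usr/bin/env Rscript
# Runs the whole analysis in order. Equivalent to
# melpathsim::run_pipeline("results"), but step by step with narration.
for (f in c("analysis/01_synthesize_cohort.R",
            "analysis/02_simulate_pathway.R",
            "analysis/03_evaluate_completeness.R")) {
  message("== ", f, " ==")
  source(f)
}
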