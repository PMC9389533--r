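# Shared settings for the analysis scripts. Each numbered script can be run
# on its own from the repository root; the cohort is regenerated
# deterministically from MASTER_SEED wherever it is needed, so no bulky
# intermediate has to survive between scripts.

library(ttroi)

MASTER_SEED <- 117L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

get_cohort <- function() simulate_cohort(default_cohort(), default_params(),
                                         seed = MASTER_SEED)
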