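# Shared configuration for the analysis drivers: the synthetic cohort is
# regenerated deterministically from this seed in every script, so each
# driver is independently runnable and the whole workflow is reproducible
# end to end.
library(cralekit)

COHORT_SEED <- 42L
N_ANIMALS <- 5L
TIMELINE <- cohort_timeline(epoch_s = 300, n_epochs = 5L) # 25 min of CPR
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

make_cohort <- function() gen_cohort(N_ANIMALS, TIMELINE, seed = COHORT_SEED)
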