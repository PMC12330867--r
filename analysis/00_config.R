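# Shared configuration for the analysis scripts. Every script regenerates the
# synthetic cohort deterministically from this seed, so the scripts can be run
# independently and in any order.

library(cineflow)

COHORT_SEED <- 20260923
N_YOUNG <- 7
N_OLD <- 7
RESULTS_DIR <- "results"

dir.create(RESULTS_DIR, showWarnings = FALSE)

load_cohort <- function() {
  make_cohort(N_YOUNG, N_OLD, seed = COHORT_SEED)
}
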