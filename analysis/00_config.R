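# Shared settings for the numbered analysis scripts: one seeded
# cross-tissue study configuration and the output location. Each script
# can be run on its own; stages re-derive the (cheap, fully seeded)
# simulated data instead of round-tripping it through files.

suppressMessages(library(epiconcord))
suppressMessages(library(data.table))

ANALYSIS_SEED <- 101L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# the worked study: two tissues x two sexes x two exposures, n = 6 per
# group, strong planted effects so the comparison layer is measured at
# near-saturated calling (see the methods vignette)
analysis_config <- function(seed = ANALYSIS_SEED) scenario_config(seed)
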