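# Shared setup for the analysis drivers: one seed, one output directory,
# and the study conditions (64 taxa, 150 columns, 7 planted core positions,
# function-coded core over a kingdom-structured background).
suppressPackageStartupMessages(library(trefoilscan))

SEED <- 20260925L
RESULTS <- file.path("results", "analysis")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

study_template <- function() make_template_structure(150, SEED + 1L)

study_family <- function(core_signal = "function") {
  evolve_family(study_template(),
                simulation_config(seed = SEED, core_signal = core_signal))
}
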