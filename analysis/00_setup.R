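# Shared setup for the analysis scripts: study-scale synthetic dataset
# (200 kb genome, 60 planted sRNAs, 2 conditions x 3 replicates) and paths.
# Each numbered script sources this file; the dataset and the pipeline result
# are cached under scratch/ so the chain can be re-entered at any step.

suppressPackageStartupMessages(library(srnascape))

RESULTS <- "results"
SCRATCH <- "scratch"
dir.create(RESULTS, showWarnings = FALSE)
dir.create(SCRATCH, showWarnings = FALSE)

STUDY_SEED <- 20260920
study_config <- synthetic_config(seed = STUDY_SEED)

study_dataset <- function() {
  f <- file.path(SCRATCH, "dataset.rds")
  if (file.exists(f)) return(readRDS(f))
  ds <- generate_dataset(study_config)
  saveRDS(ds, f)
  ds
}

study_pipeline <- function() {
  f <- file.path(SCRATCH, "pipeline.rds")
  if (file.exists(f)) return(readRDS(f))
  res <- run_pipeline(study_dataset(), verbose = TRUE)
  saveRDS(res, f)
  res
}
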