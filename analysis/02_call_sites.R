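#!/usr/bin/env Rscript
# Call TSSs/PSSs from the TEX+/TEX- 5'-end tracks, detect transcripts from
# ssRNA-seq coverage, and score both against the planted truth.

source("analysis/00_setup.R")

ds <- study_dataset()
res <- study_pipeline()

write_tsv(res$sites, file.path(RESULTS, "sites.tsv"))
write_tsv(res$transcripts, file.path(RESULTS, "transcripts.tsv"))

truth <- ds$truth$sites
key_t <- paste(truth$strand, truth$position, truth$kind)
key_c <- paste(res$sites$strand, res$sites$position, res$sites$kind)
cat(sprintf("called %d sites (%d TSS / %d PSS); planted %d\n",
            nrow(res$sites), sum(res$sites$kind == "TSS"),
            sum(res$sites$kind == "PSS"), nrow(truth)))
cat(sprintf("site recall %.3f, precision %.3f\n",
            mean(key_t %in% key_c), mean(key_c %in% key_t)))
cat(sprintf("%d transcript intervals detected\n", nrow(res$transcripts)))
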