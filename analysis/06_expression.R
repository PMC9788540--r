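#!/usr/bin/env Rscript
# Expression quantification of the candidates across conditions and
# replicates: TPM, differential expression (padj < 0.05, |log2FC| >= 1),
# top-expressed overlap, and recovery of the planted fold changes.

source("analysis/00_setup.R")

ds <- study_dataset()
res <- study_pipeline()

de <- res$expression$de
write_tsv(de, file.path(RESULTS, "differential_expression.tsv"))
write_tsv(data.frame(srna_id = rownames(res$expression$tpm), res$expression$tpm),
          file.path(RESULTS, "tpm.tsv"))

cat(sprintf("candidates: %d; up %d, down %d, ns %d\n", nrow(de),
            sum(de$status == "up"), sum(de$status == "down"),
            sum(de$status == "ns")))
tops <- res$expression$top
cat(sprintf("top-%d overlap between conditions: %d; top share %.1f%% / %.1f%%\n",
            length(tops$top[[1]]), tops$overlap,
            100 * tops$top_share[1], 100 * tops$top_share[2]))

# recovered vs planted fold changes for matched candidates
truth <- ds$truth$srnas
p5c <- ifelse(res$srnas$strand == "+", res$srnas$start, res$srnas$end)
p5t <- ifelse(truth$strand == "+", truth$start, truth$end)
m <- match(p5c, p5t)
okm <- which(!is.na(m))
comp <- data.frame(srna_id = res$srnas$id[okm],
                   planted = truth$log2fc_true[m[okm]],
                   estimated = de$log2fc[okm])
write_tsv(comp, file.path(RESULTS, "log2fc_recovery.tsv"))
cat(sprintf("log2FC recovery: cor = %.3f over %d matched candidates\n",
            cor(comp$planted, comp$estimated), nrow(comp)))
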