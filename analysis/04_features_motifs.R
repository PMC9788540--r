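#!/usr/bin/env Rscript
# Sequence/structure features per candidate, class-wise comparisons,
# GC-vs-NMFE correlation, promoter box report, TSS/PSS motif profiles and
# small-ORF scan.

source("analysis/00_setup.R")

res <- study_pipeline()

write_tsv(res$features, file.path(RESULTS, "features.tsv"))
if (!is.null(res$feature_tests)) {
  write_tsv(res$feature_tests, file.path(RESULTS, "feature_tests.tsv"))
}
if (!is.null(res$sorfs)) write_tsv(res$sorfs, file.path(RESULTS, "sorfs.tsv"))

for (m in names(res$motifs)) {
  prof <- res$motifs[[m]]
  write_tsv(data.frame(offset = prof$offsets, prof$freq, ic = prof$ic),
            file.path(RESULTS, paste0("motif_", m, ".tsv")))
  cat(sprintf("%s profile over %d sites, consensus: %s\n",
              toupper(m), prof$n_sites, prof$consensus))
}
cat(sprintf("PSS consensus at -2..+3: %s\n", consensus_at(res$motifs$pss, -2, 3)))
cat(sprintf("TSS +1 purine frequency: %.3f\n",
            sum(res$motifs$tss$freq["1", c("A", "G")])))
cat(sprintf("-10 box: %s (support %.2f); -35 box: %s (support %.2f)\n",
            res$promoter_boxes$minus10$hexamer, res$promoter_boxes$minus10$support,
            res$promoter_boxes$minus35$hexamer, res$promoter_boxes$minus35$support))

g <- res$features
gm <- aggregate(cbind(gc, nmfe) ~ group, g, mean)
if (nrow(gm) >= 4) {
  ct <- correlate_gc_nmfe(gm$gc, gm$nmfe)
  cat(sprintf("class-mean GC vs NMFE: rho = %.2f (p = %.3g, %d classes)\n",
              ct$rho, ct$p, nrow(gm)))
}
cat(sprintf("sRNAs with small ORFs: %d\n",
            if (is.null(res$sorfs)) 0L else length(unique(res$sorfs$srna_id))))
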