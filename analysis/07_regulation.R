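#!/usr/bin/env Rscript
# Regulatory candidate screens: CsrA-binding ANGGA motifs near ribosome
# binding sites, GGA structural counts per sRNA, trans-target prediction for
# inter-/intra-sRNAs, and the three-criteria classification of sRNAs
# directly related to a key-gene panel.

source("analysis/00_setup.R")

ds <- study_dataset()
res <- study_pipeline()

write_tsv(res$csra_targets, file.path(RESULTS, "csra_targets.tsv"))
cat(sprintf("CsrA candidate targets: %d genes with ANGGA near the start codon\n",
            nrow(res$csra_targets)))

# GGA pairing profile of each candidate under the base-pair proxy structure
gga <- do.call(rbind, lapply(seq_len(nrow(res$srnas)), function(i) {
  st <- fold_structure(res$srnas$sequence[i])
  data.frame(srna_id = res$srnas$id[i],
             t(count_gga_motifs(res$srnas$sequence[i], st)))
}))
write_tsv(gga, file.path(RESULTS, "gga_counts.tsv"))
sponge <- gga[order(-gga$unpaired), ][1:5, ]
cat("top CsrA-sponge-like candidates (unpaired GGA motifs):\n")
print(sponge)

ints <- do.call(rbind, lapply(names(res$interactions), function(id) {
  d <- res$interactions[[id]]
  if (nrow(d)) cbind(srna_id = id, d) else NULL
}))
write_tsv(ints, file.path(RESULTS, "trans_targets.tsv"))
cat(sprintf("trans-target predictions: %d sRNA-gene pairs for %d sRNAs\n",
            nrow(ints), length(res$interactions)))

# key-gene panel: the five most strongly down- and up-regulated host genes
tg <- ds$truth$genes[ds$truth$genes$feature_type == "CDS", ]
key <- tg$gene_id[order(-abs(tg$log2fc_true))][1:8]
rel <- classify_direct_relations(res$srnas, key, res$interactions,
                                 ds$annotation$gene_id, top_k = 10)
write_tsv(rel, file.path(RESULTS, "direct_relations.tsv"))
cat(sprintf("direct-relation calls: %d sRNA-key gene pairs (%d unique sRNAs)\n",
            nrow(rel), length(unique(rel$srna_id))))
print(table(rel$criteria))
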