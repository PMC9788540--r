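#!/usr/bin/env Rscript
# Nominate sRNA candidates by the three criteria (dRNA-seq + ssRNA-seq
# support, abundance >= 10 in one condition, anchored 5' and evidenced 3'
# ends), classify them by origin and location, cluster redundant sequences,
# and score recovery against the planted truth.

source("analysis/00_setup.R")

ds <- study_dataset()
res <- study_pipeline()

write_tsv(res$srnas, file.path(RESULTS, "srnas.tsv"))
write_tsv(res$clusters, file.path(RESULTS, "srna_clusters.tsv"))
write_fasta(setNames(chartr("U", "T", res$srnas$sequence), res$srnas$id),
            file.path(RESULTS, "srnas.fa"))

truth <- ds$truth$srnas[ds$truth$srnas$detectable, ]
p5c <- ifelse(res$srnas$strand == "+", res$srnas$start, res$srnas$end)
p3c <- ifelse(res$srnas$strand == "+", res$srnas$end, res$srnas$start)
p5t <- ifelse(truth$strand == "+", truth$start, truth$end)
p3t <- ifelse(truth$strand == "+", truth$end, truth$start)
hit <- vapply(seq_len(nrow(truth)), function(i) {
  any(res$srnas$strand == truth$strand[i] & abs(p5c - p5t[i]) <= 1 &
        abs(p3c - p3t[i]) <= 5)
}, logical(1))
cat(sprintf("%d candidates; recall over %d detectable planted sRNAs: %.3f\n",
            nrow(res$srnas), nrow(truth), mean(hit)))

s <- res$summary
cat("origin classes:\n"); print(s$origin)
cat("location classes:\n"); print(s$location)
write_tsv(s$origin, file.path(RESULTS, "summary_origin.tsv"))
write_tsv(s$location, file.path(RESULTS, "summary_location.tsv"))
write_tsv(s$subtype, file.path(RESULTS, "summary_subtype.tsv"))
cat(sprintf("redundant clusters: %d candidates in %d clusters\n",
            nrow(res$clusters), length(unique(res$clusters$cluster))))
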