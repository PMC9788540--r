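#!/usr/bin/env Rscript
# Generate the synthetic dRNA-seq/ssRNA-seq study dataset with planted truth:
# genome, annotation, coverage tracks and the truth tables the later scripts
# score against.

source("analysis/00_setup.R")

ds <- study_dataset()
print(ds)

write_tsv(ds$truth$srnas, file.path(RESULTS, "truth_srnas.tsv"))
write_tsv(ds$truth$sites, file.path(RESULTS, "truth_sites.tsv"))
write_tsv(ds$truth$genes, file.path(RESULTS, "truth_genes.tsv"))
write_fasta(ds$genome, file.path(RESULTS, "genome.fa"))
write_gff3(ds$annotation, file.path(RESULTS, "annotation.gff3"),
           seqname = names(ds$genome)[1])

tr <- ds$truth$srnas
cat(sprintf("planted sRNAs: %d (%d detectable at the abundance gate)\n",
            nrow(tr), sum(tr$detectable)))
cat(sprintf("origin split: %d ts / %d ps (%.1f%% ts)\n",
            sum(tr$origin_class == "ts"), sum(tr$origin_class == "ps"),
            100 * mean(tr$origin_class == "ts")))
print(table(tr$location_class))
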