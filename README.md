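# srnascape

Genome-wide discovery and characterization of bacterial small RNAs (sRNAs)
from differential RNA-seq coverage.

Bacterial sRNAs (~50–500 nt) regulate adaptation pathways but are hard to
annotate: they arise both from their own promoters and from ribonuclease
processing of longer transcripts, and they can sit in intergenic regions,
antisense to genes, or inside mRNAs. Differential RNA-seq (dRNA-seq)
resolves this at single-nucleotide 5′-end resolution: a 5′P-dependent
terminator exonuclease (TEX) degrades processed transcripts, so a genuine
transcription start site (TSS) is *enriched* in the TEX+ library while a
processing site (PSS) is not. `srnascape` implements the full analysis
chain over strand-specific coverage tracks:

- **Site calling** — at candidate positions with 5′-end signal ≥ *h* (default
  5 per-million units), the enrichment (TEX⁺ + c)/(TEX⁻ + c) with pseudocount
  c = 1 classifies TSS (ratio ≥ 2) versus PSS (ratio < 2, visible in TEX⁻).
- **sRNA detection** — a candidate needs dRNA-seq *and* ssRNA-seq support,
  mean ssRNA-seq coverage ≥ 10 per-million in ≥ 1 condition, a TSS/PSS at the
  5′ end and a PSS or sharp coverage decrease at the 3′ end, with length in
  [50, 500] nt. Candidates are classified by origin (ts-sRNA / ps-sRNA) and
  by location (inter / antisense / intra with subtypes 5′UTR, 5′CDS, mCDS,
  3′CDS, 3′UTR, 3′rRNA, 2CDSs / intra&as), named `sRNA<5′ position>`, and
  clustered at 70 % identity over 90 % of the shorter sequence.
- **Features and motifs** — length, GC, normalized folding score
  (NMFE = MFE/length; built-in maximum-base-pairing backend or external
  RNAfold), Wilcoxon rank-sum group comparisons, Spearman GC–NMFE
  correlation, −10/−35 promoter boxes and the RNase E-style cleavage
  consensus R N ↓ W U U across PSSs, small-ORF scan (AUG…stop, ≥ 20 aa), and
  GGA-motif pairing counts for CsrA-sponge candidates.
- **Conservation** — seeded local-alignment homolog search across reference
  genomes at the published threshold profiles (strict 75/75, loose 60/50,
  Rfam 50/50), conservation matrix with specific/local/broad categories and
  identity-versus-phylogeny correlations.
- **Expression and regulation** — TPM (Σ = 10⁶ per sample), differential
  expression (median-of-ratios normalization, log₂((mean_A+0.5)/(mean_B+0.5)),
  pooled t on log counts, BH adjustment; up/down at padj < 0.05 and
  |log₂FC| ≥ 1), top-expressed overlap, ANGGA scans near start codons, a
  seed-and-extend antisense duplex scorer for trans-targets, and the
  three-criteria classifier tying sRNAs to key genes.
- **Synthetic data** — `generate_dataset()` plants genes, sRNAs in every
  location class, promoter/cleavage motifs, a six-order-of-magnitude
  expression range and condition fold changes with full ground truth, so the
  whole pipeline is validated against planted truth.

## Worked example

The `analysis/` scripts run the whole study on a simulated 200 kb genome
with 60 planted sRNAs (2 conditions × 3 replicates, Poisson noise):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_sites.R
Rscript analysis/03_detect_srnas.R
```

which prints (abridged):

```
planted sRNAs: 60 (56 detectable at the abundance gate)
origin split: 38 ts / 22 ps (63.3% ts)

called 253 sites (182 TSS / 71 PSS); planted 253
site recall 1.000, precision 1.000

90 candidates; recall over 56 detectable planted sRNAs: 1.000
location classes:
     class count percent
1       as    11    12.2
2    inter     8     8.9
3    intra    69    76.7
4 intra_as     2     2.2
```

Every planted site is recovered at the exact position and kind; every
detectable planted sRNA (true abundance ≥ 10 per-million somewhere) is
recovered within ±1 nt at the 5′ end. The extra candidates are processed
mRNA fragments that genuinely satisfy the detection criteria. Continuing,

```sh
Rscript analysis/04_features_motifs.R
```

```
PSS profile over 71 sites, consensus: NNNNNNNNRNWUUNNNNNNN
TSS +1 purine frequency: 0.989
-10 box: UAUAAU (support 0.75); -35 box: UUGACA (support 0.77)
```

recovers the planted cleavage consensus `RNWUU` across the cut site and the
promoter boxes, and `05`–`07` cover conservation (median identity-phylogeny
ρ = 1.00 across five mutated reference genomes), expression (log₂FC
recovery r = 0.94 against planted fold changes) and the regulatory screens.
All tables land under `results/`.

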