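Package: srnascape
Title: Bacterial Small RNA Landscape Analysis from Differential RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and classifies bacterial small RNA (sRNA) candidates from
    strand-specific coverage tracks of differential RNA-seq (TEX-treated versus
    untreated dRNA-seq) and fragmented strand-specific RNA-seq. Calls
    transcription start sites (TSS) and processing sites (PSS) from 5'-end
    enrichment, detects transcripts from coverage, applies abundance and
    boundary-evidence criteria to nominate sRNA candidates, classifies them by
    5'-end origin and genomic location, profiles promoter and cleavage-site
    motifs, computes sequence and structure features, searches homologs across
    reference genomes, quantifies condition-dependent expression, and screens
    CsrA- and base-pairing-mediated regulatory candidates. Includes a synthetic
    data generator that plants sites, sRNAs, motifs and fold changes with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
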