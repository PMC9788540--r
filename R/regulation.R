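# Expression quantification, differential classification, CsrA target
# scanning, simplified antisense duplex scoring and the three-criteria
# classifier linking sRNAs to key genes.

#' Transcripts-per-million normalization
#'
#' tpm_i = (c_i / L_i) / sum_j (c_j / L_j) * 1e6, so values sum to 1e6 within
#' a sample.
#'
#' @param counts Non-negative read counts per feature.
#' @param lengths Positive feature lengths (nt).
#' @return Numeric TPM vector.
#' @export
compute_tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths)) stop("counts/lengths length mismatch")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (all(counts == 0)) stop("compute_tpm requires at least one positive count")
  rate <- counts / lengths
  rate / sum(rate) * 1e6
}

# DESeq-style median-of-ratios size factors; falls back to library-size
# ratios when no feature is positive in every sample
size_factors <- function(counts) {
  logs <- log(counts)
  ok <- apply(counts, 1, function(r) all(r > 0))
  if (any(ok)) {
    geo <- rowMeans(logs[ok, , drop = FALSE])
    sf <- apply(logs[ok, , drop = FALSE], 2, function(cl) exp(stats::median(cl - geo)))
  } else {
    ls <- colSums(counts)
    sf <- ls / exp(mean(log(ls[ls > 0])))
  }
  sf
}

#' Differential expression between two conditions
#'
#' Library sizes are normalized by median-of-ratios; the fold change is
#' log2((meanA + 0.5) / (meanB + 0.5)) on normalized counts (A = first label
#' level encountered); p-values come from a two-sided pooled-variance t-test
#' on log2(normalized + 0.5) — near-nominal at 2-3 replicates per group,
#' where the Welch approximation is markedly conservative — and are
#' BH-adjusted across all features. A feature
#' is `up` when padj < `alpha` and log2fc >= `lfc`, `down` when padj < `alpha`
#' and log2fc <= -`lfc`, else `ns`.
#'
#' @param counts Feature-by-sample count matrix (rownames = feature ids).
#' @param condition Condition label per column (exactly two levels, each with
#'   >= 2 replicates).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @return data.frame: `feature_id`, `base_mean`, `log2fc`, `pvalue`, `padj`,
#'   `status`.
#' @export
differential_expression <- function(counts, condition, alpha = 0.05, lfc = 1) {
  counts <- as.matrix(counts)
  levs <- unique(condition)
  if (length(levs) != 2L) stop("exactly two condition levels required")
  if (any(table(condition) < 2L)) stop(">= 2 replicates per condition required")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  ia <- which(condition == levs[1])
  ib <- which(condition == levs[2])
  meanA <- rowMeans(norm[, ia, drop = FALSE])
  meanB <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2((meanA + 0.5) / (meanB + 0.5))
  lg <- log2(norm + 0.5)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    if (all(counts[i, ] == 0)) return(1)
    xa <- lg[i, ia]; xb <- lg[i, ib]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      return(if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0)
    }
    tryCatch(stats::t.test(xa, xb, var.equal = TRUE)$p.value,
             error = function(e) 1)
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  status <- rep("ns", nrow(counts))
  status[padj < alpha & log2fc >= lfc] <- "up"
  status[padj < alpha & log2fc <= -lfc] <- "down"
  ids <- rownames(counts)
  if (is.null(ids)) ids <- paste0("feature", seq_len(nrow(counts)))
  data.frame(feature_id = ids, base_mean = (meanA + meanB) / 2,
             log2fc = log2fc, pvalue = p, padj = padj, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Top expressed features per condition and their overlap
#'
#' Features are ranked per condition by mean TPM, descending; ties at the
#' cutoff are broken deterministically by feature id.
#'
#' @param tpm Feature-by-sample TPM matrix (rownames = feature ids).
#' @param condition Condition label per column.
#' @param n Size of each top list (default 50).
#' @return List: `top` (named list of id vectors per condition), `overlap`
#'   (intersection size across all conditions), and `top_share` (fraction of
#'   each condition's total TPM captured by its top list).
#' @export
top_expressed <- function(tpm, condition, n = 50) {
  tpm <- as.matrix(tpm)
  if (nrow(tpm) < n) stop("fewer features than n")
  ids <- rownames(tpm)
  if (is.null(ids)) ids <- paste0("feature", seq_len(nrow(tpm)))
  tops <- list()
  share <- numeric(0)
  for (cond in unique(condition)) {
    m <- rowMeans(tpm[, condition == cond, drop = FALSE])
    ord <- order(-m, ids)
    tops[[cond]] <- ids[ord[seq_len(n)]]
    share[cond] <- sum(m[ord[seq_len(n)]]) / sum(m)
  }
  list(top = tops, overlap = length(Reduce(intersect, tops)), top_share = share)
}

extract_window <- function(gseq, center, strand, upstream, downstream) {
  glen <- nchar(gseq)
  if (strand == "+") {
    lo <- max(1L, center - upstream)
    hi <- min(glen, center + downstream)
    substr(gseq, lo, hi)
  } else {
    lo <- max(1L, center - downstream)
    hi <- min(glen, center + upstream)
    revcomp(substr(gseq, lo, hi))
  }
}

#' Scan genes for CsrA-binding ANGGA motifs near the ribosome binding site
#'
#' For each CDS the window [start codon - `upstream`, start codon +
#' `downstream`] is extracted strand-aware (truncated at contig edges) and
#' scanned for overlapping occurrences of ANGGA. Genes with at least one
#' occurrence are candidate CsrA targets, ranked by occurrence count
#' (descending) and distance of the nearest motif to the start codon
#' (ascending), then gene id.
#'
#' @param ann Annotation data.frame ([read_gff3()] layout).
#' @param genome Genome sequence.
#' @param upstream,downstream Window bounds around the start codon (nt).
#' @return data.frame of candidates: `gene_id`, `n_motifs`, `nearest_dist`,
#'   `rank`.
#' @export
scan_csra_targets <- function(ann, genome, upstream = 25, downstream = 10) {
  gseq <- toupper(as.character(genome)[1])
  cds <- ann[ann$feature_type == "CDS", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cds))) {
    strand <- cds$strand[i]
    start_pos <- if (strand == "+") cds$start[i] else cds$end[i]
    win <- extract_window(gseq, start_pos, strand, upstream, downstream)
    offset0 <- upstream + 1L  # index of the start-codon base within the window
    if (strand == "+") offset0 <- offset0 - max(0L, upstream - (start_pos - 1L))
    else offset0 <- offset0 - max(0L, upstream - (nchar(gseq) - start_pos))
    hits <- gregexpr("(?=A[ACGT]GGA)", win, perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    dists <- abs(as.integer(hits) - offset0)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = cds$gene_id[i], n_motifs = length(hits),
      nearest_dist = min(dists), stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), n_motifs = integer(0),
                      nearest_dist = integer(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_motifs, out$nearest_dist, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# pair score lookup for antisense duplexes; rows/cols indexed A,C,G,U
duplex_score_matrix <- function(gu = TRUE) {
  m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
  m["A", "U"] <- m["U", "A"] <- 2
  m["G", "C"] <- m["C", "G"] <- 3
  if (gu) m["G", "U"] <- m["U", "G"] <- 1
  m
}

encode_rna <- function(x) {
  match(strsplit(chartr("Tacgtu", "UACGUU", x), "", fixed = TRUE)[[1]],
        c("A", "C", "G", "U"))
}

# best antisense duplex between an sRNA and one target window: maximal
# gap-free complementary runs containing >= seed_min consecutive pairs
# (diagonal scan in C++)
best_duplex <- function(qi, wi, smat, seed_min) {
  m <- length(qi)
  r <- duplex_scan(rev(qi), wi, smat, as.integer(seed_min))
  if (r[1] < 0) return(NULL)
  list(score = r[1],
       srna_start = m - r[3] + 1L, srna_end = m - r[2] + 1L,
       target_start = as.integer(r[4]), target_end = as.integer(r[5]))
}

#' Predict trans-acting mRNA targets of an sRNA by antisense seed extension
#'
#' Finds all gap-free antisense duplexes between the sRNA and each gene's
#' target window that contain at least `seed_min` consecutive Watson-Crick
#' (optionally GU) pairs; a duplex is scored GC=+3, AU=+2, GU=+1 and a
#' mismatch terminates the extension. Each gene's score is its best duplex;
#' genes without any qualifying duplex are omitted. Ranks are dense with ties
#' broken by gene id.
#'
#' @param srna_seq sRNA sequence.
#' @param windows Named character vector of per-gene target windows (e.g.
#'   -150..+100 nt around the start codon, strand-aware; see
#'   [target_windows()]).
#' @param seed_min Minimum seed length (consecutive pairs, default 7).
#' @param gu Allow GU pairs (default TRUE).
#' @return data.frame: `target_gene_id`, `duplex_score`, `srna_start`,
#'   `srna_end`, `target_start`, `target_end`, `rank`.
#' @export
predict_trans_targets <- function(srna_seq, windows, seed_min = 7, gu = TRUE) {
  smat <- duplex_score_matrix(gu)
  qi <- encode_rna(toupper(srna_seq))
  rows <- list()
  for (g in names(windows)) {
    wi <- encode_rna(toupper(windows[[g]]))
    b <- best_duplex(qi, wi, smat, seed_min)
    if (is.null(b)) next
    rows[[length(rows) + 1L]] <- data.frame(
      target_gene_id = g, duplex_score = b$score,
      srna_start = b$srna_start, srna_end = b$srna_end,
      target_start = b$target_start, target_end = b$target_end,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(target_gene_id = character(0), duplex_score = numeric(0),
                      srna_start = integer(0), srna_end = integer(0),
                      target_start = integer(0), target_end = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$duplex_score, out$target_gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Extract per-gene target windows around start codons
#'
#' @param ann Annotation data.frame; only CDS features are used.
#' @param genome Genome sequence.
#' @param upstream,downstream Window bounds around the start codon (nt).
#' @return Named character vector of window sequences (sense orientation).
#' @export
target_windows <- function(ann, genome, upstream = 150, downstream = 100) {
  gseq <- toupper(as.character(genome)[1])
  cds <- ann[ann$feature_type == "CDS", , drop = FALSE]
  out <- vapply(seq_len(nrow(cds)), function(i) {
    start_pos <- if (cds$strand[i] == "+") cds$start[i] else cds$end[i]
    extract_window(gseq, start_pos, cds$strand[i], upstream, downstream)
  }, character(1))
  names(out) <- cds$gene_id
  out
}

#' Classify sRNAs directly related to key genes by the three criteria
#'
#' Criterion i: an intra-sRNA originating from (overlapping, same strand) a
#' key gene. Criterion ii: an antisense or intra&antisense sRNA overlapping a
#' key gene on the opposite strand. Criterion iii: an intra- or inter-sRNA
#' whose ranked trans-target list places the key gene within the top
#' `top_k`.
#'
#' @param srnas sRNA data.frame with `id`, `location_class`,
#'   `overlapping_gene_ids` and `antisense_gene_ids` (comma-separated).
#' @param key_gene_ids Character vector of key gene ids.
#' @param interactions Named list (by sRNA id) of [predict_trans_targets()]
#'   tables.
#' @param all_gene_ids Gene universe used to validate `key_gene_ids`.
#' @param top_k Rank cutoff for criterion iii (default 10).
#' @return data.frame: `srna_id`, `key_gene_id`, `criteria` (subset of
#'   "i","ii","iii", comma-separated).
#' @export
classify_direct_relations <- function(srnas, key_gene_ids, interactions,
                                      all_gene_ids, top_k = 10) {
  unknown <- setdiff(key_gene_ids, all_gene_ids)
  if (length(unknown)) {
    stop("unknown key gene id(s): ", paste(unknown, collapse = ", "))
  }
  split_ids <- function(x) {
    if (is.na(x) || x == "") character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
  }
  rows <- list()
  for (i in seq_len(nrow(srnas))) {
    sid <- srnas$id[i]
    cls <- srnas$location_class[i]
    same <- split_ids(srnas$overlapping_gene_ids[i])
    anti <- split_ids(srnas$antisense_gene_ids[i])
    ranked <- interactions[[sid]]
    for (g in key_gene_ids) {
      crit <- character(0)
      if (cls == "intra" && g %in% same) crit <- c(crit, "i")
      if (cls %in% c("as", "intra_as") && g %in% anti) crit <- c(crit, "ii")
      if (cls %in% c("intra", "inter") && !is.null(ranked) && nrow(ranked) > 0) {
        r <- ranked$rank[ranked$target_gene_id == g]
        if (length(r) && min(r) <= top_k) crit <- c(crit, "iii")
      }
      if (length(crit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          srna_id = sid, key_gene_id = g,
          criteria = paste(crit, collapse = ","), stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(srna_id = character(0), key_gene_id = character(0),
                      criteria = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
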