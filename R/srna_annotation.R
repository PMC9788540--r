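# sRNA candidate detection by three criteria and two-axis classification.
#
# A candidate is nominated for each (5'-site, 3'-evidence) pair such that:
# (i) the interval lies inside an ssRNA-seq transcript and has nonzero
# dRNA-seq 5'-end signal; (ii) its mean per-million ssRNA-seq coverage is at
# least `min_abund` in at least one condition; (iii) the 3' end is a
# downstream PSS or a sharp coverage decrease; and the length is within
# [min_len, max_len].

#' Default sRNA detection parameters
#'
#' @return Named list: `min_len`, `max_len` (nt), `min_abund` (per-million),
#'   `sharp_w`, `sharp_d` (sharp-decrease window and drop ratio).
#' @export
srna_params <- function(min_len = 50, max_len = 500, min_abund = 10,
                        sharp_w = 5, sharp_d = 0.5) {
  list(min_len = min_len, max_len = max_len, min_abund = min_abund,
       sharp_w = sharp_w, sharp_d = sharp_d)
}

#' Detect sRNA candidates from sites, transcripts and coverage
#'
#' @param transcripts data.frame of detected transcripts (`start`, `end`,
#'   `strand`, `condition`) pooled over conditions.
#' @param sites Merged site-call data.frame (see [merge_site_calls()]).
#' @param ss_by_condition Named list (condition) of lists (`"+"`, `"-"`) of
#'   replicate-averaged per-million `full_coverage` tracks.
#' @param drna_by_condition Named list (condition) of lists with elements
#'   `texplus` and `texminus`, each a list (`"+"`, `"-"`) of replicate-averaged
#'   `five_prime_ends` tracks.
#' @param genome Genome sequence (for candidate sequence extraction).
#' @param params See [srna_params()].
#' @return data.frame of candidates: `id`, `start`, `end`, `strand`,
#'   `origin_class`, `anchor_kind`, `anchor_position`, `end_evidence`,
#'   `length`, `sequence` (RNA, 5'->3') and one `abundance_<condition>`
#'   column per condition.
#' @export
detect_srnas <- function(transcripts, sites, ss_by_condition, drna_by_condition,
                         genome, params = srna_params()) {
  conds <- sort(names(ss_by_condition))
  gseq <- toupper(as.character(genome)[1])
  out <- list()
  for (strand in c("+", "-")) {
    ss_s <- lapply(ss_by_condition, function(x) x[[strand]])
    tex_s <- lapply(drna_by_condition, function(x) {
      list(texplus = x$texplus[[strand]], texminus = x$texminus[[strand]])
    })
    tr_s <- transcripts[transcripts$strand == strand, , drop = FALSE]
    st_s <- sites[sites$strand == strand, , drop = FALSE]
    pss_pos <- sort(st_s$position[st_s$kind == "PSS"])
    for (si in seq_len(nrow(st_s))) {
      p <- st_s$position[si]
      ends <- data.frame(end5 = integer(0), evidence = character(0))
      if (strand == "+") {
        q <- pss_pos[pss_pos >= p + params$min_len & pss_pos <= p + params$max_len]
        if (length(q)) ends <- rbind(ends, data.frame(end5 = q - 1L, evidence = "PSS"))
      } else {
        q <- pss_pos[pss_pos <= p - params$min_len & pss_pos >= p - params$max_len]
        if (length(q)) ends <- rbind(ends, data.frame(end5 = q + 1L, evidence = "PSS"))
      }
      for (cond in conds) {
        e_sd <- find_sharp_decrease(ss_s[[cond]], p, strand,
                                    w = params$sharp_w, d = params$sharp_d,
                                    max_len = params$max_len)
        if (!is.na(e_sd)) {
          ends <- rbind(ends, data.frame(end5 = e_sd, evidence = "sharp_decrease"))
        }
      }
      if (!nrow(ends)) next
      # a sharp-decrease end within the sharp window of a PSS-supported end
      # is the same boundary seen through coverage smoothing: keep the PSS
      pss_ends <- ends$end5[ends$evidence == "PSS"]
      if (length(pss_ends)) {
        near_pss <- ends$evidence == "sharp_decrease" &
          vapply(ends$end5, function(e) any(abs(e - pss_ends) <= params$sharp_w),
                 logical(1))
        ends <- ends[!near_pss, , drop = FALSE]
      }
      # evidence priority: PSS before sharp_decrease at the same 3' end
      ends$prio <- match(ends$evidence, c("terminator", "PSS", "sharp_decrease"))
      ends <- ends[order(ends$end5, ends$prio), , drop = FALSE]
      ends <- ends[!duplicated(ends$end5), , drop = FALSE]
      for (ei in seq_len(nrow(ends))) {
        e <- ends$end5[ei]
        s0 <- min(p, e); e0 <- max(p, e)
        len <- e0 - s0 + 1L
        if (len < params$min_len || len > params$max_len) next
        inside <- any(tr_s$start <= s0 & tr_s$end >= e0)
        if (!inside) next
        drna_signal <- any(vapply(tex_s, function(tx) {
          sum(tx$texplus$values[s0:e0]) + sum(tx$texminus$values[s0:e0]) > 0
        }, logical(1)))
        if (!drna_signal) next
        abund <- vapply(conds, function(cond) mean(ss_s[[cond]]$values[s0:e0]),
                        numeric(1))
        if (max(abund) < params$min_abund) next
        seq_dna <- substr(gseq, s0, e0)
        if (strand == "-") seq_dna <- revcomp(seq_dna)
        row <- data.frame(
          start = s0, end = e0, strand = strand,
          origin_class = classify_origin(st_s$kind[si]),
          anchor_kind = st_s$kind[si], anchor_position = p,
          end_evidence = ends$evidence[ei], length = len,
          sequence = chartr("T", "U", seq_dna), stringsAsFactors = FALSE
        )
        for (cond in conds) row[[paste0("abundance_", cond)]] <- abund[[cond]]
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), origin_class = character(0),
                      anchor_kind = character(0), anchor_position = integer(0),
                      end_evidence = character(0), length = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand, res$end), , drop = FALSE]
  res <- cbind(id = name_srna(res$start, res$end, res$strand), res)
  res$id <- as.character(res$id)
  rownames(res) <- NULL
  res
}

#' Classify the 5'-end origin of a candidate
#'
#' @param anchor_kind `"TSS"` or `"PSS"` of the 5'-end anchor site.
#' @return `"ts"` (transcription-starting) or `"ps"` (processing-derived).
#' @export
classify_origin <- function(anchor_kind) {
  if (any(is.na(anchor_kind)) || !all(anchor_kind %in% c("TSS", "PSS"))) {
    stop("classify_origin requires an anchor site of kind TSS or PSS")
  }
  ifelse(anchor_kind == "TSS", "ts", "ps")
}

#' Name sRNAs by their strand-aware 5'-end genomic position
#'
#' Plus-strand candidates use their start, minus-strand candidates their end.
#' When two candidates on opposite strands share a 5' position, the
#' minus-strand one gets an "m" suffix.
#'
#' @param start,end,strand Vectors of candidate coordinates.
#' @return Character vector of ids of the form `sRNA<position>`.
#' @export
name_srna <- function(start, end, strand) {
  p5 <- ifelse(strand == "+", start, end)
  id <- paste0("sRNA", p5)
  dup <- duplicated(id) | duplicated(id, fromLast = TRUE)
  id[dup & strand == "-"] <- paste0(id[dup & strand == "-"], "m")
  id
}

# gene transcript extents (gene body plus UTR allowances for CDS), truncated
# at same-strand neighbor gene bodies; optionally refined from detected
# transcripts when a unique transcript overlaps exactly that CDS
gene_extents <- function(ann, genome_length, transcripts = NULL,
                         utr5 = 50, utr3 = 80) {
  n <- nrow(ann)
  ext_start <- ann$start
  ext_end <- ann$end
  for (i in seq_len(n)) {
    if (ann$feature_type[i] != "CDS") next
    if (ann$strand[i] == "+") {
      lo <- ann$start[i] - utr5
      hi <- ann$end[i] + utr3
    } else {
      lo <- ann$start[i] - utr3
      hi <- ann$end[i] + utr5
    }
    refined <- FALSE
    if (!is.null(transcripts) && nrow(transcripts)) {
      tr <- transcripts[transcripts$strand == ann$strand[i] &
                          transcripts$start <= ann$end[i] &
                          transcripts$end >= ann$start[i], , drop = FALSE]
      tr <- unique(tr[, c("start", "end")])
      if (nrow(tr) == 1L) {
        # only usable when the transcript does not span another gene body
        others <- which(ann$strand == ann$strand[i] & seq_len(n) != i)
        spans_other <- any(tr$start[1] <= ann$end[others] &
                             tr$end[1] >= ann$start[others])
        if (!spans_other) {
          lo <- min(tr$start[1], ann$start[i])
          hi <- max(tr$end[1], ann$end[i])
          refined <- TRUE
        }
      }
    }
    if (!refined) {
      # truncate default UTR allowances at same-strand neighbor gene bodies
      same <- which(ann$strand == ann$strand[i] & seq_len(n) != i)
      left_lim <- ann$end[same][ann$end[same] < ann$start[i]]
      right_lim <- ann$start[same][ann$start[same] > ann$end[i]]
      if (length(left_lim)) lo <- max(lo, max(left_lim) + 1L)
      if (length(right_lim)) hi <- min(hi, min(right_lim) - 1L)
    }
    ext_start[i] <- max(1L, lo)
    ext_end[i] <- min(genome_length, hi)
  }
  data.frame(gene_id = ann$gene_id, feature_type = ann$feature_type,
             gene_start = ann$start, gene_end = ann$end, strand = ann$strand,
             ext_start = ext_start, ext_end = ext_end, stringsAsFactors = FALSE)
}

classify_one_location <- function(s0, e0, strand, ext) {
  ov <- ext$ext_start <= e0 & ext$ext_end >= s0
  same <- ext[ov & ext$strand == strand, , drop = FALSE]
  anti <- ext[ov & ext$strand != strand, , drop = FALSE]
  cls <- if (nrow(same) == 0L && nrow(anti) == 0L) "inter"
         else if (nrow(same) == 0L) "as"
         else if (nrow(anti) == 0L) "intra"
         else "intra_as"
  subtype <- "none"
  flag <- FALSE
  if (nrow(same)) {
    cds_ov <- same[same$feature_type == "CDS" &
                     same$gene_start <= e0 & same$gene_end >= s0, , drop = FALSE]
    if (nrow(cds_ov) >= 2L) {
      subtype <- "2CDSs"
      flag <- nrow(cds_ov) > 2L
    } else {
      # single host: the same-strand gene with the largest extent overlap
      ovlen <- pmin(same$gene_end, e0) - pmax(same$gene_start, s0) + 1L
      extlen <- pmin(same$ext_end, e0) - pmax(same$ext_start, s0) + 1L
      h <- same[order(-extlen, -ovlen, same$gene_id), , drop = FALSE][1L, ]
      gs <- h$gene_start; ge <- h$gene_end
      if (h$strand == "+") {
        u5 <- c(h$ext_start, gs - 1L); u3 <- c(ge + 1L, h$ext_end)
        tail3 <- ge
      } else {
        u5 <- c(ge + 1L, h$ext_end); u3 <- c(h$ext_start, gs - 1L)
        tail3 <- gs
      }
      in_seg <- function(seg) seg[1] <= seg[2] && s0 >= seg[1] && e0 <= seg[2]
      ov_seg <- function(seg) seg[1] <= seg[2] && s0 <= seg[2] && e0 >= seg[1]
      ov_body <- s0 <= ge && e0 >= gs
      if (h$feature_type == "CDS") {
        subtype <- if (in_seg(u5)) "5UTR"
          else if (ov_body && ov_seg(u5)) "5CDS"
          else if (s0 >= gs && e0 <= ge) "mCDS"
          else if (ov_body && ov_seg(u3)) "3CDS"
          else if (in_seg(u3)) "3UTR"
          else if (ov_seg(u5)) "5UTR"
          else if (ov_seg(u3)) "3UTR"
          else "mCDS"
      } else if (h$feature_type == "rRNA" && s0 <= tail3 && e0 >= tail3 &&
                 !(s0 >= gs && e0 <= ge)) {
        subtype <- "3rRNA"
      } else {
        # non-CDS host: geometry relative to the gene body
        subtype <- if (s0 >= gs && e0 <= ge) "mCDS"
          else if ((h$strand == "+" && s0 < gs) || (h$strand == "-" && e0 > ge)) "5CDS"
          else "3CDS"
      }
    }
  }
  list(location_class = cls, location_subtype = subtype,
       overlapping_gene_ids = paste(same$gene_id, collapse = ","),
       antisense_gene_ids = paste(anti$gene_id, collapse = ","),
       multi_cds_flag = flag)
}

#' Classify candidate locations relative to annotated gene transcripts
#'
#' Gene transcript extents are the CDS plus UTR allowances (from detected
#' transcript boundaries when a unique transcript covers exactly that CDS,
#' else fixed defaults truncated at same-strand neighbors); rRNA/tRNA extents
#' are the gene body. Classes: no overlap -> `inter`; opposite-strand overlap
#' only -> `as`; same-strand only -> `intra` (with subtype); both -> `intra_as`
#' (subtype from the same-strand overlap). The two-CDS test precedes the
#' single-gene subtype rules because a two-CDS spanner always also crosses a
#' single CDS boundary.
#'
#' @param candidates Candidate data.frame from [detect_srnas()].
#' @param ann Annotation data.frame.
#' @param genome_length Genome length (nt).
#' @param transcripts Optional detected-transcript data.frame used to refine
#'   UTR extents.
#' @param utr5,utr3 Default UTR allowances (nt).
#' @return `candidates` with `location_class`, `location_subtype`,
#'   `overlapping_gene_ids`, `antisense_gene_ids`, `multi_cds_flag` appended.
#' @export
classify_location <- function(candidates, ann, genome_length,
                              transcripts = NULL, utr5 = 50, utr3 = 80) {
  ext <- gene_extents(ann, genome_length, transcripts, utr5 = utr5, utr3 = utr3)
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    classify_one_location(candidates$start[i], candidates$end[i],
                          candidates$strand[i], ext)
  })
  candidates$location_class <- vapply(res, `[[`, character(1), "location_class")
  candidates$location_subtype <- vapply(res, `[[`, character(1), "location_subtype")
  candidates$overlapping_gene_ids <- vapply(res, `[[`, character(1), "overlapping_gene_ids")
  candidates$antisense_gene_ids <- vapply(res, `[[`, character(1), "antisense_gene_ids")
  candidates$multi_cds_flag <- vapply(res, `[[`, logical(1), "multi_cds_flag")
  candidates
}

#' Greedy longest-first redundancy clustering of sRNA sequences
#'
#' A sequence joins the first existing cluster whose representative aligns to
#' it with local-alignment identity >= `identity` over at least
#' `short_coverage` of the shorter sequence; otherwise it founds a new
#' cluster. Mirrors CD-HIT-EST style thresholds (-c 0.7, -aS 0.9).
#'
#' @param ids Candidate ids.
#' @param sequences Candidate sequences (RNA or DNA).
#' @param identity Identity threshold (fraction, default 0.70).
#' @param short_coverage Minimum aligned fraction of the shorter sequence
#'   (default 0.90).
#' @return data.frame: `id`, `cluster` (integer, 1 = first/longest founder).
#' @export
cluster_redundant <- function(ids, sequences, identity = 0.70,
                              short_coverage = 0.90) {
  if (length(ids) < 1L) stop("cluster_redundant requires >= 1 candidate")
  seqs <- chartr("Uu", "Tt", toupper(sequences))
  ord <- order(-nchar(seqs), ids)
  reps <- integer(0)           # indices (into ord-sorted vectors) of founders
  cluster_of <- integer(length(ids))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = TRUE)
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    assigned <- 0L
    for (ci in seq_along(reps)) {
      r <- ord[reps[ci]]
      aln <- Biostrings::pairwiseAlignment(
        pattern = seqs[i], subject = seqs[r], type = "local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2
      )
      pat <- as.character(Biostrings::pattern(aln))
      cols <- nchar(pat)
      if (cols == 0L) next
      idn <- Biostrings::nmatch(aln) / cols
      shorter <- min(nchar(seqs[i]), nchar(seqs[r]))
      aligned_short <- min(nchar(gsub("-", "", pat, fixed = TRUE)),
                           nchar(gsub("-", "",
                                      as.character(Biostrings::subject(aln)),
                                      fixed = TRUE)))
      if (idn >= identity && aligned_short / shorter >= short_coverage) {
        assigned <- ci
        break
      }
    }
    if (assigned == 0L) {
      reps <- c(reps, pos)
      assigned <- length(reps)
    }
    cluster_of[i] <- assigned
  }
  data.frame(id = ids, cluster = cluster_of, stringsAsFactors = FALSE)
}
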