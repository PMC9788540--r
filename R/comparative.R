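# Homolog search of sRNAs across reference genomes and conservation summaries.
#
# The search is a seed-and-extend heuristic: exact k-mer seeds (default k=11,
# both strands) select candidate subject windows, which are then aligned
# locally (match +1, mismatch -2, gap open -5, gap extend -2). Identity is
# matches / alignment columns (gap columns included, the BLAST convention) and
# coverage is aligned query nt / query length.

#' Named homolog-search threshold profiles
#'
#' `rfam` (50/50) mirrors the permissive screen used for database-annotated
#' RNAs, `strict` (75/75) the conservative genus-wide screen, `loose` (60/50)
#' the relaxed intergenic screen.
#'
#' @param name One of `"strict"`, `"loose"`, `"rfam"`.
#' @return List with `min_identity` and `min_coverage` (percent).
#' @export
threshold_profile <- function(name = c("strict", "loose", "rfam")) {
  name <- match.arg(name)
  switch(name,
         strict = list(name = "strict", min_identity = 75, min_coverage = 75),
         loose = list(name = "loose", min_identity = 60, min_coverage = 50),
         rfam = list(name = "rfam", min_identity = 50, min_coverage = 50))
}

#' Build a k-mer index of a subject genome
#'
#' @param genome Subject sequence (character or `DNAStringSet` of length 1).
#' @param k Seed length.
#' @return An index object reused across [homology_search()] calls.
#' @export
build_genome_index <- function(genome, k = 11) {
  s <- toupper(as.character(genome)[1])
  L <- nchar(s)
  if (L < k) stop("subject shorter than seed length")
  kmers <- substring(s, 1:(L - k + 1L), k:L)
  list(sequence = s, k = k, positions = split(seq_len(L - k + 1L), kmers))
}

empty_hits <- function() {
  data.frame(identity = numeric(0), query_coverage = numeric(0),
             subject_start = integer(0), subject_end = integer(0),
             strand = character(0), score = numeric(0),
             copy_index = integer(0), stringsAsFactors = FALSE)
}

align_window <- function(q, subject_seq, ws, we) {
  win <- substr(subject_seq, ws, we)
  aln <- Biostrings::pairwiseAlignment(
    pattern = q, subject = win, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2
  )
  pat <- as.character(Biostrings::pattern(aln))
  columns <- nchar(pat)
  if (columns == 0L) return(NULL)
  qaligned <- nchar(gsub("-", "", pat, fixed = TRUE))
  list(
    identity = 100 * Biostrings::nmatch(aln) / columns,
    qaligned = qaligned,
    sstart = ws + Biostrings::start(Biostrings::subject(aln)) - 1L,
    send = ws + Biostrings::end(Biostrings::subject(aln)) - 1L,
    score = Biostrings::score(aln)
  )
}

#' Search a reference genome for homologs of an sRNA sequence
#'
#' @param query sRNA sequence (>= 50 nt recommended).
#' @param genome Subject genome sequence, or `NULL` when `index` is given.
#' @param min_identity,min_coverage Percent thresholds in (0, 100].
#' @param k Seed length.
#' @param index Optional precomputed [build_genome_index()] result.
#' @return data.frame of non-overlapping hits passing both thresholds, sorted
#'   by identity descending with `copy_index` 1..n: `identity`,
#'   `query_coverage`, `subject_start`, `subject_end`, `strand`, `score`.
#' @export
homology_search <- function(query, genome = NULL, min_identity = 75,
                            min_coverage = 75, k = 11, index = NULL) {
  if (is.null(index)) index <- build_genome_index(genome, k = k)
  k <- index$k
  q0 <- chartr("U", "T", toupper(as.character(query)[1]))
  m <- nchar(q0)
  if (m < k) stop("query shorter than seed length")
  subject_seq <- index$sequence
  L <- nchar(subject_seq)
  pad <- as.integer(ceiling(0.2 * m) + 20L)
  cands <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") q0 else revcomp(q0)
    qk <- substring(q, 1:(m - k + 1L), k:m)
    seed_rows <- index$positions[unique(qk)]
    qpos_of <- split(seq_len(m - k + 1L), qk)
    spos <- integer(0); qpos <- integer(0)
    for (kmer in names(seed_rows)) {
      sp <- seed_rows[[kmer]]
      if (is.null(sp)) next
      qp <- qpos_of[[kmer]]
      spos <- c(spos, rep(sp, times = length(qp)))
      qpos <- c(qpos, rep(qp, each = length(sp)))
    }
    if (!length(spos)) next
    anchor <- spos - qpos + 1L  # projected subject position of query base 1
    o <- order(anchor)
    anchor <- anchor[o]
    grp <- cumsum(c(1L, as.integer(diff(anchor) > m)))
    for (ix in split(seq_along(anchor), grp)) {
      ws <- max(1L, min(anchor[ix]) - pad)
      we <- min(L, max(anchor[ix]) + m - 1L + pad)
      hit <- align_window(q, subject_seq, ws, we)
      if (is.null(hit)) next
      cands[[length(cands) + 1L]] <- data.frame(
        identity = hit$identity,
        query_coverage = 100 * hit$qaligned / m,
        subject_start = hit$sstart, subject_end = hit$send,
        strand = strand, score = hit$score, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(cands)) return(empty_hits())
  hits <- do.call(rbind, cands)
  hits <- hits[hits$identity >= min_identity & hits$query_coverage >= min_coverage, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(empty_hits())
  # collapse overlapping hits keeping the best (identity, then score)
  hits <- hits[order(-hits$identity, -hits$score, hits$subject_start), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    keep_i <- TRUE
    if (any(keep)) {
      kk <- which(keep)
      overlap <- hits$subject_start[i] <= hits$subject_end[kk] &
        hits$subject_end[i] >= hits$subject_start[kk]
      if (any(overlap)) keep_i <- FALSE
    }
    keep[i] <- keep_i
  }
  hits <- hits[keep, , drop = FALSE]
  hits$copy_index <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits
}

#' Conservation matrix and categories across reference genomes
#'
#' @param hit_table data.frame with columns `srna_id`, `genome_id`,
#'   `identity`, `copy_index`, and a single `profile` label.
#' @param srna_ids All query sRNA ids (rows of the matrix).
#' @param genome_ids All reference genome ids (columns).
#' @param broad_min Minimum number of reference genomes with a hit for the
#'   `broad` category (default: all of them).
#' @return List: `identity` (matrix, NA = absent), `species_count`,
#'   `category` (specific/local/broad), `multi_copy` (logical), `profile`.
#' @export
build_conservation_matrix <- function(hit_table, srna_ids, genome_ids,
                                      broad_min = length(genome_ids)) {
  if (nrow(hit_table) > 0L) {
    prof <- unique(hit_table$profile)
    if (length(prof) > 1L) {
      stop("mixed threshold profiles in hit table: ", paste(prof, collapse = ", "))
    }
  } else prof <- NA_character_
  mat <- matrix(NA_real_, nrow = length(srna_ids), ncol = length(genome_ids),
                dimnames = list(srna_ids, genome_ids))
  multi <- setNames(rep(FALSE, length(srna_ids)), srna_ids)
  if (nrow(hit_table) > 0L) {
    for (key in split(seq_len(nrow(hit_table)),
                      paste(hit_table$srna_id, hit_table$genome_id))) {
      d <- hit_table[key, , drop = FALSE]
      mat[d$srna_id[1], d$genome_id[1]] <- max(d$identity)
      if (nrow(d) >= 2L) multi[d$srna_id[1]] <- TRUE
    }
  }
  count <- rowSums(!is.na(mat))
  category <- ifelse(count == 0L, "specific",
                     ifelse(count >= broad_min, "broad", "local"))
  list(identity = mat, species_count = count, category = category,
       multi_copy = multi, profile = prof, broad_min = broad_min)
}

#' Spearman correlation of homolog identity with phylogenetic similarity
#'
#' Phylogenetic similarity is the negated patristic distance, so a positive
#' rho means identity decays with phylogenetic distance.
#'
#' @param identity Per-genome best identity for one sRNA (NA = absent).
#' @param distance Patristic distances of the same genomes to the focal strain.
#' @return List `rho`, `p`, `n`; `rho` is `NA` for degenerate (constant) input
#'   and the pair count is `NA`-skipped. Fewer than 4 complete pairs yields a
#'   warning and NA results.
#' @export
correlate_identity_phylogeny <- function(identity, distance) {
  ok <- !is.na(identity) & !is.na(distance)
  n <- sum(ok)
  if (n < 4L) {
    warning("fewer than 4 complete identity/distance pairs; skipped")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  x <- identity[ok]
  y <- -distance[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}
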