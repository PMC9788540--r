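# Per-sRNA sequence/structure features, group statistics, motif profiles
# around TSSs/PSSs, small ORFs and GGA-motif structural counts.

#' GC content of a nucleotide sequence
#'
#' Ambiguous bases (N) count as non-GC.
#'
#' @param sequence Nonempty nucleotide string (DNA or RNA, any case).
#' @return Fraction of G+C in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("gc_content requires a nonempty nucleotide string")
  }
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  sum(ch %in% c("G", "C")) / length(ch)
}

#' Fold a sequence and return its score
#'
#' Two backends: `"basepair_proxy"` returns minus the number of base pairs in
#' a maximum-pairing (Nussinov) structure with minimum hairpin loop 3 and
#' allowed pairs AU/GC/GU — a dimensionless structure-density score used
#' wherever absolute kcal/mol is not required; `"thermodynamic"` shells out to
#' an external RNAfold binary and returns the minimum free energy in kcal/mol.
#'
#' @param sequence RNA or DNA string.
#' @param backend `"basepair_proxy"` or `"thermodynamic"`.
#' @return Numeric folding score (<= 0).
#' @export
fold_mfe <- function(sequence, backend = c("basepair_proxy", "thermodynamic")) {
  backend <- match.arg(backend)
  if (backend == "basepair_proxy") {
    return(-as.numeric(nussinov_fold(sequence)$pairs))
  }
  rnafold <- Sys.which("RNAfold")
  if (rnafold == "") stop("thermodynamic backend requires RNAfold on the PATH")
  out <- system2(rnafold, args = "--noPS", input = chartr("T", "U", toupper(sequence)),
                 stdout = TRUE)
  m <- regmatches(out[2], regexpr("\\(\\s*-?[0-9.]+\\)$", out[2]))
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}

#' Dot-bracket structure of a sequence under the base-pair proxy fold
#'
#' @inheritParams fold_mfe
#' @return Dot-bracket string of the same length as `sequence`.
#' @export
fold_structure <- function(sequence, backend = c("basepair_proxy", "thermodynamic")) {
  backend <- match.arg(backend)
  if (backend == "basepair_proxy") return(nussinov_fold(sequence)$structure)
  rnafold <- Sys.which("RNAfold")
  if (rnafold == "") stop("thermodynamic backend requires RNAfold on the PATH")
  out <- system2(rnafold, args = "--noPS", input = chartr("T", "U", toupper(sequence)),
                 stdout = TRUE)
  sub("\\s.*$", "", out[2])
}

#' Length-normalized folding score
#'
#' @param mfe Folding score (kcal/mol for the thermodynamic backend).
#' @param length Sequence length in nt (> 0).
#' @return `mfe / length`.
#' @export
nmfe <- function(mfe, length) {
  if (any(length <= 0)) stop("nmfe requires length > 0")
  mfe / length
}

#' Feature table for a set of sRNA sequences
#'
#' @param ids Character vector of sRNA ids.
#' @param sequences Character vector of sequences.
#' @param backend Folding backend, see [fold_mfe()].
#' @return data.frame: `srna_id`, `length`, `gc`, `mfe`, `nmfe`.
#' @export
feature_table <- function(ids, sequences, backend = "basepair_proxy") {
  len <- nchar(sequences)
  mfe <- vapply(sequences, fold_mfe, numeric(1), backend = backend, USE.NAMES = FALSE)
  data.frame(
    srna_id = ids, length = len,
    gc = vapply(sequences, gc_content, numeric(1), USE.NAMES = FALSE),
    mfe = mfe, nmfe = nmfe(mfe, len),
    stringsAsFactors = FALSE
  )
}

#' Pairwise Wilcoxon rank-sum comparisons of feature distributions by group
#'
#' Two-sided asymptotic rank-sum test (tie-corrected normal approximation,
#' no continuity correction) for every pair of groups, for each requested
#' feature. Groups with fewer than 3 members are excluded with a warning.
#'
#' @param records Feature data.frame (e.g. from [feature_table()]) with an
#'   added grouping column.
#' @param group_col Name of the grouping column.
#' @param features Feature columns to compare.
#' @return data.frame: `feature`, `group1`, `group2`, `n1`, `n2`, `statistic`, `p`.
#' @export
compare_feature_groups <- function(records, group_col = "group",
                                   features = c("length", "gc", "nmfe")) {
  groups <- split(records, records[[group_col]])
  small <- names(groups)[vapply(groups, nrow, integer(1)) < 3L]
  if (length(small)) {
    warning("excluding groups with n < 3: ", paste(small, collapse = ", "))
    groups <- groups[!names(groups) %in% small]
  }
  if (length(groups) < 2L) stop("need at least 2 groups with n >= 3")
  gn <- names(groups)
  out <- list()
  for (f in features) {
    for (a in seq_along(gn)) {
      for (b in seq_along(gn)) {
        if (b <= a) next
        x <- groups[[a]][[f]]
        y <- groups[[b]][[f]]
        wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          feature = f, group1 = gn[a], group2 = gn[b],
          n1 = length(x), n2 = length(y),
          statistic = unname(wt$statistic), p = wt$p.value,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Spearman correlation between paired group means
#'
#' Asymptotic (t-approximation) Spearman rank correlation, used to relate
#' per-class mean GC content to mean normalized folding score.
#'
#' @param gc Numeric vector of group mean GC contents.
#' @param nmfe Numeric vector of group mean normalized folding scores.
#' @return List with `rho` and `p` (both `NA` for degenerate constant input).
#' @export
correlate_gc_nmfe <- function(gc, nmfe) {
  if (length(gc) != length(nmfe) || length(gc) < 4L) {
    stop("need >= 4 paired group means")
  }
  if (stats::sd(gc) == 0 || stats::sd(nmfe) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(gc, nmfe, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

iupac2 <- c(AG = "R", CU = "Y", AU = "W", CG = "S", GU = "K", AC = "M")

# consensus base call from a length-4 frequency vector (A,C,G,U)
consensus_base <- function(f) {
  ord <- order(f, decreasing = TRUE)
  b <- c("A", "C", "G", "U")[ord]
  if (f[ord[1]] >= 0.5 && f[ord[1]] >= 2 * f[ord[2]]) return(b[1])
  if (f[ord[1]] + f[ord[2]] >= 0.75 && f[ord[2]] >= 0.25) {
    key <- paste(sort(b[1:2]), collapse = "")
    return(unname(iupac2[key]))
  }
  "N"
}

#' Position frequency/information profile around anchored sites
#'
#' Extracts strand-aware sequence windows around each site (minus-strand sites
#' are reverse-complemented), with offset +1 denoting the site position itself
#' (the first transcribed or retained nucleotide) and offset -1 the position
#' immediately upstream; there is no offset 0. Sites too close to the genome
#' edge are skipped with a warning.
#'
#' @param sites data.frame with `position` and `strand` columns (rows of one
#'   anchor kind).
#' @param genome Genome sequence (character or `DNAStringSet` of length 1).
#' @param window Integer vector `c(from, to)` of relative offsets.
#' @return An object of class `motif_profile`: per-offset base frequencies,
#'   information content (bits), IUPAC consensus, and the number of sites used.
#' @export
motif_profile <- function(sites, genome, window = c(-10, 10)) {
  if (nrow(sites) < 10L) stop("motif_profile requires >= 10 sites")
  gseq <- as.character(genome)[1]
  glen <- nchar(gseq)
  offsets <- setdiff(seq.int(window[1], window[2]), 0L)
  wins <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]
    s <- sites$strand[i]
    gpos <- if (s == "+") ifelse(offsets > 0, p + offsets - 1L, p + offsets)
            else ifelse(offsets > 0, p - offsets + 1L, p - offsets)
    if (any(gpos < 1L | gpos > glen)) {
      skipped <- skipped + 1L
      next
    }
    ch <- substring(gseq, gpos, gpos)
    w <- paste(ch, collapse = "")
    if (s == "-") {
      # gpos already runs 5'->3' on the minus strand; complement base-wise
      w <- chartr("ACGT", "TGCA", w)
    }
    wins <- c(wins, w)
  }
  if (skipped > 0L) warning(skipped, " site(s) skipped: window beyond genome edge")
  mat <- do.call(rbind, strsplit(wins, "", fixed = TRUE))
  mat <- chartr("T", "U", mat)
  freq <- t(apply(mat, 2, function(col) {
    f <- c(A = sum(col == "A"), C = sum(col == "C"),
           G = sum(col == "G"), U = sum(col == "U"))
    f / length(col)
  }))
  rownames(freq) <- offsets
  ic <- apply(freq, 1, function(f) {
    nz <- f[f > 0]
    2 + sum(nz * log2(nz))
  })
  consensus <- paste(apply(freq, 1, consensus_base), collapse = "")
  structure(
    list(offsets = offsets, freq = freq, ic = ic, consensus = consensus,
         n_sites = length(wins)),
    class = "motif_profile"
  )
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("<motif_profile> %d sites, offsets %d..%d\nconsensus: %s\n",
              x$n_sites, min(x$offsets), max(x$offsets), x$consensus))
  invisible(x)
}

#' Consensus substring over a subrange of profile offsets
#'
#' @param profile A `motif_profile`.
#' @param from,to Offset bounds (inclusive; offset 0 does not exist).
#' @return Consensus string over the requested offsets.
#' @export
consensus_at <- function(profile, from, to) {
  idx <- which(profile$offsets >= from & profile$offsets <= to)
  paste(strsplit(profile$consensus, "", fixed = TRUE)[[1]][idx], collapse = "")
}

#' Strongest hexamer boxes upstream of TSSs
#'
#' Reports the most frequent hexamer across sites in the -10 region
#' (offsets -15..-5) and the -35 region (offsets -40..-28) of a TSS profile,
#' a deterministic replacement for de-novo promoter motif discovery.
#'
#' @param sites TSS site data.frame (`position`, `strand`).
#' @param genome Genome sequence.
#' @param window_m10,window_m35 Offset windows scanned for each box.
#' @return List with elements `minus10` and `minus35`, each
#'   `list(hexamer, support)` where support is the fraction of sites containing
#'   the hexamer in the window.
#' @export
find_promoter_boxes <- function(sites, genome,
                                window_m10 = c(-15, -5),
                                window_m35 = c(-40, -28)) {
  gseq <- as.character(genome)[1]
  scan_box <- function(window) {
    counts <- new.env(parent = emptyenv())
    n_used <- 0L
    glen <- nchar(gseq)
    offsets <- setdiff(seq.int(window[1], window[2]), 0L)
    for (i in seq_len(nrow(sites))) {
      p <- sites$position[i]; s <- sites$strand[i]
      gpos <- if (s == "+") ifelse(offsets > 0, p + offsets - 1L, p + offsets)
              else ifelse(offsets > 0, p - offsets + 1L, p - offsets)
      if (any(gpos < 1L | gpos > glen)) next
      w <- paste(substring(gseq, gpos, gpos), collapse = "")
      if (s == "-") w <- chartr("ACGT", "TGCA", w)
      n_used <- n_used + 1L
      seen <- unique(substring(w, 1:(nchar(w) - 5L), 6:nchar(w)))
      for (h in seen) assign(h, (if (exists(h, counts)) get(h, counts) else 0L) + 1L, counts)
    }
    tab <- unlist(as.list(counts))
    if (!length(tab)) return(list(hexamer = NA_character_, support = 0))
    best <- names(tab)[order(-tab, names(tab))][1]
    list(hexamer = chartr("T", "U", best), support = unname(tab[best]) / n_used)
  }
  list(minus10 = scan_box(window_m10), minus35 = scan_box(window_m35))
}

#' Find small ORFs in a sequence
#'
#' All AUG-initiated, stop-terminated reading frames on the given strand
#' (3 frames); nested starts sharing a stop are reported once per
#' (frame, stop), keeping the longest ORF. The amino-acid length excludes the
#' stop codon.
#'
#' @param sequence RNA or DNA string.
#' @param min_aa Minimum ORF length in amino acids (default 20).
#' @return data.frame: `frame` (0..2), `start_offset`, `end_offset` (1-based nt
#'   offsets within the sequence; end includes the stop codon), `aa_length`.
#' @export
find_sorfs <- function(sequence, min_aa = 20) {
  s <- chartr("T", "U", toupper(sequence))
  n <- nchar(s)
  out <- list()
  stops <- c("UAA", "UAG", "UGA")
  for (frame in 0:2) {
    starts_at <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (frame + 3L > n) next
    codons <- substring(s, starts_at, starts_at + 2L)
    open_from <- NA_integer_  # codon index of earliest AUG since last stop
    for (ci in seq_along(codons)) {
      cd <- codons[ci]
      if (cd %in% stops) {
        if (!is.na(open_from)) {
          aa <- ci - open_from  # codons from AUG to stop, excluding stop
          if (aa >= min_aa) {
            out[[length(out) + 1L]] <- data.frame(
              frame = frame,
              start_offset = starts_at[open_from],
              end_offset = starts_at[ci] + 2L,
              aa_length = aa
            )
          }
        }
        open_from <- NA_integer_
      } else if (cd == "AUG" && is.na(open_from)) {
        open_from <- ci
      }
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(0), start_offset = integer(0),
                      end_offset = integer(0), aa_length = integer(0)))
  }
  do.call(rbind, out)
}

#' Count GGA motifs by pairing status
#'
#' Every (possibly overlapping) GGA occurrence is classified by how many of
#' its three positions are unpaired in the dot-bracket structure: all three
#' unpaired, one or two unpaired (partially paired), or none unpaired.
#'
#' @param sequence RNA/DNA string.
#' @param structure Dot-bracket string of the same length, balanced brackets.
#' @return Named integer vector: `unpaired`, `partially_paired`, `paired`.
#' @export
count_gga_motifs <- function(sequence, structure) {
  s <- chartr("TU", "UU", toupper(sequence))
  if (nchar(s) != nchar(structure)) {
    stop("structure length must equal sequence length")
  }
  br <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (!all(br %in% c(".", "(", ")"))) stop("structure must be dot-bracket")
  depth <- cumsum((br == "(") - (br == ")"))
  if (any(depth < 0) || (length(depth) && depth[length(depth)] != 0)) {
    stop("unbalanced dot-bracket structure")
  }
  hits <- gregexpr("(?=GGA)", s, perl = TRUE)[[1]]
  res <- c(unpaired = 0L, partially_paired = 0L, paired = 0L)
  if (hits[1] == -1L) return(res)
  for (p in hits) {
    nun <- sum(br[p:(p + 2L)] == ".")
    if (nun == 3L) res["unpaired"] <- res["unpaired"] + 1L
    else if (nun == 0L) res["paired"] <- res["paired"] + 1L
    else res["partially_paired"] <- res["partially_paired"] + 1L
  }
  res
}
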