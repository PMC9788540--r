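# Readers/writers for the standard formats the pipeline touches, plus coverage
# normalization. All genomic coordinates are 1-based inclusive (GFF3
# convention); conversions to other conventions happen only at file boundaries.

#' Read a FASTA file of genome records
#'
#' Sequences are uppercased and U is converted to T, so RNA FASTA input is
#' accepted transparently.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(raw) == 0L) stop("malformed FASTA in ", path, ": no records")
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  bad <- which(!grepl("^[ACGTN]*$", seqs))
  if (length(bad)) {
    stop("malformed FASTA in ", path, ": record '", names(raw)[bad[1]],
         "' contains characters outside the nucleotide alphabet")
  }
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) {
    stop("malformed FASTA in ", path, ": empty sequence for record '",
         names(raw)[empty[1]], "'")
  }
  out <- Biostrings::DNAStringSet(seqs)
  # keep only the first whitespace-delimited token as the record id
  names(out) <- sub("\\s.*$", "", names(raw))
  out
}

#' Write genome records as FASTA
#'
#' @param x A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

#' Read gene annotations from a GFF3 file
#'
#' Coordinates are kept 1-based inclusive. Feature types other than CDS, rRNA
#' and tRNA are mapped to `"other"`.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `feature_type`, `start`, `end`,
#'   `strand`, `product`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import.gff3(path),
    error = function(e) stop("malformed GFF3 in ", path, ": ", conditionMessage(e))
  )
  md <- as.data.frame(gr)
  type <- as.character(md$type)
  type[!type %in% c("CDS", "rRNA", "tRNA")] <- "other"
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, nrow(md))
  if ("locus_tag" %in% names(md)) {
    lt <- as.character(md$locus_tag)
    id <- ifelse(is.na(id) | id == "", lt, id)
  }
  id[is.na(id) | id == ""] <- paste0("feature", seq_len(nrow(md)))[is.na(id) | id == ""]
  product <- if ("product" %in% names(md)) as.character(md$product) else NA_character_
  strand <- as.character(md$strand)
  if (any(!strand %in% c("+", "-"))) {
    stop("malformed GFF3 in ", path, ": feature without +/- strand")
  }
  data.frame(
    gene_id = id,
    feature_type = type,
    start = md$start,
    end = md$end,
    strand = strand,
    product = if (length(product) == nrow(md)) product else rep(NA_character_, nrow(md)),
    stringsAsFactors = FALSE
  )
}

#' Write gene annotations as GFF3
#'
#' @param ann Annotation data.frame as returned by [read_gff3()].
#' @param path Output path.
#' @param seqname Sequence (replicon) name used in column 1.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path, seqname = "chr") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand,
    type = ann$feature_type,
    ID = ann$gene_id
  )
  if (!is.null(ann$product)) gr$product <- ann$product
  gr$phase <- ifelse(ann$feature_type == "CDS", 0L, NA_integer_)
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Construct a strand-specific coverage track
#'
#' A coverage track holds one non-negative value per genome position for one
#' library type / track kind / condition / replicate / strand.
#'
#' @param values Numeric vector of per-position signal, length = genome length.
#' @param strand `"+"` or `"-"`.
#' @param library One of `"TEXplus"`, `"TEXminus"`, `"SS"`.
#' @param track_kind `"five_prime_ends"` or `"full_coverage"`.
#' @param condition Condition label.
#' @param replicate Replicate index (>= 1).
#' @param normalization `"raw"` or `"per_million"`.
#' @param total_reads Total aligned reads used for per-million scaling
#'   (recorded when known).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, strand,
                           library = c("SS", "TEXplus", "TEXminus"),
                           track_kind = c("full_coverage", "five_prime_ends"),
                           condition = "cond1", replicate = 1L,
                           normalization = c("raw", "per_million"),
                           total_reads = NA_real_) {
  library <- match.arg(library)
  track_kind <- match.arg(track_kind)
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(values), strand %in% c("+", "-"))
  if (any(values < 0)) stop("coverage values must be non-negative")
  structure(
    list(values = as.numeric(values), strand = strand, library = library,
         track_kind = track_kind, condition = condition,
         replicate = as.integer(replicate), normalization = normalization,
         total_reads = total_reads),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s/%s %s strand %s rep %d [%s], %d positions, total signal %.3g\n",
              x$library, x$track_kind, x$condition, x$strand, x$replicate,
              x$normalization, length(x$values), sum(x$values)))
  invisible(x)
}

#' Read a wiggle or bedGraph coverage file into a coverage track
#'
#' Accepts fixedStep and variableStep wiggle dialects as well as bedGraph
#' (half-open intervals, converted on load). Positions absent from the file
#' are filled with zero.
#'
#' @param path Path to the coverage file.
#' @param genome_length Genome length in nt; defines the track length.
#' @param format `"wig"` or `"bedGraph"` (default guesses from the extension).
#' @inheritParams coverage_track
#' @return A `coverage_track`.
#' @export
read_wiggle <- function(path, genome_length, format = NULL, strand = "+",
                        library = "SS", track_kind = "full_coverage",
                        condition = "cond1", replicate = 1L,
                        normalization = "per_million") {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) "bedGraph" else "wig"
  }
  vals <- numeric(genome_length)
  nonempty <- any(!grepl("^\\s*(#|track|$)", readLines(path, warn = FALSE)))
  if (nonempty) {
    gr <- tryCatch(
      rtracklayer::import(path, format = format),
      error = function(e) stop("malformed ", format, " in ", path, ": ",
                               conditionMessage(e))
    )
    if (length(gr)) {
      st <- GenomicRanges::start(gr)
      en <- GenomicRanges::end(gr)
      if (any(en > genome_length)) {
        stop("coverage position beyond genome length (", genome_length,
             ") in ", path)
      }
      sc <- gr$score
      for (i in seq_along(gr)) vals[st[i]:en[i]] <- sc[i]
    }
  }
  coverage_track(vals, strand = strand, library = library,
                 track_kind = track_kind, condition = condition,
                 replicate = replicate, normalization = normalization)
}

#' Write a coverage track as variableStep wiggle, omitting zeros
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @param seqname Sequence name for the declaration line.
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(track, path, seqname = "chr") {
  nz <- which(track$values != 0)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf('track type=wiggle_0 name="%s_%s_%s_rep%d_%s"',
                     track$library, track$track_kind, track$condition,
                     track$replicate, track$strand), con)
  writeLines(sprintf("variableStep chrom=%s", seqname), con)
  if (length(nz)) {
    writeLines(paste(nz, format(track$values[nz], trim = TRUE, scientific = FALSE,
                                digits = 10)), con)
  }
  invisible(path)
}

#' Per-million normalization of a raw coverage track
#'
#' Each value v becomes v / total_aligned_reads * 1e6, matching coverage files
#' normalized by the total number of aligned reads and multiplied by one
#' million.
#'
#' @param track A raw `coverage_track`.
#' @param total_aligned_reads Positive total read count.
#' @return The normalized `coverage_track` (normalization `"per_million"`).
#' @export
normalize_coverage <- function(track, total_aligned_reads) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$normalization != "raw") {
    stop("normalize_coverage expects a raw track, got ", track$normalization)
  }
  if (!is.numeric(total_aligned_reads) || total_aligned_reads <= 0) {
    stop("total_aligned_reads must be > 0")
  }
  track$values <- track$values / total_aligned_reads * 1e6
  track$normalization <- "per_million"
  track$total_reads <- total_aligned_reads
  track
}

#' Write a data.frame as a TSV with a header row
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# strand-aware reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
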