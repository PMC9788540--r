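# TSS/PSS calling from TEX+/TEX- 5'-end tracks and coverage-based transcript
# detection, in the spirit of TSSpredator-style enrichment classification.
#
# A 5'-end position is a candidate when max(TEX+, TEX-) >= min_height. The
# enrichment (TEX+ + c)/(TEX- + c) then separates genuine transcription starts
# (primary, 5'PPP ends survive TEX) from processed ends (5'P, degraded by TEX):
# enrichment >= factor -> TSS, otherwise PSS. A PSS additionally requires the
# processed end to be visible in the untreated library (TEX- >= min_height);
# a TEX+-only spike below the enrichment factor is discarded as noise.

#' Default parameters for site calling
#'
#' @return Named list: `min_height` (per-million), `enrichment_factor`,
#'   `pseudocount`, `cluster_window` (nt).
#' @export
site_params <- function(min_height = 5, enrichment_factor = 2,
                        pseudocount = 1, cluster_window = 3) {
  list(min_height = min_height, enrichment_factor = enrichment_factor,
       pseudocount = pseudocount, cluster_window = cluster_window)
}

empty_sites <- function() {
  data.frame(position = integer(0), strand = character(0), kind = character(0),
             height = numeric(0), enrichment = numeric(0),
             condition = character(0), stringsAsFactors = FALSE)
}

#' Call TSSs and PSSs from a TEX+/TEX- 5'-end track pair
#'
#' @param texplus,texminus Per-million `five_prime_ends` coverage tracks of the
#'   TEX-treated and untreated libraries for the same strand and condition.
#' @param params See [site_params()].
#' @return data.frame of site calls: `position`, `strand`, `kind` (TSS/PSS),
#'   `height` (signal of the defining track), `enrichment`, `condition`.
#' @export
call_sites <- function(texplus, texminus, params = site_params()) {
  stopifnot(inherits(texplus, "coverage_track"), inherits(texminus, "coverage_track"))
  if (texplus$strand != texminus$strand) {
    stop("TEX+ and TEX- tracks must be on the same strand")
  }
  if (texplus$normalization != "per_million" || texminus$normalization != "per_million") {
    stop("call_sites requires per-million normalized tracks")
  }
  if (texplus$track_kind != "five_prime_ends" || texminus$track_kind != "five_prime_ends") {
    stop("call_sites requires five_prime_ends tracks")
  }
  tp <- texplus$values
  tm <- texminus$values
  cand <- which(pmax(tp, tm) >= params$min_height)
  if (!length(cand)) return(empty_sites())
  c0 <- params$pseudocount
  enr <- (tp[cand] + c0) / (tm[cand] + c0)
  kind <- ifelse(enr >= params$enrichment_factor, "TSS", "PSS")
  height <- ifelse(kind == "TSS", tp[cand], tm[cand])
  keep <- kind == "TSS" | tm[cand] >= params$min_height
  if (!any(keep)) return(empty_sites())
  sites <- data.frame(position = cand[keep], strand = texplus$strand,
                      kind = kind[keep], height = height[keep],
                      enrichment = enr[keep], condition = texplus$condition,
                      stringsAsFactors = FALSE)
  cluster_sites(sites, params$cluster_window)
}

# merge calls within `window` nt (same strand), keeping the highest-height
# position; ties resolved toward the smaller coordinate for determinism
cluster_sites <- function(sites, window) {
  if (nrow(sites) < 2L) return(sites)
  sites <- sites[order(sites$position), , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(diff(sites$position) > window)))
  keep <- vapply(split(seq_len(nrow(sites)), grp), function(ix) {
    ix[which.max(sites$height[ix])]
  }, integer(1))
  out <- sites[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge site calls across conditions
#'
#' The union of per-condition calls is taken; when the same position (same
#' strand) is called in several conditions the call with the larger height is
#' kept and the provenance string lists every condition that called it. Kind
#' conflicts across conditions are resolved toward the higher-height call.
#'
#' @param site_list List of site-call data.frames from [call_sites()].
#' @return Merged site data.frame with a `conditions` provenance column.
#' @export
merge_site_calls <- function(site_list) {
  all <- do.call(rbind, site_list)
  if (is.null(all) || nrow(all) == 0L) {
    out <- empty_sites()
    out$conditions <- character(0)
    return(out)
  }
  key <- paste(all$strand, all$position)
  out <- do.call(rbind, lapply(split(all, key), function(d) {
    best <- d[order(-d$height, d$condition), , drop = FALSE][1L, , drop = FALSE]
    best$conditions <- paste(sort(unique(d$condition)), collapse = ",")
    best
  }))
  out <- out[order(out$strand, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect transcripts from an ssRNA-seq full-coverage track
#'
#' Maximal runs with coverage >= `t_cov`, allowing internal gaps of at most
#' `gap` nt below threshold; runs shorter than `min_len` nt are discarded.
#'
#' @param ss A per-million `full_coverage` track.
#' @param t_cov Coverage threshold (per-million units).
#' @param gap Maximum tolerated sub-threshold gap (nt).
#' @param min_len Minimum transcript length (nt).
#' @return data.frame: `start`, `end`, `strand`, `mean_coverage`.
#' @export
detect_transcripts <- function(ss, t_cov = 2, gap = 5, min_len = 20) {
  stopifnot(inherits(ss, "coverage_track"))
  if (ss$track_kind != "full_coverage") {
    stop("detect_transcripts requires a full_coverage track")
  }
  covered <- ss$values >= t_cov
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mean_coverage = numeric(0),
                      stringsAsFactors = FALSE))
  }
  # merge runs separated by gaps <= gap
  if (nrow(runs) > 1L) {
    grp <- cumsum(c(1L, as.integer(runs$start[-1L] - runs$end[-nrow(runs)] - 1L > gap)))
    runs <- do.call(rbind, lapply(split(runs, grp), function(d) {
      data.frame(start = min(d$start), end = max(d$end))
    }))
  }
  runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
  if (nrow(runs) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mean_coverage = numeric(0),
                      stringsAsFactors = FALSE))
  }
  runs$strand <- ss$strand
  runs$mean_coverage <- vapply(seq_len(nrow(runs)), function(i) {
    mean(ss$values[runs$start[i]:runs$end[i]])
  }, numeric(1))
  rownames(runs) <- NULL
  runs
}

#' Find the first sharp coverage decrease downstream of a position
#'
#' Scans downstream (strand-aware) of `start_from` and returns the first
#' position where the mean coverage over the next `w` nt drops to at most
#' `d` times the mean over the previous `w` nt; `NA` if no such position is
#' found within `max_len` nt.
#'
#' @param ss A per-million `full_coverage` track.
#' @param start_from 5'-end position to scan from.
#' @param strand `"+"` or `"-"`.
#' @param w Window size (nt) on either side of the tested boundary.
#' @param d Drop ratio threshold.
#' @param max_len Maximum scan distance (nt).
#' @return Integer position of the last retained nucleotide before the drop,
#'   or `NA_integer_`.
#' @export
find_sharp_decrease <- function(ss, start_from, strand = ss$strand,
                                w = 5, d = 0.5, max_len = 500) {
  stopifnot(inherits(ss, "coverage_track"))
  v <- ss$values
  n <- length(v)
  if (strand == "+") {
    hi <- min(start_from + max_len - 1L, n - w)
    if (start_from + w > hi) return(NA_integer_)
    for (e in seq.int(start_from + w, hi)) {
      prev <- mean(v[(e - w + 1L):e])
      nxt <- mean(v[(e + 1L):(e + w)])
      if (prev > 0 && nxt <= d * prev) return(as.integer(e))
    }
  } else {
    lo <- max(start_from - max_len + 1L, w + 1L)
    if (start_from - w < lo) return(NA_integer_)
    for (e in seq.int(start_from - w, lo)) {
      prev <- mean(v[e:(e + w - 1L)])
      nxt <- mean(v[(e - w):(e - 1L)])
      if (prev > 0 && nxt <= d * prev) return(as.integer(e))
    }
  }
  NA_integer_
}

#' Average replicate tracks
#'
#' @param tracks List of `coverage_track`s with identical metadata apart from
#'   the replicate index.
#' @return A single `coverage_track` of per-position means (replicate 0).
#' @export
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  vals <- rowMeans(do.call(cbind, lapply(tracks, `[[`, "values")))
  out <- tracks[[1L]]
  out$values <- vals
  out$replicate <- 0L
  out
}
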