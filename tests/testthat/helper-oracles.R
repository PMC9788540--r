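# Independent oracles used to verify the package's own implementations.
# Each oracle is deliberately written as a different algorithm (or a direct
# closed form) from the code path it checks.

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "U", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_dna <- function(n, gc = 0.5) chartr("U", "T", random_rna(n, gc))

.can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# exhaustive recursion over all non-crossing pairings (no memoisation);
# feasible for n <= ~16
oracle_max_pairs_exhaustive <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "", fixed = TRUE)[[1]]
  f <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- f(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (.can_pair(s[i], s[k])) {
        best <- max(best, 1L + f(i + 1L, k - 1L) +
                      (if (k < j) f(k + 1L, j) else 0L))
      }
    }
    best
  }
  if (length(s) < 2L) return(0L)
  f(1L, length(s))
}

# top-down memoised recursion in R (independent of the package's bottom-up
# C++ fill); handles n <= ~40 comfortably
oracle_max_pairs <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < 2L) return(0L)
  memo <- matrix(NA_integer_, n, n)
  f <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- f(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (.can_pair(s[i], s[k])) {
        best <- max(best, 1L + f(i + 1L, k - 1L) +
                      (if (k < j) f(k + 1L, j) else 0L))
      }
    }
    memo[i, j] <<- best
    best
  }
  f(1L, n)
}

# regex-on-codons sORF oracle
oracle_sorfs <- function(seq, min_aa = 20) {
  s <- chartr("T", "U", toupper(seq))
  n <- nchar(s)
  rows <- list()
  for (f in 0:2) {
    if (f + 3L > n) next
    at <- seq.int(f + 1L, n - 2L, by = 3L)
    codons <- substring(s, at, at + 2L)
    cstr <- paste(ifelse(codons %in% c("UAA", "UAG", "UGA"), "#",
                         ifelse(codons == "AUG", "M", "x")), collapse = "")
    m <- gregexpr("M[Mx]*#", cstr)[[1]]
    if (m[1] == -1L) next
    for (k in seq_along(m)) {
      ncod <- attr(m, "match.length")[k]
      aa <- ncod - 1L
      if (aa < min_aa) next
      start <- at[m[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, start_offset = start,
        end_offset = start + ncod * 3L - 1L, aa_length = aa)
    }
  }
  if (!length(rows)) {
    return(data.frame(frame = integer(0), start_offset = integer(0),
                      end_offset = integer(0), aa_length = integer(0)))
  }
  do.call(rbind, rows)
}

# position-by-position brute GGA scan
oracle_gga <- function(seq, structure) {
  s <- chartr("TU", "UU", toupper(seq))
  br <- strsplit(structure, "", fixed = TRUE)[[1]]
  res <- c(unpaired = 0L, partially_paired = 0L, paired = 0L)
  for (i in seq_len(nchar(s) - 2L)) {
    if (substr(s, i, i + 2L) != "GGA") next
    nun <- sum(br[i:(i + 2L)] == ".")
    res[if (nun == 3L) "unpaired" else if (nun == 0L) "paired"
        else "partially_paired"] <-
      res[if (nun == 3L) "unpaired" else if (nun == 0L) "paired"
          else "partially_paired"] + 1L
  }
  res
}

# full (unseeded) Smith-Waterman identity oracle over the whole subject
oracle_sw_identity <- function(query, subject) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = TRUE)
  best <- NULL
  for (q in c(query, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(query))))) {
    aln <- Biostrings::pairwiseAlignment(q, subject, type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 5, gapExtension = 2)
    pat <- as.character(Biostrings::pattern(aln))
    cols <- nchar(pat)
    if (cols == 0) next
    idn <- 100 * Biostrings::nmatch(aln) / cols
    cov <- 100 * nchar(gsub("-", "", pat, fixed = TRUE)) / nchar(query)
    if (is.null(best) || Biostrings::score(aln) > best$score) {
      best <- list(identity = idn, coverage = cov,
                   score = Biostrings::score(aln))
    }
  }
  best
}

# all-equal-length-substring antisense duplex oracle
oracle_duplex_score <- function(srna, window, seed_min = 7, gu = TRUE) {
  code <- function(x) match(strsplit(chartr("Tacgtu", "UACGUU", x), "",
                                     fixed = TRUE)[[1]], c("A", "C", "G", "U"))
  smat <- matrix(0, 4, 4)
  smat[1, 4] <- smat[4, 1] <- 2
  smat[3, 2] <- smat[2, 3] <- 3
  if (gu) smat[3, 4] <- smat[4, 3] <- 1
  qi <- code(srna); wi <- code(window)
  m <- length(qi); n <- length(wi)
  best <- NA_real_
  for (l in seed_min:min(m, n)) {
    for (i in 1:(m - l + 1)) {
      qseg <- rev(qi[i:(i + l - 1)])
      for (j in 1:(n - l + 1)) {
        wseg <- wi[j:(j + l - 1)]
        if (any(is.na(qseg)) || any(is.na(wseg))) next
        sc <- smat[cbind(qseg, wseg)]
        if (all(sc > 0)) best <- max(best, sum(sc), na.rm = TRUE)
      }
    }
  }
  best
}

# closed-form asymptotic rank-sum p (tie-corrected, no continuity correction)
oracle_wilcox <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- (W - mu) / sqrt(sigma2)
  list(statistic = W, p = 2 * stats::pnorm(-abs(z)))
}

# Spearman rho as Pearson on ranks, p via the t approximation
oracle_spearman <- function(x, y) {
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  stat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(stat), n - 2))
}

# shared acceptance-scale dataset (generated once per test run)
.fixture_env <- new.env(parent = emptyenv())

acceptance_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- generate_dataset(synthetic_config(seed = 20260920))
  }
  .fixture_env$ds
}

acceptance_pipeline <- function() {
  if (is.null(.fixture_env$res)) {
    .fixture_env$res <- run_pipeline(acceptance_dataset(), verbose = FALSE)
  }
  .fixture_env$res
}

# small fast dataset for module-level tests
small_dataset <- function(noise = 0.2, seed = 42) {
  key <- paste0("small_", noise, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_dataset(synthetic_config(
      genome_length = 60000, n_cds = 40, n_rrna = 1, n_trna = 3,
      n_srna_per_class = c(inter = 3, as = 3, `5UTR` = 2, `5CDS` = 2, mCDS = 2,
                           `3CDS` = 2, `3UTR` = 2, `3rRNA` = 1, `2CDSs` = 2,
                           intra_as = 1),
      noise = noise, seed = seed))
  }
  .fixture_env[[key]]
}

# match recovered candidates to planted sRNAs: strand-aware 5' end within
# tol5, 3' end within tol3
match_candidates <- function(cands, truth, tol5 = 1, tol3 = 5) {
  p5c <- ifelse(cands$strand == "+", cands$start, cands$end)
  p3c <- ifelse(cands$strand == "+", cands$end, cands$start)
  p5t <- ifelse(truth$strand == "+", truth$start, truth$end)
  p3t <- ifelse(truth$strand == "+", truth$end, truth$start)
  idx <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    j <- which(cands$strand == truth$strand[i] &
                 abs(p5c - p5t[i]) <= tol5 & abs(p3c - p3t[i]) <= tol3)
    if (length(j)) idx[i] <- j[1]
  }
  idx
}
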