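test_that("origin classification maps anchor kind to ts/ps", {
  expect_equal(classify_origin("TSS"), "ts")
  expect_equal(classify_origin("PSS"), "ps")
  expect_error(classify_origin(NA), "anchor")
})

test_that("sRNA naming uses the strand-aware 5' position with uniqueness", {
  expect_equal(name_srna(3935639L, 3935800L, "+"), "sRNA3935639")
  expect_equal(name_srna(4307500L, 4307718L, "-"), "sRNA4307718")
  ids <- name_srna(c(100L, 50L), c(150L, 100L), c("+", "-"))
  expect_equal(ids, c("sRNA100", "sRNA100m"))
  expect_false(any(duplicated(ids)))
})

# a hand-built locus exercising every location rule:
# '+' CDS [1000,1600] with UTR allowances 50/80, '-' CDS [3000,3600],
# rRNA '+' [5000,6500], 2 close same-strand CDSs [8000,8400] & [8550,8950],
# convergent pair [11000,11500]'+' / [11560,12060]'-'
loc_ann <- data.frame(
  gene_id = c("cdsA", "cdsB", "rrn1", "opA", "opB", "cvA", "cvB"),
  feature_type = c("CDS", "CDS", "rRNA", "CDS", "CDS", "CDS", "CDS"),
  start = c(1000L, 3000L, 5000L, 8000L, 8550L, 11000L, 11560L),
  end = c(1600L, 3600L, 6500L, 8400L, 8950L, 11500L, 12060L),
  strand = c("+", "-", "+", "+", "+", "+", "-"),
  product = NA)

loc_case <- function(start, end, strand) {
  cand <- data.frame(start = start, end = end, strand = strand)
  got <- classify_location(cand, loc_ann, 20000L)
  c(got$location_class, got$location_subtype)
}

test_that("location classes and subtypes follow the decision rules", {
  expect_equal(loc_case(2000, 2200, "+"), c("inter", "none"))
  expect_equal(loc_case(1100, 1400, "-"), c("as", "none"))        # inside '+' CDS
  expect_equal(loc_case(955, 999, "+"), c("intra", "5UTR"))       # within 5'UTR
  expect_equal(loc_case(970, 1100, "+"), c("intra", "5CDS"))      # spans CDS start
  expect_equal(loc_case(1100, 1400, "+"), c("intra", "mCDS"))     # inside CDS
  expect_equal(loc_case(1500, 1650, "+"), c("intra", "3CDS"))     # spans CDS end
  expect_equal(loc_case(1610, 1670, "+"), c("intra", "3UTR"))     # within 3'UTR
  # minus-strand gene mirrors the geometry (5' end at the higher coordinate)
  expect_equal(loc_case(3601, 3645, "-"), c("intra", "5UTR"))
  expect_equal(loc_case(3500, 3640, "-"), c("intra", "5CDS"))
  expect_equal(loc_case(2950, 3100, "-"), c("intra", "3CDS"))
  expect_equal(loc_case(6400, 6580, "+"), c("intra", "3rRNA"))    # over rRNA 3' end
  expect_equal(loc_case(8350, 8600, "+"), c("intra", "2CDSs"))    # spans two CDSs
  expect_equal(loc_case(11400, 11530, "+"), c("intra_as", "3CDS"))
})

test_that("every candidate gets exactly one class/subtype and subtype none iff inter/as", {
  set.seed(31)
  cand <- data.frame(start = sample(500:12500, 60))
  cand$end <- cand$start + sample(60:300, 60, replace = TRUE)
  cand$strand <- sample(c("+", "-"), 60, replace = TRUE)
  got <- classify_location(cand, loc_ann, 20000L)
  expect_true(all(got$location_class %in% c("inter", "as", "intra", "intra_as")))
  expect_equal(got$location_subtype == "none",
               got$location_class %in% c("inter", "as"))
  s <- summarize_classes(cbind(got, origin_class = "ts"))
  expect_equal(sum(s$location$count), 60L)
})

test_that("detect_srnas applies the three criteria on planted data", {
  ds <- small_dataset(noise = 0)
  avg <- srnascape:::averaged_tracks(ds)
  conds <- names(avg)
  sl <- list(); trl <- list()
  for (cond in conds) for (st in c("+", "-")) {
    sl[[paste(cond, st)]] <- call_sites(avg[[cond]]$texplus[[st]],
                                        avg[[cond]]$texminus[[st]])
    tr <- detect_transcripts(avg[[cond]]$ss[[st]])
    tr$condition <- cond
    trl[[paste(cond, st)]] <- tr
  }
  sites <- merge_site_calls(sl)
  transcripts <- do.call(rbind, trl)
  cands <- detect_srnas(transcripts, sites, lapply(avg, `[[`, "ss"),
                        lapply(avg, function(a) list(texplus = a$texplus,
                                                     texminus = a$texminus)),
                        ds$genome)
  cands <- srnascape:::consolidate_candidates(cands)
  truth <- ds$truth$srnas[ds$truth$srnas$detectable, ]
  idx <- match_candidates(cands, truth)
  expect_true(all(!is.na(idx)))
  # noise off: PSS-terminated sRNAs are recovered at the exact interval
  pssed <- which(truth$end_evidence == "PSS")
  expect_equal(cands$start[idx[pssed]], truth$start[pssed])
  expect_equal(cands$end[idx[pssed]], truth$end[pssed])
  expect_equal(cands$origin_class[idx], truth$origin_class)
  # all abundances pass the >= 10 gate in at least one condition
  ab <- as.matrix(cands[, grep("^abundance_", names(cands))])
  expect_true(all(apply(ab, 1, max) >= 10))
  # candidate lengths respect the size selection
  expect_true(all(cands$length >= 50 & cands$length <= 500))
})

test_that("sub-threshold abundance and short intervals are rejected", {
  glen <- 3000L
  gseq <- random_dna(glen)
  mk_cov <- function(v, st) coverage_track(v, st, library = "SS",
                                           track_kind = "full_coverage",
                                           condition = "c1",
                                           normalization = "per_million")
  mk5 <- function(v, st, lib) coverage_track(v, st, library = lib,
                                             track_kind = "five_prime_ends",
                                             condition = "c1",
                                             normalization = "per_million")
  # interval [1001,1200] with mean coverage 8: fails criterion (ii)
  ss <- rep(0, glen); ss[1001:1200] <- 8
  tp <- rep(0, glen); tm <- rep(0, glen)
  tp[1001] <- 50; tm[1001] <- 2      # TSS at 5' end
  tm[1201] <- 40; tp[1201] <- 8      # PSS at 3' end + 1
  sites <- merge_site_calls(list(call_sites(mk5(tp, "+", "TEXplus"),
                                            mk5(tm, "+", "TEXminus"))))
  trs <- detect_transcripts(mk_cov(ss, "+"))
  trs$condition <- "c1"
  ssb <- list(c1 = list(`+` = mk_cov(ss, "+"), `-` = mk_cov(rep(0, glen), "-")))
  drb <- list(c1 = list(texplus = list(`+` = mk5(tp, "+", "TEXplus"),
                                       `-` = mk5(rep(0, glen), "-", "TEXplus")),
                        texminus = list(`+` = mk5(tm, "+", "TEXminus"),
                                        `-` = mk5(rep(0, glen), "-", "TEXminus"))))
  cands <- detect_srnas(trs, sites, ssb, drb, gseq)
  expect_equal(nrow(cands), 0L)
  # raise coverage to 12: passes
  ss2 <- rep(0, glen); ss2[1001:1200] <- 12
  ssb2 <- list(c1 = list(`+` = mk_cov(ss2, "+"), `-` = mk_cov(rep(0, glen), "-")))
  trs2 <- detect_transcripts(mk_cov(ss2, "+")); trs2$condition <- "c1"
  cands2 <- detect_srnas(trs2, sites, ssb2, drb, gseq)
  expect_true(nrow(cands2) >= 1L)
  expect_equal(cands2$start[1], 1001L)
  expect_equal(cands2$end[1], 1200L)
  expect_equal(cands2$end_evidence[1], "PSS")
  # a 40-nt interval passing coverage rules is rejected by min_len
  tm3 <- rep(0, glen); tm3[1041] <- 40; tm3[1201] <- 40; tp3 <- rep(0, glen)
  tp3[1001] <- 50
  sites3 <- merge_site_calls(list(call_sites(mk5(tp3, "+", "TEXplus"),
                                             mk5(tm3, "+", "TEXminus"))))
  cands3 <- detect_srnas(trs2, sites3, ssb2, drb, gseq)
  expect_false(any(cands3$length < 50))
})

test_that("detect_srnas output is invariant to input row order", {
  ds <- small_dataset()
  avg <- srnascape:::averaged_tracks(ds)
  sl <- list(); trl <- list()
  for (cond in names(avg)) for (st in c("+", "-")) {
    sl[[paste(cond, st)]] <- call_sites(avg[[cond]]$texplus[[st]],
                                        avg[[cond]]$texminus[[st]])
    tr <- detect_transcripts(avg[[cond]]$ss[[st]]); tr$condition <- cond
    trl[[paste(cond, st)]] <- tr
  }
  sites <- merge_site_calls(sl)
  transcripts <- do.call(rbind, trl)
  ssb <- lapply(avg, `[[`, "ss")
  drb <- lapply(avg, function(a) list(texplus = a$texplus, texminus = a$texminus))
  c1 <- detect_srnas(transcripts, sites, ssb, drb, ds$genome)
  set.seed(1)
  c2 <- detect_srnas(transcripts[sample(nrow(transcripts)), ],
                     sites[sample(nrow(sites)), ], ssb, drb, ds$genome)
  o1 <- c1[order(c1$id, c1$start, c1$end), ]
  o2 <- c2[order(c2$id, c2$start, c2$end), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("redundancy clustering groups near-identical sequences only", {
  s <- random_rna(200, gc = 0.6)
  cl <- cluster_redundant(c("a", "b"), c(s, s))
  expect_equal(cl$cluster, c(1L, 1L))
  # two unrelated random sequences are singletons
  cl2 <- cluster_redundant(c("a", "b"), c(random_rna(200, 0.6), random_rna(200, 0.6)))
  expect_equal(sort(unique(cl2$cluster)), c(1L, 2L))
  # boundary case: heavily substituted copy; the cluster decision must agree
  # with the alignment oracle's identity against the 0.70 threshold
  set.seed(41)
  base <- random_dna(200, gc = 0.6)
  ch <- strsplit(base, "")[[1]]
  mut <- sample(200, 40)
  for (i in mut) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  mutant <- paste(ch, collapse = "")
  cl3 <- cluster_redundant(c("a", "b"), c(base, mutant))
  o <- oracle_sw_identity(mutant, base)
  same_cluster <- cl3$cluster[1] == cl3$cluster[2]
  expect_equal(same_cluster, o$identity >= 70 && o$coverage >= 90)
})
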