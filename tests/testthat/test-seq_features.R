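test_that("gc_content counts G+C over length, N as non-GC", {
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("AATT"), 0.0)
  expect_equal(gc_content("GCNN"), 0.5)
  expect_error(gc_content(""), "nonempty")
})

test_that("base-pair proxy folding matches exhaustive and memoised oracles", {
  expect_equal(fold_mfe("AAAA"), 0)
  expect_equal(fold_mfe("GGGGAAAACCCC"), -4)
  set.seed(11)
  for (i in 1:12) {
    s <- random_rna(sample(8:14, 1))
    expect_equal(-fold_mfe(s), oracle_max_pairs_exhaustive(s), info = s)
  }
  for (i in 1:200) {
    s <- random_rna(sample(5:25, 1), gc = runif(1, 0.3, 0.7))
    expect_equal(-fold_mfe(s), oracle_max_pairs(s), info = s)
  }
})

test_that("proxy structure is balanced and consistent with the pair count", {
  set.seed(3)
  for (i in 1:20) {
    s <- random_rna(sample(20:80, 1))
    db <- fold_structure(s)
    expect_equal(nchar(db), nchar(s))
    op <- sum(strsplit(db, "")[[1]] == "(")
    cl <- sum(strsplit(db, "")[[1]] == ")")
    expect_equal(op, cl)
    expect_equal(op, -fold_mfe(s))
  }
})

test_that("nmfe divides by length and tandem duplication never increases it", {
  expect_equal(nmfe(-10, 100), -0.1)
  expect_equal(nmfe(0, 50), 0)
  expect_equal(nmfe(-98.4, 205), -0.48)
  expect_error(nmfe(-1, 0), "length")
  set.seed(5)
  for (i in 1:10) {
    s <- random_rna(sample(10:30, 1))
    n1 <- nmfe(fold_mfe(s), nchar(s))
    s2 <- paste0(s, s)
    n2 <- nmfe(fold_mfe(s2), nchar(s2))
    expect_lte(n2, n1 + 1e-12)
  }
})

test_that("group comparisons match the closed-form rank-sum computation", {
  set.seed(7)
  g <- data.frame(
    length = c(rnorm(20, 200, 10), rnorm(20, 260, 10), rnorm(15, 230, 20)),
    gc = runif(55), nmfe = -runif(55, 0.3, 0.5),
    group = rep(c("a", "b", "c"), c(20, 20, 15)))
  res <- compare_feature_groups(g)
  expect_equal(nrow(res), 9L)  # 3 features x 3 pairs
  for (i in seq_len(nrow(res))) {
    x <- g[[res$feature[i]]][g$group == res$group1[i]]
    y <- g[[res$feature[i]]][g$group == res$group2[i]]
    o <- oracle_wilcox(x, y)
    expect_equal(res$p[i], o$p, tolerance = 1e-8)
    expect_equal(res$statistic[i], o$statistic)
  }
  # clearly separated groups are strongly significant
  row <- res[res$feature == "length" & res$group1 == "a" & res$group2 == "b", ]
  expect_lt(row$p, 1e-6)
  # identical groups give p near 1
  g2 <- data.frame(length = rep(c(1, 2, 3, 4), 2), gc = 0.5, nmfe = -0.4,
                   group = rep(c("a", "b"), each = 4))
  res2 <- compare_feature_groups(g2, features = "length")
  expect_equal(res2$p, 1, tolerance = 1e-9)
  # n < 3 groups are excluded with a warning
  g3 <- rbind(g, data.frame(length = 1, gc = 0.1, nmfe = -0.1, group = "tiny"))
  expect_warning(compare_feature_groups(g3), "tiny")
})

test_that("GC/NMFE correlation matches an independent Spearman computation", {
  expect_equal(correlate_gc_nmfe(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1))$rho, -1)
  expect_error(correlate_gc_nmfe(1:3, 1:3), ">= 4")
  expect_true(is.na(correlate_gc_nmfe(rep(1, 5), 1:5)$rho))
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(25); y <- rnorm(25)
    got <- correlate_gc_nmfe(x, y)
    o <- oracle_spearman(x, y)
    expect_equal(got$rho, o$rho, tolerance = 1e-8)
    expect_equal(got$p, o$p, tolerance = 1e-8)
  }
})

test_that("motif profile frequencies, IC and consensus behave per contract", {
  gseq <- paste(rep("ACGT", 300), collapse = "")
  sites <- data.frame(position = seq(101, 401, by = 20), strand = "+")
  prof <- motif_profile(sites, gseq, window = c(-5, 5))
  expect_true(all(abs(rowSums(prof$freq) - 1) < 1e-9))
  # genome is a fixed 4-periodic repeat and sites are 20-periodic:
  # every window is identical, so IC is 2 bits everywhere
  expect_true(all(abs(prof$ic - 2) < 1e-9))
  expect_true(all(prof$ic >= 0 & prof$ic <= 2))
  expect_error(motif_profile(sites[1:5, ], gseq), ">= 10")
  # minus-strand profile of the same sites equals the reverse complement view
  sm <- data.frame(position = sites$position, strand = "-")
  pm <- motif_profile(sm, gseq, window = c(-5, 5))
  expect_true(all(abs(rowSums(pm$freq) - 1) < 1e-9))
  # order invariance
  p2 <- motif_profile(sites[sample(nrow(sites)), ], gseq, window = c(-5, 5))
  expect_equal(p2$consensus, prof$consensus)
})

test_that("consensus calling emits single bases, 2-letter codes and N", {
  # single base: freq >= 0.5 and >= 2x runner-up
  expect_equal(srnascape:::consensus_base(c(A = 0.7, C = 0.3, G = 0, U = 0)), "A")
  # two-letter IUPAC: top two >= 0.75 total, each >= 0.25
  expect_equal(srnascape:::consensus_base(c(A = 0.5, C = 0, G = 0.45, U = 0.05)), "R")
  expect_equal(srnascape:::consensus_base(c(A = 0.4, C = 0.05, G = 0.15, U = 0.4)), "W")
  expect_equal(srnascape:::consensus_base(c(A = 0.3, C = 0.3, G = 0.2, U = 0.2)), "N")
})

test_that("sORF finder matches the regex oracle and its stated examples", {
  s <- paste0("AUG", paste(rep("GCU", 20), collapse = ""), "UAA")
  got <- find_sorfs(s)
  expect_equal(nrow(got), 1L)
  expect_equal(got$aa_length, 21L)
  expect_equal(got$start_offset, 1L)
  expect_equal(got$end_offset, nchar(s))
  expect_equal(nrow(find_sorfs("CCCCCCUUUUUU")), 0L)
  set.seed(13)
  for (i in 1:100) {
    x <- random_rna(400, gc = runif(1, 0.4, 0.65))
    got <- find_sorfs(x, min_aa = 10)
    want <- oracle_sorfs(x, min_aa = 10)
    rownames(got) <- rownames(want) <- NULL
    o <- order(got$frame, got$start_offset)
    w <- order(want$frame, want$start_offset)
    expect_equal(got[o, ], want[w, ], info = x)
  }
})

test_that("GGA motif counting classifies pairing states and matches brute scan", {
  expect_equal(count_gga_motifs("GGA", "..."),
               c(unpaired = 1L, partially_paired = 0L, paired = 0L))
  expect_equal(count_gga_motifs("GGAGGA", "((.))."),
               c(unpaired = 0L, partially_paired = 2L, paired = 0L))
  expect_error(count_gga_motifs("GGA", ".."), "length")
  expect_error(count_gga_motifs("GGAA", "(()."))
  set.seed(17)
  for (i in 1:50) {
    s <- random_rna(sample(30:120, 1), gc = 0.6)
    db <- fold_structure(s)
    expect_equal(count_gga_motifs(s, db), oracle_gga(s, db), info = s)
  }
})
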