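test_that("TPM normalization follows the rate definition and sums to 1e6", {
  expect_equal(compute_tpm(c(10, 10), c(100, 200)),
               c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-9)
  expect_equal(compute_tpm(5, 123), 1e6)
  expect_equal(compute_tpm(rep(7, 8), rep(50, 8)), rep(1e6 / 8, 8))
  set.seed(2)
  tpm <- compute_tpm(rpois(40, 100), sample(50:500, 40))
  expect_equal(sum(tpm), 1e6, tolerance = 1e-3)
  expect_error(compute_tpm(c(0, 0), c(1, 1)), "positive count")
  expect_error(compute_tpm(c(1, -1), c(1, 1)), "non-negative")
})

test_that("identical replicate sets yield zero fold change and ns status", {
  m <- matrix(rep(c(10, 20, 30, 40), 6), ncol = 6)
  rownames(m) <- paste0("f", 1:4)
  de <- differential_expression(m, rep(c("A", "B"), each = 3))
  expect_equal(de$log2fc, rep(0, 4))
  expect_equal(de$status, rep("ns", 4))
  expect_equal(de$pvalue, rep(1, 4))
})

test_that("all-zero features are ns with p = 1 and status partition is exhaustive", {
  set.seed(4)
  m <- rbind(matrix(rnbinom(5 * 6, mu = 100, size = 10), ncol = 6),
             rep(0, 6))
  rownames(m) <- paste0("f", 1:6)
  de <- differential_expression(m, rep(c("A", "B"), each = 3))
  expect_equal(de$status[6], "ns")
  expect_equal(de$pvalue[6], 1)
  expect_true(all(de$status %in% c("up", "down", "ns")))
  # BH monotonicity: padj ordering preserves p ordering
  o <- order(de$pvalue)
  expect_true(all(diff(de$padj[o]) >= -1e-12))
})

test_that("top-expressed lists are deterministic and overlap as constructed", {
  set.seed(6)
  tpm <- matrix(runif(120, 1, 1000), nrow = 20,
                dimnames = list(paste0("f", 1:20), NULL))
  labs <- rep(c("A", "B"), each = 3)
  t1 <- top_expressed(tpm, labs, n = 5)
  perm <- sample(20)
  t2 <- top_expressed(tpm[perm, ], labs, n = 5)
  expect_equal(sort(t1$top$A), sort(t2$top$A))
  expect_equal(t1$overlap, t2$overlap)
  # identical expression in both conditions -> full overlap
  tpm2 <- cbind(tpm[, 1:3], tpm[, 1:3])
  t3 <- top_expressed(tpm2, labs, n = 7)
  expect_equal(t3$overlap, 7L)
  expect_error(top_expressed(tpm[1:3, ], labs, n = 5), "fewer features")
})

test_that("CsrA ANGGA scan matches a direct regex oracle", {
  set.seed(9)
  glen <- 12000
  gseq <- random_dna(glen, gc = 0.55)
  starts <- seq(200, glen - 400, by = 240)
  ann <- data.frame(gene_id = sprintf("g%03d", seq_along(starts)),
                    feature_type = "CDS", start = starts, end = starts + 150,
                    strand = rep(c("+", "-"), length.out = length(starts)),
                    product = NA)
  res <- scan_csra_targets(ann, gseq)
  # oracle: extract each window directly and regex-count overlapping ANGGA
  for (i in seq_len(nrow(ann))) {
    p0 <- if (ann$strand[i] == "+") ann$start[i] else ann$end[i]
    win <- if (ann$strand[i] == "+") substr(gseq, p0 - 25, p0 + 10) else
      srnascape:::revcomp(substr(gseq, p0 - 10, p0 + 25))
    nhit <- length(gregexpr("(?=A.GGA)", win, perl = TRUE)[[1]])
    if (gregexpr("(?=A.GGA)", win, perl = TRUE)[[1]][1] == -1L) nhit <- 0L
    in_res <- ann$gene_id[i] %in% res$gene_id
    expect_equal(in_res, nhit >= 1, info = ann$gene_id[i])
    if (in_res) expect_equal(res$n_motifs[res$gene_id == ann$gene_id[i]], nhit)
  }
  # upstream AAGGA at a fixed offset counts as one occurrence
  g2 <- paste0(paste(rep("C", 100), collapse = ""), "AAGGA",
               paste(rep("C", 12), collapse = ""),
               "ATGAAACCC", paste(rep("C", 50), collapse = ""))
  ann2 <- data.frame(gene_id = "x", feature_type = "CDS", start = 118,
                     end = 126, strand = "+", product = NA)
  r2 <- scan_csra_targets(ann2, g2)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$n_motifs, 1L)
})

test_that("duplex scores match the all-substring oracle and stated arithmetic", {
  # exact reverse complement of a 20-nt window segment: 10 GC + 10 AU -> 50
  win <- c(g1 = "GGGGGGGGGGAAAAAAAAAA")
  srna <- "UUUUUUUUUUCCCCCCCCCC"
  got <- predict_trans_targets(srna, win)
  expect_equal(got$duplex_score, 50)
  expect_equal(got$rank, 1L)
  # no complementarity -> no predictions
  expect_equal(nrow(predict_trans_targets("AAAAAAAAAA",
                                          c(g = "AAAAAAAAAAAA"))), 0L)
  set.seed(21)
  for (i in 1:40) {
    s <- random_rna(30)
    w <- setNames(random_rna(sample(40:60, 1)), "g")
    got <- predict_trans_targets(s, w)
    want <- oracle_duplex_score(s, w[[1]])
    if (nrow(got) == 0) expect_true(is.na(want))
    else expect_equal(got$duplex_score, want)
  }
  # GU pairs only count when enabled
  s <- "UUUUUUUUUU"
  wgu <- c(g = "GGGGGGGGGG")
  expect_equal(predict_trans_targets(s, wgu, gu = TRUE)$duplex_score, 10)
  expect_equal(nrow(predict_trans_targets(s, wgu, gu = FALSE)), 0L)
})

test_that("duplex scoring is symmetric under reverse-complement exchange", {
  set.seed(23)
  for (i in 1:10) {
    s <- random_rna(25)
    w <- random_rna(35)
    a <- predict_trans_targets(s, c(g = w))
    b <- predict_trans_targets(w, c(g = s))
    if (nrow(a) == 0) expect_equal(nrow(b), 0L)
    else expect_equal(a$duplex_score, b$duplex_score)
  }
})

test_that("direct-relation criteria follow the three-rule classifier", {
  srnas <- data.frame(
    id = c("s1", "s2", "s3", "s4"),
    location_class = c("intra", "as", "inter", "intra_as"),
    overlapping_gene_ids = c("alkB1", "", "", "almA"),
    antisense_gene_ids = c("", "alkB2", "", "ompS"))
  ints <- list(
    s3 = data.frame(target_gene_id = c("ompS", "mcp"), duplex_score = c(30, 20),
                    rank = 1:2),
    s1 = data.frame(target_gene_id = "cheR", duplex_score = 25, rank = 1))
  genes <- c("alkB1", "alkB2", "almA", "ompS", "mcp", "cheR")
  rel <- classify_direct_relations(srnas, c("alkB1", "alkB2", "ompS", "cheR"),
                                   ints, genes, top_k = 10)
  get <- function(s, g) rel$criteria[rel$srna_id == s & rel$key_gene_id == g]
  expect_equal(get("s1", "alkB1"), "i")
  expect_equal(get("s2", "alkB2"), "ii")
  expect_equal(get("s3", "ompS"), "iii")
  expect_equal(get("s1", "cheR"), "iii")
  expect_equal(get("s4", "ompS"), "ii")
  # rank cutoff excludes deep-ranked targets
  rel2 <- classify_direct_relations(srnas, "mcp",
                                    list(s3 = data.frame(target_gene_id = "mcp",
                                                         duplex_score = 5,
                                                         rank = 11)),
                                    genes, top_k = 10)
  expect_equal(nrow(rel2), 0L)
  expect_error(classify_direct_relations(srnas, "nope", ints, genes), "nope")
})
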