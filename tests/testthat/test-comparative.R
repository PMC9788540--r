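test_that("exact substring queries hit with full identity and coverage", {
  set.seed(51)
  subject <- random_dna(5000, gc = 0.6)
  q <- substr(subject, 1201, 1320)
  h <- homology_search(q, subject, min_identity = 75, min_coverage = 75)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 100)
  expect_equal(h$query_coverage, 100)
  expect_equal(h$strand, "+")
  expect_equal(c(h$subject_start, h$subject_end), c(1201L, 1320L))
})

test_that("reverse-complement queries return the same hits with flipped strand", {
  set.seed(52)
  subject <- random_dna(4000, gc = 0.55)
  q <- substr(subject, 501, 620)
  qr <- srnascape:::revcomp(q)
  h1 <- homology_search(q, subject, 60, 50)
  h2 <- homology_search(qr, subject, 60, 50)
  expect_equal(h1$subject_start, h2$subject_start)
  expect_equal(h1$subject_end, h2$subject_end)
  expect_equal(h1$identity, h2$identity)
  expect_true(all(h1$strand != h2$strand))
})

test_that("hit counts are monotone in thresholds and random queries miss", {
  set.seed(53)
  ds <- small_dataset()
  subject <- mutate_genome(ds$genome, 0.10, seed = 3)
  tr <- ds$truth$srnas
  idx <- build_genome_index(subject)
  n_loose <- 0L; n_strict <- 0L
  for (i in seq_len(min(8, nrow(tr)))) {
    q <- substr(as.character(ds$genome)[1], tr$start[i], tr$end[i])
    n_loose <- n_loose + nrow(homology_search(q, index = idx,
                                              min_identity = 60,
                                              min_coverage = 50))
    n_strict <- n_strict + nrow(homology_search(q, index = idx,
                                                min_identity = 75,
                                                min_coverage = 75))
  }
  expect_lte(n_strict, n_loose)
  # unrelated random queries find nothing at 60/50
  for (i in 1:5) {
    q <- random_dna(200, gc = 0.6)
    expect_equal(nrow(homology_search(q, index = idx, min_identity = 60,
                                      min_coverage = 50)), 0L)
  }
})

test_that("mutated-locus identity matches the binomial expectation band", {
  set.seed(54)
  ds <- small_dataset()
  mut <- mutate_genome(ds$genome, 0.10, seed = 9)
  tr <- ds$truth$srnas
  tr <- tr[tr$end - tr$start + 1 >= 150, ]
  idx <- build_genome_index(mut)
  ids <- numeric(0)
  for (i in seq_len(min(6, nrow(tr)))) {
    q <- substr(as.character(ds$genome)[1], tr$start[i], tr$end[i])
    h <- homology_search(q, index = idx, min_identity = 60, min_coverage = 50)
    if (nrow(h)) ids <- c(ids, h$identity[1])
  }
  expect_gte(length(ids), 4)
  # 90% +/- 4 (binomial 95% band at ~200 nt)
  expect_true(all(ids >= 86 & ids <= 94))
})

test_that("seeded search identity agrees with the full Smith-Waterman oracle", {
  set.seed(55)
  for (i in 1:12) {
    subject <- random_dna(1500, gc = 0.55)
    qlen <- sample(50:60, 1)
    at <- sample(200:1200, 1)
    q <- substr(subject, at, at + qlen - 1)
    # plant a few substitutions
    ch <- strsplit(q, "")[[1]]
    for (j in sample(qlen, sample(0:4, 1))) {
      ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    }
    q <- paste(ch, collapse = "")
    h <- homology_search(q, subject, min_identity = 50, min_coverage = 50)
    o <- oracle_sw_identity(q, subject)
    expect_gte(nrow(h), 1L)
    expect_equal(h$identity[1], o$identity, tolerance = 1 / 100 * o$identity + 1e-9)
    expect_lte(abs(h$identity[1] - o$identity), 1)
  }
})

test_that("conservation matrix counts species and categorizes correctly", {
  hits <- data.frame(
    srna_id = c("s1", "s1", "s2", "s2", "s2"),
    genome_id = c("gA", "gB", "gA", "gA", "gC"),
    identity = c(90, 80, 85, 82, 95),
    copy_index = c(1L, 1L, 1L, 2L, 1L),
    profile = "strict")
  m <- build_conservation_matrix(hits, c("s1", "s2", "s3"), c("gA", "gB", "gC"))
  expect_equal(unname(m$species_count), c(2L, 2L, 0L))
  expect_equal(unname(m$category), c("local", "local", "specific"))
  expect_true(m$multi_copy[["s2"]])
  expect_equal(m$identity["s2", "gA"], 85)  # best of the two copies
  full <- data.frame(srna_id = "s1", genome_id = c("gA", "gB", "gC"),
                     identity = 80, copy_index = 1L, profile = "strict")
  m2 <- build_conservation_matrix(full, "s1", c("gA", "gB", "gC"))
  expect_equal(unname(m2$category), "broad")
  mixed <- rbind(hits, data.frame(srna_id = "s3", genome_id = "gB",
                                  identity = 60, copy_index = 1L,
                                  profile = "loose"))
  expect_error(build_conservation_matrix(mixed, c("s1", "s2", "s3"),
                                         c("gA", "gB", "gC")), "mixed")
})

test_that("identity/phylogeny correlation has the documented sign convention", {
  # identity strictly decreasing with distance -> rho = +1 vs similarity
  r <- correlate_identity_phylogeny(c(95, 90, 85, 80, 70), c(1, 2, 3, 4, 5))
  expect_equal(r$rho, 1)
  expect_true(is.na(correlate_identity_phylogeny(rep(80, 5), 1:5)$rho))
  expect_warning(r2 <- correlate_identity_phylogeny(c(90, 80, NA, NA), 1:4),
                 "fewer than 4")
  expect_true(is.na(r2$rho))
  # matches the independent Spearman computation
  set.seed(56)
  idv <- runif(10, 60, 100); dv <- runif(10, 0, 5)
  got <- correlate_identity_phylogeny(idv, dv)
  o <- oracle_spearman(idv, -dv)
  expect_equal(got$rho, o$rho, tolerance = 1e-8)
  expect_equal(got$p, o$p, tolerance = 1e-8)
})

test_that("genomes mutated with distance-proportional rates correlate with identity", {
  set.seed(57)
  ds <- small_dataset()
  tr <- ds$truth$srnas
  tr <- tr[tr$end - tr$start + 1 >= 150, ]
  dist <- c(g1 = 0.02, g2 = 0.05, g3 = 0.09, g4 = 0.13, g5 = 0.18)
  idx <- lapply(seq_along(dist), function(k) {
    build_genome_index(mutate_genome(ds$genome, dist[k], seed = 100 + k))
  })
  rhos <- numeric(0)
  for (i in seq_len(min(6, nrow(tr)))) {
    q <- substr(as.character(ds$genome)[1], tr$start[i], tr$end[i])
    ident <- vapply(idx, function(ix) {
      h <- homology_search(q, index = ix, min_identity = 50, min_coverage = 50)
      if (nrow(h)) h$identity[1] else NA_real_
    }, numeric(1))
    if (sum(!is.na(ident)) >= 4) {
      rhos <- c(rhos, correlate_identity_phylogeny(ident, unname(dist))$rho)
    }
  }
  expect_gte(length(rhos), 4)
  expect_gt(median(rhos), 0.8)
})
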