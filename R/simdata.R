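# Synthetic dRNA-seq / ssRNA-seq dataset generator with full ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# a GC-rich single-replicon bacterial genome; non-overlapping CDS/rRNA/tRNA
# genes on both strands with fixed 5'UTR/3'UTR allowances; planted sRNAs
# realizing every requested location class; primary 5' ends (TSS) enriched in
# the TEX+ library and processed 5' ends (PSS) depleted; -10/-35 promoter
# boxes and a +1 purine at every TSS; an RNWUU cleavage motif spanning
# -2..+3 of every PSS; ssRNA-seq body coverage proportional to a log-uniform
# expression level spanning six orders of magnitude; condition-specific fold
# changes; and per-replicate Poisson noise.

#' Configuration for the synthetic dataset generator
#'
#' Defaults encode the study conditions the analysis is validated under:
#' 200 kb genome at GC 0.616, 150 CDSs, sRNAs in every location class,
#' 63.4% transcription-start origins, expression log-uniform over 1..1e6
#' per-million units, 23.1%/22.1% up-/down-regulated features with |log2FC|
#' drawn from [1, 4], 10x TEX enrichment at TSSs, 0.2x at PSSs, 3 replicates
#' in 2 conditions and Poisson background with mean 0.2.
#'
#' @param genome_length Genome length (nt).
#' @param gc_content Genome GC fraction.
#' @param n_cds,n_rrna,n_trna Gene counts.
#' @param n_srna_per_class Named integer vector of planted sRNA counts per
#'   location class/subtype (`inter`, `as`, `5UTR`, `5CDS`, `mCDS`, `3CDS`,
#'   `3UTR`, `3rRNA`, `2CDSs`, `intra_as`).
#' @param tss_fraction Fraction of sRNAs with a TSS (rather than PSS) origin.
#' @param expression_range Range of true abundances (per-million units),
#'   sampled log-uniformly.
#' @param de_fraction_up,de_fraction_down Fractions of features with planted
#'   positive/negative log2 fold change (alkane vs acetate).
#' @param fold_change_range Range of |log2FC| for regulated features.
#' @param noise Poisson background mean added to every track (0 disables all
#'   Poisson sampling; tracks then carry expected values).
#' @param tex_enrichment_true TEX+/TEX- ratio planted at TSSs.
#' @param tex_depletion_true TEX+/TEX- ratio planted at PSSs.
#' @param replicates Replicates per condition.
#' @param conditions Condition labels (first = alkane-like treatment).
#' @param utr5,utr3 Planted UTR allowances (nt).
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(genome_length = 200000, gc_content = 0.616,
                             n_cds = 150, n_rrna = 3, n_trna = 10,
                             n_srna_per_class = c(
                               inter = 10, as = 12, `5UTR` = 6, `5CDS` = 6,
                               mCDS = 6, `3CDS` = 6, `3UTR` = 6, `3rRNA` = 2,
                               `2CDSs` = 4, intra_as = 2),
                             tss_fraction = 0.634,
                             expression_range = c(1, 1e6),
                             de_fraction_up = 0.231, de_fraction_down = 0.221,
                             fold_change_range = c(1, 4),
                             noise = 0.2,
                             tex_enrichment_true = 10,
                             tex_depletion_true = 0.2,
                             replicates = 3,
                             conditions = c("alkane", "acetate"),
                             utr5 = 50, utr3 = 80,
                             seed = 1) {
  stopifnot(gc_content > 0, gc_content < 1,
            tss_fraction >= 0, tss_fraction <= 1,
            de_fraction_up >= 0, de_fraction_down >= 0,
            de_fraction_up + de_fraction_down <= 1,
            all(expression_range > 0), all(fold_change_range > 0),
            noise >= 0, tex_enrichment_true > 1, tex_depletion_true < 1,
            replicates >= 1, length(conditions) == 2)
  structure(
    list(genome_length = genome_length, gc_content = gc_content,
         n_cds = n_cds, n_rrna = n_rrna, n_trna = n_trna,
         n_srna_per_class = n_srna_per_class, tss_fraction = tss_fraction,
         expression_range = expression_range,
         de_fraction_up = de_fraction_up, de_fraction_down = de_fraction_down,
         fold_change_range = fold_change_range, noise = noise,
         tex_enrichment_true = tex_enrichment_true,
         tex_depletion_true = tex_depletion_true,
         replicates = replicates, conditions = conditions,
         utr5 = utr5, utr3 = utr3, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Planned ts/ps origin counts
#'
#' @param n Total number of sRNAs.
#' @param tss_fraction Fraction with TSS origin.
#' @return Named integer vector `c(ts = round(tss_fraction * n), ps = rest)`.
#' @export
plan_origins <- function(n, tss_fraction) {
  ts <- round(tss_fraction * n)
  c(ts = as.integer(ts), ps = as.integer(n - ts))
}

# length-safe shuffle (sample(x) on a length-1 integer means sample.int)
shuffle <- function(x) x[sample.int(length(x))]

sample_dna <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# lay out genes left-to-right; special pair units support the 2CDSs and
# intra_as sRNA geometries
place_genes <- function(cfg) {
  n2 <- unname(cfg$n_srna_per_class["2CDSs"]); if (is.na(n2)) n2 <- 0L
  nc <- unname(cfg$n_srna_per_class["intra_as"]); if (is.na(nc)) nc <- 0L
  n_single <- cfg$n_cds - 2L * n2 - 2L * nc
  if (n_single < 0) stop("generation error: n_cds too small for special pairs")
  units <- shuffle(c(rep("single", n_single), rep("rrna", cfg$n_rrna),
                     rep("trna", cfg$n_trna), rep("pair2cds", n2),
                     rep("pairconv", nc)))
  rows <- list()
  cursor <- 500L
  pair_id <- 0L
  add <- function(start, end, strand, type, role, pair) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = sprintf("g%04d", length(rows) + 1L), feature_type = type,
      start = as.integer(start), end = as.integer(end), strand = strand,
      role = role, pair = pair, stringsAsFactors = FALSE)
  }
  cds_len <- function() 3L * sample(134:300, 1)
  for (u in units) {
    cursor <- cursor + sample(250:450, 1)
    if (u == "single") {
      len <- cds_len(); st <- sample(c("+", "-"), 1)
      add(cursor, cursor + len - 1L, st, "CDS", "single", NA_integer_)
      cursor <- cursor + len
    } else if (u == "rrna") {
      st <- sample(c("+", "-"), 1)
      add(cursor, cursor + 1499L, st, "rRNA", "rrna", NA_integer_)
      cursor <- cursor + 1500L
    } else if (u == "trna") {
      st <- sample(c("+", "-"), 1)
      add(cursor, cursor + 79L, st, "tRNA", "trna", NA_integer_)
      cursor <- cursor + 80L
    } else if (u == "pair2cds") {
      pair_id <- pair_id + 1L
      st <- sample(c("+", "-"), 1)
      lenA <- cds_len(); lenB <- cds_len()
      add(cursor, cursor + lenA - 1L, st, "CDS", "pair2cds_A", pair_id)
      cursor <- cursor + lenA + 150L
      add(cursor, cursor + lenB - 1L, st, "CDS", "pair2cds_B", pair_id)
      cursor <- cursor + lenB
    } else { # pairconv: '+' gene then '-' gene, convergent, 60 nt body gap
      pair_id <- pair_id + 1L
      lenA <- cds_len(); lenB <- cds_len()
      add(cursor, cursor + lenA - 1L, "+", "CDS", "pairconv_A", pair_id)
      cursor <- cursor + lenA + 60L
      add(cursor, cursor + lenB - 1L, "-", "CDS", "pairconv_B", pair_id)
      cursor <- cursor + lenB
    }
    if (cursor > cfg$genome_length - 600L) {
      stop("generation error: genes do not fit; use a larger genome_length")
    }
  }
  do.call(rbind, rows)
}

# place one sRNA of the requested class; returns c(start, end) and strand
place_srna_in_host <- function(subtype, host, cfg) {
  gs <- host$start; ge <- host$end; st <- host$strand
  body <- ge - gs + 1L
  swap <- function(s, e, strand) list(start = as.integer(min(s, e)),
                                      end = as.integer(max(s, e)),
                                      strand = strand)
  if (subtype == "5UTR") {
    if (st == "+") return(swap(gs - cfg$utr5, gs - 1L, "+"))
    return(swap(ge + 1L, ge + cfg$utr5, "-"))
  }
  if (subtype == "5CDS") {
    u <- sample(15:40, 1)
    len <- sample(61:min(200L, body - 20L + u), 1)
    if (st == "+") return(swap(gs - u, gs - u + len - 1L, "+"))
    return(swap(ge + u - len + 1L, ge + u, "-"))
  }
  if (subtype == "mCDS" || subtype == "as") {
    len <- sample(61:min(250L, body - 30L), 1)
    off <- sample(10:(body - len - 10L), 1)
    strand <- if (subtype == "as") (if (st == "+") "-" else "+") else st
    return(swap(gs + off, gs + off + len - 1L, strand))
  }
  if (subtype == "3CDS") {
    u <- sample(15:40, 1)
    len <- sample(61:min(200L, body - 20L + u), 1)
    if (st == "+") return(swap(ge + u - len + 1L, ge + u, "+"))
    return(swap(gs - u, gs - u + len - 1L, "-"))
  }
  if (subtype == "3UTR") {
    len <- sample(61:75, 1)
    a <- sample(0:(cfg$utr3 - len), 1)
    if (st == "+") return(swap(ge + 1L + a, ge + a + len, "+"))
    return(swap(gs - a - len, gs - 1L - a, "-"))
  }
  if (subtype == "3rRNA") {
    u <- sample(40:100, 1); v <- sample(20:60, 1)
    if (st == "+") return(swap(ge - u, ge + v, "+"))
    return(swap(gs - v, gs + u, "-"))
  }
  stop("unknown host subtype ", subtype)
}

place_srnas <- function(cfg, genes, ext) {
  counts <- cfg$n_srna_per_class
  singles <- which(genes$role == "single" & genes$feature_type == "CDS" &
                     genes$end - genes$start + 1L >= 420L)
  singles <- shuffle(singles)
  rrnas <- shuffle(which(genes$role == "rrna"))
  pair2 <- unique(genes$pair[genes$role == "pair2cds_A"])
  pairc <- unique(genes$pair[genes$role == "pairconv_A"])
  take_single <- function() {
    if (!length(singles)) stop("generation error: host pool exhausted; ",
                               "use a larger genome_length or more CDSs")
    h <- singles[1]; singles <<- singles[-1]; h
  }
  rows <- list()
  add <- function(pl, class, subtype, host_ids) {
    rows[[length(rows) + 1L]] <<- data.frame(
      start = pl$start, end = pl$end, strand = pl$strand,
      location_class = class, location_subtype = subtype,
      host_gene_ids = host_ids, stringsAsFactors = FALSE)
  }
  host_subtypes <- c("5UTR", "5CDS", "mCDS", "3CDS", "3UTR")
  for (sub in names(counts)) {
    k <- counts[[sub]]
    if (k == 0) next
    for (i in seq_len(k)) {
      if (sub %in% host_subtypes) {
        h <- genes[take_single(), ]
        add(place_srna_in_host(sub, h, cfg), "intra", sub, h$gene_id)
      } else if (sub == "as") {
        h <- genes[take_single(), ]
        add(place_srna_in_host("as", h, cfg), "as", "none", h$gene_id)
      } else if (sub == "3rRNA") {
        if (!length(rrnas)) stop("generation error: not enough rRNA hosts")
        h <- genes[rrnas[1], ]; rrnas <- rrnas[-1]
        add(place_srna_in_host("3rRNA", h, cfg), "intra", "3rRNA", h$gene_id)
      } else if (sub == "2CDSs") {
        if (!length(pair2)) stop("generation error: not enough 2CDS pairs")
        p <- pair2[1]; pair2 <- pair2[-1]
        gA <- genes[genes$pair %in% p & genes$role == "pair2cds_A", ]
        gB <- genes[genes$pair %in% p & genes$role == "pair2cds_B", ]
        u <- sample(30:80, 1); v <- sample(30:80, 1)
        pl <- list(start = as.integer(gA$end - u), end = as.integer(gB$start + v),
                   strand = gA$strand)
        add(pl, "intra", "2CDSs", paste(gA$gene_id, gB$gene_id, sep = ","))
      } else if (sub == "intra_as") {
        if (!length(pairc)) stop("generation error: not enough convergent pairs")
        p <- pairc[1]; pairc <- pairc[-1]
        gA <- genes[genes$pair %in% p & genes$role == "pairconv_A", ]
        u <- sample(60:120, 1); v <- sample(5:50, 1)
        pl <- list(start = as.integer(gA$end - u), end = as.integer(gA$end + v),
                   strand = "+")
        add(pl, "intra_as", "3CDS", gA$gene_id)
      } else if (sub == "inter") {
        # free intergenic zones between merged transcript extents
        occ <- IRanges::reduce(IRanges::IRanges(ext$ext_start, ext$ext_end))
        free <- IRanges::gaps(occ, start = 200L, end = cfg$genome_length - 200L)
        used <- do.call(rbind, rows)
        wide <- which(IRanges::width(free) >= 200L)
        placed <- FALSE
        for (zi in shuffle(wide)) {
          zs <- IRanges::start(free)[zi] + 60L
          ze <- IRanges::end(free)[zi] - 60L
          len <- sample(61:min(250L, ze - zs + 1L), 1)
          s0 <- zs + sample(0:(ze - zs + 1L - len), 1)
          e0 <- s0 + len - 1L
          clash <- !is.null(used) && nrow(used) &&
            any(used$start <= e0 + 100L & used$end >= s0 - 100L)
          if (!clash) {
            add(list(start = s0, end = e0, strand = sample(c("+", "-"), 1)),
                "inter", "none", "")
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("generation error: no free intergenic zone; ",
                          "use a larger genome_length")
      } else {
        stop("unknown sRNA class ", sub)
      }
    }
  }
  do.call(rbind, rows)
}

# overwrite genome characters (character-vector genome), strand-aware:
# offsets use the +1 = anchor convention (no offset 0)
plant_bases <- function(gchars, anchor, strand, offsets, bases_rna) {
  bases <- chartr("U", "T", bases_rna)
  for (i in seq_along(offsets)) {
    o <- offsets[i]
    gpos <- if (strand == "+") (if (o > 0) anchor + o - 1L else anchor + o)
            else (if (o > 0) anchor - o + 1L else anchor - o)
    b <- substr(bases, i, i)
    if (strand == "-") b <- chartr("ACGT", "TGCA", b)
    gchars[gpos] <- b
  }
  gchars
}

sample_promoter <- function() {
  m10 <- strsplit("TATAAT", "")[[1]]
  m35 <- strsplit("TTGACA", "")[[1]]
  mut <- function(box) {
    if (stats::runif(1) < 0.2) {
      i <- sample(6, 1)
      box[i] <- sample(setdiff(c("A", "C", "G", "T"), box[i]), 1)
    }
    box
  }
  list(m10 = paste(mut(m10), collapse = ""), m35 = paste(mut(m35), collapse = ""))
}

sample_rnwuu <- function() {
  paste0(sample(c("A", "G"), 1), sample(c("A", "C", "G", "U"), 1),
         sample(c("A", "U"), 1), "UU")
}

spike_height <- function(expr) pmin(5e4, 20 + 0.02 * expr)

#' Generate a synthetic dataset with ground truth
#'
#' @param config A [synthetic_config()].
#' @param outdir Optional directory; when given, FASTA/GFF3/wiggle tracks and
#'   truth TSVs are written there (see [write_dataset()]).
#' @return List with `genome` (DNAStringSet), `annotation`, `truth` (list of
#'   data.frames `srnas`, `sites`, `genes`), `tracks` (nested list
#'   `[[condition]][[replicate]][[library]][[strand]]` of `coverage_track`s)
#'   and `config`.
#' @export
generate_dataset <- function(config = synthetic_config(), outdir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  L <- cfg$genome_length
  gchars <- sample_dna(L, cfg$gc_content)
  genes <- place_genes(cfg)
  ann <- genes[, c("gene_id", "feature_type", "start", "end", "strand")]
  ann$product <- paste0("synthetic ", genes$role)
  ext <- gene_extents(ann, L, transcripts = NULL, utr5 = cfg$utr5, utr3 = cfg$utr3)
  srnas <- place_srnas(cfg, genes, ext)
  n <- nrow(srnas)

  # origins: 5UTR-subtype sRNAs share their host mRNA TSS and are forced ts
  plan <- plan_origins(n, cfg$tss_fraction)
  origin <- rep("ps", n)
  forced <- which(srnas$location_subtype == "5UTR")
  n_ts_left <- max(0L, plan[["ts"]] - length(forced))
  pool <- setdiff(seq_len(n), forced)
  origin[forced] <- "ts"
  origin[sample(pool, min(n_ts_left, length(pool)))] <- "ts"
  srnas$origin_class <- origin
  srnas$end_evidence <- ifelse(
    srnas$location_class %in% c("inter", "as"),
    sample(c("PSS", "sharp_decrease"), n, replace = TRUE), "PSS")
  srnas$p5 <- ifelse(srnas$strand == "+", srnas$start, srnas$end)
  srnas$p3_site <- ifelse(srnas$end_evidence == "PSS",
                          ifelse(srnas$strand == "+", srnas$end + 1L,
                                 srnas$start - 1L), NA_integer_)

  # expression (per-million units): sRNAs log-uniform over the full range,
  # host genes boosted so transcript extents stay well detectable
  lr <- log10(cfg$expression_range)
  base <- 10^stats::runif(n, lr[1], lr[2])
  u <- stats::runif(n)
  lfc <- numeric(n)
  fcr <- cfg$fold_change_range
  lfc[u < cfg$de_fraction_up] <- stats::runif(sum(u < cfg$de_fraction_up), fcr[1], fcr[2])
  dn <- u >= cfg$de_fraction_up & u < cfg$de_fraction_up + cfg$de_fraction_down
  lfc[dn] <- -stats::runif(sum(dn), fcr[1], fcr[2])
  cond_alk <- cfg$conditions[1]
  cond_base <- cfg$conditions[2]
  expr <- matrix(0, n, 2, dimnames = list(NULL, cfg$conditions))
  expr[, cond_base] <- base
  expr[, cond_alk] <- base * 2^lfc
  srnas$log2fc_true <- lfc
  srnas[[paste0("expr_", cond_alk)]] <- expr[, cond_alk]
  srnas[[paste0("expr_", cond_base)]] <- expr[, cond_base]
  srnas$detectable <- apply(expr, 1, max) >= 10

  ng <- nrow(genes)
  host_ids <- unique(unlist(strsplit(srnas$host_gene_ids[srnas$host_gene_ids != ""], ",")))
  is_host <- genes$gene_id %in% host_ids | genes$role %in%
    c("pair2cds_A", "pair2cds_B", "pairconv_A", "pairconv_B")
  gbase <- ifelse(is_host, stats::runif(ng, 20, 100),
                  10^stats::runif(ng, log10(2), log10(50)))
  gbase[genes$feature_type == "rRNA"] <- stats::runif(sum(genes$feature_type == "rRNA"), 300, 800)
  gbase[genes$feature_type == "tRNA"] <- stats::runif(sum(genes$feature_type == "tRNA"), 100, 400)
  gu <- stats::runif(ng)
  glfc <- numeric(ng)
  glfc[gu < cfg$de_fraction_up] <- stats::runif(sum(gu < cfg$de_fraction_up), fcr[1], fcr[2])
  gdn <- gu >= cfg$de_fraction_up & gu < cfg$de_fraction_up + cfg$de_fraction_down
  glfc[gdn] <- -stats::runif(sum(gdn), fcr[1], fcr[2])
  gexpr <- matrix(0, ng, 2, dimnames = list(NULL, cfg$conditions))
  gexpr[, cond_base] <- gbase
  gexpr[, cond_alk] <- gbase * 2^glfc

  # planted sites: gene TSSs at mRNA transcript starts, sRNA 5' sites,
  # sRNA 3' PSSs. Gene promoters are planted first so sRNA motifs win on
  # the rare overlap.
  gene_tss <- ifelse(genes$strand == "+", ext$ext_start, ext$ext_end)
  site_rows <- list()
  add_site <- function(pos, strand, kind, role, h_alk, h_base) {
    site_rows[[length(site_rows) + 1L]] <<- data.frame(
      position = as.integer(pos), strand = strand, kind = kind, role = role,
      height_alk = h_alk, height_base = h_base, stringsAsFactors = FALSE)
  }
  for (i in seq_len(ng)) {
    if (genes$feature_type[i] != "CDS") next
    p <- gene_tss[i]; st <- genes$strand[i]
    pr <- sample_promoter()
    gchars <- plant_bases(gchars, p, st, -12:-7, pr$m10)
    gchars <- plant_bases(gchars, p, st, -35:-30, pr$m35)
    gchars <- plant_bases(gchars, p, st, 1L, sample(c("A", "G"), 1))
    add_site(p, st, "TSS", "gene_tss",
             spike_height(gexpr[i, cond_alk]), spike_height(gexpr[i, cond_base]))
  }
  for (i in seq_len(n)) {
    p <- srnas$p5[i]; st <- srnas$strand[i]
    if (srnas$origin_class[i] == "ts") {
      pr <- sample_promoter()
      gchars <- plant_bases(gchars, p, st, -12:-7, pr$m10)
      gchars <- plant_bases(gchars, p, st, -35:-30, pr$m35)
      gchars <- plant_bases(gchars, p, st, 1L, sample(c("A", "G"), 1))
      add_site(p, st, "TSS", "srna_5p",
               spike_height(expr[i, cond_alk]), spike_height(expr[i, cond_base]))
    } else {
      gchars <- plant_bases(gchars, p, st, c(-2L, -1L, 1L, 2L, 3L), sample_rnwuu())
      add_site(p, st, "PSS", "srna_5p",
               spike_height(expr[i, cond_alk]), spike_height(expr[i, cond_base]))
    }
    if (!is.na(srnas$p3_site[i])) {
      q <- srnas$p3_site[i]
      gchars <- plant_bases(gchars, q, st, c(-2L, -1L, 1L, 2L, 3L), sample_rnwuu())
      add_site(q, st, "PSS", "srna_3p",
               spike_height(expr[i, cond_alk]), spike_height(expr[i, cond_base]))
    }
  }
  sites <- do.call(rbind, site_rows)
  # collapse duplicate positions (shared gene/sRNA TSS), keep max height
  key <- paste(sites$strand, sites$position)
  dup_conflict <- tapply(sites$kind, key, function(k) length(unique(k)) > 1L)
  if (any(dup_conflict)) {
    stop("generation error: conflicting site kinds planted at one position")
  }
  o <- order(sites$strand, sites$position, -pmax(sites$height_alk, sites$height_base))
  sites <- sites[o, ][!duplicated(key[o]), , drop = FALSE]
  rownames(sites) <- NULL

  genome_seq <- paste(gchars, collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(genome_seq, "synthetic_chr"))

  # internal geometry checker: the planted intervals must classify to their
  # intended classes under the default UTR allowances before tracks are made
  chk <- classify_location(srnas[, c("start", "end", "strand")], ann, L,
                           transcripts = NULL, utr5 = cfg$utr5, utr3 = cfg$utr3)
  bad <- which(chk$location_class != srnas$location_class |
                 chk$location_subtype != srnas$location_subtype)
  if (length(bad)) {
    stop("generation error: planted sRNA geometry failed self-check at rows ",
         paste(utils::head(bad, 5), collapse = ", "))
  }

  # expected per-position lambda per condition: full coverage and 5'-end tracks
  lam <- list()
  for (cond in cfg$conditions) {
    ss <- list(`+` = numeric(L), `-` = numeric(L))
    tp <- list(`+` = numeric(L), `-` = numeric(L))
    tm <- list(`+` = numeric(L), `-` = numeric(L))
    for (i in seq_len(ng)) {
      st <- genes$strand[i]
      span <- ext$ext_start[i]:ext$ext_end[i]
      ss[[st]][span] <- ss[[st]][span] + gexpr[i, cond]
    }
    for (i in seq_len(n)) {
      st <- srnas$strand[i]
      span <- srnas$start[i]:srnas$end[i]
      ss[[st]][span] <- ss[[st]][span] + expr[i, cond]
    }
    hcol <- if (cond == cond_alk) "height_alk" else "height_base"
    for (i in seq_len(nrow(sites))) {
      st <- sites$strand[i]; p <- sites$position[i]; h <- sites[[hcol]][i]
      if (sites$kind[i] == "TSS") {
        tp[[st]][p] <- tp[[st]][p] + h
        tm[[st]][p] <- tm[[st]][p] + h / cfg$tex_enrichment_true
      } else {
        tm[[st]][p] <- tm[[st]][p] + h
        tp[[st]][p] <- tp[[st]][p] + h * cfg$tex_depletion_true
      }
    }
    lam[[cond]] <- list(ss = ss, texplus = tp, texminus = tm)
  }

  tracks <- list()
  for (cond in cfg$conditions) {
    tracks[[cond]] <- list()
    for (r in seq_len(cfg$replicates)) {
      rep_tracks <- list()
      for (lib in c("SS", "TEXplus", "TEXminus")) {
        kind <- if (lib == "SS") "full_coverage" else "five_prime_ends"
        lam_lib <- switch(lib, SS = lam[[cond]]$ss,
                          TEXplus = lam[[cond]]$texplus,
                          TEXminus = lam[[cond]]$texminus)
        rep_tracks[[lib]] <- list()
        for (st in c("+", "-")) {
          lv <- lam_lib[[st]] + cfg$noise
          vals <- if (cfg$noise > 0) stats::rpois(L, lv) else lam_lib[[st]]
          rep_tracks[[lib]][[st]] <- coverage_track(
            vals, strand = st, library = lib, track_kind = kind,
            condition = cond, replicate = r, normalization = "per_million")
        }
      }
      tracks[[cond]][[r]] <- rep_tracks
    }
  }

  srnas$id <- name_srna(srnas$start, srnas$end, srnas$strand)
  srnas <- srnas[order(srnas$start, srnas$strand), , drop = FALSE]
  rownames(srnas) <- NULL
  truth_genes <- cbind(genes[, c("gene_id", "feature_type", "start", "end",
                                 "strand", "role")],
                       data.frame(expr_alk = gexpr[, cond_alk],
                                  expr_base = gexpr[, cond_base],
                                  log2fc_true = glfc))
  ds <- list(genome = genome, annotation = ann,
             truth = list(srnas = srnas, sites = sites, genes = truth_genes),
             tracks = tracks, config = cfg)
  class(ds) <- "synthetic_dataset"
  if (!is.null(outdir)) write_dataset(ds, outdir)
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d nt genome, %d genes, %d planted sRNAs, %d planted sites\n",
              x$config$genome_length, nrow(x$annotation),
              nrow(x$truth$srnas), nrow(x$truth$sites)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits genome FASTA, annotation GFF3, one variableStep wiggle per
#' library/condition/replicate/strand under `tracks/`, and truth TSVs.
#'
#' @param ds A dataset from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(ds$genome, file.path(dir, "genome.fa"))
  write_gff3(ds$annotation, file.path(dir, "annotation.gff3"),
             seqname = names(ds$genome)[1])
  for (cond in names(ds$tracks)) {
    for (r in seq_along(ds$tracks[[cond]])) {
      for (lib in names(ds$tracks[[cond]][[r]])) {
        for (st in c("+", "-")) {
          tr <- ds$tracks[[cond]][[r]][[lib]][[st]]
          fn <- sprintf("%s_%s_rep%d_%s.wig", lib, cond, r,
                        if (st == "+") "fwd" else "rev")
          write_wiggle(tr, file.path(dir, "tracks", fn),
                       seqname = names(ds$genome)[1])
        }
      }
    }
  }
  write_tsv(ds$truth$srnas, file.path(dir, "truth_srnas.tsv"))
  write_tsv(ds$truth$sites, file.path(dir, "truth_sites.tsv"))
  write_tsv(ds$truth$genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}

#' Mutate a genome into a synthetic homolog
#'
#' Applies i.i.d. substitutions at the given per-site rate (every substitution
#' changes the base, so expected identity of a surviving locus is 1 - rate)
#' and replaces the loci of `deleted_srna_ids` with random sequence so the
#' homolog is absent there.
#'
#' @param genome Genome sequence (character or DNAStringSet).
#' @param substitution_rate Per-site substitution rate in [0, 0.5).
#' @param srnas Truth sRNA table (needed when `deleted_srna_ids` is nonempty).
#' @param deleted_srna_ids Ids of sRNA loci to erase.
#' @param seed Integer seed.
#' @param gc_content GC of the random replacement sequence.
#' @return A `DNAStringSet` of length 1 (the homolog genome).
#' @export
mutate_genome <- function(genome, substitution_rate, srnas = NULL,
                          deleted_srna_ids = character(0), seed = 1,
                          gc_content = 0.5) {
  if (substitution_rate < 0 || substitution_rate >= 0.5) {
    stop("substitution_rate must be in [0, 0.5)")
  }
  set.seed(as.integer(seed))
  ch <- strsplit(toupper(as.character(genome)[1]), "", fixed = TRUE)[[1]]
  L <- length(ch)
  if (substitution_rate > 0) {
    hit <- which(stats::runif(L) < substitution_rate)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  if (length(deleted_srna_ids)) {
    if (is.null(srnas)) stop("srnas table required to delete sRNA loci")
    for (id in deleted_srna_ids) {
      row <- srnas[srnas$id == id, , drop = FALSE]
      if (nrow(row) == 0L) stop("unknown sRNA id: ", id)
      span <- row$start[1]:row$end[1]
      ch[span] <- sample_dna(length(span), gc_content)
    }
  }
  Biostrings::DNAStringSet(setNames(paste(ch, collapse = ""), "homolog"))
}
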