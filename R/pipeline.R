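# End-to-end orchestration: site calling -> transcript detection -> sRNA
# detection and classification -> features/motifs -> conservation ->
# expression and regulatory screens, plus the summary statistics layer.

#' Percentage with round-half-away-from-zero
#'
#' The reporting convention used throughout the results: `percent(14, 549)`
#' is 2.6.
#'
#' @param k Numerator count (0 <= k <= n).
#' @param n Denominator count (> 0).
#' @param decimals Decimal places (default 1).
#' @return Rounded percentage.
#' @export
percent <- function(k, n, decimals = 1) {
  if (any(n <= 0)) stop("percent requires n > 0")
  if (any(k < 0 | k > n)) stop("percent requires 0 <= k <= n")
  x <- 100 * k / n
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Class count/percentage summary of classified sRNAs
#'
#' @param srnas Classified candidate data.frame (`origin_class`,
#'   `location_class`, `location_subtype`).
#' @return List of data.frames `origin`, `location`, `subtype`, each with
#'   `class`, `count`, `percent` columns (percent of the grand total).
#' @export
summarize_classes <- function(srnas) {
  n <- nrow(srnas)
  tab <- function(x) {
    t <- table(x)
    data.frame(class = names(t), count = as.integer(t),
               percent = if (n > 0) percent(as.integer(t), n) else numeric(length(t)),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(origin = tab(srnas$origin_class),
       location = tab(srnas$location_class),
       subtype = tab(paste(srnas$location_class, srnas$location_subtype, sep = "/")),
       total = n)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror [synthetic_config()] fields
#'   plus optional `site`, `srna` parameter blocks.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

# replicate-averaged per-condition track accessors for a synthetic bundle
averaged_tracks <- function(ds) {
  conds <- names(ds$tracks)
  out <- list()
  for (cond in conds) {
    reps <- ds$tracks[[cond]]
    out[[cond]] <- list(
      ss = list(
        `+` = average_tracks(lapply(reps, function(r) r$SS$`+`)),
        `-` = average_tracks(lapply(reps, function(r) r$SS$`-`))),
      texplus = list(
        `+` = average_tracks(lapply(reps, function(r) r$TEXplus$`+`)),
        `-` = average_tracks(lapply(reps, function(r) r$TEXplus$`-`))),
      texminus = list(
        `+` = average_tracks(lapply(reps, function(r) r$TEXminus$`+`)),
        `-` = average_tracks(lapply(reps, function(r) r$TEXminus$`-`)))
    )
  }
  out
}

# one candidate per strand-aware 5' end: 3'-evidence priority
# (terminator > PSS > sharp_decrease), then length, then coordinates
consolidate_candidates <- function(cands) {
  if (nrow(cands) < 2L) return(cands)
  p5 <- ifelse(cands$strand == "+", cands$start, cands$end)
  key <- paste(cands$strand, p5)
  prio <- match(cands$end_evidence, c("terminator", "PSS", "sharp_decrease"))
  o <- order(key, prio, -cands$length, cands$start)
  out <- cands[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full sRNA landscape pipeline on a dataset bundle
#'
#' Stages: replicate averaging, per-condition TSS/PSS calling and merging,
#' transcript detection, sRNA candidate detection (one candidate kept per
#' 5' end), origin/location classification, redundancy clustering, feature
#' and motif computation, optional homolog conservation, expression
#' quantification with differential classification, CsrA target scanning,
#' trans-target prediction for inter-/intra-sRNAs and, when key genes are
#' given, the three-criteria direct-relation calls.
#'
#' @param ds A `synthetic_dataset` bundle (or a [synthetic_config()], which is
#'   generated first).
#' @param site_par,srna_par Parameter lists ([site_params()], [srna_params()]).
#' @param reference_genomes Optional named list of homolog genome sequences.
#' @param conservation_profile Threshold profile name for the homolog screen.
#' @param key_gene_ids Optional key gene ids for direct-relation calls.
#' @param top_k Rank cutoff for criterion iii.
#' @param outdir Optional output directory for TSV/GFF3/FASTA outputs.
#' @param verbose Log one line per stage.
#' @return List with elements `sites`, `transcripts`, `srnas`, `clusters`,
#'   `features`, `feature_tests`, `motifs`, `promoter_boxes`, `sorfs`,
#'   `conservation`, `expression`, `summary`.
#' @export
run_pipeline <- function(ds, site_par = site_params(), srna_par = srna_params(),
                         reference_genomes = NULL,
                         conservation_profile = "strict",
                         key_gene_ids = NULL, top_k = 10,
                         outdir = NULL, verbose = TRUE) {
  if (inherits(ds, "synthetic_config")) ds <- generate_dataset(ds)
  say <- function(...) if (verbose) message(sprintf(...))
  conds <- names(ds$tracks)
  glen <- nchar(as.character(ds$genome)[1])
  avg <- averaged_tracks(ds)

  site_list <- list()
  for (cond in conds) {
    for (st in c("+", "-")) {
      site_list[[paste(cond, st)]] <-
        call_sites(avg[[cond]]$texplus[[st]], avg[[cond]]$texminus[[st]], site_par)
    }
  }
  sites <- merge_site_calls(site_list)
  say("site_calling: %d merged sites (%d TSS, %d PSS)",
      nrow(sites), sum(sites$kind == "TSS"), sum(sites$kind == "PSS"))

  tr_list <- list()
  for (cond in conds) {
    for (st in c("+", "-")) {
      tr <- detect_transcripts(avg[[cond]]$ss[[st]])
      if (nrow(tr)) tr$condition <- cond
      tr_list[[paste(cond, st)]] <- tr
    }
  }
  transcripts <- do.call(rbind, tr_list[vapply(tr_list, nrow, integer(1)) > 0])
  if (is.null(transcripts)) {
    transcripts <- data.frame(start = integer(0), end = integer(0),
                              strand = character(0), mean_coverage = numeric(0),
                              condition = character(0))
  }
  rownames(transcripts) <- NULL
  say("transcripts: %d intervals", nrow(transcripts))

  ss_by_condition <- lapply(avg, `[[`, "ss")
  drna_by_condition <- lapply(avg, function(a) list(texplus = a$texplus,
                                                    texminus = a$texminus))
  cands <- detect_srnas(transcripts, sites, ss_by_condition, drna_by_condition,
                        ds$genome, srna_par)
  cands <- consolidate_candidates(cands)
  cands <- classify_location(cands, ds$annotation, glen, transcripts,
                             utr5 = ds$config$utr5, utr3 = ds$config$utr3)
  say("srna_annotation: %d candidates", nrow(cands))

  clusters <- if (nrow(cands)) cluster_redundant(cands$id, cands$sequence) else NULL
  features <- if (nrow(cands)) feature_table(cands$id, cands$sequence) else NULL
  feature_tests <- NULL
  if (!is.null(features)) {
    features$group <- cands$location_class
    enough <- names(which(table(features$group) >= 3))
    if (length(enough) >= 2) {
      feature_tests <- compare_feature_groups(features[features$group %in% enough, ])
    }
  }

  motifs <- list()
  boxes <- NULL
  tss_sites <- sites[sites$kind == "TSS", , drop = FALSE]
  pss_sites <- sites[sites$kind == "PSS", , drop = FALSE]
  if (nrow(tss_sites) >= 10) {
    motifs$tss <- motif_profile(tss_sites, ds$genome, window = c(-50, 1))
    boxes <- find_promoter_boxes(tss_sites, ds$genome)
  }
  if (nrow(pss_sites) >= 10) {
    motifs$pss <- motif_profile(pss_sites, ds$genome, window = c(-10, 10))
  }

  sorfs <- NULL
  if (nrow(cands)) {
    noncoding_classes <- cands$location_class %in% c("inter", "as")
    sorf_list <- lapply(which(noncoding_classes), function(i) {
      s <- find_sorfs(cands$sequence[i])
      if (nrow(s)) s$srna_id <- cands$id[i]
      s
    })
    sorf_list <- sorf_list[vapply(sorf_list, nrow, integer(1)) > 0]
    if (length(sorf_list)) sorfs <- do.call(rbind, sorf_list)
  }
  say("seq_features: %d sRNAs with sORFs", length(unique(sorfs$srna_id)))

  conservation <- NULL
  if (!is.null(reference_genomes) && nrow(cands)) {
    prof <- threshold_profile(conservation_profile)
    hit_rows <- list()
    for (gname in names(reference_genomes)) {
      idx <- build_genome_index(reference_genomes[[gname]])
      for (i in seq_len(nrow(cands))) {
        h <- homology_search(cands$sequence[i], index = idx,
                             min_identity = prof$min_identity,
                             min_coverage = prof$min_coverage)
        if (nrow(h)) {
          h$srna_id <- cands$id[i]
          h$genome_id <- gname
          h$profile <- prof$name
          hit_rows[[length(hit_rows) + 1L]] <- h
        }
      }
    }
    hits <- if (length(hit_rows)) do.call(rbind, hit_rows)
            else cbind(empty_hits(), data.frame(srna_id = character(0),
                                                genome_id = character(0),
                                                profile = character(0)))
    conservation <- list(
      hits = hits,
      matrix = build_conservation_matrix(hits, cands$id, names(reference_genomes))
    )
    say("comparative: %d hits across %d genomes", nrow(hits),
        length(reference_genomes))
  }

  expression <- NULL
  if (nrow(cands) >= 2) {
    samp_names <- character(0)
    cond_of <- character(0)
    counts <- NULL
    for (cond in conds) {
      for (r in seq_along(ds$tracks[[cond]])) {
        col <- vapply(seq_len(nrow(cands)), function(i) {
          tr <- ds$tracks[[cond]][[r]]$SS[[cands$strand[i]]]
          round(sum(tr$values[cands$start[i]:cands$end[i]]))
        }, numeric(1))
        counts <- cbind(counts, col)
        samp_names <- c(samp_names, sprintf("%s_rep%d", cond, r))
        cond_of <- c(cond_of, cond)
      }
    }
    colnames(counts) <- samp_names
    rownames(counts) <- cands$id
    de <- differential_expression(counts, cond_of)
    tpm <- apply(counts, 2, compute_tpm, lengths = cands$length)
    rownames(tpm) <- cands$id
    topn <- min(50L, nrow(cands))
    tops <- top_expressed(tpm, cond_of, n = topn)
    expression <- list(counts = counts, condition = cond_of, de = de,
                       tpm = tpm, top = tops)
    say("regulation: %d up, %d down of %d candidates",
        sum(de$status == "up"), sum(de$status == "down"), nrow(de))
  }

  csra <- scan_csra_targets(ds$annotation, ds$genome)
  interactions <- list()
  relations <- NULL
  if (nrow(cands)) {
    wins <- target_windows(ds$annotation, ds$genome)
    for (i in which(cands$location_class %in% c("inter", "intra"))) {
      interactions[[cands$id[i]]] <- predict_trans_targets(cands$sequence[i], wins)
    }
    if (!is.null(key_gene_ids)) {
      relations <- classify_direct_relations(cands, key_gene_ids, interactions,
                                             ds$annotation$gene_id, top_k = top_k)
    }
  }

  summary <- summarize_classes(cands)
  res <- list(sites = sites, transcripts = transcripts, srnas = cands,
              clusters = clusters, features = features,
              feature_tests = feature_tests, motifs = motifs,
              promoter_boxes = boxes, sorfs = sorfs,
              conservation = conservation, expression = expression,
              csra_targets = csra, interactions = interactions,
              relations = relations, summary = summary)
  if (!is.null(outdir)) write_pipeline_outputs(res, ds, outdir)
  res
}

#' Write the main pipeline tables to a directory
#'
#' @param res [run_pipeline()] result.
#' @param ds The dataset bundle the result came from.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, ds, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$sites, file.path(outdir, "sites.tsv"))
  write_tsv(res$transcripts, file.path(outdir, "transcripts.tsv"))
  write_tsv(res$srnas, file.path(outdir, "srnas.tsv"))
  if (!is.null(res$clusters)) write_tsv(res$clusters, file.path(outdir, "clusters.tsv"))
  if (!is.null(res$features)) write_tsv(res$features, file.path(outdir, "features.tsv"))
  if (!is.null(res$feature_tests)) {
    write_tsv(res$feature_tests, file.path(outdir, "feature_tests.tsv"))
  }
  if (!is.null(res$sorfs)) write_tsv(res$sorfs, file.path(outdir, "sorfs.tsv"))
  if (!is.null(res$expression)) {
    write_tsv(res$expression$de, file.path(outdir, "differential_expression.tsv"))
  }
  write_tsv(res$csra_targets, file.path(outdir, "csra_targets.tsv"))
  if (nrow(res$srnas)) {
    write_fasta(setNames(chartr("U", "T", res$srnas$sequence), res$srnas$id),
                file.path(outdir, "srnas.fa"))
  }
  for (m in names(res$motifs)) {
    prof <- res$motifs[[m]]
    write_tsv(data.frame(offset = prof$offsets, prof$freq, ic = prof$ic),
              file.path(outdir, paste0("motif_", m, ".tsv")))
  }
  invisible(outdir)
}
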