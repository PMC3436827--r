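## End-to-end pipeline on synthetic data: generate -> scan -> homologs ->
## retention -> clusters, under a single seed.

#' Assign homology hits to genes of the target genome
#'
#' A hit belongs to an ortholog gene when it overlaps the gene's span.
#'
#' @param hits hits data.frame with `chrom`, `start`, `end`.
#' @param genes [gene_models] of the target genome.
#' @return `hits` with an `ortholog_id` column (NA where no gene overlaps).
#' @export
assign_hits_to_genes <- function(hits, genes) {
  g <- genes$genes
  hits$ortholog_id <- vapply(seq_len(nrow(hits)), function(i) {
    hit <- g$chrom == hits$chrom[i] & g$start < hits$end[i] &
      g$end > hits$start[i]
    if (any(hit)) g$gene_id[which(hit)[1]] else NA_character_
  }, character(1))
  hits
}

#' Run the full synthetic-data pipeline
#'
#' Generates a reference genome and a duplicated genome, emits alignments,
#' detects UCNEs by sliding-window identity, finds their homologs in the
#' duplicate genome with shuffle-calibrated E-values, tallies retention
#' patterns and winner scores with a permutation null, and reconstructs
#' syntenic clusters and subclusters. Every random draw is governed by the
#' seed in `config`.
#'
#' @param config a [synth_config()].
#' @param window,identity_threshold,min_len detection parameters
#'   (defaults 61, 95, 200).
#' @param evalue_threshold homolog acceptance cutoff (default 1e-4).
#' @param n_shuffles shuffles for E-value calibration (default 500).
#' @param null_shuffles shuffles for the permutation null (default 500).
#' @param max_gap,assoc_dist cluster chaining gap and gene association
#'   distance (defaults 5e5, 1e5).
#' @return list with the per-stage outputs (`reference`, `wgd`, `blocks`,
#'   `ucnes`, `hits`, `cases`, `eligible`, `case_matrices`,
#'   `winner_scores`, `null_histogram`, `clusters`, `subclusters`,
#'   `retention`) and a `log` of per-stage record counts.
#' @export
run_pipeline <- function(config, window = 61, identity_threshold = 95,
                         min_len = 200, evalue_threshold = 1e-4,
                         n_shuffles = 500, null_shuffles = 500,
                         max_gap = 5e5, assoc_dist = 1e5) {
  log <- list()
  reference <- generate_reference(config)
  wgd <- simulate_wgd(reference, config)
  blocks <- emit_alignments(reference, wgd)
  log$blocks <- length(blocks)

  ucnes <- scan_ucnes(blocks, reference$genes, window = window,
                      threshold = identity_threshold, min_len = min_len)
  log$ucnes_detected <- nrow(ucnes)

  ## homolog search per UCNE against alignment-derived candidates
  set.seed(config$seed + 30000L)
  ref_seq <- reference$seq[["chr1"]]
  hit_list <- lapply(seq_len(nrow(ucnes)), function(i) {
    u <- ucnes[i, ]
    cand <- extract_candidate_regions(u, blocks)
    hits <- find_homologs(u$ucne_id, subseq_chr(ref_seq, u$start, u$end),
                          cand, threshold = evalue_threshold,
                          n_shuffles = n_shuffles)
    hits
  })
  hits <- do.call(rbind, hit_list)
  log$hits <- nrow(hits)
  log$hits_accepted <- sum(hits$accepted)
  hits <- assign_hits_to_genes(hits, wgd$genes)

  ## retention patterns and winner scores
  cases <- tally_patterns(ucnes, hits, wgd$orthologs)
  eligible <- eligibility_filter(cases)
  log$cases <- nrow(cases)
  log$eligible <- nrow(eligible)
  case_matrices <- lapply(seq_len(nrow(eligible)), function(i) {
    g <- eligible$ref_gene_id[i]; sp <- eligible$genome[i]
    ug <- ucnes$ucne_id[ucnes$host_genes == g &
                          ucnes$position_class %in% c("intronic", "UTR")]
    og <- wgd$orthologs$ortholog_id[wgd$orthologs$ref_gene_id == g &
                                      wgd$orthologs$genome == sp]
    conservation_matrix(ug, hits, og, genome = sp)
  })
  ws <- if (length(case_matrices)) winner_scores(case_matrices) else numeric(0)
  null_hist <- if (length(case_matrices)) {
    permutation_null(case_matrices, n_shuffles = null_shuffles,
                     seed = config$seed + 40000L)
  } else NULL

  ## clusters: second-genome coordinates from alignment provenance
  u2 <- ucnes
  u2$chrom2 <- NA_character_; u2$start2 <- NA_real_; u2$end2 <- NA_real_
  for (i in seq_len(nrow(u2))) {
    cand <- extract_candidate_regions(u2[i, ], blocks, flank = 0)
    if (nrow(cand)) {
      u2$chrom2[i] <- cand$chrom[1]
      u2$start2[i] <- cand$start[1]
      u2$end2[i] <- cand$end[1]
    }
  }
  clusters <- build_clusters(u2, max_gap = max_gap)
  log$clusters <- nrow(clusters$clusters)
  subclusters <- lapply(seq_len(nrow(clusters$clusters)), function(k) {
    ids <- strsplit(clusters$clusters$ucne_ids[k], ";")[[1]]
    find_subclusters(ids, hits, max_gap = max_gap)
  })
  names(subclusters) <- clusters$clusters$cluster_id
  retention <- do.call(rbind, lapply(names(subclusters), function(cid) {
    ids <- strsplit(clusters$clusters$ucne_ids[
      clusters$clusters$cluster_id == cid], ";")[[1]]
    r <- classify_cluster_retention(ids, subclusters[[cid]])
    if (is.null(r)) return(NULL)
    cbind(cluster_id = cid, r)
  }))

  list(reference = reference, wgd = wgd, blocks = blocks, ucnes = ucnes,
       hits = hits, cases = cases, eligible = eligible,
       case_matrices = case_matrices, winner_scores = ws,
       null_histogram = null_hist, clusters = clusters,
       subclusters = subclusters, retention = retention,
       log = unlist(log))
}
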