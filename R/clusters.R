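## Dual-genome UCNE clusters, orthologous syntenic subclusters in a
## duplicated genome, assembly-aware merging, and target/bystander calls.

#' Group UCNEs into dual-genome syntenic clusters
#'
#' Single-linkage chaining along the reference: two UCNEs adjacent in
#' reference order are linked iff they lie on the same chromosome in both
#' genomes and are separated by at most `max_gap` in both. Clusters are the
#' maximal linked runs. A UCNE without second-genome coordinates is
#' unlinkable and forms a singleton.
#'
#' @param ucnes data.frame with reference coordinates (`chrom`, `start`,
#'   `end`) and second-genome coordinates (`chrom2`, `start2`, `end2`; NA
#'   allowed), plus `ucne_id`.
#' @param max_gap maximal spacing between neighbors in either genome
#'   (default 5e5 = 0.5 Mb).
#' @return list of class `ucne_clusters`: `members` (the input with a
#'   `cluster_id` column, in reference order with a `cluster_index` giving
#'   each UCNE's rank within its cluster) and `clusters` (summary:
#'   `cluster_id`, `chrom`, `start`, `end`, `n_ucnes`, `ucne_ids`).
#' @export
build_clusters <- function(ucnes, max_gap = 5e5) {
  u <- ucnes[order(ucnes$chrom, ucnes$start), , drop = FALSE]
  n <- nrow(u)
  if (n == 0) stop("no UCNEs to cluster")
  linked <- rep(FALSE, n)  # linked[i]: row i links to row i-1
  if (n > 1) {
    for (i in 2:n) {
      same1 <- u$chrom[i] == u$chrom[i - 1]
      ok2 <- !is.na(u$chrom2[i]) && !is.na(u$chrom2[i - 1]) &&
        u$chrom2[i] == u$chrom2[i - 1]
      if (!same1 || !ok2) next
      g1 <- interval_gap(u$chrom[i - 1], u$start[i - 1], u$end[i - 1],
                         u$chrom[i], u$start[i], u$end[i])
      g2 <- interval_gap(u$chrom2[i - 1], u$start2[i - 1], u$end2[i - 1],
                         u$chrom2[i], u$start2[i], u$end2[i])
      linked[i] <- g1 <= max_gap && g2 <= max_gap
    }
  }
  grp <- cumsum(!linked)
  u$cluster_id <- sprintf("CL_%03d", grp)
  u$cluster_index <- stats::ave(seq_len(n), grp, FUN = seq_along)
  cl <- do.call(rbind, lapply(split(u, u$cluster_id), function(d) {
    data.frame(cluster_id = d$cluster_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end), n_ucnes = nrow(d),
               ucne_ids = paste(d$ucne_id, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  cl <- cl[order(-cl$n_ucnes, cl$cluster_id), , drop = FALSE]
  rownames(cl) <- NULL
  structure(list(members = u, clusters = cl), class = "ucne_clusters")
}

#' Genes associated with a UCNE cluster
#'
#' A gene is associated if it hosts an intronic/UTR member UCNE or flanks
#' an intergenic member. Only protein-coding genes with annotated CDS and
#' not marked as pseudogenes qualify.
#'
#' @param members data.frame of the cluster's member UCNEs (needs
#'   `position_class`, `host_genes`).
#' @param genes a [gene_models] object.
#' @return character vector of gene ids.
#' @export
associate_genes <- function(members, genes) {
  ids <- unique(unlist(strsplit(members$host_genes, ";")))
  ids <- ids[!is.na(ids) & nzchar(ids)]
  g <- genes$genes
  coding <- g$gene_id[g$biotype == "protein_coding" & !g$pseudogene &
                        g$gene_id %in% unique(genes$cds$gene_id)]
  sort(intersect(ids, coding))
}

#' Orthologous syntenic subclusters of a cluster in one genome
#'
#' Chains the accepted, non-paralog hits of the cluster's member UCNEs per
#' target chromosome/scaffold: neighbors at most `max_gap` apart belong to
#' the same subcluster. The subcluster retaining the most distinct UCNEs is
#' the major one (ties broken by bitscore sum, then by name); all others
#' are minor.
#'
#' @param ucne_ids the cluster's member UCNE ids (in reference order).
#' @param hits hits data.frame for one genome (`ucne_id`, `chrom`, `start`,
#'   `end`, `bitscore`, `accepted`, `paralog_flag`).
#' @param max_gap maximal spacing between neighboring hits (default 5e5).
#' @return data.frame with one row per subcluster: `subcluster_id`,
#'   `chrom`, `start`, `end`, `n_ucnes`, `ucne_ids`, `bitscore_sum`,
#'   `role` (`"major"`/`"minor"`), `merged_from` (empty; see
#'   [merge_assembly_fragments()]); zero rows when there are no hits.
#' @export
find_subclusters <- function(ucne_ids, hits, max_gap = 5e5) {
  h <- hits[hits$ucne_id %in% ucne_ids & hits$accepted & !hits$paralog_flag, ,
            drop = FALSE]
  empty <- data.frame(subcluster_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_ucnes = integer(0), ucne_ids = character(0),
                      bitscore_sum = numeric(0), role = character(0),
                      merged_from = character(0))
  if (!nrow(h)) return(empty)
  ## best hit per (UCNE, locus)
  key <- paste(h$ucne_id, h$chrom, h$start, h$end)
  h <- h[order(key, -h$bitscore), , drop = FALSE]
  h <- h[!duplicated(paste(h$ucne_id, h$chrom, h$start, h$end)), , drop = FALSE]
  h <- h[order(h$chrom, h$start), , drop = FALSE]
  grp <- integer(nrow(h)); grp[1] <- 1L
  if (nrow(h) > 1) {
    for (i in 2:nrow(h)) {
      gap <- interval_gap(h$chrom[i - 1], h$start[i - 1], h$end[i - 1],
                          h$chrom[i], h$start[i], h$end[i])
      grp[i] <- if (gap <= max_gap) grp[i - 1] else grp[i - 1] + 1L
    }
  }
  sc <- do.call(rbind, lapply(split(h, grp), function(d) {
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               n_ucnes = length(unique(d$ucne_id)),
               ucne_ids = paste(unique(d$ucne_id), collapse = ";"),
               bitscore_sum = sum(d$bitscore), stringsAsFactors = FALSE)
  }))
  sc <- sc[order(-sc$n_ucnes, -sc$bitscore_sum, sc$chrom, sc$start), ,
           drop = FALSE]
  sc$subcluster_id <- sprintf("SC_%02d", seq_len(nrow(sc)))
  sc$role <- c("major", rep("minor", nrow(sc) - 1))
  sc$merged_from <- ""
  rownames(sc) <- NULL
  sc[, c("subcluster_id", "chrom", "start", "end", "n_ucnes", "ucne_ids",
         "bitscore_sum", "role", "merged_from")]
}

#' Merge assembly-fragment minor subclusters into the major one
#'
#' Automates the assembly-error rescue: a minor subcluster is merged into
#' the major iff it satisfies condition (iii) -- its member UCNEs occupy a
#' reference-cluster index range disjoint from the major's -- together with
#' (i) it lies on a scaffold not assigned to any chromosome, or (ii) its
#' span is flanked by annotated assembly gaps on both sides (nearest gap
#' within `flank_window`). Merging pools members and records provenance in
#' `merged_from`; a review report of every considered minor is attached as
#' the `"review"` attribute.
#'
#' @param subclusters data.frame from [find_subclusters()].
#' @param cluster_order named integer vector: member UCNE id -> rank within
#'   the reference cluster.
#' @param assembly list with `unplaced` (character vector of scaffold
#'   names) and `gaps` (data.frame `chrom`, `start`, `end`), either may be
#'   empty.
#' @param flank_window how close the flanking gaps must be (default 5e4).
#' @return updated subclusters data.frame (merged minors removed, major's
#'   membership and `merged_from` updated).
#' @export
merge_assembly_fragments <- function(subclusters, cluster_order, assembly,
                                     flank_window = 5e4) {
  if (!nrow(subclusters) || sum(subclusters$role == "minor") == 0)
    return(subclusters)
  stopifnot(any(subclusters$role == "major"))
  unplaced <- assembly$unplaced %||c% character(0)
  gaps <- assembly$gaps
  imaj <- which(subclusters$role == "major")[1]
  idx_range <- function(ids) {
    r <- cluster_order[strsplit(ids, ";")[[1]]]
    c(min(r), max(r))
  }
  gap_flanked <- function(row) {
    if (is.null(gaps) || !nrow(gaps)) return(FALSE)
    g <- gaps[gaps$chrom == row$chrom, , drop = FALSE]
    up <- any(g$end <= row$start & row$start - g$end <= flank_window)
    dn <- any(g$start >= row$end & g$start - row$end <= flank_window)
    up && dn
  }
  review <- list()
  drop <- logical(nrow(subclusters))
  maj_range <- idx_range(subclusters$ucne_ids[imaj])
  for (i in which(subclusters$role == "minor")) {
    row <- subclusters[i, ]
    c1 <- row$chrom %in% unplaced
    c2 <- gap_flanked(row)
    mr <- idx_range(row$ucne_ids)
    c3 <- mr[2] < maj_range[1] || mr[1] > maj_range[2]
    merged <- (c1 || c2) && c3
    review[[length(review) + 1L]] <-
      data.frame(subcluster_id = row$subcluster_id, unplaced = c1,
                 gap_flanked = c2, nonoverlapping = c3, merged = merged)
    if (merged) {
      subclusters$ucne_ids[imaj] <-
        paste(unique(c(strsplit(subclusters$ucne_ids[imaj], ";")[[1]],
                       strsplit(row$ucne_ids, ";")[[1]])), collapse = ";")
      subclusters$n_ucnes[imaj] <-
        length(strsplit(subclusters$ucne_ids[imaj], ";")[[1]])
      subclusters$bitscore_sum[imaj] <-
        subclusters$bitscore_sum[imaj] + row$bitscore_sum
      subclusters$merged_from[imaj] <-
        paste(c(strsplit(subclusters$merged_from[imaj], ";")[[1]],
                row$subcluster_id), collapse = ";")
      maj_range <- range(c(maj_range, mr))
      drop[i] <- TRUE
    }
  }
  out <- subclusters[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "review") <- do.call(rbind, review)
  out
}

`%||c%` <- function(x, y) if (is.null(x)) y else x

#' Genes associated with a syntenic subcluster in a duplicated genome
#'
#' A gene is associated iff the gap between its span and the nearest member
#' hit is at most `max_dist` (0 when overlapping, which covers genes
#' hosting an intronic/UTR member). Only protein-coding, non-pseudogene
#' genes qualify.
#'
#' @param subcluster one row of a [find_subclusters()] table.
#' @param hits the genome's hits data.frame (member hits are looked up by
#'   `ucne_id` and chromosome).
#' @param genes [gene_models] of the duplicated genome.
#' @param max_dist association distance (default 1e5 = 0.1 Mb).
#' @return character vector of associated gene ids.
#' @export
associate_fish_genes <- function(subcluster, hits, genes, max_dist = 1e5) {
  ids <- strsplit(subcluster$ucne_ids, ";")[[1]]
  h <- hits[hits$ucne_id %in% ids & hits$chrom == subcluster$chrom &
              hits$accepted & !hits$paralog_flag, , drop = FALSE]
  h <- h[h$start >= subcluster$start & h$end <= subcluster$end, , drop = FALSE]
  g <- genes$genes
  g <- g[g$biotype == "protein_coding" & !g$pseudogene, , drop = FALSE]
  if (!nrow(h) || !nrow(g)) return(character(0))
  assoc <- vapply(seq_len(nrow(g)), function(i) {
    d <- interval_gap(g$chrom[i], g$start[i], g$end[i],
                      h$chrom, h$start, h$end)
    any(d <= max_dist)
  }, logical(1))
  sort(g$gene_id[assoc])
}

#' Call target versus bystander genes
#'
#' A cluster-associated gene is a potential target iff it has a
#' UCNE-associated ortholog in every genome with data; all others
#' (including genes with no ortholog anywhere) are bystanders.
#'
#' @param associations data.frame with columns `ref_gene_id`, `genome`,
#'   `associated` (logical), one row per (gene, genome) with data.
#' @param genes optional character vector of all cluster genes; genes
#'   without any association row are called bystanders.
#' @return data.frame `gene_id`, `n_genomes`, `n_associated`, `call`.
#' @export
call_targets <- function(associations, genes = NULL) {
  ids <- unique(c(associations$ref_gene_id, genes))
  rows <- lapply(ids, function(g) {
    d <- associations[associations$ref_gene_id == g, , drop = FALSE]
    data.frame(gene_id = g, n_genomes = nrow(d),
               n_associated = sum(d$associated),
               call = if (nrow(d) > 0 && all(d$associated)) "target"
                      else "bystander",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Retention pattern of a UCNE cluster in one genome
#'
#' Classifies the cluster-level (a,b,c) pattern from the (post-merge)
#' subclusters: `a` member UCNEs present only in the major subcluster, `b`
#' in major and at least one minor, `c` only in minor(s).
#'
#' @param ucne_ids the cluster's member UCNE ids.
#' @param subclusters data.frame from [find_subclusters()] /
#'   [merge_assembly_fragments()].
#' @return one-row data.frame `a`, `b`, `c`, `label`, `major_subcluster`;
#'   `NULL` when no member UCNE survives.
#' @export
classify_cluster_retention <- function(ucne_ids, subclusters) {
  if (!nrow(subclusters)) return(NULL)
  maj <- subclusters[subclusters$role == "major", , drop = FALSE][1, ]
  in_major <- ucne_ids %in% strsplit(maj$ucne_ids, ";")[[1]]
  minors <- subclusters[subclusters$role == "minor", , drop = FALSE]
  in_minor <- ucne_ids %in% unique(unlist(strsplit(minors$ucne_ids, ";")))
  a <- sum(in_major & !in_minor)
  b <- sum(in_major & in_minor)
  c <- sum(!in_major & in_minor)
  if (a + b + c == 0) return(NULL)
  data.frame(a = a, b = b, c = c, label = classify_pattern(a, b, c),
             major_subcluster = maj$subcluster_id, stringsAsFactors = FALSE)
}
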