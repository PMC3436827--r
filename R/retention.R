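## Retention-pattern analysis of UCNEs across duplicate (post-WGD) orthologs.
##
## For each reference gene and each duplicated genome we count, over the
## gene's intronic/UTR UCNEs, how many are retained only by the ortholog
## with the most UCNEs (the "major ortholog", count a), by both major and
## at least one minor ortholog (b), and only by minor ortholog(s) (c).
## The (a,b,c) triplet is classified as winner-takes-all, concordant or
## reciprocal retention.

#' Classify a UCNE retention pattern
#'
#' Applies the retention-pattern rule to one or more (a,b,c) triplets, where
#' `a` is the number of UCNEs retained only by the major ortholog, `b` the
#' number retained by both major and minor ortholog(s) and `c` the number
#' retained only by minor ortholog(s). With n = a+b+c, a case is
#' `"winner"` (winner-takes-all) if a/n > 0.8, `"reciprocal"` if c/n > 0.2,
#' and `"concordant"` otherwise. Both inequalities are strict; the two
#' conditions cannot hold simultaneously (a/n > 0.8 and c/n > 0.2 would
#' need a + c > n).
#'
#' @param a,b,c non-negative integer vectors (recycled to common length).
#' @param winner_cut threshold on a/n for winner-takes-all (default 0.8).
#' @param reciprocal_cut threshold on c/n for reciprocal retention
#'   (default 0.2).
#' @return character vector in `c("winner", "concordant", "reciprocal")`.
#' @examples
#' classify_pattern(22, 1, 0)  # winner
#' classify_pattern(18, 6, 0)  # concordant: 18/24 = 0.75 <= 0.8
#' classify_pattern(6, 1, 2)   # reciprocal: 2/9 > 0.2
#' @export
classify_pattern <- function(a, b, c, winner_cut = 0.8, reciprocal_cut = 0.2) {
  n <- max(length(a), length(b), length(c))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n)
  if (any(a < 0 | b < 0 | c < 0)) stop("a, b, c must be non-negative")
  tot <- a + b + c
  if (any(tot == 0)) stop("retention pattern undefined for a+b+c = 0")
  ifelse(a / tot > winner_cut, "winner",
         ifelse(c / tot > reciprocal_cut, "reciprocal", "concordant"))
}

#' Tally the UCNE retention pattern of one gene in one genome
#'
#' Presence of a UCNE in an ortholog means at least one accepted,
#' non-paralog homology hit assigned to that ortholog. The ortholog with
#' the highest UCNE count is the major ortholog; ties are broken by larger
#' bitscore sum, then lexicographically by id (and flagged).
#'
#' @param ucne_ids character vector: the gene's intronic/UTR UCNE ids.
#' @param hits data.frame of homology hits with columns `ucne_id`,
#'   `ortholog_id`, `accepted`, `paralog_flag`, `bitscore` (already
#'   restricted to the genome of interest, or carrying a `genome` column
#'   plus the `genome` argument).
#' @param ortholog_ids character vector of the gene's ortholog ids in this
#'   genome.
#' @param genome optional genome id used to subset `hits` and label output.
#' @return one-row data.frame with columns `genome`, `n_orthologs`, `a`,
#'   `b`, `c`, `major_ortholog_id`, `major_tie`, `n_retained`; or `NULL`
#'   (with a message) when `ortholog_ids` is empty.
#' @export
tally_pattern <- function(ucne_ids, hits, ortholog_ids, genome = NA_character_) {
  if (length(ortholog_ids) == 0) {
    message("tally_pattern: no orthologs -- case skipped")
    return(NULL)
  }
  if (!is.na(genome) && "genome" %in% names(hits)) {
    hits <- hits[hits$genome == genome, , drop = FALSE]
  }
  hits <- hits[hits$ucne_id %in% ucne_ids &
                 hits$ortholog_id %in% ortholog_ids &
                 hits$accepted & !hits$paralog_flag, , drop = FALSE]
  ## presence and bitscore matrices: UCNE x ortholog
  pres <- matrix(FALSE, length(ucne_ids), length(ortholog_ids),
                 dimnames = list(ucne_ids, ortholog_ids))
  bsc <- matrix(0, length(ucne_ids), length(ortholog_ids),
                dimnames = list(ucne_ids, ortholog_ids))
  if (nrow(hits)) {
    for (k in seq_len(nrow(hits))) {
      i <- hits$ucne_id[k]; j <- hits$ortholog_id[k]
      pres[i, j] <- TRUE
      bsc[i, j] <- max(bsc[i, j], hits$bitscore[k])
    }
  }
  counts <- colSums(pres)
  best <- max(counts)
  cand <- which(counts == best)
  tie <- length(cand) > 1 && best > 0
  if (length(cand) > 1) {
    ss <- colSums(bsc)[cand]
    cand <- cand[ss == max(ss)]
    if (length(cand) > 1) cand <- cand[order(names(cand))][1]
  }
  major <- colnames(pres)[cand[1]]
  in_major <- pres[, major]
  in_minor <- if (ncol(pres) > 1) {
    rowSums(pres[, colnames(pres) != major, drop = FALSE]) > 0
  } else rep(FALSE, nrow(pres))
  data.frame(genome = genome,
             n_orthologs = length(ortholog_ids),
             a = sum(in_major & !in_minor),
             b = sum(in_major & in_minor),
             c = sum(!in_major & in_minor),
             major_ortholog_id = major,
             major_tie = tie,
             n_retained = sum(in_major),
             stringsAsFactors = FALSE)
}

#' Tally retention patterns for all genes and genomes
#'
#' @param ucnes data.frame of UCNEs with columns `ucne_id`,
#'   `position_class`, `host_genes`; only intronic/UTR UCNEs enter the
#'   tallies, attributed to their host gene.
#' @param hits homology hits as in [tally_pattern()], with a `genome`
#'   column and an `ortholog_id` column.
#' @param orthologs data.frame with columns `ref_gene_id`, `genome`,
#'   `ortholog_id` (one row per ortholog copy).
#' @param label logical: add the `label` column via [classify_pattern()]
#'   for cases with a+b+c > 0.
#' @return data.frame of cases (gene x genome), one row each, with the
#'   columns of [tally_pattern()] plus `ref_gene_id` and optionally
#'   `label` (NA when no UCNE was retained).
#' @export
tally_patterns <- function(ucnes, hits, orthologs, label = TRUE) {
  ucnes <- ucnes[ucnes$position_class %in% c("intronic", "UTR"), , drop = FALSE]
  out <- list()
  for (g in unique(orthologs$ref_gene_id)) {
    ug <- ucnes$ucne_id[ucnes$host_genes == g]
    if (!length(ug)) next
    og <- orthologs[orthologs$ref_gene_id == g, , drop = FALSE]
    for (sp in unique(og$genome)) {
      row <- tally_pattern(ug, hits, og$ortholog_id[og$genome == sp], genome = sp)
      if (is.null(row)) next
      out[[length(out) + 1L]] <- cbind(ref_gene_id = g, row,
                                       stringsAsFactors = FALSE)
    }
  }
  cases <- if (length(out)) do.call(rbind, out) else
    data.frame(ref_gene_id = character(0))
  if (label && nrow(cases)) {
    tot <- cases$a + cases$b + cases$c
    cases$label <- NA_character_
    nz <- tot > 0
    if (any(nz)) cases$label[nz] <-
        classify_pattern(cases$a[nz], cases$b[nz], cases$c[nz])
  }
  rownames(cases) <- NULL
  cases
}

#' Filter cases eligible for winner-score statistics
#'
#' Keeps cases with two or more orthologs where three or more intronic/UTR
#' UCNEs are retained in the major ortholog.
#'
#' @param cases data.frame from [tally_patterns()] (needs `n_orthologs`
#'   and `n_retained` = a+b).
#' @param min_orthologs,min_major_ucnes eligibility cutoffs (defaults 2, 3).
#' @return the eligible subset of `cases`.
#' @export
eligibility_filter <- function(cases, min_orthologs = 2, min_major_ucnes = 3) {
  if (!nrow(cases)) return(cases)
  n_ret <- if ("n_retained" %in% names(cases)) cases$n_retained else
    cases$a + cases$b
  cases[cases$n_orthologs >= min_orthologs & n_ret >= min_major_ucnes, ,
        drop = FALSE]
}

#' Conservation-score matrix of one case
#'
#' Builds the UCNE x ortholog matrix of conservation scores c_ij: the
#' bitscore of the best accepted non-paralog hit of UCNE i assigned to
#' ortholog j, and 0 where no such hit exists.
#'
#' @inheritParams tally_pattern
#' @return numeric matrix with UCNE ids as rownames, ortholog ids as
#'   colnames.
#' @export
conservation_matrix <- function(ucne_ids, hits, ortholog_ids,
                                genome = NA_character_) {
  if (!is.na(genome) && "genome" %in% names(hits)) {
    hits <- hits[hits$genome == genome, , drop = FALSE]
  }
  hits <- hits[hits$ucne_id %in% ucne_ids &
                 hits$ortholog_id %in% ortholog_ids &
                 hits$accepted & !hits$paralog_flag, , drop = FALSE]
  m <- matrix(0, length(ucne_ids), length(ortholog_ids),
              dimnames = list(ucne_ids, ortholog_ids))
  if (nrow(hits)) {
    for (k in seq_len(nrow(hits))) {
      i <- hits$ucne_id[k]; j <- hits$ortholog_id[k]
      m[i, j] <- max(m[i, j], hits$bitscore[k])
    }
  }
  m
}

#' Winner score of one eligible case
#'
#' The winner score W is the percentage of the total conservation score
#' attributable to the major ortholog: with c_ij the conservation score of
#' UCNE i in ortholog j, C_total = sum_ij c_ij, the major column is the one
#' with the largest column sum, C_major is that sum and
#' W = 100 * C_major / C_total. With k orthologs W is bounded below by
#' 100/k and above by 100 (all score in one copy).
#'
#' @param cij numeric matrix of conservation scores (UCNEs x orthologs),
#'   e.g. from [conservation_matrix()].
#' @return list with elements `W`, `C_total`, `C_major`,
#'   `major_ortholog_id` (colname or column index), `cij`.
#' @examples
#' winner_score(cbind(major = c(100, 50, 30), minor = c(0, 0, 20)))$W  # 90
#' @export
winner_score <- function(cij) {
  cij <- as.matrix(cij)
  if (any(cij < 0)) stop("conservation scores must be non-negative")
  C_total <- sum(cij)
  if (C_total == 0) stop("winner score undefined: all conservation scores are zero")
  cs <- colSums(cij)
  jmax <- which.max(cs)
  list(W = 100 * cs[[jmax]] / C_total,
       C_total = C_total,
       C_major = cs[[jmax]],
       major_ortholog_id = if (!is.null(colnames(cij))) colnames(cij)[jmax] else jmax,
       cij = cij)
}

#' Winner scores of a list of cases
#'
#' @param case_matrices list of c_ij matrices.
#' @return numeric vector of winner scores.
#' @export
winner_scores <- function(case_matrices) {
  vapply(case_matrices, function(m) winner_score(m)$W, numeric(1))
}

## histogram frequencies over (breaks[i], breaks[i+1]] bins; include.lowest
## so a value equal to the first break is counted.
score_histogram <- function(w, breaks) {
  idx <- cut(w, breaks = breaks, include.lowest = TRUE, right = TRUE)
  as.vector(table(idx)) / length(w)
}

#' Permutation null distribution of winner scores
#'
#' Builds the expected winner-score histogram under a random-retention
#' model: in each shuffle, the conservation scores of every UCNE are
#' independently permuted across that gene's ortholog columns (preserving
#' each row's multiset of scores), the major ortholog is re-identified and
#' winner scores are recomputed for every case; histogram frequencies are
#' averaged over shuffles.
#'
#' @param case_matrices list of c_ij matrices of the eligible cases.
#' @param n_shuffles number of shuffled datasets (default 500).
#' @param breaks histogram bin edges on the winner-score scale (default
#'   width-5 bins over 0-100).
#' @param seed optional RNG seed.
#' @return data.frame of class `null_histogram` with columns `bin_lo`,
#'   `bin_hi`, `mean_freq`, `sd_freq`; attribute `n_shuffles`.
#' @export
permutation_null <- function(case_matrices, n_shuffles = 500,
                             breaks = seq(0, 100, by = 5), seed = NULL) {
  if (!length(case_matrices)) stop("no eligible cases")
  if (!is.null(seed)) set.seed(seed)
  nb <- length(breaks) - 1
  freq <- matrix(0, n_shuffles, nb)
  for (s in seq_len(n_shuffles)) {
    w <- vapply(case_matrices, function(m) {
      perm <- t(apply(m, 1, function(row) row[sample.int(length(row))]))
      winner_score(perm)$W
    }, numeric(1))
    freq[s, ] <- score_histogram(w, breaks)
  }
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    mean_freq = colMeans(freq), sd_freq = apply(freq, 2, sd))
  attr(out, "n_shuffles") <- n_shuffles
  class(out) <- c("null_histogram", class(out))
  out
}
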