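## Homolog detection by optimal local alignment with shuffle-calibrated
## E-values, and ortholog/paralog discrimination.
##
## Candidate sequences are scored against each UCNE by Smith-Waterman local
## alignment; significance is calibrated per (query, subject) pair by
## shuffling the subject in 20-bp windows, fitting an extreme-value
## (Gumbel) distribution to the shuffled score sample by maximum
## likelihood, and converting the upper-tail probability to an E-value.
## Candidates at E <= 1e-4 are accepted as homologs.

#' Nucleotide local-alignment scoring scheme
#'
#' DNA defaults in the SSEARCH tradition: match +5, mismatch -4, gap open
#' 12, gap extend 4. `lambda` and `K` are Karlin-Altschul parameters used
#' only to put raw scores on the bitscore scale.
#'
#' @param match,mismatch match score and mismatch penalty (signed).
#' @param gap_open,gap_extend gap penalties (non-negative costs).
#' @param lambda,K bitscore scale parameters (`lambda > 0`).
#' @return list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap_open = 12,
                           gap_extend = 4, lambda = 0.192, K = 0.176) {
  stopifnot(gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

## substitution matrix over A,C,G,T,N: ambiguity codes score as mismatches
substitution_matrix <- function(scheme) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scheme$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m)[1:4] <- scheme$match
  m["N", "N"] <- scheme$mismatch
  m
}

bit_score <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment via [Biostrings::pairwiseAlignment()]
#' under the given scoring scheme. The raw score is floored at 0 (the
#' empty local alignment); the bitscore is
#' `(lambda * raw - ln K) / ln 2`.
#'
#' @param query,subject character scalars or `DNAString`s.
#' @param scheme a [scoring_scheme()].
#' @param score_only logical: skip span extraction (faster).
#' @return list with `raw`, `bitscore`, and (unless `score_only`)
#'   `query_span` and `subject_span` (1-based closed alignment spans).
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        score_only = FALSE) {
  stopifnot(nchar(as.character(query)) > 0, nchar(as.character(subject)) > 0)
  sm <- substitution_matrix(scheme)
  if (score_only) {
    raw <- Biostrings::pairwiseAlignment(
      pattern = as.character(query), subject = as.character(subject),
      type = "local", substitutionMatrix = sm,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      scoreOnly = TRUE)
    raw <- max(0, raw)
    return(list(raw = raw, bitscore = max(0, bit_score(raw, scheme))))
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = as.character(query), subject = as.character(subject),
    type = "local", substitutionMatrix = sm,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  raw <- max(0, BiocGenerics::score(pa))
  list(raw = raw,
       bitscore = max(0, bit_score(raw, scheme)),
       query_span = c(BiocGenerics::start(Biostrings::pattern(pa)),
                      BiocGenerics::end(Biostrings::pattern(pa))),
       subject_span = c(BiocGenerics::start(Biostrings::subject(pa)),
                        BiocGenerics::end(Biostrings::subject(pa))))
}

## scores of one query against many subjects in one C call
local_align_scores <- function(query, subjects, scheme) {
  sc <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(subjects),
    subject = as.character(query),
    type = "local", substitutionMatrix = substitution_matrix(scheme),
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE)
  pmax(0, sc)
}

## permute a sequence within consecutive windows of `window` bases; the
## remainder (< window bases) is permuted as its own short window
shuffle_in_windows <- function(sequence, window = 20) {
  x <- strsplit(sequence, "")[[1]]
  n <- length(x)
  grp <- (seq_len(n) - 1) %/% window
  idx <- unlist(lapply(split(seq_len(n), grp), function(i) {
    if (length(i) > 1) i[sample.int(length(i))] else i
  }), use.names = FALSE)
  paste(x[idx], collapse = "")
}

## ML fit of a Gumbel distribution; moment-based start values
fit_gumbel <- function(x) {
  beta0 <- sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772156649 * beta0
  nll <- function(p) {
    beta <- exp(p[2])
    z <- (x - p[1]) / beta
    length(x) * log(beta) + sum(z + exp(-z))
  }
  fit <- optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead")
  list(mu = fit$par[1], beta = exp(fit$par[2]))
}

#' Shuffle-calibrated E-value of a local alignment
#'
#' The subject is shuffled `n_shuffles` times in consecutive windows of
#' `shuffle_window` bases (the remainder is permuted as its own short
#' window) and re-aligned to the query. A Gumbel distribution is fitted to
#' the shuffled scores by maximum likelihood and the E-value is
#' `db_size * P(score >= observed)` under the fit, which resolves
#' probabilities far below `1/n_shuffles`. If the shuffled scores are
#' degenerate (zero variance, e.g. a mononucleotide subject), the empirical
#' rank p-value `(r + 1) / (n_shuffles + 1)` is used instead.
#'
#' @param query,subject character scalars (A/C/G/T).
#' @param scheme a [scoring_scheme()].
#' @param n_shuffles number of shuffles (>= 100; default 500).
#' @param shuffle_window shuffle window in bases (default 20).
#' @param db_size effective database size: number of candidate regions the
#'   query is tested against (default 1).
#' @param seed optional RNG seed (E-values are reproducible given a seed).
#' @return list with `evalue`, `pvalue`, `raw`, `bitscore`, `mu`, `beta`
#'   (NA under the rank fallback) and `n_shuffles`.
#' @export
shuffle_evalue <- function(query, subject, scheme = scoring_scheme(),
                           n_shuffles = 500, shuffle_window = 20,
                           db_size = 1, seed = NULL) {
  stopifnot(n_shuffles >= 100)
  if (!is.null(seed)) set.seed(seed)
  obs <- local_align(query, subject, scheme, score_only = TRUE)
  shuffled <- vapply(seq_len(n_shuffles),
                     function(i) shuffle_in_windows(subject, shuffle_window),
                     character(1))
  sc <- local_align_scores(query, shuffled, scheme)
  if (sd(sc) < sqrt(.Machine$double.eps)) {
    r <- sum(sc >= obs$raw)
    p <- (r + 1) / (n_shuffles + 1)
    mu <- beta <- NA_real_
  } else {
    fit <- fit_gumbel(sc)
    mu <- fit$mu; beta <- fit$beta
    ## upper tail of the Gumbel: P(S >= s) = 1 - exp(-exp(-(s - mu)/beta))
    p <- -expm1(-exp(-(obs$raw - mu) / beta))
    p <- min(1, max(p, .Machine$double.xmin))
  }
  list(evalue = db_size * p, pvalue = p, raw = obs$raw,
       bitscore = obs$bitscore, mu = mu, beta = beta,
       n_shuffles = n_shuffles)
}

#' Score candidate regions against a UCNE and accept homologs
#'
#' One hit per candidate region; a candidate is accepted iff its
#' shuffle-calibrated E-value is `<= threshold` (the threshold itself is
#' accepted). Minus-strand candidates are expected to carry their sequence
#' already in alignment orientation with coordinates on the forward strand
#' (as produced by [extract_candidate_regions()]).
#'
#' @param ucne_id id of the query UCNE.
#' @param ucne_seq query sequence (character).
#' @param candidates data.frame with columns `chrom`, `start`, `end`,
#'   `strand`, `seq` and optionally `genome`.
#' @param scheme a [scoring_scheme()].
#' @param threshold E-value acceptance cutoff (default 1e-4).
#' @param n_shuffles,shuffle_window see [shuffle_evalue()].
#' @param db_size effective database size; default: number of candidate
#'   regions evaluated for this UCNE.
#' @param seed optional RNG seed.
#' @return hits data.frame: `ucne_id`, `genome`, `chrom`, `start`, `end`,
#'   `strand`, `raw`, `bitscore`, `evalue`, `accepted`, `paralog_flag`
#'   (initialized `FALSE`), `seq`. Zero rows when there are no candidates
#'   (the UCNE is lost).
#' @export
find_homologs <- function(ucne_id, ucne_seq, candidates,
                          scheme = scoring_scheme(), threshold = 1e-4,
                          n_shuffles = 500, shuffle_window = 20,
                          db_size = NULL, seed = NULL) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    return(data.frame(ucne_id = character(0), genome = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      raw = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), accepted = logical(0),
                      paralog_flag = logical(0), seq = character(0)))
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(db_size)) db_size <- nrow(candidates)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    ev <- shuffle_evalue(ucne_seq, candidates$seq[i], scheme,
                         n_shuffles = n_shuffles,
                         shuffle_window = shuffle_window, db_size = db_size)
    data.frame(ucne_id = ucne_id,
               genome = if ("genome" %in% names(candidates))
                 candidates$genome[i] else NA_character_,
               chrom = candidates$chrom[i], start = candidates$start[i],
               end = candidates$end[i], strand = candidates$strand[i],
               raw = ev$raw, bitscore = ev$bitscore, evalue = ev$evalue,
               accepted = ev$evalue <= threshold, paralog_flag = FALSE,
               seq = candidates$seq[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compile reference-genome paralogs of each UCNE
#'
#' Aligns every UCNE against candidate reference-genome regions (e.g. all
#' reference sequence present in the reference-outgroup alignments),
#' excluding the UCNE's own locus, and records candidates accepted at
#' `E <= threshold` as paralogs. Paralogs need not themselves qualify as
#' UCNEs.
#'
#' @param ucnes UCNE data.frame with `ucne_id`, `chrom`, `start`, `end` and
#'   a `seq` column.
#' @param self_candidates data.frame of reference regions with `chrom`,
#'   `start`, `end`, `strand`, `seq`.
#' @param scheme,threshold,n_shuffles,shuffle_window,seed as in
#'   [find_homologs()].
#' @return named list (class `paralog_catalog`): `ucne_id` -> data.frame of
#'   paralog regions (with sequences); empty data.frame when none.
#' @export
build_paralog_catalog <- function(ucnes, self_candidates,
                                  scheme = scoring_scheme(),
                                  threshold = 1e-4, n_shuffles = 500,
                                  shuffle_window = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cat_list <- lapply(seq_len(nrow(ucnes)), function(i) {
    u <- ucnes[i, ]
    cand <- self_candidates
    own <- cand$chrom == u$chrom & cand$start < u$end & cand$end > u$start
    cand <- cand[!own, , drop = FALSE]
    hits <- find_homologs(u$ucne_id, u$seq, cand, scheme,
                          threshold = threshold, n_shuffles = n_shuffles,
                          shuffle_window = shuffle_window)
    hits[hits$accepted, c("chrom", "start", "end", "strand", "evalue", "seq"),
         drop = FALSE]
  })
  names(cat_list) <- ucnes$ucne_id
  structure(cat_list, class = "paralog_catalog")
}

#' Flag homology hits that track a paralog rather than the UCNE
#'
#' For each accepted hit, the hit sequence is compared against every
#' reference paralog of the UCNE; if some paralog achieves a strictly
#' lower E-value against the hit than the UCNE itself does, the hit is
#' flagged as a paralog (and is excluded from all retention tallies
#' downstream). Exact E-value ties keep ortholog status.
#'
#' @param hits hits data.frame from [find_homologs()] (needs `seq`).
#' @param ucne_seq the UCNE's own sequence.
#' @param paralogs data.frame of the UCNE's catalog entry from
#'   [build_paralog_catalog()] (may have zero rows).
#' @param scheme,n_shuffles,shuffle_window,seed as in [shuffle_evalue()].
#' @return `hits` with `paralog_flag` updated.
#' @export
flag_paralogs <- function(hits, ucne_seq, paralogs,
                          scheme = scoring_scheme(), n_shuffles = 500,
                          shuffle_window = 20, seed = NULL) {
  if (!nrow(hits) || is.null(paralogs) || nrow(paralogs) == 0) return(hits)
  if (!is.null(seed)) set.seed(seed)
  for (i in which(hits$accepted)) {
    subj <- hits$seq[i]
    e_self <- shuffle_evalue(ucne_seq, subj, scheme,
                             n_shuffles = n_shuffles,
                             shuffle_window = shuffle_window)$evalue
    e_par <- vapply(paralogs$seq, function(p) {
      shuffle_evalue(p, subj, scheme, n_shuffles = n_shuffles,
                     shuffle_window = shuffle_window)$evalue
    }, numeric(1))
    hits$paralog_flag[i] <- min(e_par) < e_self
  }
  hits
}

#' Extract candidate target regions for a UCNE from alignment blocks
#'
#' Finds blocks whose reference interval overlaps the UCNE, maps the UCNE's
#' reference range (plus `flank` columns on each side) to alignment
#' columns, and returns the gap-free target sequence of that column slice
#' with its target-genome coordinates. Minus-strand targets are returned in
#' alignment orientation with forward-strand coordinates.
#'
#' @param interval one-row data.frame (or list) with `chrom`, `start`,
#'   `end` on the reference.
#' @param blocks list of `alignment_block`s.
#' @param flank extra alignment columns on each side (default 50).
#' @return data.frame with `genome`, `chrom`, `start`, `end`, `strand`,
#'   `seq`; zero rows when no block overlaps.
#' @export
extract_candidate_regions <- function(interval, blocks, flank = 50) {
  out <- list()
  for (b in blocks) {
    if (b$ref$chrom != interval$chrom) next
    if (b$ref$start >= interval$end || b$ref$end <= interval$start) next
    r <- strsplit(b$ref_row, "")[[1]]
    ref_cols <- which(r != "-")
    refpos <- b$ref$start + seq_along(ref_cols) - 1
    sel <- ref_cols[refpos >= interval$start & refpos < interval$end]
    if (!length(sel)) next
    c1 <- max(1, min(sel) - flank)
    c2 <- min(length(r), max(sel) + flank)
    t <- strsplit(b$target_row, "")[[1]]
    tslice <- t[c1:c2]
    seq <- paste(tslice[tslice != "-"], collapse = "")
    if (!nchar(seq)) next
    ## target coordinates (strand-native) of the slice
    tn <- cumsum(t != "-")
    ts <- b$target$start + (if (c1 > 1) tn[c1 - 1] else 0)
    te <- b$target$start + tn[c2]
    if (identical(b$target$strand, "-")) {
      fs <- b$target$src_size - te
      fe <- b$target$src_size - ts
      ts <- fs; te <- fe
    }
    out[[length(out) + 1L]] <- data.frame(
      genome = b$target$genome, chrom = b$target$chrom, start = ts, end = te,
      strand = b$target$strand, seq = seq, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(genome = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), seq = character(0)))
  }
  do.call(rbind, out)
}
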