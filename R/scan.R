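## UCNE detection from pairwise alignment blocks.
##
## Identity is computed asymmetrically with the reference fixed: windows of
## 61 alignment columns are centered on reference bases, gap and ambiguous
## columns count as mismatches, and the first/last full-window values are
## copied outward to the flanking reference bases. Maximal runs of >= 95%
## identity are then cleaned of coding overlap and length-filtered.

#' Per-base identity profile of an alignment block
#'
#' Slides a window of `window` alignment columns along the block and
#' assigns `100 * matches / window` to the reference base at the window
#' center. A column matches when reference and target carry the same
#' unambiguous base (gaps and N/ambiguity codes count as mismatches).
#' Reference bases too close to a block end to own a full window inherit
#' the value of the first (or last) full window; blocks shorter than the
#' window get the whole-block identity at every reference base.
#'
#' @param block an `alignment_block` (see [read_maf()]).
#' @param window odd window size in alignment columns (default 61).
#' @return list of class `conservation_profile` with elements `chrom`,
#'   `start`, `end` (reference interval) and `identity` (one value in
#'   `[0, 100]` per reference base).
#' @export
compute_identity_profile <- function(block, window = 61) {
  stopifnot(window >= 1, window %% 2 == 1)
  r <- strsplit(toupper(block$ref_row), "")[[1]]
  t <- strsplit(toupper(block$target_row), "")[[1]]
  stopifnot(length(r) == length(t))
  n <- length(r)
  if (n == 0) {
    return(structure(list(chrom = block$ref$chrom, start = block$ref$start,
                          end = block$ref$start, identity = numeric(0)),
                     class = "conservation_profile"))
  }
  bases <- c("A", "C", "G", "T")
  m <- (r == t) & (r %in% bases) & (t %in% bases)
  ref_cols <- which(r != "-")
  if (n < window) {
    ident_per_base <- rep(100 * sum(m) / n, length(ref_cols))
  } else {
    h <- (window - 1) / 2
    cs <- cumsum(c(0, m))
    centers <- (h + 1):(n - h)                      # columns with a full window
    win_id <- 100 * (cs[centers + h + 1] - cs[centers - h]) / window
    col_val <- rep(NA_real_, n)
    col_val[centers] <- win_id
    col_val[seq_len(h)] <- win_id[1]
    col_val[(n - h + 1):n] <- win_id[length(win_id)]
    ident_per_base <- col_val[ref_cols]
  }
  structure(list(chrom = block$ref$chrom, start = block$ref$start,
                 end = block$ref$start + length(ref_cols),
                 identity = ident_per_base),
            class = "conservation_profile")
}

#' Extract maximal ultraconserved runs from an identity profile
#'
#' @param profile a `conservation_profile`, or a data.frame with columns
#'   `chrom`, `pos` (0-based base position) and `identity` (positions need
#'   not be contiguous; runs break at coverage gaps).
#' @param threshold minimal percent identity (default 95); runs are maximal
#'   stretches of consecutive bases with identity `>= threshold`.
#' @return data.frame of intervals (`chrom`, `start`, `end`), 0-based
#'   half-open, ordered by position.
#' @export
extract_ultraconserved <- function(profile, threshold = 95) {
  if (inherits(profile, "conservation_profile")) {
    df <- data.frame(chrom = profile$chrom,
                     pos = seq(profile$start, length.out = length(profile$identity)),
                     identity = profile$identity)
  } else df <- profile
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    keep <- d$identity >= threshold
    if (!any(keep)) next
    pos <- d$pos[keep]
    ## break runs where positions are not consecutive
    brk <- c(TRUE, diff(pos) != 1)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      p <- pos[grp == g]
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start = p[1],
                                            end = p[length(p)] + 1)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Remove coding overlap from candidate intervals
#'
#' Set-difference of each interval with the union of all CDS intervals of
#' the gene models; an interval overlapping a CDS may be split into
#' several non-coding fragments.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param genes a [gene_models] object.
#' @return data.frame of fragments (`chrom`, `start`, `end`, `source` = row
#'   index of the originating interval).
#' @export
subtract_coding <- function(intervals, genes) {
  subtract_intervals(intervals, all_cds(genes))
}

#' Length-filter fragments into UCNEs
#'
#' Keeps fragments of at least `min_len` bases (strictly shorter ones are
#' eliminated) and assigns stable ids in (chrom, start) order.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param min_len minimal element length (default 200).
#' @param id_prefix prefix for generated ids.
#' @return data.frame with `ucne_id`, `chrom`, `start`, `end`, `strand`,
#'   `length`.
#' @export
filter_length <- function(intervals, min_len = 200, id_prefix = "UCNE") {
  len <- intervals$end - intervals$start
  keep <- intervals[len >= min_len, , drop = FALSE]
  keep <- keep[order(keep$chrom, keep$start), , drop = FALSE]
  data.frame(ucne_id = sprintf("%s_%04d", id_prefix, seq_len(nrow(keep))),
             chrom = keep$chrom, start = keep$start, end = keep$end,
             strand = ".", length = keep$end - keep$start,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify UCNE genomic position relative to gene models
#'
#' A UCNE overlapping any UTR base is `"UTR"` (UTR wins over intronic);
#' otherwise a UCNE overlapping a gene span is `"intronic"`; all others are
#' `"intergenic"`, with the two flanking genes recorded. UCNEs are assumed
#' free of CDS overlap (run [subtract_coding()] first).
#'
#' @param ucnes data.frame with `chrom`, `start`, `end` (and any id
#'   columns, preserved).
#' @param genes a [gene_models] object.
#' @return `ucnes` with columns `position_class` and `host_genes`
#'   (`;`-separated gene ids: hosts for genic UCNEs, flanking genes for
#'   intergenic ones) appended.
#' @export
classify_position <- function(ucnes, genes) {
  g <- genes$genes
  utr <- genes$utrs
  pc <- character(nrow(ucnes))
  hg <- character(nrow(ucnes))
  for (i in seq_len(nrow(ucnes))) {
    ch <- ucnes$chrom[i]; s <- ucnes$start[i]; e <- ucnes$end[i]
    in_utr <- utr$chrom == ch & utr$start < e & utr$end > s
    if (any(in_utr)) {
      pc[i] <- "UTR"
      hg[i] <- paste(unique(utr$gene_id[in_utr]), collapse = ";")
      next
    }
    in_gene <- g$chrom == ch & g$start < e & g$end > s
    if (any(in_gene)) {
      pc[i] <- "intronic"
      hg[i] <- paste(unique(g$gene_id[in_gene]), collapse = ";")
      next
    }
    pc[i] <- "intergenic"
    up <- g[g$chrom == ch & g$end <= s, , drop = FALSE]
    dn <- g[g$chrom == ch & g$start >= e, , drop = FALSE]
    flank <- c(if (nrow(up)) up$gene_id[which.max(up$end)],
               if (nrow(dn)) dn$gene_id[which.min(dn$start)])
    hg[i] <- paste(flank, collapse = ";")
  }
  ucnes$position_class <- pc
  ucnes$host_genes <- hg
  ucnes
}

#' Detect UCNEs from a set of alignment blocks
#'
#' Full detection pipeline: per-block identity profiles (where blocks
#' overlap on the reference, the per-base maximum identity is used),
#' maximal runs at `>= threshold` identity, subtraction of coding overlap,
#' length filtering and positional classification.
#'
#' @param blocks list of `alignment_block`s.
#' @param genes a [gene_models] object for the reference.
#' @param window sliding-window size in columns (default 61).
#' @param threshold minimal percent identity (default 95).
#' @param min_len minimal UCNE length (default 200).
#' @return UCNE data.frame as from [filter_length()] plus
#'   `position_class`, `host_genes` and a `counts` attribute with per-stage
#'   bookkeeping.
#' @export
scan_ucnes <- function(blocks, genes, window = 61, threshold = 95,
                       min_len = 200) {
  profs <- lapply(blocks, compute_identity_profile, window = window)
  cover <- do.call(rbind, lapply(profs, function(p) {
    if (!length(p$identity)) return(NULL)
    data.frame(chrom = p$chrom, pos = seq(p$start, length.out = length(p$identity)),
               identity = p$identity)
  }))
  if (is.null(cover) || !nrow(cover)) {
    ucnes <- filter_length(data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0)), min_len)
    return(classify_position(ucnes, genes))
  }
  ## overlapping blocks: per-base maximum identity (best-alignment semantics)
  agg <- stats::aggregate(identity ~ chrom + pos, data = cover, FUN = max)
  runs <- extract_ultraconserved(agg, threshold = threshold)
  noncoding <- subtract_coding(runs, genes)
  ucnes <- filter_length(noncoding, min_len = min_len)
  ucnes <- classify_position(ucnes, genes)
  attr(ucnes, "counts") <- c(blocks = length(blocks),
                             conserved_runs = nrow(runs),
                             noncoding_fragments = nrow(noncoding),
                             ucnes = nrow(ucnes))
  ucnes
}
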