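## Genomic intervals.
##
## All coordinates in this package are 0-based, half-open [start, end), the
## BED convention. Interval tables are plain data frames; merge and
## set-difference are implemented directly (sorted sweep) because they sit
## inside per-gene loops where per-call overhead dominates.

#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `strand`, using 0-based half-open coordinates. Most functions in the
#' package consume and produce this representation.
#'
#' @param chrom character vector of chromosome/scaffold names.
#' @param start,end integer vectors, 0-based half-open; `start < end`.
#' @param strand character vector in `+`, `-`, `.` (default `"."`).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: start=%s end=%s (need 0 <= start < end)",
                 what, bad[1], df$start[bad[1]], df$end[bad[1]]))
  }
  invisible(df)
}

#' Gap between two intervals
#'
#' Distance in bases between two intervals on the same chromosome: 0 when
#' they overlap or abut, otherwise the number of bases strictly between them.
#' Vectorized; intervals on different chromosomes get `Inf`.
#'
#' @param chrom1,start1,end1 first interval (0-based half-open).
#' @param chrom2,start2,end2 second interval.
#' @return numeric vector of gaps.
#' @export
interval_gap <- function(chrom1, start1, end1, chrom2, start2, end2) {
  gap <- pmax(0, pmax(start1, start2) - pmin(end1, end2))
  gap[as.character(chrom1) != as.character(chrom2)] <- Inf
  gap
}

## merge overlapping/abutting intervals per chromosome (sorted sweep)
merge_intervals <- function(df) {
  if (nrow(df) < 2) return(df[, c("chrom", "start", "end"), drop = FALSE])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  hi <- stats::ave(df$end, df$chrom, FUN = cummax)
  new_run <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                 df$start[-1] > hi[-nrow(df)])
  grp <- cumsum(new_run)
  data.frame(chrom = df$chrom[new_run],
             start = df$start[new_run],
             end = as.numeric(tapply(df$end, grp, max)),
             stringsAsFactors = FALSE)
}

## Set-difference of intervals x with union of intervals y, both interval
## dfs. Rows of x may be split; the output keeps a `source` column with the
## row index of x each fragment came from.
subtract_intervals <- function(x, y) {
  if (nrow(x) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), source = integer(0)))
  }
  if (nrow(y) == 0) {
    out <- x[, c("chrom", "start", "end")]
    out$source <- seq_len(nrow(x))
    rownames(out) <- NULL
    return(out)
  }
  ym <- merge_intervals(y)
  frag_chrom <- character(0); frag_s <- numeric(0); frag_e <- numeric(0)
  frag_src <- integer(0)
  for (i in seq_len(nrow(x))) {
    s <- x$start[i]; e <- x$end[i]; ch <- x$chrom[i]
    yy <- ym[ym$chrom == ch & ym$start < e & ym$end > s, , drop = FALSE]
    cur <- s
    if (nrow(yy)) {
      for (k in seq_len(nrow(yy))) {
        if (yy$start[k] > cur) {
          frag_chrom <- c(frag_chrom, ch)
          frag_s <- c(frag_s, cur); frag_e <- c(frag_e, yy$start[k])
          frag_src <- c(frag_src, i)
        }
        cur <- max(cur, yy$end[k])
      }
    }
    if (cur < e) {
      frag_chrom <- c(frag_chrom, ch)
      frag_s <- c(frag_s, cur); frag_e <- c(frag_e, e)
      frag_src <- c(frag_src, i)
    }
  }
  data.frame(chrom = frag_chrom, start = frag_s, end = frag_e,
             source = frag_src, stringsAsFactors = FALSE)
}
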