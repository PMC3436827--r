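## Gene models: span + exon/CDS structure, with UTRs derived as exon - CDS.

#' Construct a set of gene models
#'
#' A gene model records the gene span, its exons and its coding (CDS)
#' intervals; untranslated regions (UTRs) are derived as exon minus CDS and
#' introns as span minus exons. Coordinates are 0-based half-open.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, and optionally `biotype` (default `"protein_coding"`) and
#'   `pseudogene` (logical, default `FALSE`).
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @param cds data.frame with the same columns; every CDS base must fall
#'   inside an exon of the same gene.
#' @return an object of class `gene_models`: a list with elements `genes`,
#'   `exons`, `cds`, `utrs` (computed).
#' @export
gene_models <- function(genes, exons, cds) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (is.null(genes$strand)) genes$strand <- "+"
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  if (is.null(genes$pseudogene)) genes$pseudogene <- FALSE
  validate_intervals(genes, "gene")
  if (nrow(exons)) validate_intervals(exons, "exon")
  if (nrow(cds)) validate_intervals(cds, "CDS")

  ## CDS must be contained in the union of exons, per gene
  for (g in unique(cds$gene_id)) {
    cg <- cds[cds$gene_id == g, , drop = FALSE]
    eg <- exons[exons$gene_id == g, , drop = FALSE]
    left <- subtract_intervals(cg, eg)
    if (nrow(left)) {
      stop(sprintf("gene %s: CDS interval [%d,%d) falls outside annotated exons",
                   g, left$start[1], left$end[1]))
    }
  }

  ## UTRs: exon - CDS, per gene
  utr_list <- lapply(unique(exons$gene_id), function(g) {
    eg <- exons[exons$gene_id == g, , drop = FALSE]
    cg <- cds[cds$gene_id == g, , drop = FALSE]
    frag <- subtract_intervals(eg, cg)
    if (!nrow(frag)) return(NULL)
    data.frame(gene_id = g, chrom = frag$chrom, start = frag$start,
               end = frag$end, stringsAsFactors = FALSE)
  })
  utr_list <- utr_list[!vapply(utr_list, is.null, logical(1))]
  utrs <- if (length(utr_list)) do.call(rbind, utr_list) else
    data.frame(gene_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0))
  rownames(utrs) <- NULL

  structure(list(genes = genes, exons = exons, cds = cds, utrs = utrs),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons, %d CDS, %d UTR fragments\n",
              nrow(x$genes), nrow(x$exons), nrow(x$cds), nrow(x$utrs)))
  invisible(x)
}

## union of all CDS intervals across genes (for coding subtraction)
all_cds <- function(gm) gm$cds[, c("chrom", "start", "end")]
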