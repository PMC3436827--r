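## File formats. Coordinates are 0-based half-open internally and in BED;
## GFF3 is converted from/to its 1-based closed convention at the boundary.

#' Construct a pairwise alignment block
#'
#' @param ref,target lists with `genome`, `chrom`, `start`, `end`, `strand`,
#'   `src_size` (0-based half-open, forward-strand coordinates).
#' @param ref_row,target_row aligned rows of equal length; `-` is the gap
#'   character; each row's non-gap count must equal its interval length.
#' @return list of class `alignment_block`.
#' @export
alignment_block <- function(ref, target, ref_row, target_row) {
  stopifnot(nchar(ref_row) == nchar(target_row))
  for (f in c("start", "end", "src_size")) {
    ref[[f]] <- as.numeric(ref[[f]])
    target[[f]] <- as.numeric(target[[f]])
  }
  ngr <- nchar(gsub("-", "", ref_row))
  ngt <- nchar(gsub("-", "", target_row))
  if (ngr != ref$end - ref$start) {
    stop(sprintf("ref row has %d bases but interval spans %d", ngr,
                 ref$end - ref$start))
  }
  if (ngt != target$end - target$start) {
    stop(sprintf("target row has %d bases but interval spans %d", ngt,
                 target$end - target$start))
  }
  structure(list(ref = ref, target = target, ref_row = ref_row,
                 target_row = target_row),
            class = "alignment_block")
}

revcomp_gapped <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgtNn", "TGCAtgcaNn", x), "")[[1]]),
        collapse = "")
}

#' Write alignment blocks as MAF
#'
#' @param blocks list of `alignment_block`s.
#' @param path output file.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a score=0", con)
    srow <- function(x, row) {
      size <- x$end - x$start
      start <- if (identical(x$strand, "-")) x$src_size - x$end else x$start
      sprintf("s %s.%s %d %d %s %d %s", x$genome, x$chrom, start, size,
              x$strand, x$src_size, row)
    }
    writeLines(srow(b$ref, b$ref_row), con)
    writeLines(srow(b$target, b$target_row), con)
    writeLines("", con)
  }
}

#' Read a pairwise MAF file
#'
#' Parses `a`/`s` records into `alignment_block`s. Only pairwise blocks
#' (exactly two `s` rows) are supported; the first row is the reference.
#' Blocks whose reference row is on the minus strand are normalized to the
#' reference forward strand (both rows reverse-complemented); target minus
#' strand is preserved, with `start`/`end` converted to forward-strand
#' coordinates.
#'
#' @param path MAF file path.
#' @return list of `alignment_block`s.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  i <- 1
  parse_s <- function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    src <- f[2]
    dot <- regexpr(".", src, fixed = TRUE)
    genome <- substr(src, 1, dot - 1)
    chrom <- substr(src, dot + 1, nchar(src))
    start <- as.numeric(f[3]); size <- as.numeric(f[4])
    strand <- f[5]; src_size <- as.numeric(f[6])
    fwd_start <- if (strand == "-") src_size - start - size else start
    list(genome = genome, chrom = chrom, start = fwd_start,
         end = fwd_start + size, strand = strand, src_size = src_size,
         row = f[7])
  }
  while (i <= length(lines)) {
    if (startsWith(lines[i], "a")) {
      j <- i + 1
      srows <- list()
      while (j <= length(lines) && startsWith(lines[j], "s")) {
        srows[[length(srows) + 1L]] <- parse_s(lines[j])
        j <- j + 1
      }
      if (length(srows) != 2) {
        stop(sprintf("MAF block at line %d has %d 's' rows; only pairwise MAF is supported",
                     i, length(srows)))
      }
      r <- srows[[1]]; t <- srows[[2]]
      if (r$strand == "-") {
        r$row <- revcomp_gapped(r$row); t$row <- revcomp_gapped(t$row)
        r$strand <- "+"
        t$strand <- if (t$strand == "-") "+" else "-"
      }
      blocks[[length(blocks) + 1L]] <- alignment_block(
        ref = r[c("genome", "chrom", "start", "end", "strand", "src_size")],
        target = t[c("genome", "chrom", "start", "end", "strand", "src_size")],
        ref_row = r$row, target_row = t$row)
      i <- j
    } else i <- i + 1
  }
  blocks
}

#' Read a BED3/BED6 file
#'
#' @param path BED file; 0-based half-open, preserved as-is. Malformed
#'   lines (wrong column count, non-numeric or inverted coordinates) raise
#'   an error naming the line.
#' @return data.frame `chrom`, `start`, `end` and, for BED6+, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  rows <- strsplit(lines[keep], "\t")
  lineno <- which(keep)
  ncol <- lengths(rows)
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  if (any(ncol < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields",
                 lineno[which(ncol < 3)[1]]))
  }
  n <- min(ncol)
  get <- function(k) vapply(rows, `[`, character(1), k)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: invalid coordinates '%s'-'%s'",
                 lineno[bad[1]], get(2)[bad[1]], get(3)[bad[1]]))
  }
  out <- data.frame(chrom = get(1), start = start, end = end,
                    stringsAsFactors = FALSE)
  if (n >= 4) out$name <- get(4)
  if (n >= 5) out$score <- suppressWarnings(as.numeric(get(5)))
  if (n >= 6) out$strand <- get(6)
  out
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally
#'   `name` (or `ucne_id`), `score`, `strand`.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df, "BED record")
  name <- if (!is.null(df$name)) df$name else if (!is.null(df$ucne_id))
    df$ucne_id else NULL
  cols <- data.frame(chrom = df$chrom, start = format(df$start, scientific = FALSE, trim = TRUE),
                     end = format(df$end, scientific = FALSE, trim = TRUE))
  if (!is.null(name)) {
    cols$name <- name
    cols$score <- if (!is.null(df$score)) df$score else 0
    cols$strand <- if (!is.null(df$strand)) df$strand else "."
  }
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `exon` and `CDS` features (1-based closed coordinates,
#' per the format).
#'
#' @param gm a [gene_models] object.
#' @param path output file.
#' @export
write_gff3 <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- gm$genes
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\tgrbcontext\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start + 1, end, strand, attrs)
  }
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    writeLines(fmt(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i],
                   sprintf("ID=%s;biotype=%s%s", gid, g$biotype[i],
                           if (g$pseudogene[i]) ";pseudo=true" else "")), con)
    e <- gm$exons[gm$exons$gene_id == gid, , drop = FALSE]
    for (k in seq_len(nrow(e))) {
      writeLines(fmt(e$chrom[k], "exon", e$start[k], e$end[k], g$strand[i],
                     sprintf("ID=%s.exon%d;Parent=%s", gid, k, gid)), con)
    }
    cc <- gm$cds[gm$cds$gene_id == gid, , drop = FALSE]
    for (k in seq_len(nrow(cc))) {
      writeLines(fmt(cc$chrom[k], "CDS", cc$start[k], cc$end[k], g$strand[i],
                     sprintf("ID=%s.cds%d;Parent=%s", gid, k, gid)), con)
    }
  }
}

gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Read gene models from GFF3
#'
#' Consumes `gene`, `exon` and `CDS` features; exons and CDS are attached
#' to genes via `Parent` (transcript layers, if present, are resolved
#' transitively). GFF3 1-based closed coordinates are converted to the
#' internal 0-based half-open convention; with multiple transcripts, the
#' union of CDS is used downstream.
#'
#' @param path GFF3 file path.
#' @return a [gene_models] object (CDS outside exons raises a validation
#'   error).
#' @export
read_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t")
  bad <- which(lengths(f) != 9)
  if (length(bad)) stop(sprintf("malformed GFF3 line %d", bad[1]))
  df <- data.frame(chrom = vapply(f, `[`, "", 1),
                   type = vapply(f, `[`, "", 3),
                   start = as.numeric(vapply(f, `[`, "", 4)) - 1,
                   end = as.numeric(vapply(f, `[`, "", 5)),
                   strand = vapply(f, `[`, "", 7),
                   attrs = vapply(f, `[`, "", 9),
                   stringsAsFactors = FALSE)
  df$id <- gff_attr(df$attrs, "ID")
  df$parent <- gff_attr(df$attrs, "Parent")
  ## resolve Parent chains (e.g. exon -> mRNA -> gene)
  gene_ids <- df$id[df$type == "gene"]
  to_gene <- function(p) {
    seen <- character(0)
    while (!is.na(p) && !(p %in% gene_ids) && !(p %in% seen)) {
      seen <- c(seen, p)
      p <- df$parent[match(p, df$id)]
    }
    p
  }
  g <- df[df$type == "gene", , drop = FALSE]
  genes <- data.frame(gene_id = g$id, chrom = g$chrom, start = g$start,
                      end = g$end, strand = g$strand,
                      biotype = ifelse(is.na(gff_attr(g$attrs, "biotype")),
                                       "protein_coding",
                                       gff_attr(g$attrs, "biotype")),
                      pseudogene = !is.na(gff_attr(g$attrs, "pseudo")),
                      stringsAsFactors = FALSE)
  feat <- function(type) {
    d <- df[df$type == type, , drop = FALSE]
    if (!nrow(d)) return(data.frame(gene_id = character(0),
                                    chrom = character(0), start = numeric(0),
                                    end = numeric(0)))
    data.frame(gene_id = vapply(d$parent, to_gene, character(1)),
               chrom = d$chrom, start = d$start, end = d$end,
               stringsAsFactors = FALSE)
  }
  gene_models(genes, feat("exon"), feat("CDS"))
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
}

#' Read FASTA into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read/write tab-separated tables with a header line
#'
#' The TSV-with-header format is the inter-stage contract for hits,
#' ortholog and pattern tables.
#'
#' @param df data.frame (for writing).
#' @param path file path.
#' @return for `read_tsv`, a data.frame.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "")
}

#' Write an ortholog table
#'
#' @param orthologs data.frame with `ref_gene_id`, `genome`, `ortholog_id`,
#'   `orthology_confidence`.
#' @param path output file.
#' @export
write_ortholog_table <- function(orthologs, path) write_tsv(orthologs, path)

#' @rdname write_ortholog_table
#' @export
read_ortholog_table <- function(path) read_tsv(path)

#' Write synthetic ground truth as JSON
#'
#' @param ground_truth the `ground_truth` element of a `synth_reference`
#'   or `synth_wgd`.
#' @param path output file.
#' @export
write_ground_truth <- function(ground_truth, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("write_ground_truth requires the jsonlite package")
  }
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA)
}
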