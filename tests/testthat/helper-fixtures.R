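# Small builders used across test files.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one plus-strand gene: 5'UTR [0,100), CDS exon [100,250), intron [250,1250),
# CDS exon [1250,1400), 3'UTR [1400,1500), on chrom "chr1" shifted by `shift`
toy_gene <- function(gene_id = "G1", shift = 0, chrom = "chr1",
                     pseudogene = FALSE, biotype = "protein_coding") {
  genes <- data.frame(gene_id = gene_id, chrom = chrom, start = 0 + shift,
                      end = 1500 + shift, strand = "+", biotype = biotype,
                      pseudogene = pseudogene)
  exons <- data.frame(gene_id = gene_id, chrom = chrom,
                      start = c(0, 1250) + shift, end = c(250, 1500) + shift)
  cds <- data.frame(gene_id = gene_id, chrom = chrom,
                    start = c(100, 1250) + shift, end = c(250, 1400) + shift)
  list(genes = genes, exons = exons, cds = cds)
}

toy_gene_models <- function(...) {
  parts <- list(...)
  if (!length(parts)) parts <- list(toy_gene())
  gene_models(do.call(rbind, lapply(parts, `[[`, "genes")),
              do.call(rbind, lapply(parts, `[[`, "exons")),
              do.call(rbind, lapply(parts, `[[`, "cds")))
}

# gapless alignment block from two equal-length rows
toy_block <- function(ref_row, target_row, chrom = "chr1", start = 0,
                      tchrom = "t1", tstart = 0, tstrand = "+",
                      src_size = 1e6) {
  alignment_block(
    ref = list(genome = "ref", chrom = chrom, start = start,
               end = start + nchar(gsub("-", "", ref_row)), strand = "+",
               src_size = src_size),
    target = list(genome = "dup", chrom = tchrom, start = tstart,
                  end = tstart + nchar(gsub("-", "", target_row)),
                  strand = tstrand, src_size = src_size),
    ref_row = ref_row, target_row = target_row)
}

# hits table row builder
toy_hit <- function(ucne_id, ortholog_id, bitscore = 100, accepted = TRUE,
                    paralog_flag = FALSE, genome = "dup", chrom = "c1",
                    start = 0, end = 300) {
  data.frame(ucne_id = ucne_id, genome = genome, chrom = chrom,
             start = start, end = end, strand = "+", raw = bitscore,
             bitscore = bitscore, evalue = 1e-10, accepted = accepted,
             paralog_flag = paralog_flag, ortholog_id = ortholog_id,
             stringsAsFactors = FALSE)
}

all_pairs <- function(N) which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
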