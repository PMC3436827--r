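## Synthetic reference + post-WGD duplicated genomes with known ground truth.
##
## The generator emulates the data regime of the real analysis: a reference
## genome whose genes host clustered UCNEs in introns (and optionally UTRs),
## with a share of intergenic UCNEs between genes; a duplicated genome in
## which every gene is present in n_copies and UCNE survival follows a
## configurable retention scenario; strong background divergence outside
## UCNEs and near-zero divergence inside surviving UCNEs.

#' Configuration for the synthetic genome generator
#'
#' Defaults describe a compact but realistic regime: strongly diverged
#' background (30\% substitutions, on the order of the neutral divergence
#' between distant amniotes) against nearly frozen UCNEs (1\%, comfortably
#' inside the >= 95\% identity definition), genes hosting a handful of
#' clustered UCNEs each, and two post-duplication copies per gene.
#'
#' @param n_genes number of genes on the reference chromosome.
#' @param ucnes_per_gene UCNEs per gene: a count, or a length-2 range
#'   sampled uniformly per gene.
#' @param ucne_length_bp length-2 range of UCNE lengths (min >= 200).
#' @param intergenic_fraction proportion of each gene's UCNEs placed in the
#'   intergenic region downstream of the gene (rounded half-up).
#' @param utr_ucne_fraction proportion of genic UCNEs placed in the 3'UTR
#'   instead of an intron (default 0).
#' @param cluster_gap_bp maximal spacing between adjacent UCNEs of a
#'   cluster; placement never exceeds it.
#' @param background_divergence per-base substitution probability outside
#'   UCNEs in the duplicated genome.
#' @param ucne_divergence per-base substitution probability inside
#'   surviving UCNEs (must be well below 0.05).
#' @param retention_scenario one of `"winner"`, `"concordant"`,
#'   `"reciprocal"`, `"random"`.
#' @param retention_prob per-UCNE survival probability (per copy for
#'   `"random"`).
#' @param n_copies duplicate copies per gene (>= 1, default 2).
#' @param intron_length_bp,exon_length_bp,utr_length_bp,gene_spacing_bp
#'   gene geometry (uniform layout: 5'UTR, alternating CDS exons and
#'   introns, 3'UTR).
#' @param scatter_copies logical; place each duplicated gene region on its
#'   own scaffold instead of one chromosome per copy (exercises subcluster
#'   merging downstream).
#' @param inject_indels logical; have [emit_alignments()] inject short
#'   (1-5 bp) deletions outside UCNEs.
#' @param seed RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 5, ucnes_per_gene = 5,
                         ucne_length_bp = c(200, 600),
                         intergenic_fraction = 0.3,
                         utr_ucne_fraction = 0,
                         cluster_gap_bp = 50000,
                         background_divergence = 0.3,
                         ucne_divergence = 0.01,
                         retention_scenario = c("winner", "concordant",
                                                "reciprocal", "random"),
                         retention_prob = 0.9,
                         n_copies = 2,
                         intron_length_bp = 2000,
                         exon_length_bp = 150,
                         utr_length_bp = 300,
                         gene_spacing_bp = 4000,
                         scatter_copies = FALSE,
                         inject_indels = FALSE,
                         seed = 1) {
  retention_scenario <- match.arg(retention_scenario)
  probs <- c(intergenic_fraction, utr_ucne_fraction, background_divergence,
             ucne_divergence, retention_prob)
  stopifnot(all(probs >= 0 & probs <= 1), n_copies >= 1, n_genes >= 1)
  if (length(ucne_length_bp) == 1) ucne_length_bp <- rep(ucne_length_bp, 2)
  stopifnot(ucne_length_bp[1] >= 200, ucne_length_bp[2] >= ucne_length_bp[1])
  if (length(ucnes_per_gene) == 1) ucnes_per_gene <- rep(ucnes_per_gene, 2)
  structure(list(n_genes = n_genes, ucnes_per_gene = ucnes_per_gene,
                 ucne_length_bp = ucne_length_bp,
                 intergenic_fraction = intergenic_fraction,
                 utr_ucne_fraction = utr_ucne_fraction,
                 cluster_gap_bp = cluster_gap_bp,
                 background_divergence = background_divergence,
                 ucne_divergence = ucne_divergence,
                 retention_scenario = retention_scenario,
                 retention_prob = retention_prob,
                 n_copies = n_copies,
                 intron_length_bp = intron_length_bp,
                 exon_length_bp = exon_length_bp,
                 utr_length_bp = utr_length_bp,
                 gene_spacing_bp = gene_spacing_bp,
                 scatter_copies = scatter_copies,
                 inject_indels = inject_indels,
                 seed = seed),
            class = "synth_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a DNA sequence at a fixed substitution rate
#'
#' Each base is independently substituted, with probability `rate`, by one
#' of the three other bases chosen uniformly. Length is preserved; no
#' indels.
#'
#' @param sequence character scalar (A/C/G/T).
#' @param rate substitution probability per base in `[0, 1]`.
#' @param seed optional RNG seed.
#' @return mutated sequence (character scalar).
#' @export
mutate_sequence <- function(sequence, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  x <- strsplit(sequence, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) {
    cur <- match(x[hit], bases)
    ## offset 1..3 from the current base, cyclic: always a different base
    x[hit] <- bases[((cur - 1 + sample.int(3, length(hit), replace = TRUE)) %% 4) + 1]
  }
  paste(x, collapse = "")
}

#' Generate a synthetic reference genome with clustered UCNEs
#'
#' Builds one reference chromosome carrying `n_genes` genes with a fixed
#' 5'UTR-CDS(exons)-3'UTR layout and uniform intron lengths. Intronic UCNEs
#' are placed one per intron (introns are created as needed), an optional
#' share in the 3'UTR, and the configured intergenic share between
#' consecutive genes. UCNEs never overlap CDS, adjacent UCNEs are within
#' `cluster_gap_bp`, and every UCNE has exactly one ground-truth record.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_reference` with elements `seq` (named
#'   character vector of chromosome sequences), `genes` ([gene_models]),
#'   `ucnes` (data.frame: `ucne_id`, `chrom`, `start`, `end`, `strand`,
#'   `length`, `position_class`, `host_genes`), `ground_truth` and
#'   `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  pad <- 20L
  if (config$ucne_length_bp[2] + 2 * pad > config$intron_length_bp) {
    stop(sprintf("gene %s: intron length %d bp cannot host a UCNE of up to %d bp",
                 "G1", config$intron_length_bp, config$ucne_length_bp[2]))
  }
  genes <- exons <- cds <- ucnes <- list()
  cursor <- 1000L  # leading margin
  uid <- 0L
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%02d", g)
    n_ucne <- if (config$ucnes_per_gene[1] == config$ucnes_per_gene[2])
      config$ucnes_per_gene[1] else
      sample(config$ucnes_per_gene[1]:config$ucnes_per_gene[2], 1)
    k_inter <- round_half_up(n_ucne * config$intergenic_fraction)
    k_genic <- n_ucne - k_inter
    k_utr <- round_half_up(k_genic * config$utr_ucne_fraction)
    k_intron <- k_genic - k_utr
    if (k_utr > 0 &&
        config$utr_length_bp < config$ucne_length_bp[2] + 2 * pad) {
      stop(sprintf("gene %s: 3'UTR of %d bp cannot host a UCNE of up to %d bp",
                   gid, config$utr_length_bp, config$ucne_length_bp[2]))
    }

    e <- config$exon_length_bp; u <- config$utr_length_bp
    il <- config$intron_length_bp
    gstart <- cursor
    ## exon 1: 5'UTR + CDS; k_intron introns each followed by a CDS exon;
    ## last exon extended by the 3'UTR
    ex <- list(); cd <- list()
    p <- gstart
    ex[[1]] <- c(p, p + u + e); cd[[1]] <- c(p + u, p + u + e)
    p <- p + u + e
    intron_spans <- list()
    for (k in seq_len(k_intron)) {
      intron_spans[[k]] <- c(p, p + il)
      p <- p + il
      ex[[k + 1]] <- c(p, p + e)
      cd[[k + 1]] <- c(p, p + e)
      p <- p + e
    }
    ## 3'UTR appended to the last exon
    ex[[length(ex)]][2] <- ex[[length(ex)]][2] + u
    utr3 <- c(p, p + u)
    p <- p + u
    gend <- p

    genes[[g]] <- data.frame(gene_id = gid, chrom = "chr1", start = gstart,
                             end = gend, strand = "+",
                             biotype = "protein_coding", pseudogene = FALSE)
    exons[[g]] <- data.frame(gene_id = gid, chrom = "chr1",
                             start = vapply(ex, `[`, numeric(1), 1),
                             end = vapply(ex, `[`, numeric(1), 2))
    cds[[g]] <- data.frame(gene_id = gid, chrom = "chr1",
                           start = vapply(cd, `[`, numeric(1), 1),
                           end = vapply(cd, `[`, numeric(1), 2))

    place <- function(lo, hi, len) {
      lo + sample.int(hi - lo - len + 1, 1) - 1
    }
    for (k in seq_len(k_intron)) {
      len <- sample(config$ucne_length_bp[1]:config$ucne_length_bp[2], 1)
      s <- place(intron_spans[[k]][1] + pad, intron_spans[[k]][2] - pad, len)
      uid <- uid + 1L
      ucnes[[uid]] <- data.frame(ucne_id = sprintf("UCNE_%04d", uid),
                                 chrom = "chr1", start = s, end = s + len,
                                 strand = ".", length = len,
                                 position_class = "intronic",
                                 host_genes = gid)
    }
    if (k_utr > 0) {
      for (k in seq_len(k_utr)) {
        len <- sample(config$ucne_length_bp[1]:config$ucne_length_bp[2], 1)
        s <- place(utr3[1] + 2, utr3[2] - 2, len)
        uid <- uid + 1L
        ucnes[[uid]] <- data.frame(ucne_id = sprintf("UCNE_%04d", uid),
                                   chrom = "chr1", start = s, end = s + len,
                                   strand = ".", length = len,
                                   position_class = "UTR",
                                   host_genes = gid)
      }
    }
    ## intergenic UCNEs downstream of the gene, chained within cluster_gap
    cursor <- gend
    next_gid <- if (g < config$n_genes) sprintf("G%02d", g + 1) else NA
    if (k_inter > 0) {
      for (k in seq_len(k_inter)) {
        len <- sample(config$ucne_length_bp[1]:config$ucne_length_bp[2], 1)
        gap <- sample(200:min(800, config$cluster_gap_bp), 1)
        s <- cursor + gap
        uid <- uid + 1L
        ucnes[[uid]] <- data.frame(ucne_id = sprintf("UCNE_%04d", uid),
                                   chrom = "chr1", start = s, end = s + len,
                                   strand = ".", length = len,
                                   position_class = "intergenic",
                                   host_genes = paste(stats::na.omit(c(gid, next_gid)),
                                                      collapse = ";"))
        cursor <- s + len
      }
    }
    cursor <- cursor + config$gene_spacing_bp
  }
  chrom_len <- cursor + 1000L

  ucnes <- do.call(rbind, ucnes)
  rownames(ucnes) <- NULL
  gm <- gene_models(do.call(rbind, genes), do.call(rbind, exons),
                    do.call(rbind, cds))
  seq <- setNames(random_dna(chrom_len), "chr1")

  gt <- list(ucnes = data.frame(ucne_id = ucnes$ucne_id,
                                position_class = ucnes$position_class,
                                host_genes = ucnes$host_genes,
                                stringsAsFactors = FALSE))
  structure(list(seq = seq, genes = gm, ucnes = ucnes, ground_truth = gt,
                 config = config),
            class = "synth_reference")
}

subseq_chr <- function(seq, start, end) substr(seq, start + 1, end)

`subseq_chr<-` <- function(seq, start, end, value) {
  substr(seq, start + 1, end) <- value
  seq
}

#' Simulate a whole-genome duplication of a synthetic reference
#'
#' Creates `n_copies` duplicated copies of every reference gene (by default
#' one duplicate chromosome per copy, mirroring reference coordinates; with
#' `scatter_copies`, one scaffold per gene region), an ortholog table, and
#' duplicate-genome sequences in which surviving UCNEs stay nearly intact
#' (`ucne_divergence`) on a strongly diverged background
#' (`background_divergence`); lost UCNEs are replaced by unrelated random
#' sequence. UCNE survival follows the configured retention scenario:
#' \describe{
#'   \item{winner}{survivors (probability `retention_prob` each) all land
#'     in the gene's designated copy;}
#'   \item{concordant}{survivors are present in all copies;}
#'   \item{reciprocal}{each survivor lands in one uniformly random copy;}
#'   \item{random}{independent Bernoulli(`retention_prob`) per (UCNE, copy).}
#' }
#'
#' @param reference a `synth_reference` from [generate_reference()].
#' @param config the same [synth_config()] (scenario and divergence fields
#'   are read from it).
#' @return list of class `synth_wgd` with elements `seq` (named character
#'   vector of duplicate chromosomes/scaffolds), `genes` ([gene_models] of
#'   the duplicated genome), `ucnes` (data.frame of surviving UCNE copies:
#'   `ucne_id`, `copy`, `ortholog_id`, `chrom`, `start`, `end`),
#'   `orthologs` (data.frame: `ref_gene_id`, `genome`, `ortholog_id`,
#'   `orthology_confidence`), `ground_truth`, `genome` (id, `"dup"`),
#'   `config`.
#' @export
simulate_wgd <- function(reference, config = reference$config) {
  stopifnot(inherits(reference, "synth_reference"))
  set.seed(config$seed + 10000L)
  nc <- config$n_copies
  copy_tag <- letters[seq_len(nc)]
  ref_ucnes <- reference$ucnes
  genes <- reference$genes$genes

  ## survival draws: matrix UCNE x copy
  nU <- nrow(ref_ucnes)
  surv <- matrix(FALSE, nU, nc)
  designated <- setNames(sample.int(nc, nrow(genes), replace = TRUE),
                         genes$gene_id)
  ## attribute each UCNE to a gene for the winner designation (intergenic
  ## UCNEs follow their upstream flanking gene)
  anchor_gene <- vapply(strsplit(ref_ucnes$host_genes, ";"), `[`,
                        character(1), 1)
  alive <- runif(nU) < config$retention_prob
  if (config$retention_scenario == "winner") {
    surv[cbind(which(alive), designated[anchor_gene[alive]])] <- TRUE
  } else if (config$retention_scenario == "concordant") {
    surv[alive, ] <- TRUE
  } else if (config$retention_scenario == "reciprocal") {
    surv[cbind(which(alive), sample.int(nc, sum(alive), replace = TRUE))] <- TRUE
  } else { # random
    surv[] <- runif(nU * nc) < config$retention_prob
  }

  ## duplicated annotation: per copy, either a mirrored chromosome or
  ## scattered per-gene scaffolds
  dup_genes <- dup_exons <- dup_cds <- list()
  dup_ucnes <- list()
  seqs <- character(0)
  orth <- list()
  for (k in seq_len(nc)) {
    tag <- copy_tag[k]
    if (!config$scatter_copies) {
      chrom <- paste0("dup_", tag)
      seqs[chrom] <- mutate_sequence(reference$seq[["chr1"]],
                                     config$background_divergence)
    }
    for (gi in seq_len(nrow(genes))) {
      gid <- genes$gene_id[gi]
      oid <- paste0(gid, "_", tag)
      ## region: gene span plus downstream intergenic segment
      rstart <- max(0, genes$start[gi] - 900L)
      rend <- if (gi < nrow(genes)) genes$start[gi + 1] - 50L else
        nchar(reference$seq[["chr1"]])
      if (config$scatter_copies) {
        chrom <- sprintf("dup_%s_sc%02d", tag, gi)
        base <- mutate_sequence(subseq_chr(reference$seq[["chr1"]], rstart, rend),
                                config$background_divergence)
        seqs[chrom] <- base
        off <- -rstart
      } else {
        off <- 0L
      }
      shift <- function(x) x + off
      sel_e <- reference$genes$exons$gene_id == gid
      sel_c <- reference$genes$cds$gene_id == gid
      dup_genes[[length(dup_genes) + 1L]] <-
        data.frame(gene_id = oid, chrom = chrom,
                   start = shift(genes$start[gi]), end = shift(genes$end[gi]),
                   strand = "+", biotype = "protein_coding", pseudogene = FALSE)
      de <- reference$genes$exons[sel_e, ]
      de$gene_id <- oid; de$chrom <- chrom
      de$start <- shift(de$start); de$end <- shift(de$end)
      dup_exons[[length(dup_exons) + 1L]] <- de
      dc <- reference$genes$cds[sel_c, ]
      dc$gene_id <- oid; dc$chrom <- chrom
      dc$start <- shift(dc$start); dc$end <- shift(dc$end)
      dup_cds[[length(dup_cds) + 1L]] <- dc
      orth[[length(orth) + 1L]] <-
        data.frame(ref_gene_id = gid, genome = "dup", ortholog_id = oid,
                   orthology_confidence = "ortholog")

      ## UCNEs anchored to this gene that fall inside the region
      in_region <- ref_ucnes$start >= rstart & ref_ucnes$end <= rend &
        anchor_gene == gid
      for (ui in which(in_region)) {
        s0 <- ref_ucnes$start[ui]; e0 <- ref_ucnes$end[ui]
        refseq <- subseq_chr(reference$seq[["chr1"]], s0, e0)
        if (surv[ui, k]) {
          seqs[chrom] <- `subseq_chr<-`(seqs[chrom], shift(s0), shift(e0),
                                        mutate_sequence(refseq, config$ucne_divergence))
          dup_ucnes[[length(dup_ucnes) + 1L]] <-
            data.frame(ucne_id = ref_ucnes$ucne_id[ui], copy = tag,
                       ortholog_id = if (ref_ucnes$position_class[ui] == "intergenic")
                         NA_character_ else oid,
                       chrom = chrom, start = shift(s0), end = shift(e0))
        } else {
          ## lost: wipe homology by substituting unrelated sequence
          seqs[chrom] <- `subseq_chr<-`(seqs[chrom], shift(s0), shift(e0),
                                        random_dna(e0 - s0))
        }
      }
    }
  }
  dup_ucnes <- if (length(dup_ucnes)) do.call(rbind, dup_ucnes) else
    data.frame(ucne_id = character(0), copy = character(0),
               ortholog_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0))
  gm <- gene_models(do.call(rbind, dup_genes), do.call(rbind, dup_exons),
                    do.call(rbind, dup_cds))
  orthologs <- do.call(rbind, orth)
  colnames(surv) <- copy_tag
  gt <- list(designated_copy = designated,
             survival = cbind(data.frame(ucne_id = ref_ucnes$ucne_id),
                              as.data.frame(surv)))
  structure(list(seq = seqs, genes = gm, ucnes = dup_ucnes,
                 orthologs = orthologs, ground_truth = gt, genome = "dup",
                 config = config),
            class = "synth_wgd")
}

#' Ground-truth homology hits for a synthetic duplicated genome
#'
#' Bypasses the alignment stage: every surviving UCNE copy becomes one
#' accepted, non-paralog hit with a length-proportional bitscore. Used to
#' exercise the retention and cluster statistics in isolation from the
#' homology-search stage.
#'
#' @param wgd a `synth_wgd` from [simulate_wgd()].
#' @param reference the matching `synth_reference` (for UCNE lengths).
#' @param scheme a [scoring_scheme()] used for the bitscore scale.
#' @return hits data.frame with the columns consumed by
#'   [tally_patterns()] and [find_subclusters()].
#' @export
hits_from_truth <- function(wgd, reference,
                            scheme = scoring_scheme()) {
  u <- wgd$ucnes
  if (!nrow(u)) {
    return(data.frame(ucne_id = character(0), genome = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      raw = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), accepted = logical(0),
                      paralog_flag = logical(0), ortholog_id = character(0)))
  }
  len <- u$end - u$start
  raw <- scheme$match * len
  data.frame(ucne_id = u$ucne_id, genome = wgd$genome, chrom = u$chrom,
             start = u$start, end = u$end, strand = "+", raw = raw,
             bitscore = bit_score(raw, scheme), evalue = 1e-30,
             accepted = TRUE, paralog_flag = FALSE,
             ortholog_id = u$ortholog_id,
             stringsAsFactors = FALSE)
}

#' Emit pairwise alignment blocks between reference and duplicate genome
#'
#' One block per duplicated gene region (gene span plus its downstream
#' intergenic segment), pairing the reference segment with the homologous
#' duplicate segment. By default blocks are gapless; with
#' `inject_indels` in the config, 1-5 bp deletions are injected into the
#' duplicate row outside UCNEs (gap columns in the target row).
#'
#' @param reference a `synth_reference`.
#' @param wgd the `synth_wgd` derived from it.
#' @return list of `alignment_block` objects (see [read_maf()] for the
#'   structure); round-trips losslessly through [write_maf()]/[read_maf()].
#' @export
emit_alignments <- function(reference, wgd) {
  config <- wgd$config
  set.seed(config$seed + 20000L)
  genes <- reference$genes$genes
  nc <- config$n_copies
  copy_tag <- letters[seq_len(nc)]
  blocks <- list()
  ref_len <- nchar(reference$seq[["chr1"]])
  for (k in seq_len(nc)) {
    tag <- copy_tag[k]
    for (gi in seq_len(nrow(genes))) {
      rstart <- max(0, genes$start[gi] - 900L)
      rend <- if (gi < nrow(genes)) genes$start[gi + 1] - 50L else ref_len
      if (!config$scatter_copies) {
        chrom <- paste0("dup_", tag); tstart <- rstart
      } else {
        chrom <- sprintf("dup_%s_sc%02d", tag, gi); tstart <- 0L
      }
      ref_row <- subseq_chr(reference$seq[["chr1"]], rstart, rend)
      tgt_row <- subseq_chr(wgd$seq[[chrom]], tstart, tstart + (rend - rstart))
      tlen <- nchar(tgt_row)
      if (config$inject_indels) {
        ## delete 1-5 bp from the target outside UCNEs: target row gets gaps
        u_in <- reference$ucnes[reference$ucnes$start >= rstart &
                                  reference$ucnes$end <= rend, , drop = FALSE]
        n_indel <- max(1L, round_half_up((rend - rstart) / 5000))
        cols <- strsplit(tgt_row, "")[[1]]
        for (d in seq_len(n_indel)) {
          len <- sample.int(5, 1)
          for (try in 1:50) {
            at <- sample.int(length(cols) - len, 1)
            pos0 <- rstart + at - 1
            if (!any(pos0 < u_in$end & (pos0 + len) > u_in$start)) break
          }
          cols[at:(at + len - 1)] <- "-"
        }
        tgt_row <- paste(cols, collapse = "")
        tlen <- sum(cols != "-")
      }
      blocks[[length(blocks) + 1L]] <- alignment_block(
        ref = list(genome = "ref", chrom = "chr1", start = rstart,
                   end = rend, strand = "+", src_size = ref_len),
        target = list(genome = wgd$genome, chrom = chrom, start = tstart,
                      end = tstart + tlen, strand = "+",
                      src_size = nchar(wgd$seq[[chrom]])),
        ref_row = ref_row, target_row = tgt_row)
    }
  }
  blocks
}
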