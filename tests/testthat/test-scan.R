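test_that("identity profile: window counts, flank fill and short blocks", {
  s <- rand_seq(61, seed = 1)
  # all columns match
  p <- compute_identity_profile(toy_block(s, s), window = 61)
  expect_equal(p$identity, rep(100, 61))
  expect_equal(c(p$start, p$end), c(0, 61))
  # zero matches
  p0 <- compute_identity_profile(toy_block(s, mutate_sequence(s, 1)), 61)
  expect_equal(p0$identity, rep(0, 61))
  # exactly 3 mismatch columns: the center base sees 58/61
  x <- strsplit(s, "")[[1]]
  y <- x
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  for (i in c(10, 31, 50)) y[i] <- flip(y[i])
  p3 <- compute_identity_profile(toy_block(s, paste(y, collapse = "")), 61)
  expect_equal(p3$identity[31], 100 * 58 / 61)
  # single full window: flanks inherit its value
  expect_equal(p3$identity, rep(100 * 58 / 61, 61))
  # block shorter than the window: whole-block identity everywhere
  sh <- rand_seq(10, seed = 2)
  sh2 <- sh
  substr(sh2, 1, 1) <- if (substr(sh, 1, 1) == "A") "C" else "A"
  psh <- compute_identity_profile(toy_block(sh, sh2), 61)
  expect_equal(psh$identity, rep(90, 10))
  # flank copying on a longer block: first 30 bases share the first full
  # window's value
  s2 <- rand_seq(200, seed = 3)
  y2 <- strsplit(s2, "")[[1]]; y2[40] <- flip(y2[40])
  pl <- compute_identity_profile(toy_block(s2, paste(y2, collapse = "")), 61)
  expect_equal(pl$identity[1:30], rep(pl$identity[31], 30))
  expect_equal(pl$identity[171:200], rep(pl$identity[170], 30))
  expect_true(all(pl$identity >= 0 & pl$identity <= 100))
  expect_equal(length(pl$identity), 200)
})

test_that("gaps and ambiguity codes count as mismatches", {
  s <- paste(rep("ACGTA", 4), collapse = "")  # 20 bases
  gapped <- paste0(substr(s, 1, 10), "--", substr(s, 13, 20))
  b <- alignment_block(
    ref = list(genome = "r", chrom = "c", start = 0, end = 20, strand = "+",
               src_size = 100),
    target = list(genome = "t", chrom = "c", start = 0, end = 18,
                  strand = "+", src_size = 100),
    ref_row = s, target_row = gapped)
  p <- compute_identity_profile(b, window = 61)
  expect_equal(p$identity, rep(100 * 18 / 20, 20))
  nn <- sub("A", "N", s)
  pn <- compute_identity_profile(toy_block(s, nn), window = 61)
  expect_equal(pn$identity, rep(100 * 19 / 20, 20))
})

test_that("ultraconserved runs are maximal and threshold-monotone", {
  prof <- structure(list(chrom = "c", start = 100, end = 400,
                         identity = rep(100, 300)),
                    class = "conservation_profile")
  r <- extract_ultraconserved(prof)
  expect_equal(r, data.frame(chrom = "c", start = 100, end = 400),
               ignore_attr = TRUE)
  # one low base splits the run into two abutting intervals
  prof$identity[151] <- 90
  r2 <- extract_ultraconserved(prof)
  expect_equal(r2$start, c(100, 251))
  expect_equal(r2$end, c(250, 400))
  # uniformly sub-threshold
  prof$identity <- rep(94, 300)
  expect_equal(nrow(extract_ultraconserved(prof)), 0)
  # monotonicity: raising the threshold never lengthens output intervals
  set.seed(8)
  prof$identity <- 90 + 10 * runif(300)
  lo <- extract_ultraconserved(prof, threshold = 95)
  hi <- extract_ultraconserved(prof, threshold = 97)
  expect_lte(sum(hi$end - hi$start), sum(lo$end - lo$start))
  for (i in seq_len(nrow(hi))) {
    expect_true(any(lo$start <= hi$start[i] & lo$end >= hi$end[i]))
  }
})

test_that("coding subtraction splits and removes intervals", {
  gm <- toy_gene_models()  # CDS at [100,250) and [1250,1400)
  # no overlap: unchanged
  iv <- data.frame(chrom = "chr1", start = 300, end = 800)
  expect_equal(subtract_coding(iv, gm)[, 1:3], iv, ignore_attr = TRUE)
  # fully inside a CDS: removed
  iv2 <- data.frame(chrom = "chr1", start = 110, end = 240)
  expect_equal(nrow(subtract_coding(iv2, gm)), 0)
  # 450-bp interval overlapping a central 100-bp CDS: two fragments, 350 bp
  gm2 <- gene_models(
    data.frame(gene_id = "G", chrom = "c", start = 0, end = 2000,
               strand = "+"),
    data.frame(gene_id = "G", chrom = "c", start = 1175, end = 1275),
    data.frame(gene_id = "G", chrom = "c", start = 1175, end = 1275))
  fr <- subtract_coding(data.frame(chrom = "c", start = 1000, end = 1450), gm2)
  expect_equal(nrow(fr), 2)
  expect_equal(sum(fr$end - fr$start), 350)
})

test_that("length filter is strict at 200 bp and ids follow position", {
  iv <- data.frame(chrom = c("c2", "c1", "c1", "c1"),
                   start = c(0, 500, 0, 900), end = c(199, 700, 150, 1080))
  u <- filter_length(iv)
  # 199 and the 150+180 fragments of a split element are dropped
  expect_equal(nrow(u), 1)
  expect_equal(u$start, 500)
  u2 <- filter_length(data.frame(chrom = "c", start = 0, end = 200))
  expect_equal(nrow(u2), 1)  # exactly 200 kept
  # stable ids ordered by (chrom, start)
  iv3 <- data.frame(chrom = c("c2", "c1"), start = c(0, 0),
                    end = c(300, 300))
  expect_equal(filter_length(iv3)$ucne_id, c("UCNE_0001", "UCNE_0002"))
  expect_equal(filter_length(iv3)$chrom, c("c1", "c2"))
})

test_that("position classification: UTR wins, intergenic records flanks", {
  gm <- toy_gene_models(toy_gene("G1"), toy_gene("G2", shift = 10000))
  u <- data.frame(chrom = "chr1",
                  start = c(400, 30, 1380, 2000, 20000),
                  end = c(700, 80, 1450, 2300, 20300))
  r <- classify_position(u, gm)
  expect_equal(r$position_class,
               c("intronic", "UTR", "UTR", "intergenic", "intergenic"))
  expect_equal(r$host_genes[1], "G1")
  expect_equal(r$host_genes[2], "G1")   # 5'UTR
  expect_equal(r$host_genes[3], "G1")   # straddles 3'UTR: UTR wins
  expect_equal(r$host_genes[4], "G1;G2")
  expect_equal(r$host_genes[5], "G2")   # beyond the last gene: one flank
})

test_that("scan pipeline recovers planted UCNEs with bounded boundary smear", {
  # frozen UCNEs (zero divergence) on a strongly diverged background;
  # planted elements >= 260 bp must be recovered within +/- 30 bp
  planted_total <- 0L
  recovered <- 0L
  for (s in 1:12) {
    cfg <- synth_config(n_genes = 2, ucnes_per_gene = 4, ucne_divergence = 0,
                        background_divergence = 0.3,
                        retention_scenario = "concordant",
                        retention_prob = 1, seed = 100 + s)
    ref <- generate_reference(cfg)
    wgd <- simulate_wgd(ref, cfg)
    blocks <- emit_alignments(ref, wgd)
    found <- scan_ucnes(blocks, ref$genes)
    big <- ref$ucnes[ref$ucnes$length >= 260, , drop = FALSE]
    planted_total <- planted_total + nrow(big)
    for (i in seq_len(nrow(big))) {
      hit <- found$chrom == big$chrom[i] &
        abs(found$start - big$start[i]) <= 30 &
        abs(found$end - big$end[i]) <= 30
      recovered <- recovered + any(hit)
    }
  }
  expect_gte(recovered / planted_total, 0.95)
})

test_that("overlapping blocks take the per-base maximum identity", {
  s <- rand_seq(300, seed = 41)
  good <- toy_block(s, s, start = 0)
  bad <- toy_block(s, mutate_sequence(s, 1), start = 0)
  gm <- gene_models(
    data.frame(gene_id = "G", chrom = "chr9", start = 0, end = 10,
               strand = "+"),
    data.frame(gene_id = "G", chrom = "chr9", start = 0, end = 10),
    data.frame(gene_id = "G", chrom = "chr9", start = 0, end = 10))
  u <- scan_ucnes(list(good, bad), gm)
  expect_equal(nrow(u), 1)
  expect_equal(c(u$start, u$end), c(0, 300))
})
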