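test_that("local alignment scores follow the scheme", {
  s <- rand_seq(200, seed = 1)
  la <- local_align(s, s)
  expect_equal(la$raw, 5 * 200)  # match = +5
  expect_equal(la$bitscore, (0.192 * 1000 - log(0.176)) / log(2))
  expect_equal(la$subject_span, c(1, 200))
  # all-mismatch short sequences: local score floors at 0
  expect_equal(local_align("AAAA", "CCCC")$raw, 0)
  # a query scores low against unrelated sequence
  r <- local_align(s, rand_seq(200, seed = 2))$raw
  expect_lt(r, 200)
  expect_error(local_align("", s))
})

test_that("window shuffling permutes within windows and keeps composition", {
  s <- rand_seq(65, seed = 3)
  set.seed(4)
  sh <- grbcontext:::shuffle_in_windows(s, 20)
  expect_equal(nchar(sh), 65)
  x <- strsplit(s, "")[[1]]; y <- strsplit(sh, "")[[1]]
  # composition preserved per window, including the short 5-base remainder
  for (w in list(1:20, 21:40, 41:60, 61:65)) {
    expect_equal(sort(x[w]), sort(y[w]))
  }
})

test_that("shuffle E-values separate true homologs from background", {
  q <- rand_seq(300, seed = 5)
  # identical sequences: E far below the acceptance cutoff
  ev <- shuffle_evalue(q, q, n_shuffles = 100, db_size = 10, seed = 6)
  expect_lt(ev$evalue, 1e-10)
  # unrelated subject: observed score within the shuffled distribution
  ev2 <- shuffle_evalue(q, rand_seq(300, seed = 7), n_shuffles = 100,
                        db_size = 10, seed = 6)
  expect_gt(ev2$evalue, 1e-3)
  # determinism
  ev3 <- shuffle_evalue(q, q, n_shuffles = 100, db_size = 10, seed = 6)
  expect_identical(ev$evalue, ev3$evalue)
  # degenerate subject falls back to the empirical rank
  # every shuffle of a mononucleotide subject scores exactly like the
  # observed alignment, so the rank p-value is (100 + 1) / (100 + 1) = 1
  ev4 <- shuffle_evalue(q, strrep("A", 100), n_shuffles = 100, seed = 6)
  expect_true(is.na(ev4$mu))
  expect_equal(ev4$pvalue, 1)
  expect_error(shuffle_evalue(q, q, n_shuffles = 50), "n_shuffles")
})

test_that("E-values are monotone in the raw score", {
  q <- rand_seq(300, seed = 8)
  subj <- rand_seq(300, seed = 9)
  fit <- shuffle_evalue(q, subj, n_shuffles = 100, seed = 10)
  p <- function(s) -expm1(-exp(-(s - fit$mu) / fit$beta))
  scores <- seq(0, 2000, by = 50)
  expect_true(all(diff(p(scores)) <= 0))
})

test_that("find_homologs accepts at E <= threshold, including the boundary", {
  u <- rand_seq(300, seed = 11)
  cand <- data.frame(genome = "dup", chrom = c("c1", "c2"),
                     start = 0, end = 300, strand = "+",
                     seq = c(u, rand_seq(300, seed = 12)),
                     stringsAsFactors = FALSE)
  hits <- find_homologs("U1", u, cand, n_shuffles = 100, seed = 13)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$accepted, c(TRUE, FALSE))
  expect_equal(hits$evalue <= 1e-4, hits$accepted)
  # the cutoff itself is accepted: re-threshold at the background hit's E
  hits2 <- find_homologs("U1", u, cand[2, ], n_shuffles = 100, seed = 13,
                         threshold = hits$evalue[2])
  expect_true(hits2$accepted)
  # no candidates: the UCNE is lost
  expect_equal(nrow(find_homologs("U1", u, cand[0, ])), 0)
})

test_that("mutated UCNE copies are accepted at 5% divergence", {
  set.seed(14)
  ok <- vapply(1:20, function(i) {
    u <- rand_seq(300)
    m <- mutate_sequence(u, 0.05)
    ev <- shuffle_evalue(u, m, n_shuffles = 100, db_size = 5)
    ev$evalue <= 1e-4
  }, logical(1))
  expect_true(all(ok))
})

test_that("random sequence pairs are essentially never accepted", {
  set.seed(15)
  acc <- vapply(1:50, function(i) {
    ev <- shuffle_evalue(rand_seq(300), rand_seq(300), n_shuffles = 100,
                         db_size = 5)
    ev$evalue <= 1e-4
  }, logical(1))
  expect_equal(sum(acc), 0)
})

test_that("paralog catalog lists planted paralogs and skips the own locus", {
  set.seed(16)
  useq <- rand_seq(300)
  par <- mutate_sequence(useq, 0.05)  # ~95% identical planted paralog
  ucnes <- data.frame(ucne_id = "U1", chrom = "chr1", start = 1000,
                      end = 1300, seq = useq, stringsAsFactors = FALSE)
  cand <- data.frame(chrom = c("chr1", "chr5", "chr6"),
                     start = c(1000, 0, 0), end = c(1300, 300, 300),
                     strand = "+",
                     seq = c(useq, par, rand_seq(300)),
                     stringsAsFactors = FALSE)
  cat <- build_paralog_catalog(ucnes, cand, n_shuffles = 100, seed = 17)
  expect_equal(cat$U1$chrom, "chr5")  # own locus excluded, random rejected
  # no similar locus: empty entry
  cat2 <- build_paralog_catalog(ucnes, cand[c(1, 3), ], n_shuffles = 100,
                                seed = 17)
  expect_equal(nrow(cat2$U1), 0)
})

test_that("paralog flagging follows the lower-E rule with ties kept", {
  set.seed(18)
  useq <- rand_seq(400)
  par <- mutate_sequence(useq, 0.25)        # divergent paralog
  hit_from_par <- mutate_sequence(par, 0.05) # fish sequence tracks the paralog
  hit_from_u <- mutate_sequence(useq, 0.05)
  paralogs <- data.frame(chrom = "chr9", start = 0, end = 400, strand = "+",
                         evalue = 1e-12, seq = par, stringsAsFactors = FALSE)
  mk_hit <- function(seq) {
    h <- toy_hit("U1", "O1")
    h$seq <- seq
    h
  }
  h1 <- flag_paralogs(mk_hit(hit_from_par), useq, paralogs,
                      n_shuffles = 100, seed = 19)
  expect_true(h1$paralog_flag)
  h2 <- flag_paralogs(mk_hit(hit_from_u), useq, paralogs,
                      n_shuffles = 100, seed = 19)
  expect_false(h2$paralog_flag)
  # no paralogs: flag stays false
  h3 <- flag_paralogs(mk_hit(hit_from_u), useq, paralogs[0, ],
                      n_shuffles = 100, seed = 19)
  expect_false(h3$paralog_flag)
})

test_that("candidate extraction maps alignment columns to target coordinates", {
  ref <- rand_seq(500, seed = 20)
  b <- toy_block(ref, ref, start = 1000, tchrom = "s1", tstart = 4000)
  cand <- extract_candidate_regions(
    data.frame(chrom = "chr1", start = 1200, end = 1300), list(b), flank = 50)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end), c(4000 + 150, 4000 + 350))
  expect_equal(cand$seq, substr(ref, 151, 350))
  # no overlapping block
  none <- extract_candidate_regions(
    data.frame(chrom = "chr2", start = 0, end = 100), list(b))
  expect_equal(nrow(none), 0)
  # gapped target: gap columns are dropped from the candidate sequence
  rr <- "ACGTACGTAC"
  tt <- "ACG--CGTAC"
  bg <- alignment_block(
    ref = list(genome = "r", chrom = "chr1", start = 0, end = 10,
               strand = "+", src_size = 10),
    target = list(genome = "d", chrom = "t1", start = 0, end = 8,
                  strand = "+", src_size = 8),
    ref_row = rr, target_row = tt)
  cg <- extract_candidate_regions(
    data.frame(chrom = "chr1", start = 0, end = 10), list(bg), flank = 0)
  expect_equal(cg$seq, "ACGCGTAC")
  expect_equal(c(cg$start, cg$end), c(0, 8))
})
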