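ucne_row <- function(id, start, start2, chrom = "chr1", chrom2 = "gg1",
                     len = 300) {
  data.frame(ucne_id = id, chrom = chrom, start = start, end = start + len,
             chrom2 = chrom2, start2 = start2, end2 = start2 + len,
             stringsAsFactors = FALSE)
}

test_that("cluster chaining requires both genomes to agree", {
  # 0.4 Mb apart in both genomes: one cluster
  u <- rbind(ucne_row("u1", 0, 0), ucne_row("u2", 4e5, 4e5))
  cl <- build_clusters(u)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n_ucnes, 2)
  # 0.4 Mb in the reference but 0.6 Mb in the second genome: two clusters
  u2 <- rbind(ucne_row("u1", 0, 0), ucne_row("u2", 4e5, 6.1e5))
  expect_equal(nrow(build_clusters(u2)$clusters), 2)
  # different second-genome chromosomes: two clusters
  u3 <- rbind(ucne_row("u1", 0, 0), ucne_row("u2", 4e5, 4e5, chrom2 = "gg2"))
  expect_equal(nrow(build_clusters(u3)$clusters), 2)
  # missing second-genome coordinates: unlinkable singleton
  u4 <- rbind(ucne_row("u1", 0, 0), ucne_row("u2", 1e4, NA))
  u4$chrom2[2] <- NA
  expect_equal(nrow(build_clusters(u4)$clusters), 2)
  # maximality: no two clusters could be linked under the gap rule
  set.seed(30)
  starts <- cumsum(sample(c(1e4, 6e5), 20, replace = TRUE))
  u5 <- do.call(rbind, lapply(seq_along(starts), function(i)
    ucne_row(sprintf("u%02d", i), starts[i], starts[i])))
  cl5 <- build_clusters(u5)
  m <- cl5$members[order(cl5$members$start), ]
  brk <- which(m$cluster_id[-1] != m$cluster_id[-nrow(m)])
  for (i in brk) {
    expect_gt(m$start[i + 1] - m$end[i], 5e5)
  }
})

test_that("gene association honors position class and coding status", {
  gm <- toy_gene_models(toy_gene("G1"), toy_gene("G2", shift = 10000),
                        toy_gene("PS1", shift = 20000, pseudogene = TRUE))
  members <- data.frame(position_class = c("intronic", "intergenic"),
                        host_genes = c("G1", "G1;G2"))
  expect_equal(associate_genes(members, gm), c("G1", "G2"))
  # pseudogene flanks are excluded
  members2 <- data.frame(position_class = "intergenic",
                         host_genes = "G2;PS1")
  expect_equal(associate_genes(members2, gm), "G2")
})

test_that("subcluster reconstruction chains hits and ranks the major", {
  ids <- sprintf("u%02d", 1:6)
  # all on one scaffold: a single major subcluster
  h <- do.call(rbind, lapply(1:6, function(i)
    toy_hit(ids[i], NA, chrom = "sfA", start = i * 1e4, end = i * 1e4 + 300)))
  sc <- find_subclusters(ids, h)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$role, "major")
  expect_equal(sc$n_ucnes, 6)
  # split 4 / 2 across chromosomes: the major holds 4
  h2 <- h
  h2$chrom[5:6] <- "sfB"
  sc2 <- find_subclusters(ids, h2)
  expect_equal(sc2$n_ucnes[sc2$role == "major"], 4)
  expect_equal(sc2$chrom[sc2$role == "major"], "sfA")
  # a singleton 2 Mb away on the same chromosome becomes a separate minor
  h3 <- h
  h3$start[6] <- h3$start[5] + 2e6
  h3$end[6] <- h3$start[6] + 300
  sc3 <- find_subclusters(ids, h3)
  expect_equal(nrow(sc3), 2)
  expect_equal(sc3$n_ucnes, c(5, 1))
  # paralog-flagged hits never enter subclusters
  h4 <- h
  h4$paralog_flag[1] <- TRUE
  expect_equal(find_subclusters(ids, h4)$n_ucnes, 5)
  # no hits: empty result
  expect_equal(nrow(find_subclusters(ids, h[0, ])), 0)
})

test_that("assembly-aware merging needs (unplaced or gap-flanked) and disjoint ranges", {
  ids <- sprintf("u%02d", 1:10)
  cluster_order <- setNames(1:10, ids)
  mk_sc <- function(id, chrom, start, end, members, role) {
    data.frame(subcluster_id = id, chrom = chrom, start = start, end = end,
               n_ucnes = length(members),
               ucne_ids = paste(members, collapse = ";"),
               bitscore_sum = 100 * length(members), role = role,
               merged_from = "", stringsAsFactors = FALSE)
  }
  major <- mk_sc("SC_01", "chrA", 0, 5e5, ids[1:7], "major")
  # (i) + (iii): minor on an unplaced scaffold covering members 8-10
  minor1 <- mk_sc("SC_02", "scaf_7", 0, 1e5, ids[8:10], "minor")
  m1 <- merge_assembly_fragments(rbind(major, minor1), cluster_order,
                                 assembly = list(unplaced = "scaf_7"))
  expect_equal(nrow(m1), 1)
  expect_equal(m1$n_ucnes, 10)
  expect_equal(m1$merged_from, "SC_02")
  expect_true(attr(m1, "review")$merged)
  # placed, not gap-flanked: kept separate
  m2 <- merge_assembly_fragments(rbind(major, minor1), cluster_order,
                                 assembly = list(unplaced = character(0)))
  expect_equal(nrow(m2), 2)
  # (ii) + (iii): gap-flanked region on a placed chromosome
  minor2 <- mk_sc("SC_02", "chrB", 2e5, 3e5, ids[8:10], "minor")
  gaps <- data.frame(chrom = "chrB", start = c(1.9e5, 3.1e5),
                     end = c(1.95e5, 3.2e5))
  m3 <- merge_assembly_fragments(rbind(major, minor2), cluster_order,
                                 assembly = list(gaps = gaps))
  expect_equal(nrow(m3), 1)
  # (iii) fails: member range overlaps the major's
  minor3 <- mk_sc("SC_02", "scaf_7", 0, 1e5, ids[5:8], "minor")
  m4 <- merge_assembly_fragments(rbind(major, minor3), cluster_order,
                                 assembly = list(unplaced = "scaf_7"))
  expect_equal(nrow(m4), 2)
  expect_false(attr(m4, "review")$merged)
})

test_that("gene association in the duplicated genome uses the distance rule", {
  # subcluster spanning [1e5, 2e5] with member hits at both ends
  sc <- data.frame(subcluster_id = "SC_01", chrom = "sfA", start = 1e5,
                   end = 2e5, n_ucnes = 2, ucne_ids = "u1;u2",
                   bitscore_sum = 200, role = "major", merged_from = "",
                   stringsAsFactors = FALSE)
  hits <- rbind(toy_hit("u1", NA, chrom = "sfA", start = 1e5, end = 1e5 + 300),
                toy_hit("u2", NA, chrom = "sfA", start = 2e5 - 300, end = 2e5))
  mk_gene <- function(id, start, end) {
    g <- toy_gene(id, shift = 0, chrom = "sfA")
    g$genes$start <- start; g$genes$end <- end
    g$exons$start <- c(start, end - 250); g$exons$end <- c(start + 250, end)
    g$cds$start <- c(start + 100, end - 250)
    g$cds$end <- c(start + 250, end - 100)
    g
  }
  gm <- toy_gene_models(
    mk_gene("host", 9e4, 1.6e5),       # overlaps a member hit: distance 0
    mk_gene("near", 2.4e5, 2.5e5),     # 40 kb from the nearest member
    mk_gene("far", 3.6e5, 3.7e5))      # 160 kb away
  expect_equal(associate_fish_genes(sc, hits, gm), c("host", "near"))
  # the relaxed 0.5 Mb radius also captures the distant gene
  expect_equal(associate_fish_genes(sc, hits, gm, max_dist = 5e5),
               c("far", "host", "near"))
})

test_that("target calls require association in every genome with data", {
  assoc <- data.frame(
    ref_gene_id = c(rep("G1", 5), rep("G2", 5), rep("G3", 4)),
    genome = c(rep(paste0("fish", 1:5), 2), paste0("fish", 1:4)),
    associated = c(rep(TRUE, 5), c(TRUE, TRUE, TRUE, TRUE, FALSE),
                   rep(TRUE, 4)))
  calls <- call_targets(assoc, genes = c("G1", "G2", "G3", "G4"))
  expect_equal(calls$call[calls$gene_id == "G1"], "target")
  expect_equal(calls$call[calls$gene_id == "G2"], "bystander")  # 4/5
  expect_equal(calls$call[calls$gene_id == "G3"], "target")     # 4/4 with data
  expect_equal(calls$call[calls$gene_id == "G4"], "bystander")  # no ortholog
})

test_that("cluster retention classification matches hand-checked patterns", {
  ids <- sprintf("u%03d", 1:90)
  mk <- function(major_ids, minor_ids_list) {
    sc <- data.frame(subcluster_id = "SC_01", chrom = "A", start = 0, end = 1,
                     n_ucnes = length(major_ids),
                     ucne_ids = paste(major_ids, collapse = ";"),
                     bitscore_sum = 1, role = "major", merged_from = "",
                     stringsAsFactors = FALSE)
    for (m in minor_ids_list) {
      sc <- rbind(sc, data.frame(subcluster_id = paste0("SC_0", nrow(sc) + 1),
                                 chrom = "B", start = 0, end = 1,
                                 n_ucnes = length(m),
                                 ucne_ids = paste(m, collapse = ";"),
                                 bitscore_sum = 1, role = "minor",
                                 merged_from = "", stringsAsFactors = FALSE))
    }
    sc
  }
  # all-in-major: (67, 0, 0) is winner-takes-all
  r1 <- classify_cluster_retention(ids[1:67], mk(ids[1:67], list()))
  expect_equal(c(r1$a, r1$b, r1$c), c(67, 0, 0))
  expect_equal(r1$label, "winner")
  # (24, 6, 15): 15/45 = 0.333 > 0.2, reciprocal
  r2 <- classify_cluster_retention(
    ids[1:60], mk(ids[1:30], list(ids[25:30], ids[31:45])))
  expect_equal(c(r2$a, r2$b, r2$c), c(24, 6, 15))
  expect_equal(r2$label, "reciprocal")
  # (13, 8, 18): 18/39 = 0.462, reciprocal
  r3 <- classify_cluster_retention(
    ids[1:50], mk(ids[1:21], list(ids[14:39])))
  expect_equal(c(r3$a, r3$b, r3$c), c(13, 8, 18))
  expect_equal(r3$label, "reciprocal")
  # nothing survives
  expect_null(classify_cluster_retention(ids[1:10],
                                         mk(character(0), list())[0, ]))
})
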