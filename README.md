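# grbcontext

Genomic-context analysis of ultraconserved non-coding elements (UCNEs) in
duplicated genomes.

## The problem

Vertebrate UCNEs — non-coding sequences ≥ 200 bp with ≥ 95% identity
between species as distant as human and chicken — form large syntenic
clusters (genomic regulatory blocks, GRBs) around key developmental genes.
Why they are that conserved is unknown. The teleost whole-genome duplication
(WGD) provides a discriminating experiment: after duplication, each element
can survive in either gene copy. Independently acting enhancers should end
up scattered over the two copies (*reciprocal* retention); cooperatively
acting elements must be co-retained, producing a *winner-takes-all* pattern
in which one copy keeps (nearly) all elements and the other none.

`grbcontext` is an R package for this analysis, aimed at comparative
genomicists studying regulatory-element evolution after polyploidy. It
covers:

* **Detection** — sliding-window identity over pairwise alignment blocks
  (61-bp windows, ≥ 95%), coding-overlap subtraction, 200-bp length filter,
  intronic/UTR/intergenic classification.
* **Homology** — Smith–Waterman local alignment (match +5 / mismatch −4 /
  gap 12/4), E-values calibrated by shuffling the candidate in 20-bp
  windows 500 times and fitting a Gumbel tail; homologs accepted at
  E ≤ 1e−4; ortholog/paralog discrimination by lower-E comparison against a
  reference paralog catalog.
* **Retention statistics** — per gene and genome, counts `a` (UCNEs only in
  the major ortholog), `b` (in both), `c` (only in minors):
  winner-takes-all if `a/(a+b+c) > 0.8`, reciprocal if `c/(a+b+c) > 0.2`,
  else concordant; bitscore-weighted winner scores
  `W = 100 · C_major / C_total` with a permutation null (per-UCNE scores
  shuffled across ortholog columns, 500 shuffles).
* **Clusters** — dual-genome chaining at ≤ 0.5 Mb, orthologous syntenic
  subclusters with assembly-aware merging of fragments, gene association at
  ≤ 0.1 Mb, target-vs-bystander calls.
* **Simulation** — stochastic evolution of a duplicated cluster of N
  elements with a fraction q of interacting pairs; breaks and knockouts are
  accepted only if every interacting pair stays connected to the target in
  at least one copy; run to fixation, endpoints classified as above.
* **Synthetic data** — a generator of reference + duplicated genomes with
  known ground truth (four retention scenarios), so the whole pipeline is
  testable offline.

## Worked example

Generate a small winner-takes-all genome, duplicate it, and classify
retention per gene; then relate connectivity to retention by simulation:

```r
library(grbcontext)

cfg <- synth_config(n_genes = 3, ucnes_per_gene = 5, intergenic_fraction = 0,
                    retention_scenario = "winner", retention_prob = 0.9,
                    seed = 42)
ref <- generate_reference(cfg)
wgd <- simulate_wgd(ref, cfg)
hits <- hits_from_truth(wgd, ref)
cases <- tally_patterns(ref$ucnes, hits, wgd$orthologs)
cases[, c("ref_gene_id", "genome", "a", "b", "c", "major_ortholog_id", "label")]
#>   ref_gene_id genome a b c major_ortholog_id  label
#> 1         G01    dup 4 0 0             G01_a winner
#> 2         G02    dup 5 0 0             G02_b winner
#> 3         G03    dup 5 0 0             G03_a winner
```

Each row is one gene in the duplicated genome: all surviving UCNEs sit in a
single ortholog (`a` > 0, `b = c = 0`), so every gene classifies as
winner-takes-all, and the bitscore-weighted winner score confirms complete
bias:

```r
w <- winner_score(conservation_matrix(
  ref$ucnes$ucne_id[ref$ucnes$host_genes == "G01"], hits,
  c("G01_a", "G01_b"), genome = "dup"))
sprintf("G01 winner score: %.1f (major: %s)", w$W, w$major_ortholog_id)
#> "G01 winner score: 100.0 (major: G01_a)"

sim_sweep(N = 20, q = c(0.2, 0.6, 1), n_reps = 500, seed = 1)
#>    N   q reps frac_winner frac_concordant frac_reciprocal     se
#> 1 20 0.2  500       0.720           0.168           0.112 0.0201
#> 2 20 0.6  500       0.882           0.118           0.000 0.0144
#> 3 20 1.0  500       1.000           0.000           0.000 0.0000
```

The winner-takes-all fraction rises with the connectivity q of the
cis-interaction network: ~72% already at q = 0.2, ~88% at q = 0.6, and
exactly 1 at q = 1 (full connectivity forces one intact copy — provable by
a clique-cover argument and verified by exhaustive enumeration in the
tests). A real dataset would enter through `read_maf()` / `read_gff()` /
`read_bed()` and flow through `scan_ucnes()`, `find_homologs()`,
`tally_patterns()` and `build_clusters()`; `run_pipeline()` chains all
stages on a synthetic configuration under one seed.

The methods vignette (`vignettes/grb-retention-analysis.Rmd`) documents the
model, parameter defaults, numerical conventions and known limitations.

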