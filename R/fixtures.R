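#' Curated UCNE retention-pattern compendium
#'
#' Retention patterns of human UCNEs across five teleost genomes (Fugu,
#' medaka, stickleback, Tetraodon, zebrafish), curated from the literature:
#' per-species (a,b,c) triplets for the top UCNE-enriched genes
#' (intronic/UTR UCNEs, `which = "genes"`) and for the largest UCNE
#' clusters (`which = "clusters"`), together with the per-gene/per-cluster
#' tallies of winner-takes-all, concordant and reciprocal classifications.
#' Species without two annotated orthologs (or without retained UCNEs) are
#' absent. Two cluster rows sit on or across the strict classification
#' boundaries and carry an explanatory `note` in the expected-tally table.
#'
#' @param which `"genes"` or `"clusters"`.
#' @return list with `patterns` (columns `gene`/`cluster`, `n_ucnes`,
#'   `genome`, `a`, `b`, `c`) and `expected` (classification tallies per
#'   gene/cluster).
#' @export
retention_fixture <- function(which = c("genes", "clusters")) {
  which <- match.arg(which)
  stem <- if (which == "genes") "gene" else "cluster"
  pat <- system.file("extdata", paste0(stem, "_retention_patterns.tsv"),
                     package = "grbcontext", mustWork = TRUE)
  exp <- system.file("extdata", paste0(stem, "_retention_expected.tsv"),
                     package = "grbcontext", mustWork = TRUE)
  list(patterns = read_tsv(pat), expected = read_tsv(exp))
}
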