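## Signed interaction networks at calibrated cutoffs, bioprocess crosstalk
## enrichment, and network topology statistics with group contrasts.

#' Call signed genetic interactions
#'
#' Emits an edge for every unordered pair whose E-score passes the
#' aggravating (`E <= cutoffs[1]`, boundary inclusive) or alleviating
#' (`E >= cutoffs[2]`) cutoff and, when `use_fdr` is on, whose
#' Benjamini-Hochberg adjusted empirical p-value across all testable pairs
#' is at most `fdr_q`. An empty network is a valid result.
#'
#' @param es An `escore_matrix` with p-values attached (unless
#'   `use_fdr = FALSE`).
#' @param cutoffs Length-2 numeric `(negative, positive)`; default
#'   `c(-2, 2)`.
#' @param fdr_q FDR level for the p-value gate.
#' @param use_fdr Require the FDR gate in addition to the score cutoff.
#' @return data.frame of class `interaction_edges`: `gene_a`, `gene_b`,
#'   `condition`, `E`, `p`, `adj_p`, `sign`; attribute `cutoffs` and
#'   `n_tested`.
#' @export
call_interactions <- function(es, cutoffs = c(-2, 2), fdr_q = 0.05,
                              use_fdr = TRUE) {
  stopifnot(length(cutoffs) == 2L, cutoffs[1] < 0, cutoffs[2] > 0)
  pairs <- escore_pairs(es)
  if (use_fdr && all(is.na(pairs$p)))
    stopf("p-values not attached; run attach_pvalues() or set use_fdr = FALSE")
  pairs$adj_p <- if (all(is.na(pairs$p))) NA_real_ else bh_adjust(pairs$p)
  hit <- pairs$E <= cutoffs[1] | pairs$E >= cutoffs[2]
  if (use_fdr) hit <- hit & !is.na(pairs$adj_p) & pairs$adj_p <= fdr_q
  edges <- pairs[hit, , drop = FALSE]
  edges$sign <- ifelse(edges$E <= cutoffs[1], "aggravating", "alleviating")
  rownames(edges) <- NULL
  structure(edges, cutoffs = cutoffs, n_tested = nrow(pairs),
            class = c("interaction_edges", "data.frame"))
}

#' Bioprocess crosstalk enrichment of an interaction network
#'
#' Runs [bioprocess_pair_enrichment()] separately for aggravating and
#' alleviating edges against the testable universe, marking significant
#' label pairs; elevated interaction density between two bioprocesses is
#' the network-level "crosstalk" signal.
#'
#' @param edges [call_interactions()] output.
#' @param universe_pairs All testable pairs (e.g. [escore_pairs()] of the
#'   same matrix).
#' @param annotations Gene -> bioprocess map.
#' @param alpha Significance level on adjusted p.
#' @return Named list (`aggravating`, `alleviating`) of enrichment tables.
#' @export
crosstalk_matrix <- function(edges, universe_pairs, annotations,
                             alpha = 0.05) {
  res <- lapply(c(aggravating = "aggravating", alleviating = "alleviating"),
                function(s) {
                  bioprocess_pair_enrichment(
                    edges[edges$sign == s, c("gene_a", "gene_b"), drop = FALSE],
                    universe_pairs, annotations, alpha = alpha)
                })
  res
}

#' Per-gene network topology statistics
#'
#' Degree and exact betweenness centrality (unweighted shortest paths,
#' normalized by `(n-1)(n-2)/2`) of the simple undirected graph formed by
#' the edges (duplicate pairs merged).
#'
#' @param edges data.frame with `gene_a`, `gene_b` (e.g.
#'   [call_interactions()] output).
#' @return data.frame `gene`, `degree`, `betweenness`.
#' @export
topology_stats <- function(edges) {
  if (nrow(edges) == 0L)
    return(data.frame(gene = character(0), degree = integer(0),
                      betweenness = numeric(0), stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  g <- igraph::simplify(g)
  data.frame(gene = igraph::V(g)$name,
             degree = unname(igraph::degree(g)),
             betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                                      normalized = TRUE)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare interaction properties between gene groups
#'
#' Three contrasts used on essential vs non-essential genes (or any
#' two-level grouping):
#' `fisher_ratio` contrasts the alleviating:aggravating edge-count ratio
#' between groups (pairs whose two genes fall in different groups are
#' excluded) with a two-sided Fisher exact test; `wilcoxon` and `ks`
#' compare the per-gene distribution of a topology statistic (degree or
#' betweenness) between groups. The Wilcoxon test uses exact enumeration
#' when both samples have at most 12 tie-free observations.
#'
#' @param x For `fisher_ratio`: an edge data.frame with `gene_a`, `gene_b`,
#'   `sign`. For `wilcoxon`/`ks`: a [topology_stats()] data.frame.
#' @param groups Named vector gene -> group label (exactly 2 levels used).
#' @param test One of `"fisher_ratio"`, `"wilcoxon"`, `"ks"`.
#' @param value Column compared for the distribution tests.
#' @return List with `test`, `statistic`, `p.value`, and either `table`
#'   (fisher_ratio) or `medians`.
#' @export
group_compare <- function(x, groups,
                          test = c("fisher_ratio", "wilcoxon", "ks"),
                          value = "degree") {
  test <- match.arg(test)
  lev <- sort(unique(stats::na.omit(as.vector(groups))))
  if (length(lev) != 2L) stopf("groups must have exactly 2 levels")

  if (test == "fisher_ratio") {
    ga <- groups[x$gene_a]; gb <- groups[x$gene_b]
    same <- !is.na(ga) & !is.na(gb) & ga == gb
    if (!any(same)) stopf("no within-group edges to contrast")
    tab <- table(factor(ga[same], levels = lev),
                 factor(x$sign[same], levels = c("alleviating", "aggravating")))
    if (any(rowSums(tab) == 0L)) stopf("a group has no edges")
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    return(list(test = "fisher_ratio", statistic = unname(ft$estimate),
                p.value = ft$p.value, table = tab))
  }

  grp <- groups[x$gene]
  v1 <- x[[value]][!is.na(grp) & grp == lev[1L]]
  v2 <- x[[value]][!is.na(grp) & grp == lev[2L]]
  if (length(v1) == 0L || length(v2) == 0L)
    stopf("empty group in comparison")
  if (test == "wilcoxon") {
    exact <- length(v1) <= 12L && length(v2) <= 12L &&
      !anyDuplicated(c(v1, v2))
    wt <- suppressWarnings(stats::wilcox.test(v1, v2, exact = exact))
    return(list(test = "wilcoxon", statistic = unname(wt$statistic),
                p.value = wt$p.value,
                medians = c(stats::median(v1), stats::median(v2))))
  }
  kt <- suppressWarnings(stats::ks.test(v1, v2))
  list(test = "ks", statistic = unname(kt$statistic), p.value = kt$p.value,
       medians = c(stats::median(v1), stats::median(v2)))
}
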