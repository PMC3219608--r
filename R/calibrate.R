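## Enrichment-calibrated E-score cutoffs: sweep |E| thresholds, count
## bioprocess label pairs significantly enriched for interactions, and pick
## the cutoff per sign that maximizes the count, with a label-shuffled
## control curve.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (thin wrapper over
#' [stats::p.adjust()]); the i-th output corresponds to the i-th input.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Bioprocess-pair interaction enrichment
#'
#' For every unordered pair of bioprocess labels (A, B), tests whether
#' interaction edges fall between A and B more often than expected from the
#' composition of the testable universe, via a one-sided (enrichment)
#' Fisher exact test on the 2x2 table
#' (edge vs non-edge) x (between A,B vs elsewhere), i.e. the hypergeometric
#' tail. P-values are Benjamini-Hochberg adjusted across all label pairs;
#' `enriched` marks adjusted p <= `alpha`. Label pairs with no testable
#' pairs are skipped and recorded with NA.
#'
#' @param edge_pairs data.frame with `gene_a`, `gene_b`: the interaction
#'   edges at the current threshold.
#' @param universe_pairs data.frame with `gene_a`, `gene_b`: all testable
#'   pairs (defined E-score, masked pairs excluded); must contain the
#'   edges.
#' @param annotations Gene -> bioprocess map (named vector or two-column
#'   data.frame); unannotated genes are excluded.
#' @param alpha Adjusted-p enrichment level.
#' @return data.frame `label_a`, `label_b`, `n_pairs`, `n_edges`,
#'   `odds_ratio`, `p`, `adj_p`, `enriched`.
#' @export
bioprocess_pair_enrichment <- function(edge_pairs, universe_pairs,
                                       annotations, alpha = 0.05) {
  ann <- as_annotation(annotations)
  lab <- sort(unique(ann))
  lab_pairs <- expand.grid(i = seq_along(lab), j = seq_along(lab))
  lab_pairs <- lab_pairs[lab_pairs$i <= lab_pairs$j, , drop = FALSE]

  label_pair_key <- function(pairs) {
    la <- ann[pairs$gene_a]; lb <- ann[pairs$gene_b]
    ok <- !is.na(la) & !is.na(lb)
    paste(pmin(la, lb), pmax(la, lb), sep = "\r")[ok]
  }
  uk <- label_pair_key(universe_pairs)
  ek <- if (nrow(edge_pairs) > 0L) label_pair_key(edge_pairs) else character(0)
  N <- length(uk)
  Etot <- length(ek)
  ucount <- table(uk)
  ecount <- table(ek)

  keys <- paste(lab[lab_pairs$i], lab[lab_pairs$j], sep = "\r")
  n_pairs <- as.integer(ucount[keys]); n_pairs[is.na(n_pairs)] <- 0L
  n_edges <- as.integer(ecount[keys]); n_edges[is.na(n_edges)] <- 0L

  p <- odds <- rep(NA_real_, length(keys))
  for (k in seq_along(keys)) {
    if (n_pairs[k] == 0L) next
    a <- n_edges[k]
    b <- Etot - a
    cc <- n_pairs[k] - a
    dd <- (N - n_pairs[k]) - b
    ft <- stats::fisher.test(matrix(c(a, b, cc, dd), 2L, byrow = TRUE),
                             alternative = "greater")
    p[k] <- ft$p.value
    odds[k] <- unname(ft$estimate)
  }
  adj <- rep(NA_real_, length(keys))
  tested <- !is.na(p)
  adj[tested] <- bh_adjust(p[tested])
  data.frame(label_a = lab[lab_pairs$i], label_b = lab[lab_pairs$j],
             n_pairs = n_pairs, n_edges = n_edges, odds_ratio = odds,
             p = p, adj_p = adj,
             enriched = !is.na(adj) & adj <= alpha,
             stringsAsFactors = FALSE)
}

#' Threshold sweep for E-score cutoff calibration
#'
#' For each |E| threshold on the grid and each sign, counts bioprocess label
#' pairs significantly enriched among the interactions at that threshold
#' ([bioprocess_pair_enrichment()]). The chosen cutoff per sign is the
#' smallest |threshold| attaining the maximum count (the tie-break retains
#' sensitivity at equal enrichment evidence). The same counts are computed
#' with gene labels shuffled `n_shuffles` times: the shuffled mean per
#' threshold is the control curve, and the shuffled maximum is retained for
#' the specificity check. If no threshold yields any enriched label pair
#' for a sign, calibration for that sign fails explicitly (NA cutoff,
#' `failed` flag).
#'
#' @param es An `escore_matrix` (or a long pair data.frame with `gene_a`,
#'   `gene_b`, `E`).
#' @param annotations Gene -> bioprocess map.
#' @param grid Thresholds on |E|; must cover [1, 4] in steps <= 0.5.
#' @param n_shuffles Label shuffles for the control curve.
#' @param alpha Enrichment level per label pair.
#' @param seed Seed for the shuffles.
#' @return Object of class `calibration_result`: `sweep` data.frame
#'   (`threshold`, `sign`, `enriched_count`, `shuffled_mean`,
#'   `shuffled_max`), `chosen` (named vector `negative`, `positive`),
#'   `failed` flag.
#' @export
threshold_sweep <- function(es, annotations, grid = seq(1, 4, by = 0.5),
                            n_shuffles = 20L, alpha = 0.05, seed = 1L) {
  if (min(grid) > 1 || max(grid) < 4 || max(diff(sort(grid))) > 0.5 + 1e-9)
    stopf("threshold grid must cover [1, 4] in steps <= 0.5")
  pairs <- if (inherits(es, "escore_matrix")) escore_pairs(es) else es
  ann <- as_annotation(annotations)
  pairs <- pairs[pairs$gene_a %in% names(ann) & pairs$gene_b %in% names(ann), ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) stopf("no annotated testable pairs")
  grid <- sort(grid)

  count_curve <- function(ann_use) {
    out <- expand.grid(threshold = grid,
                       sign = c("aggravating", "alleviating"),
                       stringsAsFactors = FALSE)
    out$count <- NA_integer_
    for (k in seq_len(nrow(out))) {
      t <- out$threshold[k]
      sel <- if (out$sign[k] == "aggravating") pairs$E <= -t else pairs$E >= t
      enr <- bioprocess_pair_enrichment(pairs[sel, , drop = FALSE], pairs,
                                        ann_use, alpha = alpha)
      out$count[k] <- sum(enr$enriched, na.rm = TRUE)
    }
    out
  }

  real <- count_curve(ann)
  genes_u <- intersect(names(ann), unique(c(pairs$gene_a, pairs$gene_b)))
  set.seed(seed)
  shuffled <- matrix(NA_integer_, nrow(real), n_shuffles)
  for (s in seq_len(n_shuffles)) {
    ann_s <- ann
    ann_s[genes_u] <- sample(ann[genes_u])
    shuffled[, s] <- count_curve(ann_s)$count
  }
  sweep_df <- data.frame(threshold = real$threshold, sign = real$sign,
                         enriched_count = real$count,
                         shuffled_mean = rowMeans(shuffled),
                         shuffled_max = apply(shuffled, 1L, max),
                         stringsAsFactors = FALSE)

  pick <- function(sgn) {
    sub <- sweep_df[sweep_df$sign == sgn, , drop = FALSE]
    if (max(sub$enriched_count) == 0L) return(NA_real_)
    min(sub$threshold[sub$enriched_count == max(sub$enriched_count)])
  }
  tneg <- pick("aggravating")
  tpos <- pick("alleviating")
  structure(list(sweep = sweep_df,
                 chosen = c(negative = if (is.na(tneg)) NA_real_ else -tneg,
                            positive = tpos),
                 failed = is.na(tneg) || is.na(tpos),
                 alpha = alpha, n_shuffles = n_shuffles, seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  if (x$failed) {
    cat("calibration_result: FAILED (no threshold with enriched label pairs)\n")
  } else {
    cat(sprintf("calibration_result: chosen cutoffs E <= %.2f (aggravating), E >= %.2f (alleviating)\n",
                x$chosen["negative"], x$chosen["positive"]))
  }
  invisible(x)
}
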