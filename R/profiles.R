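## Genetic-interaction profile correlations and evidence-set shift tests:
## genes acting together share interaction partners, so their E-score
## profiles across the array correlate.

#' Pairwise correlation of genetic-interaction profiles
#'
#' For every pair of query genes, the Pearson (optionally Spearman)
#' correlation of their E-score profiles over the array genes measured for
#' both, excluding array positions that involve either gene of the pair
#' (otherwise a strong direct interaction between the two would leak into
#' its own profile correlation). Pairs with fewer than `min_overlap` shared
#' partners, or a constant profile, get NA.
#'
#' @param es An `escore_matrix`.
#' @param min_overlap Minimum shared measured partners (default 30).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame of class `profile_correlation`: `gene_a`, `gene_b`,
#'   `r`, `n_overlap`.
#' @export
profile_correlation <- function(es, min_overlap = 30L,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  E <- es$E
  genes <- rownames(E)
  nq <- length(genes)
  if (nq < 2L) stopf("need at least two query profiles")
  cols <- colnames(E)
  res <- vector("list", nq * (nq - 1L) / 2L)
  k <- 0L
  for (i in seq_len(nq - 1L)) {
    xi <- E[i, ]
    for (j in seq(i + 1L, nq)) {
      xj <- E[j, ]
      use <- is.finite(xi) & is.finite(xj) & cols != genes[i] & cols != genes[j]
      k <- k + 1L
      n <- sum(use)
      r <- NA_real_
      if (n >= min_overlap) {
        sx <- stats::sd(xi[use]); sy <- stats::sd(xj[use])
        if (sx > 0 && sy > 0)
          r <- stats::cor(xi[use], xj[use], method = method)
      }
      res[[k]] <- c(i, j, r, n)
    }
  }
  m <- do.call(rbind, res)
  out <- data.frame(gene_a = genes[m[, 1L]], gene_b = genes[m[, 2L]],
                    r = m[, 3L], n_overlap = as.integer(m[, 4L]),
                    stringsAsFactors = FALSE)
  swap <- out$gene_a > out$gene_b
  tmp <- out$gene_a[swap]; out$gene_a[swap] <- out$gene_b[swap]
  out$gene_b[swap] <- tmp
  structure(out[order(out$gene_a, out$gene_b), , drop = FALSE],
            method = method, min_overlap = min_overlap,
            class = c("profile_correlation", "data.frame"))
}

#' Test whether evidence-supported pairs have shifted profile correlations
#'
#' Compares the profile-correlation distribution of pairs carrying external
#' evidence (operon co-membership, co-expression, protein-protein
#' interaction) against randomly drawn measured pairs, with a two-sample
#' Kolmogorov-Smirnov test; reports the KS statistic, p-value and both
#' medians. Functionally linked genes are expected to shift toward positive
#' correlation.
#'
#' @param corrs A [profile_correlation()] result.
#' @param evidence_pairs Two-column data.frame (or matrix) of gene pairs.
#' @param n_random Number of random pairs (default 10x the usable evidence
#'   pairs, capped at the pool size).
#' @param seed Seed for the random draw.
#' @param min_pairs Minimum evidence pairs with a defined correlation.
#' @return List: `D`, `p.value`, `median_evidence`, `median_random`,
#'   `n_evidence`, `n_random`, `seed`.
#' @export
evidence_shift_test <- function(corrs, evidence_pairs, n_random = NULL,
                                seed = 1L, min_pairs = 20L) {
  ev <- as.data.frame(evidence_pairs, stringsAsFactors = FALSE)
  ek <- pair_key(as.character(ev[[1L]]), as.character(ev[[2L]]))
  ck <- pair_key(corrs$gene_a, corrs$gene_b)
  defined <- is.finite(corrs$r)
  r_ev <- corrs$r[defined & ck %in% ek]
  if (length(r_ev) < min_pairs)
    stopf("only %d evidence pair(s) with a defined correlation (need >= %d)",
          length(r_ev), min_pairs)
  pool <- corrs$r[defined]
  n_random <- n_random %||% (10L * length(r_ev))
  set.seed(seed)
  r_rand <- if (n_random <= length(pool)) sample(pool, n_random)
  else sample(pool, n_random, replace = TRUE)
  kt <- suppressWarnings(stats::ks.test(r_ev, r_rand))
  list(D = unname(kt$statistic), p.value = kt$p.value,
       median_evidence = stats::median(r_ev),
       median_random = stats::median(r_rand),
       n_evidence = length(r_ev), n_random = n_random, seed = seed)
}
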