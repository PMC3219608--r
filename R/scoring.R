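## Multiplicative-model epistasis scoring: single-mutant fitness estimated
## from the screen itself, standardized E-scores, and empirical p-values
## from a replicate-resampling null.

#' Estimate single-mutant fitness from a screen matrix
#'
#' Under the multiplicative model the double-mutant fitness of a
#' non-interacting pair is `Wi * Wj`; because interactions are a minority,
#' robust marginals of the screen matrix recover the single-mutant terms.
#' The array-gene fitness `Wj` is the median over queries of `Wij` for that
#' column; the query fitness `Wi` is the median over arrays of `Wij / Wj`.
#' The array estimates are rescaled to median 1 and the query estimates
#' carry the complementary scale, so the product `Wi * Wj` stays calibrated
#' to the measured `Wij` (the genome-wide typical fitness is 1 by the plate
#' normalization).
#'
#' Note that on plate-median-normalized data the query marginal absorbs the
#' per-screen plate scale; it is a relative, within-screen quantity.
#'
#' @param screen A [screen_matrix()].
#' @param min_obs Minimum unmasked observations for a gene's fitness to be
#'   defined (genes below are excluded from scoring).
#' @param min_genes Minimum number of queries and arrays required.
#' @param dead_threshold Array genes whose fitness falls below
#'   `dead_threshold` times the median array fitness (no growth anywhere)
#'   are excluded.
#' @return Object of class `single_fitness`: list with named vectors
#'   `query` and `array` (NA = excluded) and data.frame `excluded`.
#' @export
estimate_single_fitness <- function(screen, min_obs = 5L, min_genes = 20L,
                                    dead_threshold = 0.05) {
  stopifnot(inherits(screen, "screen_matrix"))
  W <- screen$W
  if (nrow(W) < min_genes || ncol(W) < min_genes)
    stopf("estimate_single_fitness needs >= %d queries and arrays (have %d x %d)",
          min_genes, nrow(W), ncol(W))
  excluded <- data.frame(gene = character(0), side = character(0),
                         reason = character(0), stringsAsFactors = FALSE)

  wj <- col_medians(W)
  n_col <- colSums(!is.na(W))
  few <- n_col < min_obs
  if (any(few)) {
    excluded <- rbind(excluded,
                      data.frame(gene = colnames(W)[few], side = "array",
                                 reason = "too_few_observations",
                                 stringsAsFactors = FALSE))
    wj[few] <- NA_real_
  }
  dead <- !is.na(wj) & wj < dead_threshold * stats::median(wj, na.rm = TRUE)
  if (any(dead)) {
    excluded <- rbind(excluded,
                      data.frame(gene = colnames(W)[dead], side = "array",
                                 reason = "no_growth", stringsAsFactors = FALSE))
    wj[dead] <- NA_real_
  }

  wi <- row_medians(sweep(W, 2L, wj, `/`))
  n_row <- rowSums(!is.na(sweep(W, 2L, wj, `/`)))
  few_q <- n_row < min_obs
  if (any(few_q)) {
    excluded <- rbind(excluded,
                      data.frame(gene = rownames(W)[few_q], side = "query",
                                 reason = "too_few_observations",
                                 stringsAsFactors = FALSE))
    wi[few_q] <- NA_real_
  }

  sc <- stats::median(wj, na.rm = TRUE)
  if (is.finite(sc) && sc > 0) {
    wj <- wj / sc
    wi <- wi * sc
  }
  structure(list(query = wi, array = wj, excluded = excluded),
            class = "single_fitness")
}

#' Compute E-scores under the multiplicative model
#'
#' The E-score of pair (i, j) is the standardized deviation of the measured
#' double-mutant fitness from the multiplicative expectation:
#' `E = (Wij - Wi * Wj) / sigma_hat`, with
#' `sigma_hat = sqrt(sd_ij^2 / n_ij + sigma0^2)`. `sigma0`, the modal
#' replicate standard deviation across the matrix, regularizes cells whose
#' few replicates happen to agree closely (which would otherwise produce
#' arbitrarily large scores). Negative E-scores are aggravating (synthetic
#' sick/lethal), positive are alleviating; by construction a score of +-2
#' is roughly two standard errors from neutrality. When both orientations
#' of a pair were measured (each gene as query against the other as array)
#' the inverse-variance-weighted mean is reported for both cells, and
#' orientation disagreements beyond `flag_delta` are listed in the `qc`
#' field.
#'
#' @param screen A [screen_matrix()].
#' @param fitness A [estimate_single_fitness()] result (or compatible list
#'   with `query`/`array` vectors).
#' @param sigma0 Regularizing standard deviation; default the modal
#'   (moderated) replicate SD of the matrix.
#' @param var_prior_df Prior degrees of freedom for moderating each cell's
#'   replicate variance toward the global relative-variance trend
#'   (`0` keeps the raw per-cell variance).
#' @param merge_orientations Merge reciprocal measurements (default TRUE).
#' @param center_surface Median-center the score surface by row and column
#'   (default TRUE); removes residual shared offsets from the estimated
#'   fitness reference without touching sparse true interactions.
#' @param standardize Scale the final score surface to unit central spread
#'   (robust MAD; default TRUE). Skipped for matrices with fewer than 50
#'   scored cells and for deviation-free (all-zero) surfaces.
#' @param flag_delta Orientation |E| disagreement beyond which a pair is
#'   flagged.
#' @return Object of class `escore_matrix`: `E`, `sigma` (merged),
#'   `sigma_cell` (per-orientation), `p` (NULL until
#'   [attach_pvalues()]), `condition`, `sigma0`, `screen`, `fitness`, `qc`.
#' @export
compute_escores <- function(screen, fitness, sigma0 = NULL,
                            var_prior_df = 10, merge_orientations = TRUE,
                            center_surface = TRUE, standardize = TRUE,
                            flag_delta = 4) {
  stopifnot(inherits(screen, "screen_matrix"))
  W <- screen$W
  wi <- fitness$query[rownames(W)]
  wj <- fitness$array[colnames(W)]
  expected <- wi %o% wj
  ## moderate the per-cell replicate variance toward its array gene's
  ## relative-variance trend (relative variance x size^2): with 2-3
  ## replicates the raw sample variance has only 1-2 df, and its noise
  ## would otherwise dominate the score denominator. The trend is pooled
  ## per array column because both the allele and its fixed plate position
  ## (edge columns, short rows) carry their own noise level.
  n <- screen$n_obs
  ok <- n >= 2L & !screen$mask & is.finite(screen$sd) & W > 0
  rel_s2 <- (screen$sd / W)^2
  corr <- (n - 1L) / stats::qchisq(0.5, pmax(n - 1L, 1L))  # median-unbiased
  rel_corr <- rel_s2 * corr
  rel_corr[!ok] <- NA
  s0_rel2 <- stats::median(rel_corr, na.rm = TRUE)
  if (!is.finite(s0_rel2) || s0_rel2 <= 0)
    s0_rel2 <- stats::median(rel_s2[ok], na.rm = TRUE)
  col_rel2 <- apply(rel_corr, 2L, stats::median, na.rm = TRUE)
  col_n <- colSums(!is.na(rel_corr))
  col_rel2[col_n < 10L | !is.finite(col_rel2) | col_rel2 <= 0] <- s0_rel2
  ## shrink each column trend toward the global trend (20 pseudo-cells):
  ## keeps genuine allele/position noise levels, damps estimation noise
  col_rel2 <- (20 * s0_rel2 + col_n * col_rel2) / (20 + col_n)
  trend2 <- matrix(col_rel2, nrow(W), ncol(W), byrow = TRUE)
  sd_mod2 <- W^2 * (var_prior_df * trend2 + (n - 1L) * rel_s2) /
    (var_prior_df + n - 1L)
  bad <- !is.finite(sd_mod2)
  sd_mod2[bad] <- (screen$sd^2)[bad]
  sd_mod <- sqrt(sd_mod2)

  if (is.null(sigma0)) {
    sds <- sd_mod[ok]
    sigma0 <- modal_value(sds[is.finite(sds)])
  }
  if (!is.finite(sigma0) || sigma0 <= 0)
    stopf("sigma0 must be positive (got %s)", format(sigma0))
  sigma_cell <- sqrt(sd_mod^2 / n + sigma0^2)
  sigma_cell[n < 2L | screen$mask] <- NA_real_
  E <- (W - expected) / sigma_cell
  if (center_surface) {
    ## remove residual per-row/per-column score offsets (shared
    ## fitness-reference error); medians are robust to the minority of
    ## true interactions and leave a zero matrix untouched
    for (pass in 1:2) {
      E <- sweep(E, 2L, col_medians(E))
      E <- sweep(E, 1L, row_medians(E))
    }
  }
  sigma <- sigma_cell

  qc <- data.frame(gene_a = character(0), gene_b = character(0),
                   E_ab = numeric(0), E_ba = numeric(0),
                   stringsAsFactors = FALSE)
  if (merge_orientations) {
    common <- intersect(rownames(E), colnames(E))
    if (length(common) >= 2L) {
      M <- E[common, common, drop = FALSE]
      S <- sigma[common, common, drop = FALSE]
      Mt <- t(M); St <- t(S)
      both <- is.finite(M) & is.finite(Mt)
      w1 <- 1 / S^2; w2 <- 1 / St^2
      merged <- M
      merged[both] <- (M[both] * w1[both] + Mt[both] * w2[both]) /
        (w1[both] + w2[both])
      only_t <- !is.finite(M) & is.finite(Mt)
      merged[only_t] <- Mt[only_t]
      smerged <- S
      smerged[both] <- sqrt(1 / (w1[both] + w2[both]))
      smerged[only_t] <- St[only_t]
      disagree <- both & abs(M - Mt) > flag_delta & upper.tri(M)
      if (any(disagree)) {
        idx <- which(disagree, arr.ind = TRUE)
        qc <- data.frame(gene_a = common[idx[, 1L]], gene_b = common[idx[, 2L]],
                         E_ab = M[disagree], E_ba = Mt[disagree],
                         stringsAsFactors = FALSE)
      }
      E[common, common] <- merged
      sigma[common, common] <- smerged
    }
  }
  ## standardize the score surface to unit central spread, so that +-2
  ## reads as about two standard deviations of the neutral peak; the MAD
  ## ignores the interaction tails, and small matrices (or an exactly
  ## multiplicative, deviation-free screen) are left on the raw scale
  scale_factor <- 1
  if (standardize && sum(is.finite(E)) >= 50L) {
    s <- stats::mad(E[is.finite(E)])
    # a numerically-zero spread marks a deviation-free surface, not a
    # scale to standardize away
    if (is.finite(s) && s > 1e-6) {
      scale_factor <- s
      E <- E / s
      sigma_cell <- sigma_cell * s
      sigma <- sigma * s
    }
  }
  structure(list(E = E, sigma = sigma, sigma_cell = sigma_cell, p = NULL,
                 condition = screen$condition, sigma0 = sigma0,
                 scale_factor = scale_factor,
                 array_relvar = stats::setNames(col_rel2, colnames(W)),
                 screen = screen, fitness = fitness, qc = qc),
            class = "escore_matrix")
}

#' @export
print.escore_matrix <- function(x, ...) {
  cat(sprintf("escore_matrix [%s]: %d x %d, %d scored pairs, sigma0 = %.4g%s\n",
              x$condition, nrow(x$E), ncol(x$E), sum(is.finite(x$E)),
              x$sigma0, if (is.null(x$p)) "" else ", p-values attached"))
  invisible(x)
}

## pooled null of standardized deviations from cross-cell replicate
## residual resampling. Replicate residuals around each cell's own mean
## are free of any planted interaction; on the relative (per-size) scale
## they are exchangeable across cells under multiplicative noise. Each
## null draw for a cell therefore averages n randomly borrowed relative
## residuals (variance-rescaled by sqrt(n'/(n'-1)) at the donor so a
## centered residual has the full noise variance), multiplies by the
## cell's own mean size, and standardizes by the cell's sigma_hat --
## exactly how the observed score's numerator behaves under no
## interaction. Borrowing across cells (rather than flipping a cell's own
## residuals) matters at 2-3 replicates: a cell whose few replicates agree
## by chance still has full-sized mean error, and its null must say so.
escore_null_pool <- function(es, null_size, seed) {
  screen <- es$screen
  if (is.null(screen$reps))
    stopf("replicate-level data unavailable; rebuild the screen matrix from colony records")
  R <- screen$reps
  n <- screen$n_obs
  valid <- screen$n_obs >= 2L & !screen$mask & is.finite(es$sigma_cell)

  ## donor pool of standardized relative residuals (scaled by size and by
  ## the array column's relative-noise trend, so residuals from noisy and
  ## quiet positions are exchangeable; dead cells excluded: their relative
  ## scale is undefined)
  W <- screen$W
  trend_sd <- sqrt(matrix(es$array_relvar[colnames(W)], nrow(W), ncol(W),
                          byrow = TRUE))
  donor_ok <- valid & W > 0.1 * stats::median(W[valid], na.rm = TRUE) &
    is.finite(trend_sd) & trend_sd > 0
  d <- sweep(R, c(1L, 2L), W, `-`)
  d <- sweep(d, c(1L, 2L), sqrt(n / pmax(n - 1L, 1L)) / (W * trend_sd), `*`)
  dv <- matrix(d, nrow = prod(dim(R)[1:2]), ncol = dim(R)[3L])
  pool_rel <- dv[donor_ok, , drop = FALSE]
  pool_rel <- pool_rel[is.finite(pool_rel)]
  if (length(pool_rel) < 50L) stopf("too few replicate residuals for a null")

  keep <- which(valid)
  nk <- n[keep]
  sizek <- (W * trend_sd)[keep]
  sig <- es$sigma_cell[keep]   # already on the standardized score scale

  ## orientation structure, mirroring compute_escores: reciprocal
  ## measurements of a pair are inverse-variance merged, and each
  ## unordered pair contributes once to the pool
  common <- intersect(rownames(W), colnames(W))
  merge_pairs <- NULL
  primary <- valid
  if (length(common) >= 2L) {
    iq <- match(common, rownames(W)); ia <- match(common, colnames(W))
    diag_cells <- cbind(iq, ia)
    primary[diag_cells] <- FALSE
    ut <- which(upper.tri(matrix(0, length(common), length(common))),
                arr.ind = TRUE)
    c1 <- cbind(iq[ut[, 1L]], ia[ut[, 2L]])   # (a as query, b as array)
    c2 <- cbind(iq[ut[, 2L]], ia[ut[, 1L]])   # (b as query, a as array)
    both <- valid[c1] & valid[c2]
    if (any(both)) {
      c1 <- c1[both, , drop = FALSE]; c2 <- c2[both, , drop = FALSE]
      w1 <- 1 / es$sigma_cell[c1]^2
      w2 <- 1 / es$sigma_cell[c2]^2
      merge_pairs <- list(c1 = c1, c2 = c2, f1 = w1 / (w1 + w2),
                          f2 = w2 / (w1 + w2))
      primary[c2] <- FALSE   # merged value pooled once, via c1
    }
  }

  set.seed(seed)
  out <- vector("list", null_size)
  nc <- length(keep)
  nmax <- max(nk)
  U <- matrix(NA_real_, nrow(W), ncol(W))
  for (b in seq_len(null_size)) {
    draws <- matrix(pool_rel[sample.int(length(pool_rel), nc * nmax,
                                        replace = TRUE)], nc, nmax)
    if (any(nk < nmax)) draws[col(draws) > nk] <- 0
    U[keep] <- (rowSums(draws) / nk) * sizek / sig
    if (!is.null(merge_pairs))
      U[merge_pairs$c1] <- merge_pairs$f1 * U[merge_pairs$c1] +
        merge_pairs$f2 * U[merge_pairs$c2]
    out[[b]] <- U[primary & valid]
  }
  unlist(out, use.names = FALSE)
}

#' Attach empirical p-values to an E-score matrix
#'
#' Builds an empirical null for the E-score by resampling replicate
#' residuals: within each measured cell the deviations of the replicates
#' around the cell mean are variance-rescaled, randomly sign-flipped and
#' re-averaged, then standardized exactly as the observed score. The
#' resampled scores from all cells and `null_size` rounds are pooled, and
#' the two-sided p-value of each observed score is its exceedance rank in
#' the pool with the plus-one correction:
#' `p = (1 + #(|E_null| >= |E|)) / (1 + N_null)`. Because the null is built
#' from within-cell replicate scatter it is signal-free, so planted
#' interactions do not inflate it; p is monotone non-increasing in |E|.
#'
#' @param es An [compute_escores()] result built from a screen matrix with
#'   replicate-level data.
#' @param null_size Number of resampling rounds (>= 10).
#' @param seed Seed for the resampling.
#' @param keep_null Retain the sorted pooled |null| values in the result
#'   (for diagnostics; default FALSE).
#' @return `es` with `p` (matrix of two-sided empirical p-values) and
#'   `n_null` set.
#' @export
attach_pvalues <- function(es, null_size = 100L, seed = 1L,
                           keep_null = FALSE) {
  stopifnot(inherits(es, "escore_matrix"))
  if (!is_count(null_size) || null_size < 10)
    stopf("null_size must be an integer >= 10")
  pool <- sort(abs(escore_null_pool(es, null_size, seed)))
  N <- length(pool)
  p <- matrix(NA_real_, nrow(es$E), ncol(es$E), dimnames = dimnames(es$E))
  obs <- is.finite(es$E)
  cnt <- count_geq(abs(es$E[obs]), pool)
  p[obs] <- (1 + cnt) / (1 + N)
  es$p <- p
  es$n_null <- N
  if (keep_null) es$null_abs <- pool
  es
}

#' Long-form unordered pair table of an E-score matrix
#'
#' Collapses the queries x arrays matrix to one row per unordered gene pair
#' with a defined score (reciprocal orientations have already been merged
#' by [compute_escores()]).
#'
#' @param es An `escore_matrix`.
#' @return data.frame `gene_a`, `gene_b` (`gene_a < gene_b`), `E`, `p`
#'   (NA when not attached), `condition`.
#' @export
escore_pairs <- function(es) {
  stopifnot(inherits(es, "escore_matrix"))
  idx <- which(is.finite(es$E), arr.ind = TRUE)
  q <- rownames(es$E)[idx[, 1L]]
  a <- colnames(es$E)[idx[, 2L]]
  keep <- q != a
  q <- q[keep]; a <- a[keep]; idx <- idx[keep, , drop = FALSE]
  df <- data.frame(gene_a = pmin(q, a), gene_b = pmax(q, a),
                   E = es$E[idx],
                   p = if (is.null(es$p)) NA_real_ else es$p[idx],
                   condition = es$condition, stringsAsFactors = FALSE)
  df <- df[!duplicated(pair_key(df$gene_a, df$gene_b)), , drop = FALSE]
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}
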