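## Differential (condition-specific) genetic interactions: pairs whose
## E-score differs between rich and minimal medium, with an empirical
## condition-swap null at the replicate level, classification into
## condition-specific classes, and per-bioprocess enrichment.

#' Differential E-scores between two conditions
#'
#' For every pair measured in both conditions, `dE = E_second - E_first`
#' (with the rich-like condition first, positive `dE` reads "more
#' alleviating under nutrient limitation"). The empirical null swaps
#' condition labels of the replicate-level measurements within each cell:
#' the pooled replicates of the two conditions are randomly re-partitioned
#' (respecting the per-condition replicate counts) and the differential
#' score recomputed with each condition's own fitness expectation and
#' regularizer, `null_size` times. Two-sided p-values use the plus-one
#' correction against the pooled null, leaving each cell's own resamples
#' out of its count so a strongly differential pair cannot dilute its own
#' significance. Internally the two conditions are put in a canonical
#' order, so swapping the arguments negates every `dE` and leaves |dE| and
#' `p_diff` unchanged. Pairs measured in one condition only are reported
#' separately, never silently dropped.
#'
#' @param es_first,es_second `escore_matrix` objects for the two conditions
#'   (rich-like first); gene axes must overlap.
#' @param null_size Condition-swap rounds (>= 10).
#' @param seed Seed.
#' @param keep_null Retain the pooled |null| values and per-cell own-null
#'   exceedance counts (for diagnostics; default FALSE).
#' @return Object of class `differential_result`: matrices `dE` and `p`
#'   over the shared axes, long-form `pairs` (`gene_a`, `gene_b`,
#'   `E_first`, `E_second`, `dE`, `p_diff`), `single_condition` table, and
#'   `conditions`.
#' @export
differential_scores <- function(es_first, es_second, null_size = 100L,
                                seed = 1L, keep_null = FALSE) {
  stopifnot(inherits(es_first, "escore_matrix"),
            inherits(es_second, "escore_matrix"))
  if (!is_count(null_size) || null_size < 10)
    stopf("null_size must be an integer >= 10")
  qs <- intersect(rownames(es_first$E), rownames(es_second$E))
  as_ <- intersect(colnames(es_first$E), colnames(es_second$E))
  if (length(qs) == 0L || length(as_) == 0L)
    stopf("the two matrices share no gene axes")

  ## canonical internal order: by condition label, then content checksum
  key <- function(es) paste(es$condition,
                            format(sum(es$E[is.finite(es$E)]), digits = 17))
  flip <- key(es_first) > key(es_second)
  A <- if (flip) es_second else es_first      # canonical first
  B <- if (flip) es_first else es_second

  EA <- A$E[qs, as_, drop = FALSE]; EB <- B$E[qs, as_, drop = FALSE]
  dE_canon <- EB - EA
  both <- is.finite(EA) & is.finite(EB)

  ## replicate-level condition-swap null
  RA <- A$screen$reps[qs, as_, , drop = FALSE]
  RB <- B$screen$reps[qs, as_, , drop = FALSE]
  nA <- A$screen$n_obs[qs, as_, drop = FALSE]
  nB <- B$screen$n_obs[qs, as_, drop = FALSE]
  expA <- A$fitness$query[qs] %o% A$fitness$array[as_]
  expB <- B$fitness$query[qs] %o% B$fitness$array[as_]
  sigA <- A$sigma_cell[qs, as_, drop = FALSE]
  sigB <- B$sigma_cell[qs, as_, drop = FALSE]
  valid <- which(both & nA >= 2L & nB >= 2L)
  ncell <- length(valid)
  if (ncell == 0L) stopf("no pair measured with >= 2 replicates in both conditions")

  flatA <- matrix(RA, ncol = dim(RA)[3L])[valid, , drop = FALSE]
  flatB <- matrix(RB, ncol = dim(RB)[3L])[valid, , drop = FALSE]
  pool_list <- lapply(seq_len(ncell), function(i) {
    sort(c(flatA[i, ][!is.na(flatA[i, ])], flatB[i, ][!is.na(flatB[i, ])]))
  })
  n1 <- nA[valid]; n2 <- nB[valid]
  grp <- paste(n1, n2)

  ## condition-swap null, conditional on each cell's observed score
  ## denominator (the permutation re-partitions the pooled replicate
  ## values; the standardization constants stay fixed, exactly as in the
  ## observed differential score)
  set.seed(seed)
  null_abs <- vector("list", null_size)
  own_cnt <- numeric(ncell)
  obs_abs <- abs(dE_canon[valid])
  for (g in unique(grp)) {
    gi <- which(grp == g)
    k1 <- n1[gi[1L]]; ktot <- k1 + n2[gi[1L]]
    combos <- utils::combn(ktot, k1)
    P <- do.call(rbind, pool_list[gi])               # |gi| x ktot, sorted
    rs <- rowSums(P)
    e1 <- expA[valid][gi]; e2 <- expB[valid][gi]
    sg1 <- sigA[valid][gi]; sg2 <- sigB[valid][gi]
    for (b in seq_len(null_size)) {
      pick <- sample.int(ncol(combos), length(gi), replace = TRUE)
      s1 <- numeric(length(gi))
      for (r in seq_len(k1))
        s1 <- s1 + P[cbind(seq_along(gi), combos[r, pick])]
      EA_n <- (s1 / k1 - e1) / sg1
      EB_n <- ((rs - s1) / (ktot - k1) - e2) / sg2
      dn <- abs(EB_n - EA_n)
      if (is.null(null_abs[[b]])) null_abs[[b]] <- numeric(0)
      null_abs[[b]] <- c(null_abs[[b]], dn)
      own_cnt[gi] <- own_cnt[gi] + (dn >= obs_abs[gi])
    }
  }
  pool <- sort(unlist(null_abs, use.names = FALSE))
  N <- length(pool)
  tot_cnt <- count_geq(obs_abs, pool)
  pv <- (1 + tot_cnt - own_cnt) / (1 + N - null_size)

  p <- matrix(NA_real_, length(qs), length(as_), dimnames = list(qs, as_))
  p[valid] <- pv
  dE <- dE_canon
  dE[!both] <- NA_real_

  if (flip) dE <- -dE
  idx <- which(both, arr.ind = TRUE)
  ga <- qs[idx[, 1L]]; gb <- as_[idx[, 2L]]
  keep <- ga != gb
  pairs <- data.frame(gene_a = pmin(ga, gb)[keep], gene_b = pmax(ga, gb)[keep],
                      E_first = (if (flip) EB else EA)[both][keep],
                      E_second = (if (flip) EA else EB)[both][keep],
                      dE = dE[both][keep], p_diff = p[both][keep],
                      stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pair_key(pairs$gene_a, pairs$gene_b)), , drop = FALSE]
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL

  one_only <- rbind(
    single_condition_pairs(es_first, es_second, qs, as_),
    single_condition_pairs(es_second, es_first, qs, as_))

  out <- structure(list(dE = dE, p = p, pairs = pairs,
                        single_condition = one_only,
                        conditions = c(first = es_first$condition,
                                       second = es_second$condition),
                        null_size = null_size, n_null = N, seed = seed),
                   class = "differential_result")
  if (keep_null) {
    out$null_abs <- pool
    out$own_count <- own_cnt
    out$obs_abs <- obs_abs
  }
  out
}

## pairs with a score in es_a but not in es_b, on the shared axes
single_condition_pairs <- function(es_a, es_b, qs, as_) {
  Ea <- es_a$E[qs, as_, drop = FALSE]; Eb <- es_b$E[qs, as_, drop = FALSE]
  only <- is.finite(Ea) & !is.finite(Eb)
  if (!any(only))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      condition = character(0), E = numeric(0),
                      stringsAsFactors = FALSE))
  idx <- which(only, arr.ind = TRUE)
  ga <- qs[idx[, 1L]]; gb <- as_[idx[, 2L]]
  keep <- ga != gb
  df <- data.frame(gene_a = pmin(ga, gb)[keep], gene_b = pmax(ga, gb)[keep],
                   condition = es_a$condition, E = Ea[only][keep],
                   stringsAsFactors = FALSE)
  df[!duplicated(pair_key(df$gene_a, df$gene_b)), , drop = FALSE]
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("differential_result [%s vs %s]: %d pairs tested, %d measured in one condition only\n",
              x$conditions["first"], x$conditions["second"],
              nrow(x$pairs), nrow(x$single_condition)))
  invisible(x)
}

#' Classify a pair's interaction change between conditions
#'
#' Deterministic map from the per-condition interaction statuses
#' (`"aggravating"`, `"neutral"`, `"alleviating"`; rich-like condition
#' first) to the differential class. Neutral in both conditions maps to NA
#' (no change to report); same sign in both maps to a conserved class;
#' the remaining combinations are the five differential classes, with
#' opposite signs mapping to `"sign-flip"` (e.g. aggravating in minimal
#' and alleviating in rich medium).
#'
#' @param status_rich,status_minimal Status vectors.
#' @return Character vector of classes.
#' @export
interaction_change_class <- function(status_rich, status_minimal) {
  stopifnot(length(status_rich) == length(status_minimal))
  valid <- c("aggravating", "neutral", "alleviating")
  if (!all(status_rich %in% valid) || !all(status_minimal %in% valid))
    stopf("statuses must be one of %s", paste(valid, collapse = ", "))
  out <- rep(NA_character_, length(status_rich))
  r <- status_rich; m <- status_minimal
  out[r == "aggravating" & m == "aggravating"] <- "conserved-aggravating"
  out[r == "alleviating" & m == "alleviating"] <- "conserved-alleviating"
  out[r == "neutral" & m == "aggravating"] <- "minimal-specific-aggravating"
  out[r == "neutral" & m == "alleviating"] <- "minimal-specific-alleviating"
  out[r == "aggravating" & m == "neutral"] <- "rich-specific-aggravating"
  out[r == "alleviating" & m == "neutral"] <- "rich-specific-alleviating"
  out[(r == "aggravating" & m == "alleviating") |
        (r == "alleviating" & m == "aggravating")] <- "sign-flip"
  out
}

differential_classes <- c("minimal-specific-aggravating",
                          "rich-specific-aggravating",
                          "minimal-specific-alleviating",
                          "rich-specific-alleviating", "sign-flip")

#' Classify differential pairs and test bioprocess enrichment
#'
#' Assigns every pair tested in both conditions its change class from the
#' per-condition interaction calls ([interaction_change_class()]); pairs
#' neutral in both conditions are not emitted. A pair is a differential
#' call when its class is condition-specific (not conserved) and its
#' BH-adjusted condition-swap p-value passes `fdr_q`. Bioprocess enrichment
#' of the differential calls weighs genes by their incident differential
#' pairs: each pair contributes both endpoints, contrasted against the
#' endpoints of all tested pairs by one-sided Fisher tests with BH
#' correction.
#'
#' @param diff A [differential_scores()] result.
#' @param edges_rich,edges_minimal Per-condition [call_interactions()]
#'   edges at the calibrated cutoffs.
#' @param annotations Gene -> bioprocess map.
#' @param fdr_q FDR level on the condition-swap p-values.
#' @param alpha Enrichment significance level.
#' @return List: `calls` (`gene_a`, `gene_b`, `E_rich`, `E_minimal`, `dE`,
#'   `p_diff`, `adj_p`, `class`, `differential`) and `enrichment`
#'   (per-bioprocess table).
#' @export
classify_and_enrich <- function(diff, edges_rich, edges_minimal, annotations,
                                fdr_q = 0.05, alpha = 0.05) {
  stopifnot(inherits(diff, "differential_result"))
  pairs <- diff$pairs
  pairs$adj_p <- bh_adjust(pairs$p_diff)
  pk <- pair_key(pairs$gene_a, pairs$gene_b)
  status_from <- function(edges) {
    st <- rep("neutral", nrow(pairs))
    if (nrow(edges) > 0L) {
      ek <- pair_key(edges$gene_a, edges$gene_b)
      hit <- match(pk, ek)
      st[!is.na(hit)] <- edges$sign[hit[!is.na(hit)]]
    }
    st
  }
  st_r <- status_from(edges_rich)
  st_m <- status_from(edges_minimal)
  cls <- interaction_change_class(st_r, st_m)
  calls <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                      E_rich = pairs$E_first, E_minimal = pairs$E_second,
                      dE = pairs$dE, p_diff = pairs$p_diff,
                      adj_p = pairs$adj_p, class = cls,
                      stringsAsFactors = FALSE)
  calls <- calls[!is.na(calls$class), , drop = FALSE]
  calls$differential <- calls$class %in% differential_classes &
    calls$adj_p <= fdr_q
  rownames(calls) <- NULL

  ## per-bioprocess enrichment of differential-pair endpoints
  ann <- as_annotation(annotations)
  diff_genes <- c(calls$gene_a[calls$differential],
                  calls$gene_b[calls$differential])
  all_genes <- c(pairs$gene_a, pairs$gene_b)
  dl <- ann[diff_genes]; al <- ann[all_genes]
  dl <- dl[!is.na(dl)]; al <- al[!is.na(al)]
  labs <- sort(unique(al))
  enr <- data.frame(bioprocess = labs, n_diff = NA_integer_,
                    n_total = NA_integer_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(labs)) {
    a <- sum(dl == labs[k]); b <- length(dl) - a
    cc <- sum(al == labs[k]) - a; dd <- (length(al) - sum(al == labs[k])) - b
    enr$n_diff[k] <- a
    enr$n_total[k] <- sum(al == labs[k])
    enr$p[k] <- stats::fisher.test(matrix(c(a, b, cc, dd), 2L, byrow = TRUE),
                                   alternative = "greater")$p.value
  }
  enr$adj_p <- bh_adjust(enr$p)
  enr$enriched <- enr$adj_p <= alpha
  list(calls = calls, enrichment = enr)
}
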