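# Independent brute-force oracles used to cross-check the statistical
# routines the package delegates to. These are deliberately naive
# implementations (direct pmf summation, full enumeration, all-pairs BFS).

pkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# one-sided (enrichment) Fisher p by direct hypergeometric pmf summation
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b          # white balls (row 1)
  n <- c + d          # black balls
  k <- a + c          # drawn (col 1)
  lo <- max(0L, k - n); hi <- min(k, m)
  sum(dhyper(a:hi, m, n, k))
}

# two-sided Fisher p: sum of all table probabilities not exceeding the
# observed one (with the same relative tolerance R's fisher.test uses)
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up, written out longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

# two-sample KS statistic as the maximal ECDF gap over all data points
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# exact normalized betweenness by all-pairs BFS shortest-path counting
oracle_betweenness <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  n <- length(nodes)
  adj <- lapply(setNames(vector("list", n), nodes), function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    if (a == b || b %in% adj[[a]]) next
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- nsp <- matrix(0, n, n, dimnames = list(nodes, nodes))
  dist[] <- Inf
  for (s in nodes) {
    dist[s, s] <- 0; nsp[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(dist[s, w])) {
          dist[s, w] <- dist[s, v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[s, w] == dist[s, v] + 1)
          nsp[s, w] <- nsp[s, w] + nsp[s, v]
      }
      frontier <- unique(nxt)
    }
  }
  btw <- setNames(numeric(n), nodes)
  for (s in nodes) for (t in nodes) if (s < t && is.finite(dist[s, t])) {
    for (v in nodes) {
      if (v == s || v == t) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t])
        btw[v] <- btw[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}
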