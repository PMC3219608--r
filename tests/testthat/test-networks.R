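test_that("interaction calls respect cutoffs exactly", {
  set.seed(9)
  genes_q <- sprintf("q%02d", 1:50)
  genes_a <- sprintf("a%02d", 1:50)
  E <- matrix(rnorm(2500, 0, 1.5), 50, 50, dimnames = list(genes_q, genes_a))
  E[2, 5] <- -2.0      # boundary: inclusive per the <= / >= convention
  p <- matrix(1e-4, 50, 50, dimnames = dimnames(E))
  es <- toy_escores(E, p = p)

  edges <- call_interactions(es, cutoffs = c(-2, 2), use_fdr = FALSE)
  # brute-force double loop over the matrix
  cnt <- 0
  for (i in 1:50) for (j in 1:50) {
    if (is.finite(E[i, j]) && (E[i, j] <= -2 || E[i, j] >= 2)) cnt <- cnt + 1
  }
  expect_equal(nrow(edges), cnt)
  expect_true(pkey("q02", "a05") %in% pkey(edges$gene_a, edges$gene_b))
  expect_identical(edges$sign[pkey(edges$gene_a, edges$gene_b) ==
                                pkey("q02", "a05")], "aggravating")
  expect_true(all(edges$E <= -2 | edges$E >= 2))

  # all sub-threshold: an empty network is a valid result
  es0 <- toy_escores(E * 0.1, p = p)
  expect_equal(nrow(call_interactions(es0, use_fdr = FALSE)), 0L)

  # perturbing one score across the boundary changes exactly that call
  E2 <- E; E2[7, 9] <- 2.5
  stopifnot(abs(E[7, 9]) < 2)
  e1 <- call_interactions(toy_escores(E, p = p), use_fdr = FALSE)
  e2 <- call_interactions(toy_escores(E2, p = p), use_fdr = FALSE)
  expect_equal(nrow(e2), nrow(e1) + 1L)
  expect_setequal(setdiff(pkey(e2$gene_a, e2$gene_b), pkey(e1$gene_a, e1$gene_b)),
                  pkey("q07", "a09"))

  # the FDR gate removes high-p calls
  p3 <- p; p3[E <= -2 | E >= 2] <- 0.9
  expect_equal(nrow(call_interactions(toy_escores(E, p = p3), fdr_q = 0.05)), 0L)
})

test_that("crosstalk enrichment flags a planted module bridge", {
  genes <- sprintf("g%02d", 1:40)
  ann <- setNames(rep(c("division", "secretion", "transport", "LPS"),
                      each = 10), genes)
  grid <- expand.grid(i = 1:40, j = 1:40)
  grid <- grid[grid$i < grid$j, ]
  universe <- data.frame(gene_a = genes[grid$i], gene_b = genes[grid$j],
                         stringsAsFactors = FALSE)
  # aggravating bridge between division and secretion
  bridge <- universe[ann[universe$gene_a] == "division" &
                       ann[universe$gene_b] == "secretion", ][1:25, ]
  bridge$sign <- "aggravating"
  scatter <- universe[seq(3, nrow(universe), by = 37), ]
  scatter$sign <- "alleviating"
  edges <- rbind(bridge, scatter)

  ct <- crosstalk_matrix(edges, universe, ann)
  agg <- ct$aggravating
  hit <- (agg$label_a == "division" & agg$label_b == "secretion") |
    (agg$label_a == "secretion" & agg$label_b == "division")
  expect_true(agg$enriched[hit])
  expect_false(any(agg$enriched[!hit], na.rm = TRUE))
  # symmetric under label order; empty input gives no significance
  expect_equal(nrow(agg), nrow(ct$alleviating))
  empty <- crosstalk_matrix(edges[0, ], universe, ann)
  expect_false(any(empty$aggravating$enriched, na.rm = TRUE))
})

test_that("topology statistics match closed forms and a BFS oracle", {
  # star on 6 nodes
  star <- data.frame(gene_a = "hub", gene_b = paste0("leaf", 1:5),
                     stringsAsFactors = FALSE)
  ts <- topology_stats(star)
  expect_equal(ts$degree[ts$gene == "hub"], 5)
  expect_equal(ts$betweenness[ts$gene == "hub"], 1.0)
  expect_true(all(ts$betweenness[ts$gene != "hub"] == 0))

  # empty graph
  expect_equal(nrow(topology_stats(star[0, ])), 0L)

  # random 30-node graphs against all-pairs BFS path counting
  set.seed(4)
  for (rep in 1:3) {
    nodes <- sprintf("n%02d", 1:30)
    pairs <- t(combn(nodes, 2))
    sel <- runif(nrow(pairs)) < 0.12
    g <- data.frame(gene_a = pairs[sel, 1], gene_b = pairs[sel, 2],
                    stringsAsFactors = FALSE)
    ts <- topology_stats(g)
    oracle <- oracle_betweenness(g)
    expect_equal(ts$betweenness[match(names(oracle), ts$gene)],
                 unname(oracle), tolerance = 1e-9)
    deg_oracle <- table(c(g$gene_a, g$gene_b))
    expect_equal(ts$degree[match(names(deg_oracle), ts$gene)],
                 as.integer(deg_oracle))
  }
})

test_that("group contrasts agree with exact enumeration", {
  # Fisher ratio on [[3,1],[1,3]] equals exhaustive fixed-margin enumeration
  edges <- data.frame(
    gene_a = c("e1", "e2", "e3", "e4", "n1", "n2", "n3", "n4"),
    gene_b = c("e5", "e6", "e7", "e8", "n5", "n6", "n7", "n8"),
    sign = c("alleviating", "alleviating", "alleviating", "aggravating",
             "alleviating", "aggravating", "aggravating", "aggravating"),
    stringsAsFactors = FALSE)
  groups <- setNames(rep(c("essential", "nonessential"), each = 8),
                     c(paste0("e", 1:8), paste0("n", 1:8)))
  res <- group_compare(edges, groups, test = "fisher_ratio")
  expect_equal(res$p.value, oracle_fisher_two_sided(3, 1, 1, 3),
               tolerance = 1e-12)

  # identical degree samples: D = 0, p ~ 1
  topo <- data.frame(gene = c(paste0("e", 1:6), paste0("n", 1:6)),
                     degree = rep(c(2, 3, 5, 5, 8, 13), 2),
                     betweenness = 0, stringsAsFactors = FALSE)
  ks <- group_compare(topo, groups = setNames(rep(c("essential", "nonessential"),
                                                  each = 6), topo$gene),
                      test = "ks")
  expect_equal(ks$statistic, 0)
  expect_gt(ks$p.value, 0.99)
  wx <- group_compare(topo, groups = setNames(rep(c("essential", "nonessential"),
                                                  each = 6), topo$gene),
                      test = "wilcoxon")
  expect_gt(wx$p.value, 0.99)

  # disjoint supports: D = 1
  topo2 <- data.frame(gene = c("a", "b", "c", "x", "y", "z"),
                      degree = c(1, 2, 3, 4, 5, 6), betweenness = 0,
                      stringsAsFactors = FALSE)
  ks2 <- group_compare(topo2, setNames(rep(c("g1", "g2"), each = 3),
                                       topo2$gene), test = "ks")
  expect_equal(ks2$statistic, 1)
  expect_error(group_compare(topo2, setNames(rep("g1", 6), topo2$gene)),
               "2 levels")
})

test_that("essential genes with boosted interaction rates emerge as hubs", {
  tr <- generate_ground_truth(n_genes = 150, n_modules = 5,
                              within_rate = 0.2, between_rate = 0.02,
                              essential_fraction = 0.3, essential_boost = 2.2,
                              conditions = "rich", seed = 41)
  scr <- sim_processed_screen(tr, n_query = 50, seed = 42,
                              noise = noise_model(seed = 43))
  es <- attach_pvalues(compute_escores(scr, estimate_single_fitness(scr)),
                       null_size = 50, seed = 44)
  edges <- call_interactions(es)
  topo <- topology_stats(edges)
  grp <- ifelse(tr$essential, "essential", "nonessential")
  res <- group_compare(topo, grp, test = "wilcoxon")
  expect_lt(res$p.value, 0.01)
  expect_gt(res$medians[1], res$medians[2])   # essential median degree higher
})
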