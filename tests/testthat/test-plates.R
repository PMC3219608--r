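make_plate <- function(n_rows, n_cols, sizes, plate = "p1", condition = "rich",
                       replicate = 1) {
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  data.frame(query = "q1", array = sprintf("a%03d", seq_len(nrow(grid))),
             plate = plate, row = grid$row, col = grid$col,
             replicate = replicate, condition = condition, size = sizes,
             missing_flag = as.integer(is.na(sizes)), stringsAsFactors = FALSE)
}

test_that("colony tables round-trip and reject malformed input", {
  df <- make_plate(4, 6, rnorm(24, 1000, 50))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_colony_table(df, path)
  back <- read_colony_table(path)
  expect_equal(back$size, df$size)
  expect_identical(back$array, df$array)

  # single valid row
  one <- df[1, ]
  write_colony_table(one, path)
  expect_equal(nrow(read_colony_table(path)), 1L)

  # duplicate key reported with line numbers
  dup <- rbind(df, df[3, ])
  write_colony_table(dup, path)
  expect_error(read_colony_table(path), "duplicate.*4.*26|duplicate")

  # unknown columns preserved on write-through
  df$batch <- "B7"
  write_colony_table(df, path)
  expect_identical(read_colony_table(path)$batch, df$batch)

  # condition parsed from a colonies_<condition>.tsv filename
  p2 <- file.path(withr::local_tempdir(), "colonies_minimal.tsv")
  write_colony_table(df[setdiff(names(df), "condition")], p2)
  expect_identical(unique(read_colony_table(p2)$condition), "minimal")
})

test_that("normalization fixes scale, gradients and edge inflation", {
  # uniform plate: every corrected size is exactly 1
  uni <- make_plate(8, 12, rep(731.5, 96))
  out <- normalize_plate(uni)
  expect_equal(out$size, rep(1, 96), tolerance = 1e-12)

  # injected multiplicative row effect: post-normalization slope ~ 0
  set.seed(42)
  grid <- expand.grid(row = 1:32, col = 1:48)
  sizes <- 1000 * (1 + 0.02 * grid$row) * exp(rnorm(nrow(grid), 0, 0.05))
  df <- make_plate(32, 48, sizes)
  out <- normalize_plate(df)
  slope <- coef(lm(log(size) ~ row, data = out))["row"]
  expect_lt(abs(slope), 0.002)

  # edge ring inflated 1.5x on an otherwise uniform plate
  edge <- grid$row %in% c(1, 32) | grid$col %in% c(1, 48)
  df2 <- make_plate(32, 48, 900 * ifelse(edge, 1.5, 1))
  out2 <- normalize_plate(df2)
  expect_lt(abs(median(out2$size[edge]) / median(out2$size[!edge]) - 1), 0.02)

  # missing stays missing; heavily missing plates are rejected
  sizes3 <- rep(800, 48); sizes3[c(3, 17)] <- NA
  out3 <- normalize_plate(make_plate(6, 8, sizes3))
  expect_identical(which(is.na(out3$size)), c(3L, 17L))
  expect_error(normalize_plate(make_plate(6, 8, c(rep(NA, 30), rep(800, 18)))),
               "rejected")
  res <- normalize_colonies(make_plate(6, 8, c(rep(NA, 30), rep(800, 18))))
  expect_identical(res$plate_qc$status, "rejected_missing")
  expect_equal(nrow(res$records), 0L)
})

test_that("normalization is idempotent and scale invariant", {
  set.seed(7)
  grid <- expand.grid(row = 1:16, col = 1:24)
  edge <- grid$row %in% c(1, 16) | grid$col %in% c(1, 24)
  sizes <- 950 * exp(0.01 * (grid$row - 8.5)) * ifelse(edge, 1.15, 1) *
    exp(rnorm(nrow(grid), 0, 0.1))
  sizes[sample(length(sizes), 20)] <- NA
  df <- make_plate(16, 24, sizes)

  once <- normalize_plate(df)
  twice <- normalize_plate(once)
  rel <- abs(twice$size - once$size) / pmax(abs(once$size), 1e-9)
  expect_lt(max(rel, na.rm = TRUE), 1e-9)

  df_scaled <- df; df_scaled$size <- df$size * 123.456
  out_scaled <- normalize_plate(df_scaled)
  expect_equal(out_scaled$size, once$size, tolerance = 1e-6)
})

test_that("replicate QC flags incoherent screens and pinning failures", {
  set.seed(11)
  arrays <- sprintf("a%03d", 1:200)
  wj <- runif(200, 0.5, 1.2)
  build <- function(query, sizes_by_rep, condition = "rich") {
    do.call(rbind, lapply(seq_along(sizes_by_rep), function(r) {
      data.frame(query = query, array = arrays, plate = paste0(query, ":r", r),
                 row = rep(1:10, 20), col = rep(1:20, each = 10), replicate = r,
                 condition = condition, size = sizes_by_rep[[r]],
                 missing_flag = as.integer(is.na(sizes_by_rep[[r]])),
                 stringsAsFactors = FALSE)
    }))
  }
  # coherent screen: replicates share the fitness signal
  good <- build("q1", lapply(1:3, function(r) wj * exp(rnorm(200, 0, 0.1))))
  # one replicate replaced by independent noise kills the mean correlation
  bad <- build("q2", list(wj * exp(rnorm(200, 0, 0.1)),
                          exp(rnorm(200, 0, 0.3)),
                          exp(rnorm(200, 0, 0.3))))
  qc <- qc_filter(rbind(good, bad))
  expect_identical(qc$report$decision[qc$report$query == "q1"], "keep")
  expect_identical(qc$report$decision[qc$report$query == "q2"], "exclude")
  expect_false("q2" %in% qc$records$query)

  # identical replicates: r = 1, nothing excluded
  same <- build("q3", rep(list(wj), 3))
  qc2 <- qc_filter(same)
  expect_equal(qc2$report$r, 1)
  expect_identical(qc2$report$decision, "keep")
  expect_equal(attr(qc2$report, "n_pinning_failures"), 0L)

  # a colony small in exactly one replicate is a pinning failure
  pin <- build("q4", rep(list(wj), 3))
  pin$size[pin$replicate == 2 & pin$array == "a005"] <- 0.01
  qc3 <- qc_filter(pin)
  expect_true(is.na(qc3$records$size[qc3$records$replicate == 2 &
                                       qc3$records$array == "a005"]))
  expect_equal(attr(qc3$report, "n_pinning_failures"), 1L)
  # but a colony dead in every replicate is kept (true synthetic lethal)
  dead <- build("q5", rep(list(replace(wj, 7, 0.001)), 3))
  qc4 <- qc_filter(dead)
  expect_false(any(is.na(qc4$records$size[qc4$records$array == "a007"])))
})

test_that("linkage masking uses circular distance and a brute-force scan agrees", {
  genes <- sprintf("g%02d", 1:40)
  set.seed(3)
  L <- 4641652
  pos <- setNames(sort(sample.int(L, 40)), genes)

  # window 0: only the query itself
  expect_identical(mask_linked("g05", genes, pos, window_bp = 0), "g05")

  # a gene 10 kb away is masked at a 30 kb window
  pos2 <- setNames(c(100000, 110000), c("q", "a"))
  expect_setequal(mask_linked("q", c("q", "a"), pos2), c("q", "a"))
  # circular wrap: distance across the origin counts
  pos3 <- setNames(c(5000, L - 5000), c("q", "a"))
  expect_true("a" %in% mask_linked("q", c("q", "a"), pos3))

  # random positions: masked set equals a linear scan oracle
  for (q in genes[c(1, 17, 40)]) {
    d <- abs(pos - pos[q]); d <- pmin(d, L - d)
    oracle <- union(q, genes[d <= 30000])
    expect_setequal(mask_linked(q, genes, pos, 30000, L), oracle)
  }
  # missing position: left unmasked with a warning
  pos_na <- pos; pos_na <- pos_na[-2]
  expect_warning(mk <- mask_linked(genes[1], genes, pos_na), "unmasked")
  expect_false(is.na(match(genes[1], mk)))
})

test_that("screen-matrix aggregation matches brute-force group means", {
  # replicate pair {0.9, 1.1}: mean 1.0, sd ~ 0.1414
  rec <- data.frame(query = "q1", array = "a1", plate = c("p:r1", "p:r2"),
                    row = 1, col = 1, replicate = 1:2, condition = "rich",
                    size = c(0.9, 1.1), missing_flag = 0L,
                    stringsAsFactors = FALSE)
  scr <- build_screen_matrix(rec)
  expect_equal(scr$W["q1", "a1"], 1.0)
  expect_equal(scr$sd["q1", "a1"], sqrt(0.02), tolerance = 1e-12)
  expect_equal(scr$n_obs["q1", "a1"], 2L)

  # aggregate of a simulated table equals an independent groupby-mean
  tr <- generate_ground_truth(n_genes = 30, n_modules = 2, seed = 5)
  rec2 <- simulate_screens(tr, layout = plate_layout(tr$genes[11:30]),
                           noise = quiet_noise(dropout = 0.15, seed = 6),
                           queries = tr$genes[1:10], conditions = "rich")
  scr2 <- build_screen_matrix(rec2)
  agg <- aggregate(size ~ query + array, data = rec2, FUN = mean,
                   na.action = na.omit)
  for (i in sample(nrow(agg), 25)) {
    expect_equal(scr2$W[agg$query[i], agg$array[i]], agg$size[i],
                 tolerance = 1e-12)
  }
  # all-missing cells carry no observations
  allna <- rec2[rec2$query == "g0001" & rec2$array == "g0011", ]
  if (all(is.na(allna$size))) expect_equal(scr2$n_obs["g0001", "g0011"], 0L)

  # self pairs are always masked; masking removes, never alters
  tr3 <- generate_ground_truth(n_genes = 25, n_modules = 2, seed = 9)
  rec3 <- simulate_screens(tr3, noise = quiet_noise(seed = 10),
                           conditions = "rich")
  scr3 <- build_screen_matrix(rec3, positions_bp = tr3$position_bp,
                              window_bp = 50000)
  expect_true(all(is.na(diag(scr3$W[tr3$genes, tr3$genes]))))
  scr3b <- build_screen_matrix(rec3)   # no linkage masking
  unmasked_both <- !scr3$mask & !scr3b$mask & !is.na(scr3$W)
  expect_equal(scr3$W[unmasked_both], scr3b$W[unmasked_both])
})
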