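test_that("ground-truth generation is deterministic and respects edge rates", {
  # fixed seed => identical networks
  t1 <- generate_ground_truth(n_genes = 60, n_modules = 3, seed = 7)
  t2 <- generate_ground_truth(n_genes = 60, n_modules = 3, seed = 7)
  expect_identical(t1, t2)

  # zero rates force an empty interaction map
  t0 <- generate_ground_truth(n_genes = 40, n_modules = 2,
                              within_rate = 0, between_rate = 0, seed = 1)
  expect_equal(nrow(t0$interactions), 0L)

  # within-module pair-edge count inside the central 99% binomial interval
  tr <- generate_ground_truth(n_genes = 100, n_modules = 5,
                              within_rate = 0.2, between_rate = 0.01, seed = 7)
  same <- tr$module[tr$interactions$gene_a] == tr$module[tr$interactions$gene_b]
  n_within <- length(unique(pkey(tr$interactions$gene_a,
                                 tr$interactions$gene_b)[same]))
  pairs_within <- 5 * choose(20, 2)
  bounds <- qbinom(c(0.005, 0.995), pairs_within, 0.2)
  expect_gte(n_within, bounds[1])
  expect_lte(n_within, bounds[2])

  # invariants: unordered storage, zero effects never stored, genes known
  expect_true(all(tr$interactions$gene_a < tr$interactions$gene_b))
  expect_true(all(tr$interactions$effect != 0))
  expect_true(all(c(tr$interactions$gene_a, tr$interactions$gene_b) %in% tr$genes))
  expect_true(all(tr$single_fitness > 0))

  # parameter validation
  expect_error(generate_ground_truth(n_genes = 10, n_modules = 2,
                                     within_rate = 0.1, between_rate = 0.5),
               "within_rate")
  expect_error(generate_ground_truth(n_genes = 3, n_modules = 2), "n_genes")
})

test_that("simulated colony sizes follow the multiplicative model", {
  tr <- generate_ground_truth(n_genes = 30, n_modules = 2,
                              within_rate = 0, between_rate = 0, seed = 3)
  # pin two fitness values and check the exact noiseless product
  tr$single_fitness[c("g0001", "g0011")] <- c(0.8, 0.5)
  rec <- simulate_screens(tr, layout = plate_layout(tr$genes[11:30]),
                          noise = quiet_noise(cv = 0), queries = tr$genes[1:10],
                          conditions = "rich", base_size = 1000)
  hit <- rec[rec$query == "g0001" & rec$array == "g0011", ]
  expect_equal(unique(hit$size), 400, tolerance = 1e-12)

  # conservation: queries x arrays x replicates records, dropouts flagged
  tr2 <- generate_ground_truth(n_genes = 30, n_modules = 2, seed = 4)
  rec2 <- simulate_screens(tr2, layout = plate_layout(tr2$genes[11:30]),
                           noise = quiet_noise(dropout = 0.2, seed = 9),
                           queries = tr2$genes[1:10], conditions = "rich")
  expect_equal(nrow(rec2), 10 * 20 * 3)
  expect_true(any(rec2$missing_flag == 1L))
  expect_identical(is.na(rec2$size), rec2$missing_flag == 1L)
})

test_that("planted spatial gradients are recoverable by regression", {
  tr <- generate_ground_truth(n_genes = 1600, n_modules = 2,
                              within_rate = 0, between_rate = 0, seed = 5)
  nn <- noise_model(multiplicative_cv = 0.05, row_gradient = 0.02,
                    col_gradient = 0, edge_boost = 0, dropout_rate = 0)
  rec <- simulate_screens(tr, layout = plate_layout(tr$genes[-1]),
                          noise = nn, queries = tr$genes[1], conditions = "rich",
                          seed = 11)
  fit <- lm(log(size) ~ row, data = rec[!is.na(rec$size), ])
  slope <- coef(fit)["row"]
  se <- summary(fit)$coefficients["row", "Std. Error"]
  expect_lt(abs(slope - 0.02), 3 * se)
})

test_that("planted deviations are realized on the multiplicative scale", {
  # mean realized log-size deviation of interacting pairs matches the
  # planted log(1 + delta) within Monte-Carlo error (>1000 colonies)
  tr <- generate_ground_truth(n_genes = 80, n_modules = 2,
                              within_rate = 0.5, between_rate = 0.2,
                              lethal_fraction = 0, conditions = "rich", seed = 13)
  rec <- simulate_screens(tr, layout = plate_layout(tr$genes[41:80]),
                          noise = quiet_noise(seed = 14), queries = tr$genes[1:40],
                          conditions = "rich")
  intr <- tr$interactions
  ik <- pkey(intr$gene_a, intr$gene_b)
  rk <- pkey(rec$query, rec$array)
  m <- match(rk, ik)
  sel <- !is.na(m) & !is.na(rec$size)
  expect_gt(sum(sel), 1000)
  ldev <- log(rec$size[sel]) -
    log(1000 * tr$single_fitness[rec$query[sel]] *
          tr$single_fitness[rec$array[sel]]) -
    log(1 + intr$effect[m[sel]])
  # lognormal noise is mean-one, so log residuals center at -sdlog^2/2
  sdlog <- sqrt(log(1 + 0.1^2))
  expect_lt(abs(mean(ldev) + sdlog^2 / 2), 4 * sd(ldev) / sqrt(sum(sel)))
})

test_that("fixtures round-trip losslessly through the colony-table reader", {
  tr <- generate_ground_truth(n_genes = 90, n_modules = 2, seed = 21)
  rec <- simulate_screens(tr, layout = plate_layout(tr$genes[31:90]),
                          noise = quiet_noise(dropout = 0.1, seed = 22),
                          queries = tr$genes[1:30])
  expect_gte(nrow(rec), 10000)
  dir <- withr::local_tempdir()
  write_fixture(tr, rec, dir)
  back <- read_fixture(dir)
  for (cond in c("rich", "minimal")) {
    a <- rec[rec$condition == cond, ]
    b <- back$records[back$records$condition == cond, ]
    ka <- paste(a$plate, a$row, a$col, a$replicate)
    kb <- paste(b$plate, b$row, b$col, b$replicate)
    expect_setequal(ka, kb)
    m <- match(ka, kb)
    expect_equal(a$size, b$size[m], tolerance = 1e-9)
    expect_identical(a$query, b$query[m])
    expect_identical(a$array, b$array[m])
  }
  expect_equal(back$edges, tr$interactions)

  # a truth with no interactions still writes a parseable empty edge table
  t0 <- generate_ground_truth(n_genes = 30, n_modules = 2,
                              within_rate = 0, between_rate = 0, seed = 1)
  rec0 <- simulate_screens(t0, layout = plate_layout(t0$genes[16:30]),
                           noise = quiet_noise(), queries = t0$genes[1:15],
                           conditions = "rich", seed = 2)
  dir0 <- withr::local_tempdir()
  write_fixture(t0, rec0, dir0)
  expect_equal(nrow(read_fixture(dir0)$edges), 0L)
})

test_that("synthetic lethality produces a detached left score mode", {
  # generator defaults plant a synthetic-lethal fraction; downstream scores
  # must show far-left mass well beyond the Gaussian expectation of the
  # central peak
  tr <- generate_ground_truth(n_genes = 120, n_modules = 6, seed = 31)
  scr <- sim_processed_screen(tr, n_query = 40, seed = 32,
                              noise = noise_model(seed = 33))
  es <- compute_escores(scr, estimate_single_fitness(scr))
  E <- es$E[is.finite(es$E)]
  centre <- median(E); spread <- mad(E)
  observed_left <- sum(E < -5)
  expected_gauss <- length(E) * pnorm(-5, mean = centre, sd = spread)
  expect_gte(observed_left, 3)
  expect_gt(observed_left, 10 * expected_gauss)
})
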