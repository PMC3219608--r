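## Synthetic eSGA screen generator: planted ground-truth interaction networks
## and raw colony-size tables with the statistical structure real screens
## show (multiplicative fitness, bimodal E-score tails, module structure,
## condition rewiring, plate artifacts, pinning dropout, replicate noise).

#' Curated bioprocess labels used by the generator
#'
#' Twenty broad functional categories in the style of curated envelope
#' bioprocess annotations. The generator assigns module labels from this
#' list; real analyses supply their own annotation map.
#'
#' @return Character vector of 20 labels.
#' @export
bioprocess_labels <- function() {
  c("cell wall biogenesis", "LPS biosynthesis", "cell division",
    "protein secretion", "outer membrane assembly", "lipid metabolism",
    "peptidoglycan hydrolysis", "membrane transport",
    "chaperones and stress response", "DNA replication and repair",
    "chromosome segregation", "transcription regulation", "translation",
    "energy metabolism", "amino acid metabolism", "nucleotide metabolism",
    "iron acquisition", "motility and chemotaxis", "signal transduction",
    "cofactor biosynthesis")
}

#' Replicate/plate noise model for simulated screens
#'
#' @param multiplicative_cv Coefficient of variation of lognormal replicate
#'   noise (fraction of colony size).
#' @param row_gradient Log-linear growth gradient per plate row: a colony in
#'   row `r` is scaled by `exp(row_gradient * (r - midrow))`.
#' @param col_gradient Same, per column.
#' @param edge_boost Multiplicative inflation `(1 + edge_boost)` applied to
#'   the outermost ring of colonies (edge colonies face less nutrient
#'   competition and grow larger).
#' @param dropout_rate Probability that a colony fails to pin; its size is
#'   emitted as missing, never silently dropped.
#' @param seed Optional integer seed used by [simulate_screens()].
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_cv = 0.1, row_gradient = 0.01,
                        col_gradient = 0.01, edge_boost = 0.2,
                        dropout_rate = 0.1, seed = NULL) {
  for (nm in c("multiplicative_cv", "row_gradient", "col_gradient",
               "edge_boost", "dropout_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stopf("noise_model: '%s' must be a single non-negative number", nm)
  }
  if (dropout_rate >= 0.5) stopf("noise_model: dropout_rate must be < 0.5")
  structure(list(multiplicative_cv = multiplicative_cv,
                 row_gradient = row_gradient, col_gradient = col_gradient,
                 edge_boost = edge_boost, dropout_rate = dropout_rate,
                 seed = seed),
            class = "noise_model")
}

#' Grid layout of array genes on replicate plates
#'
#' Assigns each array gene a fixed (plate, row, column) position, identical
#' across replicate plates. By default the grid is the 1536-format 32 x 48
#' when the array is large enough to fill it; smaller arrays get a compact
#' grid with roughly 2:3 aspect so spatial-artifact correction still has a
#' meaningful interior.
#'
#' @param arrays Character vector of array gene identifiers.
#' @param n_rows,n_cols Grid dimensions; defaults chosen from the array size.
#' @param replicates Number of replicate plates (>= 2).
#' @param seed Seed for the (deterministic) randomized placement of genes on
#'   the grid, so genomic neighbours do not share plate rows.
#' @return An object of class `plate_layout`: data.frame with columns
#'   `array`, `plate`, `row`, `col`, plus attributes `n_rows`, `n_cols`,
#'   `replicates`.
#' @export
plate_layout <- function(arrays, n_rows = NULL, n_cols = NULL,
                         replicates = 3L, seed = 1L) {
  n <- length(arrays)
  if (n < 1L) stopf("plate_layout: no array genes supplied")
  if (anyDuplicated(arrays)) stopf("plate_layout: duplicate array genes")
  if (!is_count(replicates) || replicates < 2)
    stopf("plate_layout: replicates must be an integer >= 2")
  if (is.null(n_rows) || is.null(n_cols)) {
    if (n >= 1152L) {             # >= 75% of a 1536 plate
      n_rows <- 32L; n_cols <- 48L
    } else {
      n_rows <- max(2L, ceiling(sqrt(n / 1.5)))
      n_cols <- max(2L, ceiling(n / n_rows))
    }
  }
  per_plate <- n_rows * n_cols
  n_plates <- ceiling(n / per_plate)
  ord <- withr_seed(seed, sample.int(n))
  pos <- (seq_len(n) - 1L)
  within <- pos %% per_plate
  layout <- data.frame(
    array = arrays[ord],
    plate = pos %/% per_plate + 1L,
    row   = within %/% n_cols + 1L,
    col   = within %% n_cols + 1L,
    stringsAsFactors = FALSE
  )
  layout <- layout[order(layout$array), , drop = FALSE]
  rownames(layout) <- NULL
  structure(layout, n_rows = n_rows, n_cols = n_cols,
            replicates = as.integer(replicates), class = c("plate_layout", "data.frame"))
}

## evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Multiplicative deviation needed to plant a target E-score
#'
#' Because the final score surface is standardized to unit central spread,
#' an E-score of `k` means a deviation of about `k` standard errors of the
#' replicate mean: for a pair of typical fitness, the mean of `n_rep`
#' replicates at coefficient of variation `cv` has relative standard error
#' `cv / sqrt(n_rep)`, so a planted multiplicative deviation
#' `delta = target_e * cv / sqrt(n_rep)` lands near the target score. The
#' relation is first-order (plate normalization, dropout and
#' fitness-estimation error move the realized scale by some tens of
#' percent); the generator's calibration test measures the realized scores.
#'
#' For scores kept in raw `sigma_hat` units
#' (`compute_escores(standardize = FALSE)`), the denominator is
#' `sigma_hat ~ cv * sqrt(1 + 1/n_rep)` (replicate scatter plus the modal-SD
#' regularizer), so the deviation for a target score is
#' `target_e * cv * sqrt(1 + 1/n_rep)`.
#'
#' @param target_e Target E-score (signed).
#' @param cv Replicate coefficient of variation of the noise model.
#' @param n_rep Number of replicates.
#' @param scale `"standardized"` (default; unit central spread surface) or
#'   `"sigma"` (raw `sigma_hat` units).
#' @return Deviation `delta` such that `1 + delta` is the planted factor.
#' @export
planted_effect_for_escore <- function(target_e, cv = 0.1, n_rep = 3L,
                                      scale = c("standardized", "sigma")) {
  scale <- match.arg(scale)
  if (scale == "standardized") target_e * cv / sqrt(n_rep)
  else target_e * cv * sqrt(1 + 1 / n_rep)
}

#' Generate a ground-truth genetic interaction network
#'
#' Plants a module-structured interaction network: genes are partitioned into
#' bioprocess modules, pairs within a module interact with probability
#' `within_rate`, pairs across modules with `between_rate`. Interactions are
#' signed (aggravating = negative deviation, alleviating = positive), a
#' fraction of aggravating pairs are synthetic-lethal (double-mutant fitness
#' forced to ~0, producing the detached left mode of the E-score
#' distribution), and each interacting pair is assigned one of four
#' condition classes (both conditions, first-only, second-only, sign-flip) so
#' downstream differential analysis has planted rewiring to recover.
#'
#' @param n_genes Number of genes (>= 2 * n_modules).
#' @param n_modules Number of bioprocess modules (1..20).
#' @param within_rate,between_rate Interaction probability for within-module
#'   and between-module pairs (`within_rate >= between_rate`).
#' @param effect_dist Parameters of the planted effect-size distribution:
#'   list with `mean_aggravating` (negative), `mean_alleviating` (positive),
#'   `sd`, and `prob_aggravating`. The default magnitude is three replicate
#'   standard deviations on the multiplicative scale (3 x the default noise
#'   CV of 0.1); use [planted_effect_for_escore()] to plant effects at a
#'   chosen E-score instead.
#' @param lethal_fraction Fraction of aggravating pairs forced to
#'   synthetic-lethal (deviation ~ -1).
#' @param condition_mix Named probabilities over condition classes
#'   `both`, `rich_only`, `minimal_only`, `sign_flip` (sign-flip pairs are
#'   alleviating in the first condition and aggravating in the second).
#' @param conditions Condition names; the first is the rich-like reference.
#' @param essential_fraction Fraction of genes flagged essential
#'   (hypomorphic alleles in a real screen).
#' @param essential_boost Multiplier on the interaction probability per
#'   essential gene in a pair (1 = no boost).
#' @param fitness_range Range of single-mutant relative fitness `W`.
#' @param genome_length_bp Circular chromosome length for simulated genomic
#'   positions.
#' @param seed Integer seed; identical seeds give identical networks.
#' @return An object of class `ground_truth`: list with `genes`,
#'   `single_fitness`, `essential`, `module`, `position_bp`, `conditions`,
#'   and `interactions` (data.frame `gene_a`, `gene_b`, `condition`,
#'   `effect`; `gene_a < gene_b`, zero effects never stored).
#' @export
generate_ground_truth <- function(n_genes = 200L, n_modules = 10L,
                                  within_rate = 0.15, between_rate = 0.005,
                                  effect_dist = list(mean_aggravating = -0.3,
                                                     mean_alleviating = 0.3,
                                                     sd = 0.05,
                                                     prob_aggravating = 0.7),
                                  lethal_fraction = 0.05,
                                  condition_mix = c(both = 0.55,
                                                    rich_only = 0.15,
                                                    minimal_only = 0.2,
                                                    sign_flip = 0.1),
                                  conditions = c("rich", "minimal"),
                                  essential_fraction = 0.25,
                                  essential_boost = 1,
                                  fitness_range = c(0.6, 1.1),
                                  genome_length_bp = 4641652L,
                                  seed = 1L) {
  if (!is_prob(within_rate) || !is_prob(between_rate))
    stopf("within_rate and between_rate must be probabilities in [0, 1]")
  if (within_rate < between_rate)
    stopf("within_rate must be >= between_rate")
  if (!is_count(n_modules) || n_modules < 1) stopf("n_modules must be >= 1")
  if (!is_count(n_genes) || n_genes < 2 * n_modules)
    stopf("n_genes must be >= 2 * n_modules")
  if (!is_prob(lethal_fraction)) stopf("lethal_fraction must be in [0, 1]")
  if (!is_prob(essential_fraction)) stopf("essential_fraction must be in [0, 1]")
  stopifnot(length(conditions) %in% 1:2)
  set.seed(seed)

  genes <- sprintf("g%04d", seq_len(n_genes))
  labels <- bioprocess_labels()[((seq_len(n_modules) - 1L) %% 20L) + 1L]
  module <- sample(rep(labels, length.out = n_genes))
  names(module) <- genes
  wi <- stats::runif(n_genes, fitness_range[1], fitness_range[2])
  names(wi) <- genes
  essential <- stats::runif(n_genes) < essential_fraction
  names(essential) <- genes
  position <- sort(sample.int(genome_length_bp, n_genes))
  names(position) <- genes

  ## candidate pairs and edge draws
  ut <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
  same_mod <- module[ut[, 1L]] == module[ut[, 2L]]
  rate <- ifelse(same_mod, within_rate, between_rate)
  if (essential_boost != 1) {
    ness <- essential[ut[, 1L]] + essential[ut[, 2L]]
    rate <- pmin(1, rate * essential_boost^ness)
  }
  is_edge <- stats::runif(nrow(ut)) < rate
  ia <- ut[is_edge, 1L]
  ib <- ut[is_edge, 2L]
  n_edge <- length(ia)

  interactions <- data.frame(gene_a = character(0), gene_b = character(0),
                             condition = character(0), effect = numeric(0),
                             stringsAsFactors = FALSE)
  if (n_edge > 0L) {
    aggravating <- stats::runif(n_edge) < effect_dist$prob_aggravating
    mag <- abs(stats::rnorm(n_edge,
                            mean = ifelse(aggravating,
                                          abs(effect_dist$mean_aggravating),
                                          effect_dist$mean_alleviating),
                            sd = effect_dist$sd))
    mag <- pmax(mag, 0.05)
    base_eff <- ifelse(aggravating, -pmin(mag, 0.9), mag)
    lethal <- aggravating & stats::runif(n_edge) < lethal_fraction
    base_eff[lethal] <- -1 + stats::runif(sum(lethal), 0, 0.02)

    if (length(conditions) == 2L) {
      mix <- condition_mix[c("both", "rich_only", "minimal_only", "sign_flip")]
      if (anyNA(mix) || abs(sum(mix) - 1) > 1e-8)
        stopf("condition_mix must contain both/rich_only/minimal_only/sign_flip summing to 1")
      cls <- sample(names(mix), n_edge, replace = TRUE, prob = mix)
      rows <- vector("list", n_edge)
      eff1 <- ifelse(cls == "minimal_only", NA_real_,
                     ifelse(cls == "sign_flip", abs(base_eff), base_eff))
      eff2 <- ifelse(cls == "rich_only", NA_real_,
                     ifelse(cls == "sign_flip",
                            -pmin(abs(base_eff), 0.9), base_eff))
      interactions <- rbind(
        data.frame(gene_a = genes[ia], gene_b = genes[ib],
                   condition = conditions[1L], effect = eff1,
                   stringsAsFactors = FALSE),
        data.frame(gene_a = genes[ia], gene_b = genes[ib],
                   condition = conditions[2L], effect = eff2,
                   stringsAsFactors = FALSE)
      )
      interactions <- interactions[!is.na(interactions$effect), , drop = FALSE]
    } else {
      interactions <- data.frame(gene_a = genes[ia], gene_b = genes[ib],
                                 condition = conditions[1L], effect = base_eff,
                                 stringsAsFactors = FALSE)
    }
    interactions <- interactions[interactions$effect != 0, , drop = FALSE]
    rownames(interactions) <- NULL
  }

  structure(list(genes = genes, single_fitness = wi, essential = essential,
                 module = module, position_bp = position,
                 conditions = conditions, interactions = interactions,
                 params = list(n_genes = n_genes, n_modules = n_modules,
                               within_rate = within_rate,
                               between_rate = between_rate,
                               lethal_fraction = lethal_fraction,
                               condition_mix = condition_mix,
                               essential_fraction = essential_fraction,
                               essential_boost = essential_boost,
                               seed = seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d genes, %d modules, %d planted interaction records (%d pairs)\n",
              length(x$genes), length(unique(x$module)),
              nrow(x$interactions),
              length(unique(pair_key(x$interactions$gene_a, x$interactions$gene_b)))))
  invisible(x)
}

## true deviation matrix (1+delta factors) for one condition
truth_effect_matrix <- function(truth, queries, arrays, condition) {
  D <- matrix(0, length(queries), length(arrays),
              dimnames = list(queries, arrays))
  intr <- truth$interactions[truth$interactions$condition == condition, , drop = FALSE]
  if (nrow(intr) > 0L) {
    for (ori in 1:2) {
      ga <- if (ori == 1L) intr$gene_a else intr$gene_b
      gb <- if (ori == 1L) intr$gene_b else intr$gene_a
      ok <- ga %in% queries & gb %in% arrays
      D[cbind(match(ga[ok], queries), match(gb[ok], arrays))] <- intr$effect[ok]
    }
  }
  D
}

#' Simulate raw colony-size tables from a ground-truth network
#'
#' Inverts the multiplicative epistasis model: the expected colony size of a
#' double mutant is `base_size * Wi * Wj * (1 + delta)` where `delta` is the
#' planted deviation (0 for non-interacting pairs), then applies plate
#' row/column gradients, edge-ring inflation, lognormal replicate noise, and
#' pinning dropout. One colony record is emitted for every
#' query x array x replicate combination per condition; dropouts are flagged
#' missing, never removed.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param layout A [plate_layout()] for the array genes; default lays out all
#'   of `truth$genes`.
#' @param noise A [noise_model()].
#' @param base_size Expected size (area units) of a wild-type-fitness colony.
#' @param queries Query genes screened (default: all genes).
#' @param conditions Conditions to simulate (default: `truth$conditions`).
#' @param seed Seed (overridden by `noise$seed` when set).
#' @return data.frame of colony records: `query`, `array`, `plate`, `row`,
#'   `col`, `replicate`, `condition`, `size`, `missing_flag`.
#' @export
simulate_screens <- function(truth, layout = NULL, noise = noise_model(),
                             base_size = 1000, queries = NULL,
                             conditions = NULL, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_model"))
  if (base_size <= 0) stopf("base_size must be positive")
  if (is.null(layout)) layout <- plate_layout(truth$genes)
  queries <- queries %||% truth$genes
  conditions <- conditions %||% truth$conditions
  if (!all(queries %in% truth$genes)) stopf("unknown query gene(s)")
  arrays <- layout$array
  if (!all(arrays %in% truth$genes))
    stopf("layout contains array genes absent from the ground truth")
  set.seed(noise$seed %||% seed)

  n_rows <- attr(layout, "n_rows"); n_cols <- attr(layout, "n_cols")
  reps <- attr(layout, "replicates")
  nq <- length(queries); na <- length(arrays)
  wi <- truth$single_fitness[queries]
  wj <- truth$single_fitness[arrays]

  mid_r <- (n_rows + 1) / 2; mid_c <- (n_cols + 1) / 2
  rowf <- exp(noise$row_gradient * (layout$row - mid_r))
  colf <- exp(noise$col_gradient * (layout$col - mid_c))
  on_edge <- layout$row == 1L | layout$row == n_rows |
    layout$col == 1L | layout$col == n_cols
  spatial <- rowf * colf * ifelse(on_edge, 1 + noise$edge_boost, 1)
  sdlog <- sqrt(log(1 + noise$multiplicative_cv^2))

  out <- vector("list", length(conditions))
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    D <- truth_effect_matrix(truth, queries, arrays, cond)
    expected <- base_size * (wi %o% wj) * (1 + D)   # nq x na
    blocks <- vector("list", reps)
    for (r in seq_len(reps)) {
      mu <- sweep(expected, 2L, spatial, `*`)
      if (noise$multiplicative_cv > 0) {
        lf <- exp(matrix(stats::rnorm(nq * na, -sdlog^2 / 2, sdlog), nq, na))
        mu <- mu * lf
      }
      size <- as.vector(t(mu))                      # array-major within query
      if (noise$dropout_rate > 0) {
        drop <- stats::runif(nq * na) < noise$dropout_rate
        size[drop] <- NA_real_
      }
      blocks[[r]] <- data.frame(
        query = rep(queries, each = na),
        array = rep(arrays, times = nq),
        plate = paste0(rep(queries, each = na), ":p",
                       formatC(rep(layout$plate, nq), width = 2, flag = "0"),
                       ":r", r),
        row = rep(layout$row, nq),
        col = rep(layout$col, nq),
        replicate = r,
        condition = cond,
        size = size,
        missing_flag = as.integer(is.na(size)),
        stringsAsFactors = FALSE
      )
    }
    out[[ci]] <- do.call(rbind, blocks)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$condition, res$query, res$replicate, res$plate,
                   res$row, res$col), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a simulated screen to a fixture directory
#'
#' Writes `colonies_<condition>.tsv` per condition (columns `query`, `array`,
#' `plate`, `row`, `col`, `replicate`, `size`, `missing_flag`),
#' `truth_edges.tsv` (`gene_a`, `gene_b`, `condition`, `effect`) and
#' `genes.tsv` (`gene`, `fitness`, `essential`, `module`, `genomic_pos_bp`).
#' Files round-trip losslessly through [read_colony_table()] and
#' [read_fixture()].
#'
#' @param truth A [generate_ground_truth()] object.
#' @param records Colony records from [simulate_screens()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_fixture <- function(truth, records, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (cond in unique(records$condition)) {
    path <- file.path(directory, paste0("colonies_", cond, ".tsv"))
    sub <- records[records$condition == cond,
                   c("query", "array", "plate", "row", "col",
                     "replicate", "size", "missing_flag"), drop = FALSE]
    write_tsv(sub, path)
    files <- c(files, path)
  }
  ep <- file.path(directory, "truth_edges.tsv")
  write_tsv(truth$interactions, ep)
  gp <- file.path(directory, "genes.tsv")
  write_tsv(data.frame(gene = truth$genes,
                       fitness = unname(truth$single_fitness),
                       essential = as.integer(unname(truth$essential)),
                       module = unname(truth$module),
                       genomic_pos_bp = unname(truth$position_bp),
                       stringsAsFactors = FALSE), gp)
  invisible(c(files, ep, gp))
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param directory Fixture directory.
#' @return List with `records` (all conditions bound), `edges`, `genes`.
#' @export
read_fixture <- function(directory) {
  cfiles <- list.files(directory, pattern = "^colonies_.*\\.tsv$",
                       full.names = TRUE)
  if (length(cfiles) == 0L) stopf("no colony tables in '%s'", directory)
  records <- do.call(rbind, lapply(cfiles, read_colony_table))
  edges <- read_tsv(file.path(directory, "truth_edges.tsv"))
  genes <- read_tsv(file.path(directory, "genes.tsv"))
  list(records = records, edges = edges, genes = genes)
}
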