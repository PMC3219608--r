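## Colony-table I/O, spatial plate normalization, replicate QC and
## linkage masking: everything between the raw colony-size table and the
## normalized double-mutant fitness matrix.

colony_required_cols <- c("query", "array", "plate", "row", "col",
                          "replicate", "size")

#' Read a colony-size table
#'
#' Tab-separated with header columns `query`, `array`, `plate`, `row`,
#' `col`, `replicate`, `size` and optionally `missing_flag` and
#' `condition`. Unknown columns are preserved. The key
#' (plate, row, col, replicate, condition) must be unique; violations are
#' reported with the offending file line numbers.
#'
#' @param path File path.
#' @param condition Condition label; defaults to the table's `condition`
#'   column, else is parsed from a `colonies_<condition>.tsv` filename,
#'   else `"unknown"`.
#' @return data.frame of colony records.
#' @export
read_colony_table <- function(path, condition = NULL) {
  df <- read_tsv(path)
  missing_cols <- setdiff(colony_required_cols, names(df))
  if (length(missing_cols) > 0L)
    stopf("%s: missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  for (nm in c("row", "col", "replicate", "size")) {
    if (!is.numeric(df[[nm]]))
      stopf("%s: column '%s' must be numeric", path, nm)
  }
  bad <- which(!is.na(df$size) & df$size < 0)
  if (length(bad) > 0L)
    stopf("%s: negative colony size at line(s) %s", path,
          paste(bad + 1L, collapse = ", "))
  if (is.null(condition)) {
    if ("condition" %in% names(df)) {
      condition <- NULL                     # already present
    } else {
      m <- regmatches(basename(path),
                      regexec("^colonies_(.+)\\.tsv$", basename(path)))[[1L]]
      condition <- if (length(m) == 2L) m[2L] else "unknown"
    }
  }
  if (!is.null(condition)) df$condition <- condition
  if (!"missing_flag" %in% names(df)) df$missing_flag <- as.integer(is.na(df$size))
  incons <- which(is.na(df$size) != (df$missing_flag == 1L))
  if (length(incons) > 0L)
    stopf("%s: size/missing_flag inconsistent at line(s) %s", path,
          paste(incons + 1L, collapse = ", "))
  key <- paste(df$plate, df$row, df$col, df$replicate, df$condition, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup))
    stopf("%s: duplicate (plate,row,col,replicate,condition) at line(s) %s",
          path, paste(which(dup) + 1L, collapse = ", "))
  df
}

#' Write a colony-size table
#'
#' Writes all columns present in `records` (unknown columns written
#' through), tab-separated.
#'
#' @param records Colony records data.frame.
#' @param path Output path.
#' @export
write_colony_table <- function(records, path) {
  missing_cols <- setdiff(colony_required_cols, names(records))
  if (length(missing_cols) > 0L)
    stopf("records missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  write_tsv(records, path)
  invisible(path)
}

## Fixed-point spatial normalization of one plate. Cycles, until the
## corrected sizes stop changing: (1) scale to plate median 1; (2) a
## median-polish decomposition of log size removing row and column
## effects; (3) divide the outer edge ring by (edge median / interior
## median). Because the edge ring is exactly the union of the boundary
## rows and columns, a uniform ring boost lies in the span of the
## row/column effects and the polish absorbs it; the explicit ring step is
## therefore gated behind a significance dead band (robust z on the log
## ring/interior offset), so it corrects genuine partial-ring artifacts
## but stays inert on already-flat plates -- which is what makes the whole
## transform idempotent. Step (1) makes it invariant to the raw size
## scale. Zero-size colonies (dead double mutants) are excluded from the
## log-scale fit but carried through multiplicatively; missing stays
## missing.
normalize_plate_one <- function(df, tol = 1e-6, max_iter = 400L,
                                edge_z = 2.5, edge_min_effect = 0.02) {
  nr <- max(df$row); nc <- max(df$col)
  mat <- matrix(NA_real_, nr, nc)
  mat[cbind(df$row, df$col)] <- df$size
  occupied <- matrix(FALSE, nr, nc)
  occupied[cbind(df$row, df$col)] <- TRUE

  on_edge <- outer(seq_len(nr) %in% c(1L, nr), rep(TRUE, nc), `&`) |
    outer(rep(TRUE, nr), seq_len(nc) %in% c(1L, nc), `&`)

  scale_polish <- function(mat) {
    for (iter in seq_len(max_iter)) {
      m <- stats::median(mat, na.rm = TRUE)
      if (!is.finite(m) || m <= 0) return(mat)
      lmat <- log(mat / m)
      lmat[!is.finite(lmat)] <- NA      # dead colonies excluded from fit
      keep_r <- rowSums(!is.na(lmat)) > 0L
      keep_c <- colSums(!is.na(lmat)) > 0L
      re <- numeric(nr); ce <- numeric(nc)
      if (sum(keep_r) >= 2L && sum(keep_c) >= 2L) {
        mp <- .med_polish(lmat[keep_r, keep_c, drop = FALSE], eps = 1e-14,
                          maxiter = 200L)
        re[keep_r] <- ifelse(is.na(mp$row), 0, mp$row)
        ce[keep_c] <- ifelse(is.na(mp$col), 0, mp$col)
      }
      ## snap to identity: corrections at numerical-noise level are not
      ## applied, so the transform has a strict fixed point
      if (max(abs(log(m)), abs(re), abs(ce)) < tol) break
      mat <- mat / (m * exp(outer(re, ce, `+`)))
    }
    mat
  }

  mat <- scale_polish(mat)
  ## edge-ring correction behind the significance dead band (the polish
  ## already absorbs uniform ring boosts into its boundary row/column
  ## effects, so this fires only on genuine residual ring offsets)
  lmat <- log(mat)
  lmat[!is.finite(lmat)] <- NA
  edge_vals <- lmat[on_edge & occupied]
  int_vals <- lmat[!on_edge & occupied]
  ne <- sum(is.finite(edge_vals)); ni <- sum(is.finite(int_vals))
  if (ne >= 3L && ni >= 3L) {
    off <- stats::median(edge_vals, na.rm = TRUE) -
      stats::median(int_vals, na.rm = TRUE)
    spread <- stats::mad(c(edge_vals, int_vals), na.rm = TRUE)
    se <- 1.253 * spread * sqrt(1 / ne + 1 / ni)   # SE of a median difference
    if (is.finite(off) && abs(off) > max(edge_min_effect, edge_z * se))
      mat <- scale_polish(mat * ifelse(on_edge, exp(-off), 1))
  }
  df$size <- mat[cbind(df$row, df$col)]
  df$missing_flag <- as.integer(is.na(df$size))
  df
}

#' Normalize colony sizes plate by plate
#'
#' Applies, per physical plate, the spatial normalization: plate-median
#' scaling (typical corrected colony has size 1), row/column correction by
#' median polish on the log scale, and edge-ring correction. The three steps
#' are cycled to a fixed point so the transform is idempotent and invariant
#' to the raw measurement scale. Plates with more than `max_missing` of
#' their colonies missing are rejected (dropped from the output and listed
#' in the plate QC report).
#'
#' @param records Colony records (any number of plates/conditions).
#' @param max_missing Maximum tolerated missing fraction per plate.
#' @return List: `records` (corrected sizes; rejected plates removed) and
#'   `plate_qc` (data.frame `condition`, `plate`, `n`, `frac_missing`,
#'   `status`).
#' @export
normalize_colonies <- function(records, max_missing = 0.5) {
  key <- paste(records$condition, records$plate, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  out <- vector("list", length(groups))
  qc <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    df <- records[idx, , drop = FALSE]
    fm <- mean(is.na(df$size))
    if (fm > max_missing) {
      qc[[k]] <- data.frame(condition = df$condition[1L], plate = df$plate[1L],
                            n = nrow(df), frac_missing = fm,
                            status = "rejected_missing",
                            stringsAsFactors = FALSE)
      out[[k]] <- NULL
    } else {
      out[[k]] <- normalize_plate_one(df)
      qc[[k]] <- data.frame(condition = df$condition[1L], plate = df$plate[1L],
                            n = nrow(df), frac_missing = fm, status = "ok",
                            stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- records[0, , drop = FALSE]
  rownames(res) <- NULL
  list(records = res, plate_qc = do.call(rbind, qc))
}

#' Normalize a single plate
#'
#' Convenience wrapper around the per-plate normalization for records that
#' all belong to one physical plate.
#'
#' @param records Colony records of one plate.
#' @param max_missing Maximum tolerated missing fraction.
#' @return Corrected records.
#' @export
normalize_plate <- function(records, max_missing = 0.5) {
  if (length(unique(paste(records$condition %||% "", records$plate))) != 1L)
    stopf("normalize_plate: records span more than one plate")
  fm <- mean(is.na(records$size))
  if (fm > max_missing)
    stopf("plate rejected: %.0f%% of colonies missing (QC code rejected_missing)",
          100 * fm)
  normalize_plate_one(records)
}

#' Replicate quality control
#'
#' Two filters, in order. First, a colony whose corrected size falls below
#' `size_floor` in exactly one replicate while at least one other replicate
#' grew is treated as a pinning failure and set missing (a genuinely dead
#' double mutant is small in every replicate and is untouched). Second, each
#' screen's between-replicate Pearson correlation of corrected sizes is
#' computed (mean over replicate pairs); screens below `min_replicate_corr`
#' are excluded, with every decision listed in the report.
#'
#' @param records Normalized colony records.
#' @param min_replicate_corr Minimum mean between-replicate correlation.
#' @param size_floor Corrected-size floor for the pinning-failure rule.
#' @return List: `records` (pinning failures set missing, excluded screens
#'   removed) and `report` (data.frame `condition`, `query`, `r`,
#'   `decision`, `reason`), with attribute `n_pinning_failures`.
#' @export
qc_filter <- function(records, min_replicate_corr = 0.5, size_floor = 0.05) {
  reps <- sort(unique(records$replicate))
  if (length(reps) < 2L) stopf("qc_filter needs >= 2 replicates")

  ## pinning failures
  ckey <- paste(records$condition, records$query, records$array, sep = "\r")
  low <- !is.na(records$size) & records$size < size_floor
  grown <- !is.na(records$size) & records$size >= size_floor
  n_low <- ave(low, ckey, FUN = sum)
  n_grown <- ave(grown, ckey, FUN = sum)
  fail <- low & n_low == 1L & n_grown >= 1L
  records$size[fail] <- NA_real_
  records$missing_flag <- as.integer(is.na(records$size))

  ## replicate correlation per screen
  skey <- paste(records$condition, records$query, sep = "\r")
  screens <- split(seq_len(nrow(records)), skey)
  rep_report <- lapply(screens, function(idx) {
    df <- records[idx, , drop = FALSE]
    arrays <- unique(df$array)
    m <- matrix(NA_real_, length(arrays), length(reps),
                dimnames = list(arrays, reps))
    m[cbind(match(df$array, arrays), match(df$replicate, reps))] <- df$size
    cors <- c()
    for (i in seq_along(reps)) for (j in seq_along(reps)) {
      if (i < j) {
        ok <- stats::complete.cases(m[, c(i, j)])
        cors <- c(cors, if (sum(ok) >= 3L)
          stats::cor(m[ok, i], m[ok, j]) else NA_real_)
      }
    }
    r <- mean(cors, na.rm = TRUE)
    data.frame(condition = df$condition[1L], query = df$query[1L],
               r = r,
               decision = if (is.finite(r) && r >= min_replicate_corr)
                 "keep" else "exclude",
               reason = if (!is.finite(r)) "no_overlap"
               else if (r < min_replicate_corr) "low_replicate_correlation"
               else "",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_report)
  rownames(report) <- NULL
  keep_keys <- paste(report$condition, report$query, sep = "\r")[report$decision == "keep"]
  records <- records[skey %in% keep_keys, , drop = FALSE]
  rownames(records) <- NULL
  attr(report, "n_pinning_failures") <- sum(fail)
  list(records = records, report = report)
}

#' Mask array genes linked to the query on the circular chromosome
#'
#' In conjugation-based double-mutant construction, loci near the query
#' under-recombine, biasing their colony sizes downward; array genes within
#' `window_bp` of the query (circular distance) are therefore masked, as is
#' the query gene itself. Genes without a position are left unmasked with a
#' warning.
#'
#' @param query Query gene.
#' @param arrays Array genes.
#' @param positions_bp Named vector gene -> genomic coordinate (bp).
#' @param window_bp Linkage window (default 30 kb).
#' @param genome_length_bp Circular chromosome length (default E. coli
#'   K-12, 4,641,652 bp).
#' @return Character vector of masked array genes.
#' @export
mask_linked <- function(query, arrays, positions_bp, window_bp = 30000,
                        genome_length_bp = 4641652) {
  masked <- intersect(query, arrays)
  qpos <- positions_bp[query]
  if (is.na(qpos)) {
    warnf("no position for query '%s'; only self masked", query)
    return(masked)
  }
  apos <- positions_bp[arrays]
  unknown <- arrays[is.na(apos)]
  if (length(unknown) > 0L)
    warnf("no position for %d array gene(s); left unmasked", length(unknown))
  d <- abs(apos - qpos)
  d <- pmin(d, genome_length_bp - d)
  linked <- arrays[!is.na(d) & d <= window_bp]
  union(masked, linked)
}

#' Construct a screen-matrix container
#'
#' Low-level constructor for pre-aggregated data (e.g. externally normalized
#' screens or hand-built test cases). Most users should call
#' [build_screen_matrix()] on colony records instead.
#'
#' @param W queries x arrays matrix of mean normalized double-mutant fitness.
#' @param sd Matching replicate standard-deviation matrix.
#' @param n_obs Matching replicate-count matrix.
#' @param mask Logical matrix of masked cells (default: none).
#' @param reps Optional queries x arrays x replicates array of the
#'   underlying replicate values.
#' @param condition Condition label.
#' @param array_plate Named vector array gene -> plate group.
#' @return Object of class `screen_matrix`.
#' @export
screen_matrix <- function(W, sd = NULL, n_obs = NULL, mask = NULL,
                          reps = NULL, condition = "unknown",
                          array_plate = NULL) {
  if (is.null(sd)) sd <- matrix(NA_real_, nrow(W), ncol(W), dimnames = dimnames(W))
  if (is.null(n_obs)) n_obs <- matrix(ifelse(is.na(W), 0L, 1L), nrow(W),
                                      ncol(W), dimnames = dimnames(W))
  if (is.null(mask)) mask <- matrix(FALSE, nrow(W), ncol(W), dimnames = dimnames(W))
  if (is.null(array_plate)) {
    array_plate <- rep("p01", ncol(W)); names(array_plate) <- colnames(W)
  }
  structure(list(W = W, sd = sd, n_obs = n_obs, mask = mask, reps = reps,
                 condition = condition, array_plate = array_plate),
            class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("screen_matrix [%s]: %d queries x %d arrays, %d masked cells, %.1f%% measured\n",
              x$condition, nrow(x$W), ncol(x$W), sum(x$mask),
              100 * mean(!is.na(x$W))))
  invisible(x)
}

#' Aggregate normalized colony records into a screen matrix
#'
#' Builds the queries x arrays matrix of double-mutant fitness `Wij` (mean
#' of corrected sizes across replicates), the replicate standard deviation,
#' the observation count, and the mask. The query's own gene is always
#' masked; when genomic positions are supplied, array genes within the
#' linkage window of each query are masked too ([mask_linked()]). Queries
#' with every array masked are dropped with a warning.
#'
#' @param records Normalized, QC-passed colony records of one condition.
#' @param positions_bp Optional named vector gene -> genomic position.
#' @param window_bp Linkage window passed to [mask_linked()].
#' @param genome_length_bp Circular chromosome length.
#' @return Object of class `screen_matrix`.
#' @export
build_screen_matrix <- function(records, positions_bp = NULL,
                                window_bp = 30000,
                                genome_length_bp = 4641652) {
  conds <- unique(records$condition)
  if (length(conds) != 1L)
    stopf("build_screen_matrix expects one condition; got %d", length(conds))
  queries <- sort(unique(records$query))
  arrays <- sort(unique(records$array))
  reps <- sort(unique(records$replicate))
  qi <- match(records$query, queries)
  ai <- match(records$array, arrays)
  ri <- match(records$replicate, reps)
  R <- array(NA_real_, dim = c(length(queries), length(arrays), length(reps)),
             dimnames = list(queries, arrays, reps))
  R[cbind(qi, ai, ri)] <- records$size

  n <- sml <- smlsq <- matrix(0, length(queries), length(arrays))
  for (r in seq_along(reps)) {
    x <- R[, , r]
    obs <- !is.na(x)
    n <- n + obs
    x[!obs] <- 0
    sml <- sml + x
    smlsq <- smlsq + x^2
  }
  W <- ifelse(n > 0, sml / n, NA_real_)
  sd_m <- ifelse(n >= 2, sqrt(pmax(0, (smlsq - n * W^2) / (n - 1))), NA_real_)
  dimnames(W) <- dimnames(sd_m) <- list(queries, arrays)

  mask <- matrix(FALSE, length(queries), length(arrays),
                 dimnames = list(queries, arrays))
  for (q in queries) {
    if (!is.null(positions_bp)) {
      mk <- mask_linked(q, arrays, positions_bp, window_bp, genome_length_bp)
    } else {
      mk <- intersect(q, arrays)
    }
    mask[q, mk] <- TRUE
  }
  W[mask] <- NA_real_
  sd_m[mask] <- NA_real_
  n_m <- n
  n_m[mask] <- 0L
  mode(n_m) <- "integer"
  dimnames(n_m) <- list(queries, arrays)

  all_masked <- rowSums(!mask & !is.na(W)) == 0L
  if (any(all_masked)) {
    warnf("dropping %d query screen(s) with every array masked or missing: %s",
          sum(all_masked), paste(queries[all_masked], collapse = ", "))
    keep <- !all_masked
    W <- W[keep, , drop = FALSE]; sd_m <- sd_m[keep, , drop = FALSE]
    n_m <- n_m[keep, , drop = FALSE]; mask <- mask[keep, , drop = FALSE]
    R <- R[keep, , , drop = FALSE]
    queries <- queries[keep]
  }

  ## physical plate group per array gene, taken from one reference screen
  ref <- records[records$query == records$query[1L] &
                   records$replicate == reps[1L], , drop = FALSE]
  array_plate <- rep(NA_character_, length(arrays)); names(array_plate) <- arrays
  array_plate[ref$array] <- ref$plate
  miss <- is.na(array_plate)
  if (any(miss)) {
    first <- records[!duplicated(records$array), , drop = FALSE]
    array_plate[first$array[first$array %in% arrays[miss]]] <-
      first$plate[first$array %in% arrays[miss]]
  }

  screen_matrix(W = W, sd = sd_m, n_obs = n_m, mask = mask, reps = R,
                condition = conds, array_plate = array_plate)
}
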