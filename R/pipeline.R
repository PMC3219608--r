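## End-to-end orchestration: one configuration in, a run directory of
## tables, reports and a machine-readable manifest out.

pipeline_defaults <- function() {
  list(
    colony_tables = NULL,        # named character: condition -> path
    gene_table = NULL,           # gene, fitness?, essential?, module?, genomic_pos_bp?
    annotation_table = NULL,     # gene, bioprocess (falls back to gene_table$module)
    evidence_tables = NULL,      # named character: evidence set -> path of pair lists
    out_dir = NULL,
    linkage_window_bp = 30000,
    genome_length_bp = 4641652,
    max_missing = 0.5,
    min_replicate_corr = 0.5,
    size_floor = 0.05,
    sigma0 = NULL,
    threshold_grid = seq(1, 4, by = 0.5),
    n_shuffles = 20L,
    null_size = 100L,
    fdr_q = 0.05,
    use_fdr = TRUE,
    calibrate_cutoffs = TRUE,
    default_cutoffs = c(-2, 2),
    min_overlap = 30L,
    seed = 1L
  )
}

#' Build a pipeline configuration
#'
#' Every parameter has a default; unknown keys are rejected by name. The
#' resolved configuration is written verbatim into the run manifest.
#'
#' @param ... Overrides of the default configuration (see
#'   `esgamap:::pipeline_defaults()` for the full list); at minimum
#'   `colony_tables` (named by condition) and `out_dir`.
#' @return Object of class `esga_config`.
#' @export
esga_config <- function(...) {
  cfg <- pipeline_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "esga_config")
}

## deterministic per-stage seed fan-out from the global seed
stage_seed <- function(cfg, stage) {
  offs <- c(pvalues = 1000L, sweep = 2000L, profiles = 3000L,
            differential = 4000L)
  as.integer(cfg$seed) + offs[[stage]]
}

#' Run the full eSGA analysis pipeline
#'
#' Executes, per condition: colony-table reading, plate normalization,
#' replicate QC, linkage masking and matrix construction, fitness and
#' E-score computation with empirical p-values, cutoff calibration,
#' interaction calling with crosstalk and topology summaries, and profile
#' correlations with evidence shift tests; then the cross-condition
#' differential analysis when two conditions are present. All module
#' outputs are written as TSV into `out_dir` together with `manifest.json`
#' (resolved configuration, per-stage seeds and record counts, and the
#' pair-conservation accounting). Reruns with identical configuration and
#' inputs reproduce identical outputs. Any stage failure halts the run
#' with the stage name; outputs of completed stages are retained and the
#' manifest marks the failure.
#'
#' @param config An [esga_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "esga_config"))
  cfg <- unclass(config)
  if (is.null(cfg$colony_tables) || is.null(names(cfg$colony_tables)))
    stopf("config$colony_tables must be a named (by condition) vector of paths")
  if (is.null(cfg$out_dir)) stopf("config$out_dir is required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  conditions <- names(cfg$colony_tables)

  genes <- if (!is.null(cfg$gene_table)) read_tsv(cfg$gene_table) else NULL
  positions <- NULL
  if (!is.null(genes) && "genomic_pos_bp" %in% names(genes)) {
    positions <- genes$genomic_pos_bp
    names(positions) <- genes$gene
  }
  annotations <- NULL
  if (!is.null(cfg$annotation_table)) {
    annotations <- as_annotation(read_tsv(cfg$annotation_table))
  } else if (!is.null(genes) && "module" %in% names(genes)) {
    annotations <- genes$module
    names(annotations) <- genes$gene
  }

  manifest <- list(package = "esgamap",
                   version = as.character(utils::packageVersion("esgamap")),
                   config = cfg[!vapply(cfg, is.null, logical(1))],
                   stages = list(), conditions = list())
  fail <- function(stage, cond, err) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = stage, condition = cond, status = "failed",
           error = conditionMessage(err))
    write_manifest(manifest, cfg$out_dir)
    stopf("pipeline stage '%s' (%s) failed: %s", stage, cond,
          conditionMessage(err))
  }
  ok <- function(stage, cond, ...) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      c(list(stage = stage, condition = cond, status = "complete"), list(...))
  }

  es_list <- list(); edges_list <- list(); cal_list <- list()
  for (cond in conditions) {
    records <- tryCatch(read_colony_table(cfg$colony_tables[[cond]],
                                          condition = cond),
                        error = function(e) fail("read", cond, e))
    ok("read", cond, n_records = nrow(records))

    norm <- tryCatch(normalize_colonies(records, max_missing = cfg$max_missing),
                     error = function(e) fail("normalize", cond, e))
    write_tsv(norm$plate_qc, file.path(cfg$out_dir,
                                       paste0("plate_qc_", cond, ".tsv")))
    ok("normalize", cond, n_records = nrow(norm$records),
       n_plates_rejected = sum(norm$plate_qc$status != "ok"))

    qc <- tryCatch(qc_filter(norm$records,
                             min_replicate_corr = cfg$min_replicate_corr,
                             size_floor = cfg$size_floor),
                   error = function(e) fail("qc", cond, e))
    write_tsv(qc$report, file.path(cfg$out_dir,
                                   paste0("qc_report_", cond, ".tsv")))
    ok("qc", cond, n_records = nrow(qc$records),
       n_screens_excluded = sum(qc$report$decision == "exclude"),
       n_pinning_failures = attr(qc$report, "n_pinning_failures"))

    scr <- tryCatch(build_screen_matrix(qc$records, positions_bp = positions,
                                        window_bp = cfg$linkage_window_bp,
                                        genome_length_bp = cfg$genome_length_bp),
                    error = function(e) fail("matrix", cond, e))
    fit <- tryCatch(estimate_single_fitness(scr),
                    error = function(e) fail("fitness", cond, e))
    es <- tryCatch({
      e0 <- compute_escores(scr, fit, sigma0 = cfg$sigma0)
      attach_pvalues(e0, null_size = cfg$null_size,
                     seed = stage_seed(cfg, "pvalues"))
    }, error = function(e) fail("score", cond, e))
    es_list[[cond]] <- es
    pairs <- escore_pairs(es)
    write_tsv(pairs, file.path(cfg$out_dir, paste0("escores_", cond, ".tsv")))
    ok("score", cond, n_pairs_scored = nrow(pairs), sigma0 = es$sigma0)

    cutoffs <- cfg$default_cutoffs
    if (cfg$calibrate_cutoffs && !is.null(annotations)) {
      cal <- tryCatch(threshold_sweep(es, annotations,
                                      grid = cfg$threshold_grid,
                                      n_shuffles = cfg$n_shuffles,
                                      seed = stage_seed(cfg, "sweep")),
                      error = function(e) fail("calibrate", cond, e))
      cal_list[[cond]] <- cal
      write_tsv(cal$sweep, file.path(cfg$out_dir,
                                     paste0("calibration_", cond, ".tsv")))
      if (!cal$failed) cutoffs <- unname(c(cal$chosen["negative"],
                                           cal$chosen["positive"]))
      ok("calibrate", cond, failed = cal$failed,
         cutoff_negative = cutoffs[1], cutoff_positive = cutoffs[2])
    }

    edges <- tryCatch(call_interactions(es, cutoffs = cutoffs,
                                        fdr_q = cfg$fdr_q,
                                        use_fdr = cfg$use_fdr),
                      error = function(e) fail("network", cond, e))
    edges_list[[cond]] <- edges
    write_tsv(as.data.frame(edges),
              file.path(cfg$out_dir, paste0("edges_", cond, ".tsv")))
    topo <- topology_stats(edges)
    write_tsv(topo, file.path(cfg$out_dir, paste0("topology_", cond, ".tsv")))
    if (!is.null(annotations)) {
      ct <- crosstalk_matrix(edges, pairs, annotations)
      for (s in names(ct))
        write_tsv(ct[[s]], file.path(cfg$out_dir,
                                     paste0("crosstalk_", cond, "_", s, ".tsv")))
    }
    ## pair conservation accounting for this condition
    genes_cond <- union(rownames(scr$W), colnames(scr$W))
    n_univ <- length(genes_cond) * (length(genes_cond) - 1L) / 2L
    n_tested <- nrow(pairs)
    midx <- which(scr$mask, arr.ind = TRUE)
    mg_a <- rownames(scr$W)[midx[, 1L]]; mg_b <- colnames(scr$W)[midx[, 2L]]
    n_masked <- length(unique(pair_key(mg_a, mg_b)[mg_a != mg_b]))
    n_called <- nrow(edges)
    ok("network", cond, n_edges = n_called,
       conservation = list(pairs_in = n_univ, pairs_called = n_called,
                           pairs_filtered = n_tested - n_called,
                           pairs_masked = n_masked,
                           pairs_unmeasured = n_univ - n_tested - n_masked))

    pc <- tryCatch(profile_correlation(es, min_overlap = cfg$min_overlap),
                   error = function(e) fail("profiles", cond, e))
    write_tsv(pc, file.path(cfg$out_dir,
                            paste0("profile_correlations_", cond, ".tsv")))
    ev_out <- list()
    if (!is.null(cfg$evidence_tables)) {
      for (ev in names(cfg$evidence_tables)) {
        res <- tryCatch(evidence_shift_test(
          pc, read_tsv(cfg$evidence_tables[[ev]]),
          seed = stage_seed(cfg, "profiles")),
          error = function(e) NULL)
        if (!is.null(res))
          ev_out[[ev]] <- data.frame(evidence = ev, D = res$D,
                                     p = res$p.value,
                                     median_evidence = res$median_evidence,
                                     median_random = res$median_random,
                                     n_evidence = res$n_evidence,
                                     stringsAsFactors = FALSE)
      }
      if (length(ev_out) > 0L)
        write_tsv(do.call(rbind, ev_out),
                  file.path(cfg$out_dir,
                            paste0("evidence_tests_", cond, ".tsv")))
    }
    ok("profiles", cond, n_correlations = sum(is.finite(pc$r)),
       n_evidence_sets = length(ev_out))
  }

  if (length(conditions) == 2L) {
    dif <- tryCatch(differential_scores(es_list[[1L]], es_list[[2L]],
                                        null_size = cfg$null_size,
                                        seed = stage_seed(cfg, "differential")),
                    error = function(e) fail("differential", "both", e))
    if (!is.null(annotations)) {
      ce <- classify_and_enrich(dif, edges_list[[1L]], edges_list[[2L]],
                                annotations, fdr_q = cfg$fdr_q)
      write_tsv(ce$calls, file.path(cfg$out_dir, "differential.tsv"))
      write_tsv(ce$enrichment,
                file.path(cfg$out_dir, "differential_enrichment.tsv"))
      ok("differential", "both", n_pairs = nrow(dif$pairs),
         n_differential = sum(ce$calls$differential),
         n_single_condition = nrow(dif$single_condition))
    } else {
      write_tsv(dif$pairs, file.path(cfg$out_dir, "differential.tsv"))
      ok("differential", "both", n_pairs = nrow(dif$pairs),
         n_single_condition = nrow(dif$single_condition))
    }
    write_tsv(dif$single_condition,
              file.path(cfg$out_dir, "differential_single_condition.tsv"))
  }

  write_manifest(manifest, cfg$out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}
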