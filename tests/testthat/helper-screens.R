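# Shared builders for simulated screens.

# artifact-free noise (replicate noise and optional dropout only)
quiet_noise <- function(cv = 0.1, dropout = 0, seed = NULL) {
  noise_model(multiplicative_cv = cv, row_gradient = 0, col_gradient = 0,
              edge_boost = 0, dropout_rate = dropout, seed = seed)
}

# simulate a one-condition screen with disjoint query/array sets and run it
# through the standard processing front end
sim_processed_screen <- function(truth, n_query, seed, normalize = TRUE,
                                 condition = "rich", replicates = 3L, ...) {
  qs <- truth$genes[seq_len(n_query)]
  ars <- truth$genes[-seq_len(n_query)]
  rec <- simulate_screens(truth, layout = plate_layout(ars, replicates = replicates),
                          queries = qs, conditions = condition, seed = seed, ...)
  if (normalize) rec <- normalize_colonies(rec)$records
  rec <- qc_filter(rec)$records
  build_screen_matrix(rec)
}

# hand-built screen matrix for scoring micro-tests
toy_screen <- function(W, sd = NULL, n_obs = NULL, condition = "test") {
  screen_matrix(W = W, sd = sd, n_obs = n_obs, condition = condition)
}

# hand-built escore container (enough structure for pair/network functions)
toy_escores <- function(E, p = NULL, condition = "test") {
  structure(list(E = E, sigma = E * 0 + 1, sigma_cell = E * 0 + 1, p = p,
                 condition = condition, sigma0 = 1, scale_factor = 1,
                 screen = NULL, fitness = NULL, qc = NULL),
            class = "escore_matrix")
}
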