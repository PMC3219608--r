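# esgamap

Quantitative genetic-interaction mapping for bacterial synthetic genetic
array (eSGA) screens: from replicate colony-size tables of arrayed double
mutants, grown under one or more conditions, to calibrated signed
interaction networks, bioprocess crosstalk maps, interaction-profile
correlations, and differential (condition-specific) interaction calls.

## Who it is for

Groups running colony-array double-mutant screens (eSGA/E-MAP style) in
bacteria who start from quantified colony sizes — one row per pinned
colony with its plate, grid position, replicate and condition — and need a
reproducible, tested path to interaction networks. A built-in
synthetic-screen generator plants known ground truth (module structure,
synthetic lethality, condition rewiring, plate artifacts), so the whole
pipeline is verifiable by parameter recovery without any external data.

## The model

Under the multiplicative model of epistasis, non-interacting genes combine
as `Wij ≈ Wi·Wj` (relative fitnesses from colony sizes). The interaction
score standardizes the deviation:

    E_ij = (Wij − Ŵi·Ŵj) / σ̂_ij ,   σ̂_ij = sqrt(s²_ij/n_ij + σ0²)

with single-mutant fitnesses estimated from robust marginals of the screen
itself, moderated per-cell variances, and the final score surface centered
and scaled so that E ≤ −2 (aggravating: synthetic sick/lethal) and E ≥ +2
(alleviating: buffering) read as ~2 SD cutoffs. Cutoffs are calibrated by
sweeping thresholds and maximizing significant bioprocess-pair enrichment
against a label-shuffled control; confidence comes from an empirical
replicate-resampling null; differential interactions between conditions
are tested with a replicate-level condition-swap permutation null.

## Worked example

Simulate a two-condition screen with planted ground truth and run the full
pipeline:

```r
library(esgamap)

truth <- generate_ground_truth(n_genes = 120, n_modules = 6, seed = 5)
records <- simulate_screens(truth, noise = noise_model(seed = 6))
write_fixture(truth, records, "screen_fixture")

cfg <- esga_config(
  colony_tables = c(rich    = "screen_fixture/colonies_rich.tsv",
                    minimal = "screen_fixture/colonies_minimal.tsv"),
  gene_table = "screen_fixture/genes.tsv",
  out_dir = "screen_run", seed = 3)
manifest <- run_pipeline(cfg)

edges <- read.delim("screen_run/edges_rich.tsv")
nrow(edges)
#> [1] 123
head(edges[order(edges$E), c("gene_a", "gene_b", "E", "adj_p", "sign")], 3)
#>     gene_a gene_b         E        adj_p        sign
#> 113  g0079  g0083 -26.48821 0.0004761898 aggravating
#> 118  g0085  g0117 -26.01089 0.0004761898 aggravating
#> 81   g0052  g0078 -25.94690 0.0004761898 aggravating
```

The strongest negative scores are planted synthetic-lethal pairs: their
double mutants grew ~26 standardized units below the multiplicative
expectation, and their BH-adjusted empirical p-values pass the 0.05 FDR
gate. `screen_run/` also contains, per condition, the plate and replicate
QC reports, the long-form E-score table, the calibration sweep (chosen
cutoffs echoed in `manifest.json`), crosstalk enrichment matrices,
per-gene degree/betweenness tables, profile correlations, and the
cross-condition differential calls with per-bioprocess enrichment.

Key functions if you prefer the stages individually:
`read_colony_table()` → `normalize_colonies()` → `qc_filter()` →
`build_screen_matrix()` → `estimate_single_fitness()` →
`compute_escores()` → `attach_pvalues()` → `threshold_sweep()` →
`call_interactions()` → `crosstalk_matrix()` / `topology_stats()` /
`profile_correlation()` / `differential_scores()`.

A thin command-line wrapper is installed at
`inst/scripts/esga` (`esga simulate|run`), for driving the same pipeline
from a shell.

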