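---
title: "Quantitative genetic-interaction mapping from colony-array screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetic-interaction mapping from colony-array screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esgamap)
```

## The measurement and the model

In a bacterial synthetic genetic array (eSGA) screen, a set of *query*
mutants is crossed against an arrayed library of *recipient* mutants, and
every double mutant grows as a pinned colony on replicate high-density agar
plates, typically under more than one growth condition (rich and minimal
medium). The colony area is the fitness readout.

The analysis rests on the multiplicative model of epistasis: if genes $i$
and $j$ act independently, the double-mutant fitness is the product of the
single-mutant fitnesses,

$$W_{ij} \approx W_i \, W_j ,$$

and a *genetic interaction* is a significant deviation from that
expectation. Aggravating interactions (synthetic sick/lethal, the double
mutant worse than expected) have negative scores; alleviating interactions
(buffering, typically same-pathway) have positive scores. `esgamap` turns
replicate colony-size tables into calibrated, signed interaction networks,
bioprocess crosstalk maps, interaction-profile correlations, and
differential (condition-specific) interaction calls — together with a
synthetic-screen generator that plants known ground truth so every stage
can be verified by parameter recovery.

## Spatial plate normalization

Raw colony sizes carry strong non-biological structure: overall plate
scale, row/column growth gradients, and inflated colonies on the outer
ring (edge colonies face less competition for nutrients). `normalize_plate()`
cycles three steps to a fixed point:

1. **Plate scaling** — sizes are divided by the plate median, so a typical
   corrected colony has size 1.
2. **Row/column correction** — a median-polish decomposition of log size
   removes additive row and column effects. Median polish is used because
   the minority of colonies carrying true interactions must not bias the
   correction. The inner polish runs in compiled code.
3. **Edge-ring correction** — the outer ring is divided by the ratio of
   the edge median to the interior median.

Two details matter. Because the edge ring is exactly the union of the
boundary rows and columns, a uniform ring boost lies in the span of the
row/column effects, and the polish absorbs it; an always-on ring step would
then fight the polish indefinitely (each exactly undoes the other). The
ring correction therefore fires only when the residual ring offset is
statistically significant (robust z > 2.5 and at least 2%). Second, the
iteration "snaps": corrections below $10^{-6}$ on the log scale are not
applied. This gives the transform a strict fixed point, so it is idempotent
(re-normalizing changes nothing) and invariant to the raw measurement
scale. A documented consequence of robust spatial correction is a modest
shave (roughly 10–20% on small plates) of extreme single-colony deviations,
because they leak slightly into their own row and column medians.

Plates with more than 50% missing colonies are rejected with a QC code.

## Replicate quality control

`qc_filter()` applies two rules, in order. A colony below the size floor in
exactly one replicate while the others grew is a pinning failure and is set
missing — a genuinely dead double mutant is small in *every* replicate and
is kept. Then each screen's between-replicate Pearson correlation (mean
over replicate pairs) must reach `min_replicate_corr` (default 0.5);
incoherent screens are excluded, and every decision is listed in the
report. The correlation signal comes from the spread of array-gene
fitnesses, so screens over genetically near-uniform arrays legitimately
fail this filter.

## Linkage masking

Double mutants are built by conjugation, and loci near the query
under-recombine, biasing their colony sizes. `mask_linked()` masks array
genes within a circular-chromosome window of the query (default 30 kb on a
4,641,652 bp chromosome — the window is a configurable knob recorded in the
run metadata, since published screens rarely state theirs), plus the
query's own gene. Masking only removes cells; it never alters surviving
values.

## E-scores

For each pair, `Wij` is the mean of corrected sizes over replicates, and
the score is the standardized deviation from the multiplicative
expectation:

$$E_{ij} = \frac{W_{ij} - \hat W_i \hat W_j}{\hat\sigma_{ij}}, \qquad
  \hat\sigma_{ij} = \sqrt{s^2_{ij}/n_{ij} + \sigma_0^2}.$$

The single-mutant fitnesses are estimated from the screen itself by robust
marginals: $\hat W_j$ is the median over queries of $W_{ij}$, and
$\hat W_i$ the median over arrays of $W_{ij}/\hat W_j$; the array estimates
are scaled to median 1 and the query estimates carry the complementary
scale so the product stays calibrated. On plate-normalized data the query
marginal necessarily absorbs the per-screen plate scale, so it is a
within-screen relative quantity. On a complete, exactly multiplicative
matrix this inversion is exact and every score is zero.

Three refinements stabilize the denominator and the surface:

* **Variance moderation.** With 2–3 replicates the per-cell sample variance
  has 1–2 degrees of freedom; used raw it dominates the score. Each cell's
  relative variance is shrunk toward its array column's trend (prior df
  10, columns themselves shrunk toward the global trend), because both the
  allele and its fixed plate position carry their own noise level.
  $\sigma_0$, the modal moderated replicate SD, guards the remaining
  small-variance cells.
* **Surface centering.** Residual per-row/per-column offsets (shared
  fitness-reference error) are removed by two passes of row/column median
  centering; medians ignore the sparse true interactions.
* **Standardization.** The final surface is scaled to unit central spread
  (MAD), so that $\pm 2$ reads as about two standard deviations of the
  neutral peak — the scale on which the score cutoffs are interpreted.
  `standardize = FALSE` keeps scores in raw $\hat\sigma$ units, which is
  the natural scale when the regularized denominator itself is the
  reference (the differential analysis below uses it). Matrices with fewer
  than 50 scored cells, and deviation-free matrices, are left unscaled.

When a pair was measured in both orientations, the inverse-variance
weighted mean is reported for both cells, and sign disagreements beyond
|ΔE| > 4 are flagged.

## Empirical p-values

`attach_pvalues()` builds a signal-free empirical null by resampling
replicate residuals *across* cells: within-cell residuals (which carry no
planted or biological interaction, being centered on their own cell mean)
are put on a common scale — divided by cell size and by the array column's
noise trend, variance-rescaled by $\sqrt{n/(n-1)}$ — pooled, and re-drawn
in groups of $n$ for each cell. Each draw is re-scaled to the cell,
standardized exactly like the observed score, merged across orientations,
and pooled over `null_size` rounds. The two-sided p-value is the
plus-one-corrected exceedance rank,
$p = (1 + \#\{|E_{\text{null}}| \ge |E|\})/(1 + N)$, monotone in $|E|$.

Borrowing residuals across cells (rather than flipping a cell's own) is
essential at this replicate depth: a cell whose few replicates agree by
chance still has a full-sized mean error, and its null must say so. On
interaction-free simulated screens the fraction of cells with $p<\alpha$
matches $\alpha$ within binomial error for $\alpha \in \{0.01, 0.05\}$.

## Cutoff calibration by bioprocess enrichment

Biologically real interaction sets are enriched for pairs falling within
and between annotated bioprocesses. `threshold_sweep()` counts, at each
|E| threshold and for each sign, the bioprocess label pairs significantly
enriched (one-sided Fisher exact test on the edge/universe 2×2 table,
Benjamini–Hochberg across label pairs, adjusted p ≤ 0.05), and picks the
smallest threshold attaining the maximum count — the tie-break keeps
sensitivity at equal enrichment evidence. Shuffling gene labels
(`n_shuffles`, default 20) produces the control curve (shuffled mean, with
the shuffled maximum also reported); if no threshold yields any enriched
label pair, calibration fails explicitly rather than defaulting. The
enrichment universe is the annotated testable pairs, so linkage-masked
pairs cannot masquerade as enrichment.

## Networks

`call_interactions()` emits an edge when the score passes the calibrated
cutoff (boundary inclusive: $E \le$ negative cutoff or $E \ge$ positive
cutoff) *and*, by default, its BH-adjusted empirical p-value across all
testable pairs is at most `fdr_q` (0.05). The double gate is the
conservative reading of "cutoffs plus confidence"; `use_fdr = FALSE`
disables it. `crosstalk_matrix()` repeats the label-pair enrichment
separately for aggravating and alleviating edges, and `topology_stats()`
reports degree and exact normalized betweenness (the networks here are
small enough that sampling would be a complication, not an optimization).
`group_compare()` contrasts groups — canonically essential vs
non-essential alleles — by the alleviating:aggravating ratio (two-sided
Fisher), or by degree/betweenness distributions (Wilcoxon rank-sum or
two-sample KS; Wilcoxon enumerates exactly when both samples are ≤ 12 and
tie-free).

## Profile correlations

Two genes acting in the same pathway interact with the same partners, so
their score profiles over the array correlate. `profile_correlation()`
computes Pearson correlations (Spearman available) over shared measured
partners, excluding the two positions that involve the pair's own genes —
otherwise a strong direct interaction would leak into its own profile
similarity. Pairs with fewer than `min_overlap` (30) shared partners are
undefined. `evidence_shift_test()` compares the correlation distribution
of externally supported pairs (operon co-membership, co-expression, PPI —
supplied as pair lists) against randomly drawn measured pairs with a
two-sample KS test. Correlations are computed per condition.

## Differential interactions

`differential_scores()` computes $dE = E_{\text{minimal}} -
E_{\text{rich}}$ (positive = more alleviating under nutrient limitation)
for every pair measured in both conditions; pairs seen in only one
condition are reported separately. The null swaps condition labels at the
replicate level: each cell's pooled replicates are re-partitioned at the
observed per-condition counts and the differential score recomputed with
the observed denominators held fixed — a conditional permutation, honest
under unequal replicate counts. Three implementation details: per-cell
pools are value-sorted and the two conditions are put in a canonical
internal order, making argument swap an exact antisymmetry (dE negates,
|dE| and p unchanged); each cell's own resamples are left out of its
exceedance count, so a strongly differential pair cannot dilute its own
p-value; and the plus-one correction applies as usual.

`classify_and_enrich()` maps the two per-condition calls to a change
class — the five differential classes (rich-/minimal-specific aggravating/
alleviating, sign-flip), the two conserved classes, with neutral-in-both
excluded — gates differential calls at BH-adjusted swap p ≤ `fdr_q`, and
tests per-bioprocess enrichment of differential-pair endpoints.

## The synthetic-screen generator

`generate_ground_truth()` plants a module-structured network: genes are
partitioned into bioprocess modules (within-module pair rate 0.15,
between 0.005 by default, 200 genes in 10 modules), interactions are 70%
aggravating, 5% of aggravating pairs are synthetic-lethal (double-mutant
fitness forced to ~0, producing the detached left score mode real screens
show), and each pair draws a condition class (both 0.55, rich-only 0.15,
minimal-only 0.20, sign-flip 0.10 — minimal medium reveals extra
interactions). Single fitness is uniform on [0.6, 1.1]; an optional
essential-gene rate boost models the denser connectivity of hypomorphic
alleles. `simulate_screens()` inverts the multiplicative model — expected
size $= \text{base} \cdot W_i W_j (1+\delta)$ — then applies log-linear
row/column gradients (0.01/position), a 20% edge-ring boost, mean-one
lognormal replicate noise (CV 0.1), and 10% pinning dropout (flagged, never
dropped), on a 3-replicate grid layout (32×48 when the array fills it, a
compact ~2:3 grid otherwise).

The default planted effect magnitude is 0.3 on the multiplicative scale —
three replicate standard deviations at the default noise CV — which lands
near |E| ≈ 5 on the standardized surface; `planted_effect_for_escore()`
converts a target score to a deviation on either score scale (the relation
is first-order; the generator's calibration test measures the realized
scores). What the generator does *not* emulate: batch effects across
plates beyond row/column/edge structure, neighbor competition between
colonies, growth-curve dynamics compressed into one endpoint, and
non-multiplicative noise. Passing recovery tests therefore demonstrates
the statistical machinery, not robustness to every artifact of real
plates.

## Verification scales and design choices

The package's own acceptance checks (mirrored in
`scripts/acceptance.R`) run at sizes chosen to make the statistics
meaningful on a single CPU: exact identities on a noiseless 30×60 screen;
null calibration on a 100×300 screen (≈29,000 scored pairs); recovery of
generator-default networks over 10 seeds; cutoff calibration with planted
|E| ≈ 3 effects on a 200-gene, 10-module screen; differential recovery of
single planted sign-flip pairs at E ±2.5 in raw-σ̂ units over 100
simulations (24×48 disjoint screens, 4 replicates, no dropout, scores
uncentered — the replicate-rich, artifact-free design isolates the
condition-swap statistic); and profile-shift detection over 100
simulations of 3-module screens. Two power facts shaped these designs: a differential effect of a
few noise SDs cannot clear a BH gate across thousands of tests when
several strong planted pairs pollute each other's condition-swap null, so
the differential scenario plants one pair per simulation; and
surface-standardized scores pin the neutral spread to 1 by construction,
so "±2.5" effects are only many-sigma events on the raw σ̂ scale, which is
why the differential scenario stays on that scale.

Other choices made where the design was genuinely open: replicate
aggregation by mean (not median), so the replicate SD feeds the score
denominator; Pearson (not Spearman) profile correlation, matching the
continuous score scale; one-sided enrichment tests (depletion does not
inform cutoff choice); FDR control by Benjamini–Hochberg only; the
differential sign convention (minimal minus rich) recorded in every output
header; and a single global seed fanned out to per-stage seeds by fixed
offsets so stages are independently reproducible.

## Known limitations

Query-side fitness is only identified up to the per-screen plate scale on
plate-normalized data. The spatial polish slightly shaves extreme
single-colony deviations (strongest on small plates). The empirical null
borrows residuals across cells and therefore assumes multiplicative noise
is exchangeable after size- and column-trend scaling; strong
position-specific heteroskedasticity beyond the column trend would
mis-calibrate it. Differential p-values for reciprocally measured
(merged-orientation) pairs are mildly conservative, because the swap null
is built per cell; surface centering and standardization of the input
scores add a further mild conservatism to the swap p-values (the null
does not model them), which is why the calibration checks run on raw,
uncentered scores. And with only 2–3 replicates, permutation resolution
per cell is coarse — pooled nulls are a necessity, not a choice.
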