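---
title: "Lagged co-regulation mining: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lagged co-regulation mining: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcaa)
```

## The problem and the model

Protein–protein interactions leave a temporal fingerprint in
phosphoproteomic time courses: when protein A regulates protein B, changes
in A's phosphorylation state tend to precede the corresponding changes in
B's by some lag. `dcaa` operationalizes that idea without any prior
interaction knowledge. Its input is a matrix of relative expression changes
(peptide × time point, versus a 0 h baseline; the canonical grid is
0.5, 1, 1.5, 2, 4, 6, 8, 12, 18, 24, 36, 48, 72 h), and its output is a
ranked set of candidate protein pairs with the reasoning depth at which
they were linked and an evaluation against a reference interaction set.

The pipeline makes three modelling commitments:

* **Shape, not distance.** Two peptides are related when their profiles
  *change the same way*, not when they are close in Euclidean terms. This
  motivates the three clustering criteria (trend signatures, segment
  angles, Pearson correlation) over k-means-style methods: distance-based
  clustering separates co-regulated peptides that differ only in baseline
  or amplitude.
* **Discrete lags in period units.** The lag between upstream and
  downstream events is modelled as a shift of 1–3 *periods* (intervals
  between adjacent time points), not hours. The sampling grid is strongly
  non-uniform (0.5 h steps early, 24 h late), so a fixed-hour lag would
  correspond to wildly different period offsets across the series. All
  delayed comparison happens on period vectors `T_k = t_{k+1} − t_k`.
* **Sign-level co-movement.** Two classes co-move under window `w.s.d`
  when, for every compared position, both periods move in the same
  direction or both are unchanging. Magnitudes are deliberately ignored;
  directionality re-enters statistically through the confidence asymmetry
  of the mined rules.

## Stage-by-stage notes

### Clustering

`trend_signature()` maps each of the 12 segments to +1/0/−1 with a dead
zone `zero_eps`; `cluster_full_trend()` groups identical signatures. The
partition is independent of row order because classes are keyed by the
signature itself.

The angle and Pearson criteria are *not transitive*, so some cluster-formation
rule is needed. We use deterministic leader clustering: scan
peptides in input order; a peptide joins the first class whose **first
member** (leader) satisfies the criterion, else founds a new class. This is
the simplest deterministic reading; the alternative comparisons (running
mean, all members) trade reproducibility or speed for marginal tightness,
and the order-dependence is documented rather than hidden. Angle clustering
compares `atan` slopes per segment; by default each segment spans one index
unit (`time_scale = "index"`), because raw-hour slopes would flatten every
late segment into near-zero angles. `time_scale = "hours"` is available for
users who want physical slopes. With `require_trend = TRUE` angle classes
provably refine full-trend classes; this is off by default because the
strict refinement claim only holds with that extra constraint near
zero-slope segments.

`pearson_moment()` implements the moment (single-pass algebraic) form of
the correlation. It is exact at the poles — `pearson_moment(x, x)` returns
1 and `pearson_moment(x, -x)` returns −1, because numerator and
denominator are computed from identical sums — and the test suite pins it
to an independent two-pass implementation at `1e-12`. Constant rows have
undefined correlation and become singleton classes.

### Delayed comparison and baskets

With 12 periods, window length 9 and delays up to 3, `enumerate_windows()`
yields exactly six windows (`9.1.1` … `9.3.1`), covering every lag
scenario of 1–3 periods. Window length is `n_periods − 3` by default: long
enough to be specific (a 9-position sign agreement has probability
`~0.5^9` between unrelated sign patterns), short enough to leave room for
every delay.

The matching predicate generalizes the exact rule "product of periods
positive, or both zero" with the same `zero_eps` dead zone used by trend
signatures. The generalization is *strict*: a period inside the dead zone
matches only another dead-zone period. This matters on noisy data — a flat
period's measured value is pure noise, and the raw product test would
accept it against any partner with probability one half, flooding the
baskets with spurious records.

One basket record is built per anchor class: the anchor plus every class
that lags behind it under at least one window; match-less anchors are
dropped. This per-anchor aggregation (rather than one record per pair or
per window) keeps the record count at or below the class count, which is
the structural relationship the method's record statistics exhibit, and it
makes basket construction independent of class iteration order.

### Apriori and rule derivation

Support uses the aggregated dataset's record count as denominator.
Mining is the classical level-wise algorithm with downward-closure
pruning, written directly in the package (no external mining library), and
the test suite checks it against exhaustive subset enumeration on 50
random datasets — exact set and support equality.

Rules are derived from every frequent itemset of size ≤ `max_rule_size`
(default 2) by enumerating all antecedent/consequent splits;
`confidence(X ⇐ Y) = support(X ∪ Y)/support(Y)`, threshold 0.9 by default.
Downstream reasoning consumes only 1 → 1 rules, since the matching step
links *pairs* of classes; larger rules are mined but flagged by size.

`tune_support()` scans a descending support grid and keeps the largest
support whose pairwise-rule count lands in a target range (default
50–600, "a few hundred" rules). If no grid value lands inside, the support
closest to the range wins; among equally distant candidates the smallest
support is taken when every count is below the range (it is the one
closest to producing rules), and the largest otherwise (fewer, stronger
rules).

### Reasoning and protein expansion

Pairwise rules build an undirected class graph — undirected because
reference interaction databases record undirected physical interactions;
the rule directions stay in the edge metadata. Depth 1 is the edge set;
depth 2 links endpoints of simple two-edge paths not already at depth 1;
depth 3 links endpoints of simple three-edge paths with all four classes
distinct, minus depths 1–2. For depths up to 3 this coincides with exact
graph distance, which the tests exploit by checking against an independent
shortest-path oracle. Class pairs expand to the cross product of their
member-peptides' accessions (protein groups split on `;`, so an ambiguous
peptide contributes all accessions); self-pairs are dropped and each
protein pair keeps its minimum depth.

### Evaluation

`R = m/M` over unordered pairs, against `R' = n/M'` from `replicates`
random draws of `M' = M` distinct pairs from the pair space of the protein
universe (by default, all proteins in the input matrix). The primary
significance measure is the add-one one-sided empirical p-value
`(1 + #{R' ≥ R})/(1 + replicates)` — assumption-free, with the smallest
attainable value `1/(replicates + 1)`, i.e. about 0.0099 at the default
100 replicates. A normal-approximation z-score is reported alongside; it
is `NA` when the baseline has zero variance. The per-depth and pooled
reports are both produced, since a reference database does not distinguish
reasoning depths.

## The synthetic generator

`plant_network()` and `simulate_timeseries()` emulate the study design the
pipeline targets: groups of peptides sharing change trends, plus planted
upstream → downstream influences realized as period-shifted profile copies
with additive Gaussian noise.

* **Topology.** Influences form a two-level forest: each target has exactly
  one driver, and drivers are not themselves targets. A target's profile is
  *defined* as its driver's profile shifted by the lag, so two parents or a
  cycle would define a profile twice; and chained cascades would shift a
  deep descendant's profile so far that its early values are constant
  padding, erasing the very signal whose recovery is being measured. The
  edge cap is `n_proteins − 1`.
* **Profiles.** Root profiles are piecewise linear in period space: each
  period is flat with probability `zero_prob = 0.2`, otherwise a step of
  magnitude uniform in `step_range = c(0.3, 0.8)` with random sign. Most
  periods therefore change direction informatively (flat profiles would
  make full-trend clustering degenerate), while the flat minority
  exercises the "unchanging" trend symbol and the dead-zone branch of the
  matcher. Steps are at least 5 × `noise_sd` by construction with the
  default `noise_sd = 0.02`.
* **Noise.** Independent Gaussian noise per point, applied once at the
  profile level (shared by a protein's peptides) and once per peptide row.
  This is the simplest model that stresses sign-based matching; it does
  *not* emulate mass-spectrometry missingness, intensity-dependent
  variance or batch effects. Passing benchmarks therefore demonstrate
  correctness of the machinery under the stated noise model, not
  performance on real acquisitions.

The benchmark scenario used by the end-to-end tests and the acceptance
script is 60 proteins, 40 planted edges with lags uniform in 1–3, 3
peptides per protein and `noise_sd = 0.02` — about 180 rows, sized so the
full pipeline (including the 100-replicate baseline and a ten-seed null
sweep) runs in seconds while keeping the combinatorics non-trivial. The
corresponding analysis setting `zero_eps = 0.12` is a noise-calibrated
dead zone: a flat period's measured difference accumulates profile and
peptide noise with standard deviation near `2.5 × noise_sd`, so `6 ×
noise_sd` cleanly separates flat periods (which must fall inside) from
planted steps of 0.3+ (which must not).

```{r example, eval = FALSE}
truth  <- plant_network(60, 40, c(1, 3), seed = 1)
sim    <- simulate_timeseries(truth, peptides_per_protein = 3, noise_sd = 0.02)
config <- dcaa_config(method = "full_trend", zero_eps = 0.12, seed = 1)
result <- run_pipeline(sim$matrix, truth_reference(sim$truth), config)
evaluate_recovery(subset(result$predictions, depth == 1), sim$truth)
```

With no planted edges the same machinery produces (almost) no records and
no predictions, and the hit rate against any fixed random reference is
indistinguishable from the baseline — the null behaviour the test suite
verifies over ten seeds.

## Numerical and degenerate-input choices

* `zero_eps` defaults to 0 everywhere (strict sign of the difference);
  positive values are opt-in for noisy data, and the same value is shared
  by trend signatures and the matching dead zone for coherence.
* Supports are exact rational counts evaluated in floating point;
  thresholds compare with `>=`.
* Rows with missing values are dropped at load time and counted, never
  imputed: differencing and sign logic are undefined on gaps.
* Baseline rows with `v_0 ≤ 0` are dropped (with a report) under ratio
  normalizations; the normalization method is user-selectable because
  relative-expression tables in the wild are variously log-ratios, ratios
  or differences — `log2_ratio` is the default.
* Constant rows cannot enter Pearson classes (undefined correlation) and
  become singletons; empty basket datasets stop the pipeline gracefully
  with empty downstream results rather than an error.
* All TSV outputs carry full-precision (`%.17g`) numbers so write → read
  round-trips are exact, plus a comment header with the package version, a
  configuration fingerprint and every effective parameter; two runs with
  one configuration and seed are byte-identical.

## Known limitations

* Leader clustering is order-dependent for the angle and Pearson criteria
  (by documented design); only full-trend clustering is fully
  order-invariant.
* Lags are discrete period shifts; continuous lag estimation
  (cross-correlation) is out of scope.
* The hit-rate evaluation treats the reference set as ground truth;
  reference incompleteness deflates all hit rates equally but is not
  modelled.
* No multiple-testing correction is applied across depths or clustering
  methods; the empirical p-value concerns a single pooled comparison.
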