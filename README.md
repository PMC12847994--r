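# minfluxr

Quantitative analysis of 3D MINFLUX DNA-PAINT localization data of
multi-subunit protein complexes, written for the cardiac ryanodine
receptor (RyR2) / nuclear pore complex (NPC) setting but parameterised
throughout.

MINFLUX localizes single binding events with ~2 nm per-axis precision,
which makes individual protein subunits resolvable — provided the analysis
accounts for which subunits were *not* seen. `minfluxr` covers the full
chain:

* **Trace reduction** — raw localizations sharing a MINFLUX trace ID are
  combined into docking-strand sites, and reappearing markers are merged
  into subunit locations by DBSCAN at ε = 1 nm
  (`combine_traces()`, `merge_subunits()`, `precision_summary()`).
* **Effective labeling efficiency (p_LE)** — the NPC calibration assay:
  Nup96 pores carry two 8-fold rings with 2 tag sites per segment. The
  package detects pores, fits a 3D double-ring template by maximum
  likelihood (`fit_npc_template()`), counts labeled segments (0–16), and
  fits the truncated binomial model
  `k ~ Binomial(16, 1 − (1 − p)²)` conditioned on `k ≥ kmin`
  (`estimate_labeling_efficiency()`, or `run_npc_assay()` end to end).
  Fitted ring spacing and diameter come from `estimate_npc_geometry()`.
* **Tetramer pose recovery** — 3 or 4 resolved subunits of a tag square
  (16 nm GFP square at 45° to the receptor outline, or 20 nm corner-aligned
  TagRFP square) determine the receptor's position and 3D orientation by
  assignment-enumerated Kabsch superposition (`fit_tetramer()`), with
  orientation errors reduced by the square's symmetry group
  (`tetramer_orientation_error()`). Detection algebra:
  `detection_probability(p) = 1 − (1 − p)⁴`, `subunit_count_pmf()`,
  `estimate_ple_from_subunit_counts()`.
* **Functional clustering** — DBSCAN at the 100 nm calcium-induced
  calcium-release coupling distance (`cluster_subunits()`), with
  efficiency-corrected size statistics and subunit→receptor conversion
  (`compute_cluster_stats()`, `su_to_ryr2()`).
* **Rendered-image puncta analysis** — Gaussian rendering
  (`render_2d()`), blob finding (`find_puncta()`), nearest-neighbor
  distances and one-way ANOVA + Tukey HSD group comparison
  (`nn_distances()`, `compare_nn_groups()`).
* **Synthetic ground truth** — seeded generators of NPC fields and
  tetramer/cluster fields with binomial labeling, zero-truncated-Poisson
  site visits and Gaussian localization error
  (`make_npc_ensemble()`, `make_lattice_layout()`,
  `make_tetramer_field()`, `simulate_cluster_appearance()`), so every
  stage is testable against known truth.

Fitted objects are tidyverse-friendly: `tidy()`, `glance()` and
`autoplot()` methods are provided for efficiency estimates, cluster
statistics, pore and tetramer fits, and group comparisons.

## Worked example: recover a known labeling efficiency

Simulate a field of 150 pores at 60% effective labeling efficiency, with
2 nm localization noise, tilts up to 30° and a site-visit rate of 1.18,
then run the full assay on the raw localization table alone:

```r
library(minfluxr)

sim <- make_npc_ensemble(npc_sim_config(n_npcs = 150, p_le = 0.6, seed = 42))
sim
#> <minflux_sim> 150 complexes, 4800 ground-truth sites (2827 labeled),
#>   3307 localizations in 3307 traces

assay <- run_npc_assay(sim$localizations)
assay$ple
#> <ple_estimate> p_LE = 59.6% +/- 0.9% (n = 150 structures)
assay$visit_rate
#> # A tibble: 1 × 2
#>   mean_visits_per_site n_segments
#>                  <dbl>      <int>
#> 1                 1.16       2009
```

The estimate recovers the generating 60% within its standard error, and
the corrected visit rate matches the generator's conditional mean of 1.18.
`autoplot(assay$ple)` draws the cumulative labeled-segment histogram with
the fitted curve. Downstream, cluster statistics use the estimate:

```r
subs <- merge_subunits(combine_traces(sim$localizations))
stats <- compute_cluster_stats(cluster_subunits(subs, eps = 100),
                               p_le = assay$ple$p_le)
glance(stats)[, c("n_clusters", "mean_su", "mean_su_corrected", "mean_ryr2")]
#> # A tibble: 1 × 4
#>   n_clusters mean_su mean_su_corrected mean_ryr2
#>        <int>   <dbl>             <dbl>     <dbl>
#> 1        150    22.0              36.9      9.23
```

(Here each simulated pore becomes one "cluster" of ~22 detected subunits;
dividing by p_LE and by 4 converts to corrected subunit and tetramer
counts — on RyR2 fields the same call yields receptors per cluster.)

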