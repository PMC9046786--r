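---
title: "Weighted white-matter connectome analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted white-matter connectome analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melnet)
library(dplyr)
```

# The analysis in one page

melnet implements a group analysis of structural brain networks for
melancholic versus non-melancholic major depressive disorder (MDD). Each
subject is represented by a 90-node weighted network on the AAL90 cortical
and subcortical parcellation: nodes are atlas regions, and the weight of the
edge between regions *i* and *j* is

\[ w_{ij} = \mathrm{FA}_{ij} \times \mathrm{FN}_{ij}, \]

the mean fractional anisotropy of the reconstructed tracts between the two
regions times the streamline count. The pipeline then:

1. **thresholds** each network over a sparsity grid (5%–45% of all possible
   node pairs, step 5%) keeping the strongest edges at each level;
2. computes **global metrics** (clustering coefficient \(C_p\),
   characteristic path length \(L_p\), global and local efficiency) and the
   **small-world indices** \(\gamma = C_p/C_p^{rand}\),
   \(\lambda = L_p/L_p^{rand}\), \(\sigma = \gamma/\lambda\), normalized by
   the mean of a degree-preserving random ensemble (same node count, edge
   count and degree sequence);
3. computes **six nodal metrics** — betweenness centrality (aBC), strength
   (aDC), clustering (aCP), efficiency (aEfficiency), local efficiency
   (aEloc) and mean shortest path length (aLP) — and integrates every metric
   curve over the sparsity grid (trapezoidal area under the curve, AUC), so
   no single threshold drives the result;
4. tests group differences on the AUCs with **covariate-adjusted ANCOVA**
   (gender, age, years of education), pairwise post-hoc contrasts (adding
   the MADRS total score for the patient-vs-patient contrast),
   **Freedman–Lane permutation** p-values and **Benjamini–Hochberg FDR**
   across the 90 nodes of each metric;
5. correlates implicated nodal attributes with **HRSD-17 item scores**
   (Pearson, FDR-corrected); and
6. discriminates the two patient groups from nodal betweenness features with
   a **leave-one-out cross-validated SVM**.

Because no MRI data ship with the package, a first-class synthetic-cohort
generator reproduces the study design end to end, and every stage is exposed
as an ordinary data-frame-in / tibble-out function.

# Node betweenness centrality

aBC is the fraction of shortest paths between other node pairs that pass
through a node:

\[ \mathrm{aBC}(i) = \frac{1}{(N-1)(N-2)}
   \sum_{h \ne j,\; h \ne i,\; j \ne i} \frac{\rho_{hj}(i)}{\rho_{hj}}, \]

where \(\rho_{hj}\) counts the shortest paths from *h* to *j* and
\(\rho_{hj}(i)\) those passing through *i*. `path_census()` computes exact
distances and path counts (distances by Dijkstra via igraph, counts by a
predecessor recursion over nodes in distance order); `node_betweenness()`
applies the formula over ordered pairs, so values lie in \([0, 1]\) and a
star's center scores exactly 1. Pairs in different components have
\(\rho_{hj} = 0\) and contribute nothing.

# Distances, clustering, and efficiency on weighted graphs

* **Distance rule.** FA×FN weights measure connection strength, so the edge
  length used for shortest paths is the reciprocal, \(d_{ij} = 1/w_{ij}\)
  (config-switchable to binary lengths for sensitivity checks). All
  path-based metrics share one rule per analysis.
* **Weighted clustering.** The per-node coefficient uses the geometric mean
  of triangle weights rescaled by the network-wide maximum,
  \(C_i = \frac{1}{k_i(k_i-1)} \sum_{j,h} (\hat w_{ij} \hat w_{ih}
  \hat w_{jh})^{1/3}\) with \(\hat w = w / \max(w)\). On binary graphs this
  reduces to the ordinary triangle fraction, and on a ring lattice with
  neighbor count \(k\) it matches the closed form \(3(k-2)/(4(k-1))\) (a
  frozen test).
* **Disconnected pairs.** \(L_p\) and aLP average *finite* distances only;
  efficiencies use \(1/\infty = 0\). Both conventions keep the metrics
  finite at sparse thresholds. A node isolated by thresholding has no
  defined aLP; it is recorded as an `NA` sentinel, reported with a message,
  and its AUC becomes `NA` rather than silently extrapolated.
* **Thresholding.** `threshold_by_sparsity()` keeps the
  \(\lfloor s \cdot N(N-1)/2 \rfloor\) strongest edges (capped at the
  available edge count), breaking weight ties deterministically by node
  index, so edge sets are nested along the grid and every run is
  reproducible.

# The null ensemble

Small-world indices are normalized against random networks with the same
\(N\), \(V\) and degree sequence. `generate_null_networks()` uses
Maslov–Sneppen double-edge swaps (igraph's implementation, \(10 V\)
attempted swaps per null), then reassigns the original weight multiset to
the rewired edge set by a seeded permutation. The ensemble therefore
preserves exactly what the normalization requires — topology degrees and the
weight distribution — while randomizing which edges carry which weights;
ensemble means of \(C_p\) and \(L_p\) are indistinguishable from a
swap-tracking implementation at a fraction of the cost. The conventional
ensemble size is 100 per threshold; the packaged tests use 20 (the
ensemble-mean standard error on \(\gamma\) is already below 2% there).

# The synthetic cohort generator

No raw data accompany the study design, so `generate_cohort()` emulates it:

* **Topology.** Each subject's network is an independent Watts–Strogatz
  graph: ring lattice with `k = 8` neighbors, rewiring probability
  `p = 0.1`, 90 nodes — 360 edges per subject. These defaults were fixed
  once, from the requirement that control networks exhibit the small-world
  regime under the package's own metrics: at `k = 8, p = 0.1` a 20-subject
  control cohort shows \(\gamma \approx 5\) and \(\lambda \approx 1.14\)
  (within the \([0.8, 1.2]\) band around 1 the premise requires).
* **Weights.** Edge FA is Beta(6, 6) (symmetric around 0.5, the plausible
  mid-range of white-matter FA); FN is 1 + negative binomial(size 3,
  mean 30), giving the heavy right tail typical of streamline counts.
  Weights are independent across edges and subjects.
* **Group effects.** `inject_node_effect()` plants localized abnormalities.
  `weight-scale` multiplies a node's incident weights (strength/efficiency
  effects); `edge-rewire-toward-hub` re-anchors the node's weakest edges
  onto the strongest non-neighbors to raise its betweenness. The re-anchored
  bridges receive the network's 90th-percentile weight: under the
  inverse-weight rule a weak edge is a long edge that shortest paths avoid,
  so a betweenness-raising bridge must be strong. The manipulation is
  deterministic and touches only the target node's row and column. Moving
  one of eight edges (magnitude 0.125) shifts the node's betweenness AUC by
  roughly two between-subject standard deviations; two edges (0.25, the
  melancholic-group default) by roughly three.
* **Clinical scores.** Age, education, illness duration, MADRS total and
  items 1/2/8, and the HRSD-17 items entering the melancholic-features rule
  are truncated-normal draws with per-group means and SDs taken from the
  study's printed summaries where available; HRSD item distributions are not
  printed and were chosen so that melancholic patients typically satisfy the
  rule and non-melancholic patients typically do not. Items are rounded and
  truncated to instrument ranges (MADRS items 0–6; HRSD item-specific, e.g.
  item 7 in 0–4, item 12 in 0–2); patients respect the inclusion thresholds
  MADRS ≥ 12 and HRSD-17 ≥ 17; controls carry no clinical scores. Gender is
  Bernoulli with per-group male rates matching the printed counts. After
  drawing, records are minimally adjusted so every melancholic-group subject
  satisfies the subtype rule and no non-melancholic subject does; the
  adjustment touches the fewest items able to flip the rule.
* **Subtype rule.** `assign_melancholic_subtype()` implements the two-scale
  rule — MADRS criterion A (item 8 ≥ 4, or item 1 or 2 ≥ 6) AND HRSD-17
  criterion B (item 1 or 7 ≥ 3, plus at least three of: item 6 ≥ 1;
  item 8 or 9 ≥ 2; item 12 or 16 ≥ 2; item 2 ≥ 2). Diurnal mood variation
  is not assessable from either scale and is omitted. Criterion B's
  "depressed mood" item is read as HRSD item 1. Missing items raise an
  error; the rule never silently returns false.
* **Determinism.** One master seed spawns per-group, per-subject and
  per-threshold child seeds through a splitmix-style integer recursion
  (`derive_seed()`), so identical specs give byte-identical cohorts and no
  two stages share an RNG stream.

**What the generator does not emulate:** spatial embedding and distance-
dependent connection probability, hemispheric symmetry, hub architecture
(rich clubs), measurement noise correlated across edges, or any real
anatomical covariance between regions. Tests passing on these cohorts
validate the *machinery* — metric correctness, calibration of the inference,
recoverability of planted effects — not any empirical claim about real
patient populations.

# Inference

* **ANCOVA.** `ancova_group_test()` compares nested least-squares fits
  (covariates-only vs covariates + group) and reports the model-comparison
  F. With no informative covariates this is exactly one-way ANOVA; constant
  covariates are inert and dropped with a message. Genuinely collinear
  designs raise an error naming the offending columns.
* **Permutation.** `permutation_correct()` and the batch functions implement
  Freedman–Lane residual permutation: residuals of the covariate-only model
  are permuted, the statistic recomputed on refitted responses, and
  \(p = (1 + \#\{|T^*| \ge |T|\}) / (1 + B)\). Permuting residuals rather
  than raw labels preserves the covariate structure. For two small groups
  without covariates an exhaustive mode enumerates all label assignments
  instead. The nodal batch functions permute once per iteration and evaluate
  all 90 nodes simultaneously.
* **FDR.** Benjamini–Hochberg step-up, applied per metric across the 90
  nodes (matching how nodal results are conventionally tabulated, one
  family per metric), to the permutation p-values when permutation is on
  and to parametric p-values otherwise. Global small-world metrics form
  their own seven-test family with parametric p-values.
* **MADRS as a post-hoc covariate** is undefined for controls; the pipeline
  adds it only to the patient-vs-patient contrast. Contrasts against
  controls use gender, age and education.
* A caveat worth stating: with \(B\) permutations the smallest attainable
  p-value is \(1/(B+1)\); at \(B \le 1000\) that floor exceeds the BH
  threshold \(q/90\) relevant when a single node carries the effect, so
  detection studies at that scale must either use parametric p-values or
  \(B \gtrsim 5000\). The packaged effect-recovery check uses parametric
  post-hoc p-values.

# Classification

`loocv_svm()` wraps a radial-basis SVM (`C = 1`,
`gamma = 1/n_features` — the common defaults; both exposed) in leave-one-out
cross-validation. Features are z-scored with means and SDs estimated on each
training fold only, so the held-out subject never leaks into its own
predictor; a pure-noise feature stays at chance (a frozen test). The
positive class defaults to the second group (the melancholic/patient class)
and sensitivity/specificity refer to it. Leave-one-out was chosen because
the study-scale patient sample (n = 83) is too small for stable k-fold
estimates.

# Problem sizes used by the packaged checks

The test suite exercises the full stack at sizes chosen to make each
property measurable with comfortable margins: 20-subject control cohorts
with 20 nulls per threshold for the small-world premise; exhaustive metric
verification on all 771 labeled connected graphs with 3–5 nodes plus seeded
random 6-, 7- and 12-node weighted graphs; 1000 simulated null responses
(500 permutations) for calibration; 25 cohorts of 20/20/10 subjects with a two-edge
betweenness manipulation (a ~3 SD shift, the smallest whole-edge dose whose
detection power clears 80% at FDR-corrected thresholds with 20-vs-10
groups) for effect recovery; and 100 label shuffles for classifier chance levels.

# Known limitations

* The generator's networks are homogeneous small-world graphs; they do not
  reproduce hub or modular architecture, so nodal-metric variances are not
  those of real connectomes.
* Weighted clustering follows one (widely used) of several weighted
  triangle formulations; alternatives would change \(C_p\) and \(\gamma\)
  numerically, though not the normalization logic.
* The per-metric FDR family (90 tests) is a convention; pooling all six
  metrics into one family would be more conservative.
* Real-data group differences and classifier accuracies depend on the
  original MRI cohort and are not recoverable from synthetic data; the
  package reproduces the analysis structure and validates its statistical
  behavior, not the empirical findings.
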