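---
title: "Modelling developmental change in weighted structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling developmental change in weighted structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connmature)
```

## The scientific problem

Streamline tractography summarizes a subject's white-matter anatomy as a
weighted network: 82 regions of interest (34 Desikan cortical plus 7
subcortical per hemisphere) as nodes, and the number of reconstructed
streamlines between each pair of regions as edge weights, with a parallel
matrix of mean fiber-tract lengths in millimetres. Across childhood and
early adulthood the total number of streamlines declines substantially,
yet global network properties — edge density, small-world efficiency,
modular organization — stay remarkably stable. The question this package
operationalizes is *where* that loss is concentrated: whether streamline
reduction preferentially detaches from heavy ("thick") tracts, short
tracts, and tracts inside topological modules and hemispheres, sparing the
thin, long, intermodular connections on which small-world and modular
organization depend.

The package provides the full analysis chain: validated I/O for
connectivity matrices and cohort manifests; weighted graph metrics with
null-model normalization; a subject-wise edge taxonomy; GLM trajectory
fitting with nested model selection; repeated-measures slope contrasts;
chi-squared tests of preferential detachment; FDR-controlled edgewise and
nodal analyses with false-coverage-rate (FCR) confidence intervals; and a
synthetic cohort generator so the whole chain is testable without any
imaging data.

## The trajectory model

For a per-subject measurement $y$ (a streamline total, a graph metric, a
single edge's count, a nodal role metric), three nested Gaussian linear
models are considered, with sex coded female = 0, male = 1:

1. linear: $y = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{sex} + \epsilon$
2. interaction: $y = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{sex} + \beta_3\,\mathrm{age}\cdot\mathrm{sex} + \epsilon$
3. quadratic: $y = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{sex} + \beta_3\,\mathrm{age}^2 + \epsilon$

`traj_glm()` fits one form by OLS and returns a classed object with the
usual methods. `select_model()` implements the conservative nested
selection: a higher-order term is retained only when the nested F-test
rejects at $\alpha = 0.05$ *and* both AIC and BIC prefer the bigger model;
whenever the three criteria disagree the model with fewer variables wins.
The interaction and quadratic forms compete with the linear form
separately and are never combined; if both survive, the lower-BIC model is
kept (BIC is the more parsimonious criterion, matching the "most
conservative model" rule; this tie-break is a design choice the data
rarely exercise). Within a retained linear form, the sex and then the age
main effects are dropped under the same triple criterion. The p-value
reported for "the age effect" is the F-test of deleting every term
involving age from the selected model.

Two model-comparison subtleties are worth recording. First, with
cross-sectional data and a within-subject pair of aggregates (thick vs
thin totals, say), slope equality is tested by the difference-score
regression: $d_i = A_i - B_i$ on age, whose age-coefficient F has
$(1, n-2)$ degrees of freedom — with $n = 121$ subjects that is
$F_{1,119}$, and it is algebraically identical to the class-by-age
interaction in a long-format model with per-subject intercepts (a property
the test suite verifies on random data). Second, preferential detachment
is tested by a $\chi^2$ statistic comparing the observed split of
streamline loss between two edge classes against the split expected from
class prevalence alone. The observed "loss" of a class is defined as
$|\hat\beta_1| \times$ age span (the model-predicted loss over the study
window) from the class-total fits; an alternative construction — counts of
significantly decreasing common edges per class against prevalence — is
available via the pipeline's `chi2_mode` flag, since the contingency
construction admits both readings and neither is canonical.

## Graph metrics and numerical choices

* **Distance map.** Weighted efficiency needs an edge distance; we use
  $d = 1/w$ ("stronger = closer"), the standard choice for streamline
  counts, with $d = 1/\log(1+w)$ available as an option for users who
  prefer a compressive map.
* **Efficiencies.** Global efficiency is the mean inverse shortest-path
  distance over ordered pairs, with $1/\infty = 0$, so disconnected
  subjects are handled without error. Local efficiency is the mean over
  nodes of the global efficiency of each node's neighborhood subgraph,
  retaining original weights (the weighted Latora–Marchiori
  neighborhood formulation); nodes with fewer than two neighbors
  contribute zero.
* **Null model.** "Rewired while preserving degree and strength" cannot be
  satisfied exactly for arbitrary weights, so the null model performs
  exact-degree double-edge swaps (10 per edge) on the binary topology and
  then reassigns the original weight multiset by rank-matching on endpoint
  strength, followed by 5 greedy refinement sweeps of pairwise weight
  swaps. Degrees and the weight multiset are preserved exactly; node
  strengths approximately, with a measured correlation contract (≥ 0.9 on
  networks of ≥ 50 edges) enforced in the tests. Efficiency ratios divide
  the empirical value by the mean of 100 rewired networks by default.
* **Community detection.** Louvain maximization of weighted modularity
  with 100 restarts (10 in the cohort-level helpers, where hundreds of
  subjects are processed) and resolution 1, keeping the best-Q partition;
  seeded, so results are reproducible. Per-subject partitions are the
  default for nodal metrics and module classification, with a
  consensus-partition option (detected on the cohort-mean matrix).
* **NMI.** Normalized mutual information uses the geometric-mean
  normalization $I/\sqrt{H_1 H_2}$, with the convention that two
  single-module partitions have NMI 1. This differs from igraph's
  arithmetic-mean (Danon) normalization, which is why the package carries
  its own implementation.
* **Module-role metrics.** Within-module strength z-scores standardize a
  node's intramodule strength against its module peers (sample SD; zero
  dispersion gives z = 0). The participation coefficient is
  $1 - \sum_m (k_{im}/s_i)^2$ with isolated nodes assigned 0.
* **Taxonomy tie-breaks.** An edge exactly at the subject's mean weight is
  "thin", exactly at the mean length "short": thick/long are strictly
  above the mean, which keeps the two defining sentences of the dichotomy
  consistent. Means are taken over the subject's existing edges; a flag
  includes absent pairs as zero lengths instead. Mean-splitting is
  invariant to per-subject standardization, so edge z-scores are exposed
  purely as a diagnostic.

## Multiple comparisons

Edgewise and nodal analyses correct p-values across tests by
Benjamini–Hochberg FDR at $q = 0.05$. Confidence intervals for selected
(rejected) parameters are FCR-adjusted to level $1 - Rq/m$, reducing to
the ordinary $1-q$ interval when everything is selected. Sex-specific
labels for edges require both that the pooled age-by-sex interaction
survives model selection and that the within-sex age-only slope is
significant (after BH across the per-sex tests) in exactly one sex.

## What the synthetic generator emulates

`make_template()` + `simulate_cohort()` generate cohorts with the
statistical structure the analysis assumes, under conditions fixed once as
the package's study defaults:

* 121 subjects, ages uniform on 4–40 years, balanced sexes;
* 82 nodes in two mirrored hemisphere clusters, 4 spatially coherent
  modules spanning both hemispheres, 399 base edges (12% density);
* a bimodal weight distribution: ~25% thick edges (base weight 250–600,
  long-range ones 200–320) carrying most of the streamline mass, thin
  intramodule edges at 40–80 and thin intermodule edges at 5–35 — the
  wide gap makes the subject-mean weight split essentially deterministic;
* per-module heavy scaffolds (two hubs with same-hemisphere spokes plus
  hub–hub and homotopic-like callosal edges) and hub-anchored intermodule
  tracts, so modularity maximization recovers the planted partition
  (NMI ≈ 1 in the test contract) instead of splitting weakly bound module
  halves — an early draft with fully random thick placement failed
  exactly that way;
* aggregate age slopes of −60.184 and −8.685 streamlines/year for the
  thick and thin class totals (total −68.869), with alternative target
  pairs −61.515/−7.354 for short/long and −61.25/−7.619 for intra/inter
  module when the allocation dichotomy is switched; each pair sums to the
  same total;
* a +800-streamline male offset spread over intramodule edges;
* Gaussian noise scaled so the per-subject total has SD 150 (a free
  choice: no residual variances are available for class totals, and 150
  makes the t-statistics plausible at n = 121), rounding to non-negative
  integers, a 128-edge backbone floored at weight 1, non-backbone edges
  present with probability 0.97 per subject, and 2 mm length jitter.

The age decrement is allocated across edges proportionally to base weight
within the active class pair, with the per-class rates solved from a 2×2
linear system so that the *realized* (mean-split) class aggregates have
the configured expected slopes — the system accounts for edge dropout and
for length-jitter flips near the subject-mean length threshold; with a
clean class separation it reduces to plain proportional allocation. In
sex-shifted mode the male decline onset is delayed by a configurable 6
years, emulating a later male developmental peak, which is how the
female-specific long-tract decline (−21.229/year within females) is
produced for testing the sex-specific analysis path.

What the generator does *not* emulate: spatially varying tract curvature,
non-Gaussian count noise (no Poisson/negative-binomial dispersion),
age-dependent edge birth/death, scanner or site effects, and any
registration or tractography artifacts. Passing tests therefore show that
the analysis chain recovers the statistical structure it assumes — linear
class-specific trajectories with additive sex offsets in an otherwise
stationary topology — not that it is robust to the full messiness of
empirical tractography.

## Problem sizes

The packaged checks run the parameter-recovery studies at 200 replicate
cohorts of 121 subjects per configuration, property suites on random
graphs of up to 10 nodes (100 draws), null-ensemble normalization with
20–100 rewired networks, and type-I calibration over 2,000 null fits;
these sizes give replicate-mean standard errors a few percent of the
target magnitudes while keeping a full run in the minutes range on one
core.

## Known limitations

* The repeated-measures contrast is implemented only as the
  difference-score regression (plus its algebraic long-format equivalent
  in tests); no mixed-effects machinery is included, as the cohort is
  cross-sectional.
* The packaged lobe mapping places the rostral anterior cingulate in the
  frontal lobe; atlases disagree about cingulate subdivisions, and users
  can override the mapping by supplying their own parcellation table.
* `rewire_null()` preserves strength only approximately; the refinement
  heuristic is deliberately simple and is contract-tested rather than
  optimal.
* Louvain is a heuristic; with the recommended restarts it is stable on
  networks with clear structure, but partitions of near-degenerate
  networks can vary across seeds.
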