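---
title: "Methods behind the streamclass layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the streamclass layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamclass)
```

streamclass assigns six habitat-layer classifications — size, gradient,
hydrology, temperature, network bifurcation and valley confinement — to
every reach of an NHDPlus-style stream network. This vignette explains the
models and procedures behind each layer, the tunable parameters and why
their defaults are what they are, what the synthetic-data generators emulate
(and what they deliberately do not), and the numerical choices made where
the design was genuinely open.

## The data model

A `stream_network` is purely tabular: a reach attribute table (one row per
reach, keyed by an integer `comid`) and a "from-to" edge table giving
upstream-to-downstream connections. Geometry is deliberately out of the data
model — every operation in the package needs only topology and per-reach
attributes, so shapefile parsing is out of scope. Discharge is held
internally in m³/s; the reader converts from cfs at ingest
(1 cfs = 0.0283168 m³/s) when the unit declaration says so. Holding a single
canonical unit matters because the packaged size-class thresholds are
expressed in m³/s.

Three graph utilities support the layers:

* `compute_strahler_order()` applies the Strahler rule (headwaters are 1;
  a junction where two or more contributors share the maximal order
  increments it, otherwise the maximum propagates). Divergent channels —
  reaches flagged main or secondary below a split — *inherit* the parent
  order, and a junction fed by flagged channels does not increment, since
  the rejoining channels descend from a single parent. Hydrography products
  assign divergent channels an order without documenting the rule; order
  inheritance is this package's documented stand-in, chosen because it keeps
  divergence diamonds order-neutral end to end.
* `accumulate_upstream()` sums any numeric attribute down the network. At a
  divergence, 100% of the parent's accumulation routes down the main (D1)
  channel by default so that rejoining channels never double-count; the
  fraction is configurable (`main_fraction`). When no child is flagged main,
  the lowest-comid child deterministically stands in.
* `upstream_of()` / `downstream_of()` return neighbours sorted by ascending
  comid, a purely cosmetic but determinism-preserving convention.

## The synthetic generators

The generators exist so the entire pipeline is exercisable, with known
ground truth, without any external download. They are first-class, tested
code, and all of them are strictly seeded: the same configuration reproduces
outputs bit for bit.

`generate_dendritic_network()` grows a tree upstream from a single outlet by
tip branching: at each step a random tip either extends as a chain or
bifurcates (probability `branch_prob`, default 0.7, which yields realistic
order distributions — a majority of first-order headwater reaches with an
exponential-decay frequency over higher orders). Planform geometry is not
modelled: only topology and scaling structure matter to the classification.
Two kinds of artefacts are then injected, because the bifurcation layer
exists to handle them:

* **Divergence diamonds** (rate `divergence_rate`, default 0.03): an edge
  p→q is replaced by parallel main and secondary channels that rejoin at q,
  flagged D1/D2. A fraction `misflag_rate` (default 0.1) of diamonds have
  their flags erased *after* orders are computed, emulating hydrography
  that fails to designate some divergences — these are what the generic
  divergence class D downstream is for.
* **Map-boundary splits** (rate `split_rate`, default 0.04): a reach is cut
  into two chained segments sharing an ecological unit id, emulating
  reaches discretised at quadrangle boundaries.

`attach_physical_attributes()` accumulates a lognormal local catchment area
into drainage area A and applies power laws: discharge
Q = c·A^b·exp(ε), ε ~ N(0, sd²) with defaults c = 0.01, b = 0.9, sd = 0.1
(near-linear discharge–area scaling, headwater flows of a few hundredths of
a m³/s); slope S = k·A^(−θ) with k = 0.05, θ = 0.5 (steep headwaters, low
mainstem gradients). A latitude-like coordinate diffuses upstream from the
outlet so landscape covariates are spatially smooth; elevation declines with
log drainage area.

`generate_gage_panel()` emulates gage hydrologic signatures as 13
"component scores" drawn from a Gaussian mixture whose centres sit on a
scaled simplex, so every pair of centres is exactly `separation`
within-cluster standard deviations apart. Every reach carries a latent class
and its own feature vector; sites are sampled reaches. That construction
makes extrapolation honest: the site-to-reach transfer a random forest must
learn really is present in the reach covariates. Missingness is injected
completely at random (`missing_frac`); MCAR is an assumption — the original
compilation imputed roughly 2% missing entries without characterising the
mechanism.

`generate_temperature_sites()` draws sites over reaches *with* replacement
(real monitoring networks put several stations on one reach). True mean
July–August temperature is a fixed linear surface over elevation, latitude
and log discharge, spanning roughly 7–31 °C; screening attributes come from
fixed mixtures chosen so the reference screen has both keeps and rejects in
realistic proportion (50% low/very-low disturbance, DOR uniform on 0–10%,
record windows 1990–2010 plus 3–8 years, 80% of records with ≥ 60
consecutive July–August days). The expected pass rate of the screen is
therefore computable by enumeration, and the tests pin the empirical rate to
it.

`generate_valley_inputs()` gives each reach a hydraulic-geometry river width
(w = 10·Q^0.5 with lognormal noise) and draws valley-bottom coverage and
width ratio from a three-component mixture placed inside the unconfined,
moderately-confined and confined regions of the rule space, so all classes
occur and each component's class is known ground truth. `make_dem_tile()`
builds flat, V-shaped and canyon terrain with closed-form valley widths for
testing the delineation.

What the generators do **not** emulate: daily flow series and the hydrologic
statistics computed from them (component scores are generated directly),
real covariate correlation structure, spatial autocorrelation of classes
beyond the latitude drift, class imbalance, and measurement error in
topology. Passing tests demonstrate that the machinery is correct and that
parameters are recoverable under the stated conditions — not that national
data would yield the same accuracies.

## Size and gradient

The discharge-based size classification derives thresholds from order
medians: median discharge per Strahler order, then mid-points between
consecutive medians as class breaks,
`breaks[i] = (median(order i) + median(order i+1)) / 2`. Medians must be
strictly increasing in order; a violation is a data error naming the
offending orders. Medians are computed in m³/s (the derivation is
unit-covariant only up to scale, so the canonical unit is fixed first).

The packaged national defaults are: size breaks 0.057, 0.283, 1.133, 5.663,
22.65, 70.79, 283.2 m³/s over classes HW, SC, LC, SR, MR, MS, LR, GR;
gradient breaks 0.001, 0.005, 0.02, 0.04, 0.1 (rise/run) over VL, L, M, MH,
H, S; temperature breaks 10, 15, 18, 21, 24 °C over VC, CD, CC, CL, CW, W.
Published threshold tables print touching ranges without stating
inclusivity, so one convention is fixed everywhere: bins are
lower-inclusive / upper-exclusive with the last bin open above (a slope of
exactly 0.02 is MH; a discharge of exactly 283.2 is GR). Missing values
yield an explicit `"unclassified"` label rather than an error — unclassified
reaches are a real, reportable outcome of the workflow, not a failure.

## Network bifurcation

Junction coding renders the combination of Strahler orders at the upstream
end of each reach. The published examples constrain the digit order in two
directions at once: a 1st- and 2nd-order confluence above a 2nd-order reach
codes `2.12` (ascending), while orders 5, 1, 1 above a 5th-order reach code
`5.511` (mainstem first, remainder descending). The adopted rule reproduces
both: with exactly two tributaries the digits ascend; with three or four,
orders equal to the downstream order come first and the rest descend. Edge
rules the source material never addresses are fixed explicitly: more than
four contributors keep the largest four; orders ≥ 10 cannot be single
digits, so the rendering joins tokens with hyphens (`"12.3-10"`) while the
token list stays canonical; reaches with zero *or one* upstream neighbour
code `"<order>_0"` (a single-upstream reach is a mid-channel split, not a
junction), to be overwritten by split correction where an ecological unit
exists.

Divergence classes: D1/D2 come from the main/secondary channel flags; DU
marks a reach whose immediate upstream set contains two or more flagged
channels tracing back to the *same* divergence parent (a rejoin); rejoins of
a single channel do not qualify. The generic class D marks reaches at
*non-sensical junctions*: the stored downstream order contradicts the
Strahler combination of the upstream orders and no upstream reach carries a
divergence flag — the signature of an undesignated divergence. The detection
rule is deliberately conservative: it fires only on junctions (≥ 2
contributors) and is verified against an exhaustive enumeration of small
junction configurations.

Split correction assigns every member of an ecological unit the bifurcation
and divergence class of the unit's topologically upstream-most member. The
operation is idempotent, and a unit whose members do not form one connected
directed path is skipped with a warning rather than guessed at.

## Hydrology

The hydrologic layer machinery is: impute → (optionally reduce) → cluster →
extrapolate → diagnose.

* **Imputation** is chained predictive mean matching, written in the
  package: each incomplete column is regressed on the others over its
  observed rows, and a missing entry takes the *observed* value of one of
  `k_donors` (default 5) nearest neighbours in predicted value, drawn at
  random under the seed. PMM preserves marginal distributions, unlike
  mean-fill, and the tests require it to beat mean-fill in RMSE on
  correlated panels.
* **Dimension reduction** is ordinary PCA (`stats::prcomp`), columns centred
  and by default scaled, kept behind `reduce_dimensions()` since hydrologic
  statistics arrive on heterogeneous scales. The synthetic panel generates
  component scores directly, so the pipeline default skips this step.
* **Clustering** is Ward's minimum-variance agglomeration on Euclidean
  distances (`stats::hclust`, `ward.D2`). All cuts come from one merge
  history, so solutions are nested by construction — a property the tests
  assert rather than assume. Exact merge ties have probability zero on
  continuous features; `hclust`'s internal deterministic handling is
  accepted as the tie-break.
* **Choosing k**: `select_cluster_counts()` converts merge heights into the
  within-cluster SSE profile (each `ward.D2` merge at height h adds h²/2)
  and proposes local maxima of its second difference, largest curvature
  first. This replaces visual dendrogram inspection with something
  reproducible, but the candidates are advisory — `k_list` remains the
  user's choice, and the historical solutions used 2, 4, 8, 14 and ~30
  classes.
* **Extrapolation** is a random forest (500 trees, seeded). The per-reach
  probability vector is the fraction of trees voting for each class; the
  label is the arg-max with ties broken towards the lowest class index.
  Out-of-bag misclassification is the reported error; accuracy is its
  complement. Feature importances are min–max scaled to [0, 1] ascending,
  so the most important feature scores 1.
* **Diagnostics**: `summarize_assignment_probabilities()` tabulates, per
  solution, k, n, OOB error, accuracy, the median predominant vote fraction
  and the expected (chance) probability `1/k`. The expectation is reported
  rounded *half-up* to two decimals (0.125 → 0.13), matching the convention
  of the published diagnostic tables rather than IEEE round-half-even. On
  separable synthetic panels the median vote fraction sits far above 1/k,
  reproducing the qualitative pattern reported for the national product.

## Temperature

Reference screening keeps sites with disturbance "very low" or "low", DOR
strictly below 4% (the strictness matters: 4.0% is rejected), period of
record within 1995–2015 inclusive on both ends, and at least 60 consecutive
July–August days. A missing screening attribute excludes the site, with the
first failing rule logged per site.

The regressor is a seeded random forest on the screened panel. `qwsa` (mean
annual flow divided by drainage area) is excluded from the feature set by
default and *guarded*: supplying a feature list containing it is an error,
because temperature is a function of river size and a size-standardised
discharge term is the one covariate the layer must not use.

Class partitioning uses Fisher–Jenks optimal breaks, written in the package
as the exact dynamic program over contiguous partitions of the sorted
values (no installed R package provides it). The objective is the total
within-class sum of squared deviations; optimality is pinned against
exhaustive search on small inputs, and goodness-of-variance fit
(GVF = 1 − SDCM/SDAM) is non-decreasing in k by construction. "Tabular
accuracy" is adopted as the absolute-deviation analogue of GVF
(1 − Σ|x − class mean| / Σ|x − grand mean|) — a standard diagnostic in map
classification, documented here as a substitution since the term is used in
the source literature without a formula. `select_parsimonious_k()` picks the
smallest k at which both diagnostics gain less than `plateau_delta`
(default 0.02, which reproduces plateau behaviour on well-separated
five-component synthetic mixtures) from k to k+1. Exported breaks are the
maximum value of each class (right-closed); fixed-interval binning of new
values uses the same lower-inclusive convention as size and gradient.

## Valley confinement

Flood stage is a fixed multiple (default 5×) of an empirical bankfull depth
`a·A^b·P^c` over drainage area and precipitation. The coefficients are
config-required with demonstration defaults (a = 0.2, b = 0.3, c = 0.05);
they are not calibrated values and applications should supply regional ones.

`delineate_valley_bottom()` is a simplified flood-height intersection: a
multi-source flood fill outward from the stream cells in which a cell joins
the valley bottom when 4-connected to the stream and no higher than the
elevation of the stream cell it floods from plus the flood height.
Waterbody cells are never delineated. Valley width is valley-bottom area
divided by valley-bottom length (an area-based mean width — whether the
source product used mean or maximum width per reach is unstated, and mean is
the choice consistent with its area/length bookkeeping). On synthetic
V-valleys the delineated half-width converges to the analytic h/s within one
cell at every tested resolution. The full valley-confinement toolbox
(meander cutoffs, slope thresholds) is out of scope; precomputed per-reach
summaries bypass rasters entirely.

River width is predicted by a seeded random forest on log10 width — widths
span several orders of magnitude, and only on the log scale is a
single-figure MSE meaningful — then back-transformed, so predictions are
strictly positive.

The rule engine, with cov the covered length fraction and r the
valley-to-river width ratio: fully inundated → unclassified; cov ≥ 0.5 and
r ≥ 4 → unconfined; (0.25 ≤ cov < 0.5 and r ≥ 4) or (cov ≥ 0.5 and
2 ≤ r < 4) → moderately confined; all else confined. The source rules say
both "at least four times" and ">4X"; the package resolves the conflict in
favour of ≥ on every ratio boundary and documents it, with coverage
boundaries inclusive on their lower side. For partially inundated reaches,
coverage is evaluated over the non-inundated portion and the class applies
to the whole reach. A dense-grid truth table against an independent
restatement of the rules, including all boundary values, is part of the
acceptance tests.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes the enabled layers from one configuration and one
global seed, writing one CSV per layer keyed by COMID, plus a manifest with
the seed, a hash of the scientific configuration and per-layer unclassified
counts. Randomness flows through fixed per-layer offsets of the global seed
(named substreams), so toggling one layer never changes another's output,
and a rerun with the same configuration is byte-identical — the manifest
deliberately contains no timestamps. A failing layer leaves earlier outputs
in place and raises an error naming the layer.

Default problem sizes — 500-reach networks, 200–300 gage sites, 500-tree
forests, temperature panels of a few thousand sites before screening — are
the package's chosen desk-scale study conditions: large enough that scaling
exponents, cluster structure and screening rates are estimated stably, small
enough that the whole suite runs in well under a coffee break.

## Known limitations

* The Strahler inheritance rule for divergent channels, the ≥ 2-rejoin
  requirement for DU, the largest-four truncation and the hyphenated
  rendering for orders ≥ 10 are documented conventions for situations the
  source material leaves open, not derived facts.
* The elbow and plateau selectors are heuristics; they propose, the user
  disposes.
* Ward's agglomeration is greedy: its cuts equal exhaustive minimum-SSE
  partitions on small separated data (tested), but global optimality is not
  guaranteed in general.
* The confinement layer consumes per-reach valley summaries; the simplified
  delineation is validated on synthetic terrain only.
* Synthetic panels are far cleaner than national compilations; reported
  OOB errors and vote fractions on them bound what the machinery can do,
  not what real data would give.
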