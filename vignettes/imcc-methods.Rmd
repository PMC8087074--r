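---
title: "Quantifying inter-module coordination in weighted co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-module coordination in weighted co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(imccr)
library(dplyr)
```

## The problem

Weighted gene co-expression analysis decomposes a transcriptome into
modules of tightly co-regulated genes. Most downstream interpretation
stops at the module level, but much of the biology — signal relay,
competition for shared regulators, coordinated stress responses — lives
*between* modules. When a perturbation (a disease state, a multi-target
drug) rewires a network, it is often the inter-module architecture that
changes, not the module memberships themselves.

`imccr` scores the coordination of every module pair with a single
number, the **inter-module coordination coefficient (IMCC)**, and builds
the downstream machinery on top of it: a module-level "modular map",
whole-map rewiring statistics across conditions, connector-module
detection, and a dissociation rate that quantifies how a focal module
pair scatters when conditions change.

## The score

For a weighted undirected network with adjacencies $a_{ij} \in (0,1]$
and a disjoint module partition, three parameters are computed per
module pair $(M_x, M_y)$ that shares at least one edge:

* **SW (sum of weights)** — direct connectivity:
  $SW = \sum_{i \in M_x,\, j \in M_y} a_{ij}$.
* **PS (path strength)** — indirect connectivity through three-node
  paths. For each mediator gene $m$ outside both modules,
  each outset $o \in M_x$ and end $e \in M_y$ contribute
  $(W_{m,o}/W_m)\,(W_{m,e}/W_m)$, where $W_m$ is $m$'s total incident
  weight. Each term is the product of two "routing probabilities" and is
  bounded by $1/4$.
* **CT (consistency score)** — shared-partner connectivity. Every gene
  $i$ outside both modules contributes
  $\min\!\big(CM_{x,i} - \tfrac{S}{C}CL_i,\; CM_{y,i} - \tfrac{T}{C}CL_i\big)
  \cdot \tfrac{CM_{x,i} CM_{y,i}}{CL_i} \cdot W_i$,
  where $CM_{\cdot,i}$ counts $i$'s links into each module, $CL_i$ and
  $W_i$ are $i$'s degree and weighted degree, $S, T$ the module sizes and
  $C$ the network's gene count. The min-term centers the observed link
  counts on their null expectation, so a gene only adds signal when it is
  linked to *both* modules more than its degree predicts.

SW and PS are screened with hypergeometric upper tails ($p < 0.05$): the
SW screen asks whether the pair's observed cross-edge count is enriched
among its $|M_x||M_y|$ possible cross pairs relative to the
condition-wide totals; the PS screen asks the same question of mediator
genes among the external genes adjacent to at least one of the two
modules. CT, already a contrast against a theoretical value, is screened
by a fixed cutoff ($CT > 10$, strict). Screened SW and CT are min-max
normalized and combined:

$$IMCC_1 = \alpha\,SW' + \beta\,CT', \qquad \alpha + \beta = 1,\;
\rho = \alpha/\beta; \qquad IMCC_2 = SW + PS .$$

Calibration (below) selects $\rho = 1$, at which the weighted score is
monotonically equivalent to the simple sum, so the final score is
$IMCC = SW' + CT'$ for the pairs passing both screens.

```{r}
design <- planted_design(seed = 11)      # 374 genes, 20 modules, 15 planted pairs
sim <- make_modular_network(design)
scores <- score_condition(sim$network, sim$partition)
glance(scores)
head(compute_imcc(scores), 3)
```

## Choices made where the construction was open

Several details of the score are under-determined by its defining
formulas; the package fixes them as follows.

* **Pair universe.** Only module pairs joined by at least one direct
  edge are scored; PS, CT and the screening totals use that same
  universe. Unordered gene pairs are counted throughout.
* **Hypergeometric parameterization.** The population for the SW screen
  is the summed $|M_x||M_y|$ over scored pairs with the summed observed
  cross-edge count as the marked class; the PS screen replaces edges
  with mediator genes and possible cross pairs with adjacent external
  genes. Tails are evaluated in log space via `stats::phyper` and
  cross-checked in the tests against explicit combinatorial sums.
* **Normalization scope.** Min-max normalization is applied to the
  *screened-valid* values of each parameter (a parameter that failed its
  screen never influences the normalization range). A constant vector
  normalizes to all zeros rather than 0/0.
* **CT boundary.** `ct == ct_cutoff` is not valid (strict inequality);
  the CT sum runs over genes outside both modules — a member gene's own
  links are direct, not shared-partner, evidence.
* **Both-screens rule.** A pair receives a final IMCC only when the SW
  *and* CT screens pass. Using the single surviving parameter instead is
  available for sensitivity analysis by treating the missing normalized
  value as zero, but it is not the default because it mixes evidence
  classes with different nulls.
* **Ties.** Final ranking ties break by raw SW, then lexicographic pair
  label, so output ordering is deterministic.

## Calibrating the integration against function

Whether direct or shared-partner connectivity should dominate is an
empirical question about biology, not topology. The package answers it
the way the score was designed to be answered: module pairs that share
enriched functional categories should score higher. Annotation
similarity is the Jaccard index $JS = |A \cap B| / |A \cup B|$ of the
two modules' category sets (e.g. 6 shared categories of 11 total gives
$JS = 0.54545$). `scan_rho()` recomputes $IMCC_1$ on a grid of
weighting ratios ($\rho = 1/10 \ldots 10$), fits the logarithmic model
$JS = a \ln IMCC_1 + b$ after a one-pass outlier rule (externally
studentized residual $> 3$), and keeps the $\rho$ with the best
$R^2$ (ties resolve toward $\rho = 1$). `compare_integrations()` runs
the same fit for raw SW and for $IMCC_2$ and reports the winner.

The model family offered — linear, logarithmic, power, exponential — is
the classical curve-estimation set; $R^2$ is reported on the scale on
which each model is linear (the log-y families are fitted and assessed
on their linearized scale). `imasp()` provides the topological
cross-check: the mean shortest-path hop count between the two modules'
genes, with unreachable pairs excluded and counted. Hop counts are used
because the network is a thresholded adjacency; an inverse-weight
distance variant sits behind `weighted = TRUE`.

```{r}
ann <- make_annotations(sim$partition, design$coordination, seed = 11)
scan <- scan_rho(scores, ann)
tidy(scan)
```

## The modular map and global rewiring

`build_map()` lifts the scored pairs to a module-level graph (nodes =
modules, edge weight = final IMCC). `topo_summary()` reports eight
whole-map statistics; path-based quantities use unweighted edges, and
"centrality" is Freeman degree centralization
$\sum_i (k_{max} - k_i) / ((n-1)(n-2))$ — 1 for a star, 0 for a clique —
which is the natural summary of a core–periphery architecture
(a betweenness-based centralization is available behind a flag).

Distribution shifts between conditions are assessed on the
$-\log_2(IMCC)$ scale: scores are binned into four right-closed
intervals (edges default to the reference condition's quartiles; any
explicit published edges are accepted), compared with a 2×4 chi-square
test on counts (no continuity correction; bins with expected count
below 1 are merged with a neighbour), projected by centered, unscaled
PCA of the relative frequencies, and summarized by the Euclidean
distance of each condition to the reference in the min-max-normalized
(mean weight, density, centralization) space — 0 for the reference,
at most $\sqrt{3}$.

## Connectors, the pathological module pair, and dissociation

Three detectors triangulate the modules that broker inter-module
traffic: the top 10% by normalized betweenness (ceiling, ties included);
VRCD, which deletes each module and takes
$\eta = \Delta s / \Delta t$, the ratio of the relative change in
characteristic path length to the relative change in density, calling
modules above twice the mean $\eta$; and an edge-weight filter (incident
weight strictly above 0.1). The consensus of the three is the connector
set, and the consensus pair with the strongest IMCC edge is the
pathological module pair (PMP); if no consensus pair shares an edge, no
PMP is forced.

VRCD conventions worth knowing: path lengths after deletion are averaged
over the remaining connected pairs; a module whose deletion leaves
density unchanged (every module of a clique) has no defined $\eta$ and
is excluded from the mean — a clique therefore yields an *empty*
connector set; a module whose deletion disconnects every remaining pair
destroys all communication and is a connector by definition (reported
with $\eta = \infty$); the mean is taken over signed (not absolute)
finite ratios.

`trace_pmp()` follows the PMP's genes into another condition's
partition and summarizes the scatter with the dissociation rate
$DR = (n_B / n_A)(N_A / N_B)$, which is invariant to proportional
growth of the succeeding state's module count. Genes absent from the
other partition are tallied as "lost" and excluded from $n_B$.

```{r}
dissociation_rate(2, 15, 48, 23)
```

## What the generator emulates — and what it does not

`planted_design()` + `make_modular_network()` produce networks at the
scale of a focused disease panel: 374 genes, 20 modules (within the
15–48 per-condition range such panels yield), a 30-gene background pool,
dense intra-module blocks (weights 0.6–0.95), and 15 planted pairs whose
cross-edge count and weight, mediator count (6 per unit strength, wired
to up to 4 genes per side) and annotation sharing all scale with a
planted strength in $[0,1]$. Background genes additionally attach weakly
to a single random module so the mediator screen has a non-trivial null.
`make_expression()` generates the matching block-correlated Gaussian
data (one latent profile per module; default 50 samples, noise sd 0.5);
`rewire_condition()` produces aggregated (cross edges added toward a
clique-like map) or dispersed (cross edges pruned, survivors widened,
a focal pair scattered over a known landing set) variants with ground
truth attached.

The generator reproduces the *structure* the score consumes, not
microarray physics: no heteroscedastic noise, no batch effects, no
correlated measurement error, and annotation sharing is planted rather
than arising from real pathway biology. Passing recovery tests
(Spearman between planted strength and IMCC of at least 0.8 over 15
planted pairs, exact recovery of planted dispersion) therefore
demonstrates internal consistency of the machinery, not performance on
real arrays. Conversely, condition-specific headline statistics of a
real system (absolute map topology values, calibration $R^2$ values,
per-condition module counts) depend on the particular expression cohort
and a full WGCNA run; the package's checks cover every quantity that is
computable from stated inputs — worked numbers, arithmetic identities,
and the oracle and recovery suites.

Problem sizes throughout the tests (374-gene networks, 8–10-node maps
for the enumeration oracles, 20 seeds per property) were chosen so that
brute-force oracles — triple loops for PS, combinatorial tail sums,
exhaustive shortest-path enumeration, Floyd–Warshall — remain exact and
fast; generation and scoring of a full synthetic condition takes
seconds.

## Known limitations

* The hypergeometric screens are raw (no multiplicity correction),
  matching the method's definition; with many module pairs the SW screen
  is anti-conservative.
* The VRCD ratio is sign-sensitive: a high-degree hub whose removal
  *raises* density can score negatively even when it elongates paths.
  The complete-disconnection convention above catches the extreme case,
  but intermediate hub configurations are better caught by the
  betweenness detector — which is why connectors require consensus.
* Min-max normalization couples a pair's final IMCC to the condition's
  extreme pairs; comparisons across conditions should therefore use the
  distribution machinery (binning on a common grid), not raw IMCC
  differences.
* `pick_soft_power()` uses an equal-count-bin scale-free fit index; on
  very small networks (fewer than ~3 distinct connectivity values) the
  index is undefined and the candidate with maximal defined fit is
  returned.
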