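---
title: "Structural covariance networks from regional brain morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks from regional brain morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The method

A structural covariance network is a graph whose nodes are brain regions
and whose edges are inter-regional Pearson correlations of a morphometric
measure -- cortical thickness or subcortical volume -- computed **across
subjects within a group**. Regions whose anatomy co-varies across
individuals are taken to be structurally related, so the topology of the
correlation network summarizes the covariance organization of a whole
group. Because the correlation is taken over subjects, the construction is
group-level by design: there is one network per group, not per subject,
and group inference must therefore work by re-allocating subjects between
groups rather than by comparing per-subject statistics.

`scnet` implements the full analysis chain:

1. **Ingest** (`readMorphometry`): tab-delimited tables in the dialect of
   FreeSurfer's `aparcstats2table` / `asegstats2table` (rows = subjects,
   one column per region) plus a covariate CSV (`subject_id, group, age,
   icv`). The default region catalogue has 86 bilateral entries -- 68
   Desikan-Killiany cortical parcels carrying thickness and 18 subcortical
   structures carrying volume -- but any catalogue can be supplied; the
   node set is configuration, not a constant.
2. **Nuisance correction** (`correctICV`, `residualizeAge`): volumes are
   first rescaled by each subject's intracranial volume relative to the
   sample mean (proportional correction; a regression variant is a
   switch), then every region is residualized on age by ordinary least
   squares over the pooled sample. The residuals are what all network
   construction consumes.
3. **Association matrices** (`associationMatrix`): per group, the regions
   x regions Pearson correlation matrix of residuals, with negative
   entries replaced by zero. Only positive covariance is interpreted as
   connectivity.
4. **Density thresholding** (`binarizeAtDensity`): the K = round(d P)
   strongest correlations become the edges of a binary undirected graph,
   P = N(N-1)/2, so any two groups are compared at identical wiring cost.
   `minimumDensity` finds the smallest grid density at which every group's
   network forms a single connected component; `maximumDensity` caps the
   range where the small-world index drops below 1.5, above which
   networks become increasingly random.
5. **Topology** (`clusteringCoefficient`, `characteristicPathLength`,
   `transitivityCoefficient`, `modularityQ`, `globalEfficiency`,
   `betweennessCentrality`): binary undirected metrics of segregation and
   integration, normalized against a Maslov-Sneppen degree-preserving
   rewired null ensemble (`normalizedSmallWorld`): gamma = C /
   \<C~rand~\>, lambda = L / \<L~rand~\>, sigma = gamma / lambda.
6. **Hubs** (`identifyHubs`): a region is a hub when its betweenness lies
   1 SD (liberal) or 2 SD (strict) above the network mean.
7. **Inference** (`permutationTestGlobal`, `permutationTestRegional`,
   `maxStatisticCorrection`): residual-reallocation permutation tests,
   with maximal-statistic familywise correction across the density grid
   for global metrics and Benjamini-Hochberg FDR across regions for nodal
   betweenness.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| density grid step | 0.01 | resolution of the analyzed density range (densities are reported to two decimals) |
| minimum-density criterion | `connected` | `connected` demands one component so path length is defined; `no_isolates` only forbids degree-0 nodes |
| maximum-density rule | `sigma_threshold` (1.5) | largest density at which every group still has sigma > 1.5; a `fixed` value is the alternative |
| null ensemble | 20 networks, 10 rewires/edge | Maslov-Sneppen ensemble behind gamma/lambda/sigma; disconnected nulls are rejected and resampled (up to 10x the ensemble size) so L stays finite |
| permutations | 1000 | residual re-allocations per test; the +1-smoothed percentile p never reaches 0 |
| hub SD denominator | population (n) | the sample (n-1) variant is a switch; the choice is recorded in every report |

## What the synthetic generator emulates

`generateCohort` draws regional measures from a multivariate normal whose
correlation matrix is block-structured: regions in the same community
(default: the five lobe groups) correlate at `withinCommunityR` (default
0.4), regions in different communities at `betweenCommunityR` (default
0.1) -- values typical of morphometric covariance. Planted hub regions
get their cross-community correlations raised by `hubBoost` (default
0.4), which is how a group-specific, highly connected region is built in.
Latent unit-variance values are mapped onto measurement scales (thickness
2.5 mm, SD 0.15; volume 4000 mm^3, SD 400), a linear age effect is added
(defaults: -0.005 mm/yr thickness, -10 mm^3/yr volume, ages N(35, 12^2)),
and volumes are multiplied by the subject's ICV (N(1.5e6, 1.5e5^2) mm^3)
relative to the population mean. Age and ICV are sampled independently of
group by default, so the null of "no group difference" is exactly true
and the permutation test's type-I error can be measured cleanly;
group-confounded variants are opt-in (`groupConfounds`). Default group
sizes are 23 and 16 subjects, a realistic small clinical cohort.

A boosted hub row can make the block-structured target matrix indefinite
-- in fact, a correlation of 0.5 between one region and dozens of mutually
weakly-correlated partners is geometrically infeasible, because the
implied Gram vector would have norm greater than one. The generator
therefore applies a nearest-PSD repair (eigenvalue clipping at zero with
the diagonal re-normalized to one). The realized plant is consequently
somewhat weaker than the nominal boost: with the default 86-region
catalogue a +0.4 boost realizes cross-community correlations near 0.43
instead of 0.5. This is a property of correlation geometry, not of the
sampler, and anyone interpreting recovery experiments should compare
against the *repaired* target, which the truth sidecar's parameters allow
reconstructing.

What the generator does **not** emulate: spatially autocorrelated
measurement noise, non-Gaussian morphometry distributions, site and
scanner effects, hemispheric asymmetries, and segmentation failures.
Passing recovery tests therefore demonstrate that the pipeline detects
covariance structure of the planted kind; they do not certify performance
on real MRI-derived tables.

## Numerical choices

* **Edge ranking and ties.** Binarization keeps the K largest
  correlations; ties are broken deterministically by higher correlation
  first, then the lexicographically smaller region-index pair. With a
  fixed tie rule, edge sets nest monotonically in density, and byte-level
  reproducibility holds end to end.
* **Degenerate residuals.** A zero-variance residual column yields zero
  correlations plus a warning rather than an error, so degenerate
  synthetic cases and permutation replicates do not abort a run.
* **Betweenness normalization.** Betweenness is reported as raw unordered
  pair counts. Hub detection standardizes within network, so the
  convention cannot change hub calls.
* **Mean clustering** averages over all nodes, counting degree-<2 nodes
  as 0 (the dominant convention).
* **Community detection** behind modularity Q is seeded Louvain; any
  reported Q is re-derivable from the returned partition by the Newman
  formula, which the tests assert to 1e-12.
* **Permutation replicates** are evaluated on the observed data's fixed
  density grid, including the observed minimum density, rather than
  recomputing a minimum density per replicate; a fixed grid keeps the
  null exchangeable across the metric family used by the
  maximal-statistic correction. Replicates where a metric is undefined at
  a density (a fragmented permuted network, for path length) are skipped
  and counted.
* **Two-tailed p** is the percentile position of |observed| in the
  |null| distribution with +1 smoothing: p = (1 + #\{|null| >=
  |observed|\}) / (nPerm + 1), so p is never 0 and never exceeds 1.
* **Compiled kernels.** All-pairs BFS distances, Brandes betweenness and
  the nested-density metric profile are implemented in C++ because the
  permutation engine evaluates hundreds of thousands of thresholded
  graphs; the R-level metric functions share the same kernels, and the
  test suite pins both against brute-force enumeration oracles.

## Design choices where the design was open

* **Pooled age residualization.** Residuals are fitted over both groups
  together. Per-group fitting would absorb genuine group differences into
  the nuisance model; it remains available as `scope = "per_group"`.
* **Stage order ICV then age.** Proportional ICV correction is applied
  before, and independently of, the age regression; a regression-based
  ICV correction is available behind the same switch.
* **"Not fragmented" means connected.** The minimum density demands a
  single connected component, which subsumes the weaker requirement that
  every node have at least one connection; characteristic path length is
  ill-defined across fragments. The weaker criterion is available as
  `min_density.criterion = "no_isolates"`.
* **Maximum density by sigma threshold.** The analyzed range is capped at
  the last density where sigma > 1.5 for every group; a fixed cap is the
  configurable alternative.
* **Node count is configuration.** The default catalogue has 86 regions,
  and every operation takes the catalogue from its input object, so
  analyses at other parcellation sizes need no code changes.

## Problem sizes used in validation

The shipped validation harnesses are sized for a single CPU: oracle
equivalence uses 200 random graphs of at most 8 nodes (where brute-force
path enumeration is exact and cheap); the type-I-error study uses 200
confound-free cohorts of two groups of 20 subjects over 40 regions with
200 permutations each, evaluated over a 21-density grid; planted-hub
recovery uses 50 cohorts of 100 + 100 subjects over the default 86
regions with 1999 permutations (1999 is the smallest count whose FDR
step-up can call a single region at q < 0.05 across 86 regions, since the
smallest attainable q is 86 / (nPerm + 1)).

## Known limitations

* Group-level networks only: no per-subject networks, no weighted or
  directed variants, and no association of network measures with
  per-subject covariates beyond the nuisance model.
* Regional inference on betweenness at the minimum density is
  conservative by construction. The permuted null retains the planted
  covariance structure in diluted form (every permuted group contains a
  mixture of both groups' subjects), and betweenness on just-connected
  graphs is volatile, so the null distribution of a genuinely different
  region is heavy-tailed. In the shipped recovery harness the planted
  region reaches the permutation floor (p = 1/(nPerm+1)) in most seeds,
  yet the FDR-corrected detection rate at q < 0.05 sits near 75 percent,
  short of an 80 percent power target; the 2-SD hub call, which
  does not require beating the permuted null, recovers the plant
  essentially always. Users planning regional inference should expect
  betweenness FDR calls to demand either large effects or more subjects.
* The sigma-threshold maximum density requires null ensembles per density
  and is the slowest stage of a full run; use the fixed rule for quick
  looks.
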