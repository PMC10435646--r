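# scnet — structural covariance networks from regional brain morphometry

`scnet` builds and compares group-level **structural covariance networks**:
graphs whose nodes are brain regions (cortical parcels and subcortical
structures) and whose edges are inter-regional Pearson correlations of a
morphometric measure — cortical thickness or subcortical volume — computed
across the subjects of a group. It is written for neuroimaging researchers
who have FreeSurfer-style regional summary tables (`aparcstats2table` /
`asegstats2table` output) for two groups and want the standard
graph-theoretical comparison: small-world topology against degree-preserving
null models, hub detection on betweenness centrality, and nonparametric
group inference by subject re-allocation.

## The analysis in brief

For each group, age-residualized (and, for volumes, ICV-corrected) regional
measures give an N×N association matrix *R* of Pearson correlations with
negatives set to zero. *R* is thresholded into a binary undirected adjacency
matrix *A* at an exact edge density *d* (the K = round(d·P) strongest
correlations, P = N(N−1)/2), over a density range from the smallest *d*
where every group's network is connected up to the largest *d* where the
small-world index stays above 1.5. On each network the package computes
mean clustering *C*, characteristic path length *L*, transitivity *T*,
modularity *Q*, global efficiency *E*glob and nodal betweenness *BC*, and
normalizes against an ensemble of Maslov–Sneppen rewired graphs:

γ = C/⟨C_rand⟩, λ = L/⟨L_rand⟩, σ = γ/λ (small-world if σ > 1).

A region is a **hub** when its *BC* lies 1 SD (liberal) or 2 SD (strict)
above the network mean. Group differences are tested by re-allocating
subjects' residual profiles between groups (1000 permutations by default),
rebuilding both networks per replicate, and reading a two-tailed p from the
percentile position of the observed difference; maximal statistics correct
global metrics across the density grid, Benjamini–Hochberg FDR corrects
regional betweenness across regions.

A synthetic-cohort generator (`cohortSpec`/`generateCohort`) produces
two-group morphometry tables with known covariance communities, planted
hub regions, age effects and ICV scaling, so the whole pipeline is testable
against ground truth without any imaging data.

## Worked example

```r
library(scnet)

## a small synthetic cohort: 15 + 12 subjects, 86 regions, one planted
## hub region in group A
spec <- cohortSpec(nPerGroup = c(A = 15, B = 12),
                   plantedHubs = list(A = "L Inferior temporal"),
                   seed = 42)
x   <- generateCohort(spec)
res <- residualizeAge(correctICV(x))

RA <- associationMatrix(res, "A")
RA
#> AssociationMatrix: 86 regions, group 'A' (n = 15 subjects)
#>   off-diagonal r: 2115 positive / 3655 total, max 0.878

dMin <- minimumDensity(list(RA, associationMatrix(res, "B")))
dMin
#> [1] 0.12

A <- binarizeAtDensity(RA, dMin)
A
#> BinaryNetwork: 86 nodes, 439 edges, density 0.120

normalizedSmallWorld(A, ensembleSize = 10, seed = 1)[c("gamma", "lambda", "sigma")]
#> $gamma
#> [1] 2.312063
#> $lambda
#> [1] 1.204693
#> $sigma
#> [1] 1.919214

hubs <- identifyHubs(betweennessCentrality(A), regionCatalogue(res))
head(hubs[order(-hubs$z), c("region", "lobe", "z", "hub_1sd", "hub_2sd")], 3)
#>                            region                     lobe        z hub_1sd hub_2sd
#>               R Inferior temporal temporal-limbic-striatal 3.439745    TRUE    TRUE
#>  R Banks superior temporal sulcus temporal-limbic-striatal 2.997099    TRUE    TRUE
#>               L Inferior temporal temporal-limbic-striatal 2.672814    TRUE    TRUE
```

The planted hub and its strongly covarying temporal neighbours top the
betweenness ranking as strict 2-SD hubs (z ≈ 2.7–3.4). σ ≈ 1.9 > 1 says
the group-A network is small-world: clustering well above the rewired
ensemble (γ ≈ 2.3) at near-random path length (λ ≈ 1.2).

A permutation test for a global metric over the density grid:

```r
grid <- densityGrid(dMin, 0.44, 0.01)
pt <- permutationTestGlobal(res, "global_efficiency", grid,
                            nPerm = 1000, seed = 42)
head(maxStatisticCorrection(pt), 2)
#>              metric density    observed         p p_corrected
#> 1 global_efficiency    0.12 -0.01104423 0.6493506   0.7552448
#> 2 global_efficiency    0.13 -0.01153671 0.5984016   0.7292707
```

No significant efficiency difference — the two groups come from the same
population apart from the planted hub, and a single boosted region barely
moves global efficiency.

The whole chain, with CSV/GraphML artifacts and a provenance log, is one
call: `runPipeline(readRunConfig("inst/extdata/demo_config.yaml"),
output_dir = "out")`.

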