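# CoexNets

Gene association measures and transcription-factor coordination networks
for coexpression analysis.

## What this package is for

Coexpression networks are built by scoring statistical association
between expression profiles, and the choice of the association measure
changes the network — and the biology read from it — more than most
downstream settings. CoexNets implements eight measures behind one
calling convention so they can be compared on equal footing:

| id | statistic | independence test |
|---|---|---|
| `pearson` | sample correlation r | t = r·sqrt((n−2)/(1−r²)), n−2 df |
| `spearman` | rho = r of average-tie ranks | same t form on rho |
| `kendall` | tau-b (tie-corrected) | normal approx., null var 2(2n+5)/(9n(n−1)) untied, tie-corrected otherwise |
| `weighted_rank` | rW = 1 − 6Σd²ᵢ((n−Rᵢ+1)+(n−Sᵢ+1))/(n⁴+n³−n²−n) | normal approx. with the *exact* permutation-null variance per n |
| `hoeffding` | Hoeffding's D from ranks R, S and bivariate rank Q | conservative bound min(1, Var₀(D)/D²); optional permutation p |
| `dcov` | squared distance covariance (double-centered distances) | seeded permutation test, add-one corrected |
| `theil_sen` | median of all pairwise slopes | Wilcoxon signed-rank on the slope multiset |
| `rank_theil_sen` | Theil-Sen on rank-transformed data | same |

On top of the measures, the package provides the full comparison
pipeline: genome-wide partner ranking with a deterministic tie-break
order (`associateAll`), TF coordination networks from top-100 list
overlaps with the strictly-more-than-k edge rule (`buildCoordinationMatrix`,
default n = 100, k = 30), the greedy Triple-Link decomposition into
ordered TF clusters (`tripleLinkDecompose`: heaviest-edge seed, third
member needs significant links to both seeds, later members need at
least three), pathway S/D/N scoring with slice confusion metrics and the
divide-by-nine rescaling (`sliceConfusion`), positive-gene cluster
scoring, Shapiro-Wilk normality profiling, the ten-category r-vs-rho
pair classifier, and a synthetic-data generator with planted pathway
blocks and coordinated TF groups (`simulateExpression`,
`simulateTFCoordination`) so everything runs without external data.

## Worked example

Simulate a compendium with five planted groups of eight coordinated TFs,
build the Spearman coordination network, and decompose it:

```r
library(CoexNets)

sim <- simulateTFCoordination(simConfig(noiseSd = 0.5, seed = 1))
tfs <- names(sim$truth$tfGroup)
cm  <- coordinationFromExpression(sim$matrix, tfs, "spearman",
                                  nTop = 100, kMin = 30)
cm
#> CoordinationMatrix: 40 TFs, 780 edges (nTop = 100, kMin = 30)

res <- tripleLinkDecompose(cm)
res
#> TripleLinkResult: 5 clusters, 0 singletons, threshold = 74.33
#>   cluster 1 (seed overlap 97): TF009, TF010, TF013, TF014, TF011, TF016, TF015, TF012
#>   cluster 2 (seed overlap 97): TF019, TF020, TF018, TF022, TF017, TF024, TF021, TF023
#>   cluster 3 (seed overlap 97): TF025, TF030, TF027, TF029, TF028, TF032, TF026, TF031
#>   cluster 4 (seed overlap 97): TF035, TF038, TF036, TF037, TF034, TF039, TF040, TF033
#>   cluster 5 (seed overlap 95): TF001, TF007, TF005, TF003, TF006, TF004, TF008, TF002
```

The network has 140 strong within-group edges plus several hundred weak
ones from the shared global-activity program; the significance threshold
(mean + SD of the nonzero overlaps, here 74.3) separates them, so
Triple-Link recovers the five planted groups exactly — each cluster is
one TF group, seeds ordered by decreasing overlap. A single pairwise
test looks like:

```r
associationTest(sim$matrix["TF001", ], sim$matrix["TF002", ], "spearman")
#> AssociationResult [spearman]: statistic = 0.830675, p = 2.21e-16, n = 60
```

the statistic being Spearman's rho across the 60 samples and the
p-value its two-sided t-approximation test of independence.

A command-line front end covering
`associate | network | decompose | evaluate-pathways | normality | simulate`
is installed at `inst/scripts/coexnets`, e.g.

```sh
Rscript inst/scripts/coexnets simulate --kind tf-coordination --seed 1 --output expr.tsv
Rscript inst/scripts/coexnets associate --input expr.tsv --query TF001 --method spearman --output ranked.tsv
```

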