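# RadVisSeg

Radial-coordinate visualization and cluster segmentation of
multidimensional patient questionnaire data.

## What this is for

Clinical registries score each patient on many test items at once — here
the motivating case is a staged dementia cohort (SMI, MCI, VCI, SVD, AD)
measured on the 15-item Seoul-Instrumental Activities of Daily Living
questionnaire (S-IADL, 0–3 Likert per item, higher = better daily
function). Clinicians exploring such data want to see all items at once,
carve the cohort into groups with similar profiles, and inspect what
distinguishes the groups. RadVisSeg is a reproducible batch engine for
that workflow, aimed at analysts collaborating with clinicians: every step
is a seeded function call, every output a text artifact.

## The method

Each variable $i$ with declared bounds $V_{min}(i) \le V_{max}(i)$ maps a
raw value $N(i)$ to a position between per-variable bounds
$P_{min}(i) < P_{max}(i)$:

$$N_p(i) = \frac{N(i)-V_{min}(i)}{V_{max}(i)-V_{min}(i)}
\,(P_{max}(i)-P_{min}(i)) + P_{min}(i)$$

With the default bounds 0 and 1 this is min–max normalization, $u_i \in
[0,1]$. Variables become *dimensional anchors* at equidistant angles on a
circle (2D) or vertical edges of a cylinder (3D). In 2D a patient sits at
the anchor-weighted barycenter $\sum_i u_i a_i / \sum_i u_i$ — high values
pull hard toward their anchor. The 3D variant adds height $z = H\,\bar u$:
proportional profiles that overlap in 2D separate vertically, a patient at
the minimum everywhere sits at the bottom-center of the cylinder, one at
the maximum everywhere at the top. On top of the layouts the package
provides patient-similarity graphs (cosine / Pearson / Spearman with a
0–1 edge threshold and seeded force-directed placement), hand-written
Lloyd k-means with Forgy (seeded data-point) and Random (uniform-in-volume)
initialization iterated until the centers are stationary,
parallel-coordinates axes with multi-interval conjunctive filtering,
per-cluster mean/median/composition summaries, CSV export, static
HTML/SVG renders, and a synthetic five-stage cohort generator that stands
in for the private registry the schema emulates.

## Worked example

```r
library(RadVisSeg)

cohort <- generateCohort(defaultSeparatedConfig(500, seed = 1))
cohort
#> CohortExperiment: 500 patients, 15 score items, 5 covariate(s)

u       <- normalizeScores(cohort)
anchors <- makeAnchors(selectVariables(cohort, sprintf("item_%02d", 1:15), "anchors"))
layout  <- layoutCohort(u, anchors, "radvis3d")
head(layout, 3)
#>       id            x          y         z
#> 1 P00001  0.009310262 0.02091119 0.6000000
#> 2 P00002 -0.032538931 0.07825181 0.5555556
#> 3 P00003  0.046446552 0.04182066 0.3555556

model <- kmeansRadVis(u, k = 5, init = "forgy", seed = 1,
                      space = "feature", nRestarts = 5)
model
#> ClusterModel: k = 5 (forgy init, seed 5, feature space)
#>   4 iterations, converged = TRUE, total within-SS = 115.569

s <- summarizeClusters(model, cohort)
s$sizes
#>   1   2   3   4   5
#>  95 105 108 100  92
subset(s$categorical, variable == "diagnosis" & share > 0.5)
#>    cluster  variable level     share
#> 1        1 diagnosis   SMI 1.0000000
#> 8        2 diagnosis   VCI 1.0000000
#> 14       3 diagnosis   SVD 0.9814815
#> 17       4 diagnosis   MCI 0.9900000
#> 25       5 diagnosis    AD 1.0000000
```

Each `x, y` is the patient's pull-balance across the 15 anchors; `z` is the
mean normalized score, so patient P00003 (z ≈ 0.36) functions worse day to
day than P00001 (z = 0.60). The five clusters align almost perfectly with
the five diagnosis stages — each cluster is ≥ 98 % one stage. The AD-only
three-group case study is one filter away:

```r
adIds <- applyFilter(cohort, filterSet(diagnosis = "AD"))   # 93 patients
ad3   <- kmeansRadVis(u[adIds, ], k = 3, init = "forgy", seed = 1,
                      space = "feature")
```

The same workflow runs from a shell via the thin CLI installed at
`system.file("cli", "radviseg", package = "RadVisSeg")` (subcommands
`simulate`, `layout`, `cluster`, `filter`, `run`, `render`), or
non-interactively from a YAML config via `runPipeline()`, which writes
layout/cluster/filter CSVs, HTML renders, and a JSON manifest; identical
config and seed give byte-identical CSVs.

## Documentation

`vignettes/radial-segmentation-methods.Rmd` explains the model, the 3D
combination rule and its rationale, the degenerate-input conventions,
what the synthetic generator does and does not emulate, and known
limitations. All exported functions carry roxygen documentation.
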