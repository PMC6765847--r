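---
title: "Radial-coordinate layouts and cluster segmentation of questionnaire cohorts"
author: "RadVisSeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial-coordinate layouts and cluster segmentation of questionnaire cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RadVisSeg)
```

## The problem

Clinical registries describe each patient by dozens of test items at once.
For a dementia cohort staged SMI → MCI → VCI → SVD → AD and scored on the
15-item Seoul-Instrumental Activities of Daily Living questionnaire (S-IADL,
a 0–3 Likert scale per item, higher = better daily function), a clinician
wants to *see* how patients distribute across all 15 items simultaneously,
carve the cohort into groups of similar profiles, and inspect what
distinguishes the groups. RadVisSeg is a batch engine for that workflow:
radial-coordinate projections, similarity graphs, seeded k-means
segmentation, parallel-coordinates multifiltering, and per-cluster
descriptive statistics, all reproducible from a config and a seed.

## The cohort container

A `CohortExperiment` extends `SummarizedExperiment`: the `"scores"` assay is
the items × patients matrix, `rowData` holds each item's declared value
bounds $V_{min}(i)$, $V_{max}(i)$, and `colData` holds covariates (diagnosis
stage, gender, academic background, age, education years). CSV ingestion
(`readCohort`) accepts either an explicit YAML schema — which fixes variable
kinds, bounds, category order, and whether a numeric column is a score item
or a covariate — or `"infer"`, which treats every fully numeric column as an
item with its observed range as bounds.

## The placement rule

Every layout is driven by per-variable min–max normalization. A raw value
$N(i)$ on variable $i$ maps to the position

$$N_p(i) = \frac{N(i) - V_{min}(i)}{V_{max}(i) - V_{min}(i)}
\,\bigl(P_{max}(i) - P_{min}(i)\bigr) + P_{min}(i),$$

linear between the position bounds $P_{min}(i)$, $P_{max}(i)$ (defaults 0
and 1, under which the rule is plain min–max scaling). `eq1Position`
implements exactly this; `normalizeScores` applies it column-wise and
returns the patients × variables matrix $u \in [0,1]$ used everywhere else.

Two degenerate cases need a convention the rule itself does not supply:

* **Constant variable** ($V_{min} = V_{max}$): the quotient is 0/0. We
  assign the neutral weight 0.5 and warn. A constant column carries no
  information; 0.5 keeps it from dragging every patient toward the bottom
  center of the 3D view.
* **Missing values**: a patient with any missing selected value is dropped
  from normalization (and hence layout and clustering) with a warning, and
  the dropped ids are reported. Registry practice varies here and the
  source material for this design is silent, so we chose the conservative
  option that never fabricates a value.

Values outside the declared bounds are clamped to them, with a warning.

## 2D and 3D radial layouts

`makeAnchors` places one dimensional anchor per variable at equidistant
angles, the first at 12 o'clock and subsequent anchors clockwise in input
column order (a cosmetic convention matching common radial-plot figures).
In 2D (`layoutCohort(..., "radvis2d")`) a patient sits at the weighted
barycenter of the anchor points with weights $u_i$ — the classic radial
coordinates rule: the higher a value, the harder its anchor pulls. All-zero
rows sit at the center by convention rather than being rejected.

The 2D rule overlaps records: all profiles proportional to each other
collapse onto one point, and balanced profiles pile up at the center. The
3D variant therefore treats anchors as the vertical edges of a cylinder of
height $H$ (default 1, radius 1) and adds height

$$ (x, y) = \frac{\sum_i w_i\, a_i}{\sum_i w_i}, \qquad z = H \cdot
\overline{u},$$

with $w_i$ the per-variable positions $N_p(i)$ and $a_i$ the anchor wall
positions. This is a design interpretation: the per-variable rule above is
given, and the qualitative contract is that a variable at its maximum pulls
the record toward that anchor while a record at its minimum everywhere sits
at the bottom-center of the cylinder, with height tracking the average
value. The weighted barycenter plus $z = H\bar u$ is the simplest rule
satisfying all three statements, and it provably resolves the proportional
overlap: $u$ and $c\,u$ share $(x, y)$ exactly but differ in $z$ by the
factor $c$ (a property test asserts this at $10^{-9}$).

Anchors must be numeric variables; categorical covariates (gender,
diagnosis) are rejected as anchors because heights are only comparable on a
common scale, but they are allowed as parallel-coordinates axes.

## Similarity graphs

The earlier node-link prototype is kept as a module: `similarityMatrix`
computes cosine, Pearson or Spearman similarity of patients across their
normalized values (Spearman with average ranks for ties), and
`buildSimilarityGraph` links every pair at or above a threshold in [0, 1].
Negative correlations are left raw; since the threshold is non-negative
they simply never form edges. Pairs whose metric is undefined (all-zero
vector for cosine, constant row for correlations) score 0 by convention.
`forceLayout` runs Fruchterman–Reingold placement (via igraph) from seeded
uniform initial positions, so a fixed seed reproduces the picture.

## k-means segmentation

`kmeansRadVis` is plain Lloyd iteration, written in the package because the
initialization and stopping conventions are part of the method's contract:
assign each point to the nearest center by Euclidean distance (ties to the
lowest cluster index), recompute centers as member means, and stop when no
center moves by more than $10^{-9}$ — "until the central point remains
constant" — or after 300 iterations. The total within-cluster sum of
squares is recorded after every iteration and is non-increasing; tests
assert this on every fit. Two initializations are provided:

* **Forgy**: a seeded sample of $k$ distinct data points. With a fixed seed
  the whole fit is bit-identical across runs (the classical claim that
  Forgy "always yields identical results" is true only once the selection
  is fixed; we realize it with the seed).
* **Random**: $k$ pivots drawn uniformly inside the data volume — the
  cylinder $r \times H$ when clustering layout coordinates, the bounding
  box otherwise.

An empty cluster is repaired by reseeding its center at the point farthest
from it, which keeps $k$ clusters and preserves the monotone objective.
`nRestarts` runs seeds $s, s+1, \dots$ and keeps the best objective.

Two design notes from our own measurements (both reproduced by the test
suite):

* **Clustering space.** Clustering can run on the 3D layout coordinates
  (`space = "layout3d"`, the default for the visual workflow, where the
  user segments what they see) or on the normalized 15-item matrix
  (`space = "feature"`). On the default separated synthetic cohort
  (n = 500), feature-space k = 5 recovers the true stages at ARI ≈ 0.98,
  while layout-space clustering reaches only ≈ 0.6: projecting 15
  dimensions into 3 compresses information, and low-function patients
  scatter widely in $(x, y)$ because their barycenter weights are small.
  Stage-recovery checks therefore cluster in feature space.
* **Forgy vs random restarts.** On small instances (10 points, k = 3)
  best-of-10 random-pivot restarts matched an exhaustive
  partition-enumeration optimum in every trial we ran, while best-of-10
  Forgy restarts usually settle into a near-optimal local minimum — Forgy
  centers start on data points and converge within their local basin. The
  optimum-matching test uses random init; Forgy is the right tool when
  exact repeatability is the point.

`summarizeClusters` produces the cluster index panel — per-cluster size,
mean and median of every numeric variable, and the composition share of
every categorical level — and `exportClusters` writes the clustered rows
(with layout coordinates) as a quoted CSV that `readCohort` re-loads.

## Parallel coordinates and multifiltering

`buildAxes` lays one vertical axis per variable in the requested order:
numeric axes span their declared bounds, categorical axes place their
levels at equal spacing in declared order. A `FilterSet` holds, per axis,
a union of closed intervals (numeric) or a set of levels (categorical);
`applyFilter` returns the patients passing *every* constrained axis
(conjunctive), with unconstrained axes ignored and the empty filter passing
everyone. Endpoints are inclusive — the natural reading of a drag selection
— and overlapping intervals behave as their union. A brute-force per-row
scan oracle checks equality on 1000 randomized tables. `linkedSelection`
is the reverse link: it extracts exactly the layout points of a filtered id
set, unchanged.

## Synthetic cohorts

The real registry this schema emulates is private, so `generateCohort`
simulates it: stages drawn from configurable proportions (default uniform
over the five), item scores `round(clamp(Normal(mean[stage, item], sd), 0, 3))`
— every value lands on the 0–3 grid — and independent demographics
(uniform age 55–90, education 0–18 years banded into an academic-background
level, gender draws). `defaultSeparatedConfig` fixes the stage mean
profiles at 2.8, 2.2, 1.6, 1.0, 0.4 across all 15 items with sd 0.25:
steps of 0.6 at sd 0.25 make the stages well-separated clusters, which is
the intended regime for the segmentation-recovery checks. The scale is
encoded 0–3 rather than 1–4 so the lower bound of the placement rule
coincides with score 0.

What the generator deliberately does **not** emulate: item-specific
difficulty profiles (all items share the stage mean), correlation between
demographics and stage, informative missingness, and the negative
display-score convention some reports use for S-IADL summaries. Passing
tests on this cohort demonstrate that the pipeline recovers structure that
is present and well-separated; they say nothing about recovery when stages
overlap heavily, which real cohorts do.

## Numerical and testing choices

Problem sizes were chosen to keep the full suite fast while leaving no
operation untested at realistic shape: layouts are cross-checked against a
loop-based per-row oracle on 1000+ random rows over 3–20 anchors at
$10^{-12}$; the placement rule against direct re-evaluation on 1000 random
parameter draws; k-means against `stats::kmeans` (Lloyd, identical starting
centers), against exhaustive enumeration of all $k^n$ assignments at
n = 10, k = 3, and against the known stage labels at n = 500; the
multifilter against a row-scan oracle on 1000 random tables; and the batch
pipeline byte-for-byte across repeated runs. Renders are static
self-contained HTML/SVG written by the package itself (one marker per
patient, one labelled edge per anchor, plus a small rotation script), so
figure content is testable by parsing text.

## Limitations

The engine is batch-first: the interactive brushing loop of a live tool is
replaced by config-driven filters and exports. The 3D combination rule is
one principled reading of a qualitative description, not a reconstruction
of unpublished code. Likert rounding makes adjacent stages share item
values, so recovery degrades gracefully — but it degrades — as `itemSd`
grows toward the stage step; and the layout-space clustering default
prioritizes what-you-see-is-what-you-segment over label recovery, as
quantified above.
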