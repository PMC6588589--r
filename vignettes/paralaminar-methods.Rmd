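---
title: "Models and methods behind paralaminar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paralaminar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The paralaminar nucleus (PL) of the human amygdala holds a reservoir of
immature excitatory neurons that mature over decades. Quantifying that
process takes two kinds of evidence: single-nucleus transcriptomes (to
isolate the immature population and ask how it differs between diagnoses)
and counted histology (to trace cell densities and percentages across
age). This vignette explains how `paralaminar` models both, why each
default is set where it is, and what the simulation-based tests do and do
not establish.

# The snRNA-seq pipeline

## Quality filters

A nucleus is kept when it expresses at least 400 genes (counts > 0;
boundary inclusive) **and** the fraction of its UMIs from mitochondrial
plus ribosomal genes is strictly below 10%. Genes are then kept when
expressed in at least 3 nuclei; mitochondrial genes are removed outright
(nuclear preparations should not contain them), while ribosomal genes
participate only in the fraction rule and stay in the matrix. Filters are
applied nuclei first, then genes, and are idempotent in that order.
Mitochondrial/ribosomal status comes from `gene_meta` flags, or from the
standard symbol prefixes (`MT-`, `RPL`, `RPS`) when flags are absent.

Two sequencing platforms introduce gene-level batch effects. Libraries
sequenced on both platforms ("dual samples") allow a direct per-gene test:
the fixed-effects hurdle model of platform with centered detection rate as
covariate. Genes with BH-FDR < 0.05 and composite |log2FC| > 0.1 are
removed before dimensionality reduction. The 0.1 threshold is read on the
log2 scale, matching the fold-change convention used for differential
expression.

## Normalization

`value = log2(1 + 10^4 · count / total)`. Log base 2 makes the
differential-expression thresholds coherent: 0.14 ≈ log2(1.1), a 10%
expression difference. The pseudocount keeps zeros at zero; scaling to a
common total removes library-size differences in means (though not the
zero pattern — see the detection-rate covariate below).

## Reduction, graph, communities

The normalized matrix is column-centered and decomposed by truncated SVD
(k = 50); centering makes "explained variance" well-defined for the scree
rule. The number of components retained is the last one before the
explained-variance curve plateaus, operationalized as: the smallest j such
that every later drop `ev[i] − ev[i+1]` is below `tol · ev[1]` with
tol = 0.02 (exposed as an argument; the visual scree criterion has no
canonical constant).

Nuclei are joined in a k-nearest-neighbour graph with k = round(√N),
Euclidean distance on the selected components, and distance ties broken by
nucleus index for determinism. An edge is created wherever one nucleus is
a kNN of the other, with weight equal to the Jaccard similarity of the two
neighbor sets; zero-overlap pairs are dropped. Louvain modularity
optimization (resolution 1.0, classic modularity; seeded) yields the
communities, and the reported modularity is recomputed from the final
partition. t-SNE on the selected components is provided for display only;
no statistic consumes it.

A practical note on granularity: modularity optimization at resolution 1
will split a large, internally homogeneous community when the graph is
effectively low-dimensional — a 500-nucleus Gaussian blob embedded in 2–3
informative dimensions partitions into several geometric segments under
*any* correct Louvain implementation, because the split genuinely has
higher modularity. With realistic expression spectra the selected subspace
has 10–20 informative dimensions, within-population neighbor sets lose
their geometric structure, and planted populations are returned whole.
This is why the synthetic generator includes latent expression programs
(below): clustering tests on data with an unrealistically sharp variance
plateau measure a regime real pipelines do not operate in.

## The hurdle model

Single-nucleus expression is zero-inflated: whether a gene is detected and
how much is measured when detected carry separate information. For a gene
with normalized values `y`:

* **detection part** — logistic regression of `1(y > 0)` on the design;
* **expression part** — Gaussian regression of `y` on the design, over
  nuclei with `y > 0`.

The likelihood-ratio statistic for a two-level predictor drops it from
both parts and sums the two chi-squares (df = 2). When a level has fewer
than 3 positive nuclei the expression part is unidentifiable and the test
falls back to the detection part alone (df = 1, flagged). Complete
separation in the detection part switches both fits to Firth's
bias-reduced logistic regression (penalized likelihood; implemented as
IRLS with hat-value score adjustment), keeping the LRT finite. No
empirical-Bayes shrinkage is applied across genes.

The reported **composite log2 fold change** is the difference, between the
predictor's two levels at covariate means, of the predicted mean
expression `P(detected) × E[value | detected]`. "Fold change" has no
unique definition in a two-part model; this composite uses both parts and
reduces to the continuous coefficient when detection is saturated.

Covariates follow the standard recipe: centered per-nucleus gene detection
rate (`cngeneson`) always; donor age (years), sex, RNA integrity number
(RIN) and post-mortem interval (PMI, hours) for case–control analysis.
Covariates constant within the analyzed subset are dropped with a warning.
For case–control testing both parts carry a Gaussian random intercept per
donor (`(1|ind)`; random intercept only, no slopes), fitted by maximum
likelihood through `lme4`; the full and reduced models share the random
structure so the LRT is nested. A `theta_zero` mode evaluates both
components with the random-intercept variance pinned at zero, which
reproduces the fixed-effects fit exactly and is used as a consistency
check. Mixed fits that fail numerically fall back to that evaluation and
are flagged `converged = FALSE`; non-converged genes are excluded from the
significant set.

Selection rules: markers (one cluster vs the rest, fixed effects) need
FDR < 0.05 and composite log2FC ≥ 1, with BH-FDR computed within each
cluster's tested genes. Case–control genes need FDR < 0.05, composite
|log2FC| ≥ 0.14 **and** |log2FC| ≥ 0.14 in a diagnosis-only model (the
"raw" fold change), mirroring the double fold-change filter of the
original analysis. Genes are tested when expressed in ≥ 3 nuclei of the
analyzed subset.

## Overrepresentation

Gene lists are scored against user-supplied gene sets (GMT) with the
one-sided hypergeometric tail `P(X ≥ overlap)`, using all tested genes as
the background, sets intersected with the background first, and BH-FDR
across tested terms. No ontology-hierarchy propagation is performed —
annotations are taken as given. The GMT reader is in-package because the
collection keeps the description column.

# Histology statistics

Counts arrive per confocal z-stack with region, age, donor, section and
sampled area. The package computes:

* pooled percentages `100·Σnum/Σden` (reported to one decimal);
* per-stack summaries: mean, sd (n−1), and a t-based 95% CI
  `mean ± t(0.975, n−1)·sd/√n` — this construction reproduces the
  published Ki-67 density interval (50.56–120.7 from mean 85.6, sd 86.8,
  n 26) to within rounding of the inputs;
* densities `count/area` (cells/mm²);
* cell-cluster summaries per age group: mean count per section with CI;
  median and quartiles of cluster areas by linear interpolation between
  order statistics (R quantile type 7);
* classical one-way ANOVA on untransformed group values;
* exponential age trajectories `y = a·exp(−b·age) + c` by
  Levenberg–Marquardt least squares with b ≥ 0 (the decline is a decay by
  construction), multi-start over decay rates spanning the age range, and
  the flat curve (a = 0, b = 0, c = ȳ) always evaluated as a boundary
  candidate — which also covers exactly-constant data, where the
  amplitude is unidentifiable;
* mixed-effects LRTs:
  `log(y) ~ age + region + (age|individual) + (age|section)` by maximum
  likelihood, against the nested model without the effect of interest
  (df = parameters dropped: 1 for age, levels−1 for region). Responses
  are log-transformed with offset δ = half the smallest positive value
  when zeros occur. If either fit is singular in the random slopes, both
  models are refitted with intercept-only random effects and the result
  is flagged;
* orientation summaries: a mapped cell counts as oriented "toward" the
  reference point (e.g. the PL centroid) when the angle between its
  leading-process vector and the cell-to-reference vector is under 90°
  (threshold exposed); toward-fraction = 0.5 is tested with the exact
  two-sided binomial test; the circular mean and mean resultant length
  summarize the raw process angles. Cells located exactly at the
  reference are excluded with a warning.

# The synthetic-data generator

## UMI matrices

Counts are gamma-Poisson (negative binomial, shared dispersion 0.3;
dispersion 0 gives Poisson) with per-nucleus lognormal library sizes
(meanlog log 3000, sdlog 0.3) and per-gene lognormal baseline abundances,
with mitochondrial+ribosomal genes scaled to ~4% of UMIs. On the log2
mean these shifts are added:

* **cluster markers** — each of the K planted populations up-regulates
  its own disjoint marker set (default 150 genes at log2FC 1.5). Cell
  identity programs in brain tissue span hundreds of genes; the
  recovery tests that plant only 20 markers probe marker *detection*,
  not a realistic identity program;
* **diagnosis effect** — planted genes (default 30 at log2FC 1) shifted
  only in ASD-donor nuclei of one target population, mirroring a
  disease signal confined to the immature population;
* **platform effect** — a gene subset shifted on the second platform;
  the first four donors contribute dual-platform libraries;
* **donor effect** — a per-donor, per-gene Gaussian intercept (sd 0.1 by
  default; 0.5 in confounding studies). Note a donor intercept *shared
  across genes* would cancel in library-size normalization; the
  per-gene form is what makes nuclei from one donor correlated and a
  random intercept necessary;
* **latent expression programs** — 12 factors with N(0,1) nucleus scores
  and dense Gaussian gene loadings whose scale decays geometrically
  (0.25·0.9^f). These give the simulated data the smoothly decaying
  variance spectrum of real single-cell matrices, so that the scree
  plateau falls at realistic depth (~16 PCs at default scale) rather
  than immediately after the cluster dimensions.

Marker, diagnosis and platform sets are drawn disjoint and from the upper
half of the abundance distribution: planted truth on genes detected in a
handful of nuclei would be unidentifiable at the simulated depth and
would measure sequencing depth, not method performance. Donor ages are
uniform on 4–15 years, RIN on 6.5–9, PMI on 4–30 hours, keeping the
covariate matrix full rank.

Designated QC failures are planted exactly: low-gene nuclei are truncated
to a random 150–399 expressed genes; high-mito nuclei have mitochondrial
counts raised to ~15% of UMIs; every other nucleus is deterministically
nudged to satisfy both rules (mito counts scaled down to 8% and/or zero
genes topped up to 400) so the recorded truth coincides with a brute-force
re-check by construction. Metadata, gene tables and truth (cluster
labels, gene sets, failure reasons) are returned alongside the matrix,
and matrices round-trip through a 10x-style MTX directory.

## Histology tables

Per stack: DAPI count ~ Poisson(400), marker-positive count ~
Binomial(DAPI, p) with
`p = plogis(qlogis(c + a·exp(−b·age)) + u_donor + v_section)`,
`u ~ N(0, 0.3²)`, `v ~ N(0, sd²)` (section sd 0 by default, 0.15 in
mixed-model studies so the section-level random terms have something to
estimate). Default trajectory (a, b, c) = (0.8, 0.2, 0.05) over ages
0–77 years emulates a marker fraction collapsing within the first decade;
stacks alternate between MPL and LPL and group into sections of 5.

## What the simulations do not emulate

No ambient RNA, doublets, read-level noise, cell-cycle structure, or
empirical gene-gene correlation beyond the latent factors; cluster
proportions are exchangeable rather than ontogenetically structured; the
histology generator has no spatial structure, so orientation statistics
are tested on separately constructed coordinate tables. Passing recovery
tests therefore demonstrates correctness of the statistical machinery
under the stated generative model, not performance on any real tissue.

# Numerical choices and problem sizes

* Scree tolerance 0.02 of the first component's variance; kNN ties by
  index; Louvain seeded, labels contiguous from 0.
* LRT statistics are clamped at 0; p-values from χ² with df as above.
* Firth penalization only engages on separation, for both full and
  reduced detection fits, keeping the comparison like-for-like.
* The donor-confounding false-positive study uses 16 donors (8 per
  arm). With 4 donors per arm, every gene's diagnosis contrast rides the
  same 4-vs-4 donor draw and the χ² reference is anticonservative for
  any gene-wise procedure; measuring FDR control requires donor-level
  replication. At 16 donors the random-intercept model flags ~0% of null
  genes where the fixed-effects model flags ~15%.
* Test-suite scales: clustering recovery at 1500 nuclei × 2000 genes
  (3 populations); hurdle calibration on 2000 null genes; case–control
  recovery on a ~490-nucleus population with 30 planted genes among 300
  tested; trajectory recovery at 40 donors × 10 stacks; mixed-model
  calibration over 200 null replicates and power over 50. The full suite
  runs in ~7 minutes, the acceptance script in ~5.

# Known limitations

* Mixed-model LRT p-values lean on asymptotics in the number of donors;
  with very few donors they are anticonservative (see above). The
  package reports them as the original analysis did, without small-sample
  correction.
* The composite fold change attenuates for weakly detected genes; genes
  with strong planted effects but low abundance can fall below fixed
  fold-change thresholds.
* Louvain granularity at resolution 1 depends on the effective
  dimensionality of the selected subspace; on degenerate spectra it can
  subdivide homogeneous populations (discussed above).
* The overrepresentation test treats gene sets as flat annotations; no
  parent-term closure is applied.
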