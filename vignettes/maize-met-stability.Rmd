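---
title: "Methods: yield-stability analysis for multi-environment maize trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: yield-stability analysis for multi-environment maize trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The problem

A maize breeding program evaluates a set of hybrids across several
environments — here, combinations of growing season and cropping system
(sole maize, maize+soybean, maize+sweet potato) — with replicated plots in
each environment. Two questions drive the analysis. First, *stability*:
which hybrids perform well not just on average but consistently across
environments, in the presence of genotype-by-environment interaction (GEI)?
Second, *land use*: does intercropping a hybrid with a companion crop use
land more efficiently than growing the two crops separately?

`metstab` implements the standard toolkit for this situation: a combined
analysis of variance that partitions plot-level variation; AMMI and GGE
bilinear decompositions of the genotype × environment means; the AMMI
Stability Value (ASV) and Genotype Stability Index (GSI); and the Land
Equivalent Ratio (LER). A synthetic trial generator with known ground truth
backs every stage with verifiable tests.

## Data model

The unit of input is a long-format *trial table*: one row per plot with
genotype, season, cropping system, replicate number, and one or more trait
values in t·ha⁻¹ (the two traits used throughout the examples are CWH, cob
weight with husk, a biomass trait; and GY, grain yield). An *environment*
is one season × system combination; labels `C1..Ce` are assigned
deterministically, seasons sorted then systems sorted within season, which
places sole cropping first for the usual sole/soybean/sweetpotato naming.
Validation enforces unique plot keys, finite non-negative trait values, and
records balance. Missing genotype × environment cells are an error by
default; `cell_means(..., impute = TRUE)` fills them with the additive
genotype mean + environment mean − grand mean, an explicit choice because
silent imputation hides data problems.

## Combined ANOVA

For a balanced trial with genotypes $G$, seasons $S$, systems $C$ and
replicates nested in environments, the plot model is

$$Y_{ijkl} = \mu + S_j + C_k + (SC)_{jk} + G_i + (GS)_{ij} + (GC)_{ik} +
(GSC)_{ijk} + R_{l(jk)} + \varepsilon_{ijkl}.$$

Environment effects are deliberately split into season, system and their
interaction (rather than one 6-level factor), so the table answers "how
much of the variation is due to the cropping system?" directly. Sums of
squares are sequential sums from `stats::lm()`; in a balanced design the
effect subspaces are orthogonal, so these equal the classical
marginal-means sums of squares, a fact the test suite checks against an
independent full-enumeration oracle. For the study-sized design
(24 genotypes × 2 seasons × 3 systems × 3 reps, 432 plots) the degrees of
freedom are 12, 1, 2, 2, 23, 23, 46, 46 and 276 for error (total 431).

Two conventions were genuinely open and are resolved as follows:

* **Error stratum.** A single pooled error tests every effect, matching the
  one-error-row layout this type of trial report uses; a plot-within-block
  term is not separately estimable from that layout and is folded into the
  replicate and error strata. Users wanting the stricter mixed-model
  convention can set `rep_error = TRUE`, which tests season, system and
  S × C against the replicate-within-environment mean square.
* **Descriptives.** `SD` is the plot-level standard deviation of the trait;
  `CV` is $100\sqrt{MS_{error}}/\bar Y$, the residual CV.

P-values come from the F distribution; the printed stars use `**` for
p < 0.01.

## AMMI and ASV

AMMI fits additive main effects and a multiplicative interaction: the cell
means are double-centered,

$$D_{ij} = \bar Y_{ij} - \bar Y_{i.} - \bar Y_{.j} + \bar Y_{..},$$

and $D$ is decomposed by SVD into interaction principal component axes
(IPCA). AMMI operates on cell means, not plots — replication information
enters only the ANOVA. At full rank the decomposition reconstructs the
means exactly and $\sum_k \lambda_k^2$ equals the interaction sum of
squares; both identities are asserted in tests to 1e-10.

The AMMI Stability Value weighs the first two IPCA scores by their share of
interaction sum of squares:

$$ASV_i = \sqrt{\left(\tfrac{SS_{IPCA1}}{SS_{IPCA2}}\,IPCA1_i\right)^2 +
IPCA2_i^2}, \qquad \tfrac{SS_{IPCA1}}{SS_{IPCA2}} = \lambda_1^2/\lambda_2^2.$$

The ASV literature does not agree on one score scaling; the package
defaults to the symmetric convention $u_{ik}\sqrt{\lambda_k}$ (the dominant
one) and offers $u_{ik}\lambda_k$ via `scaling = "lambda"`. Because ASV is
a sum of squares, it is invariant to the sign indeterminacy of the SVD; for
reproducible coordinates the package additionally fixes each component's
sign so that the largest-magnitude genotype score is positive. Near-tied
singular values are returned in SVD order with a warning and no rotation is
attempted. If the interaction has rank < 2, ASV is undefined and an error
says so.

## GGE and its three views

GGE keeps genotype main effects and interaction together: columns
(environments) are centered on their means and the result decomposed by
SVD. No environment scaling is applied by default (the "environment-
centered, unscaled" GGE); `scale = TRUE` divides by within-environment SD.
Scores are scaled by $\lambda^f$ (singular value partitioning): the views
use the standard pairing — environment-focused ($f=0$) for
discriminativeness-vs-representativeness, genotype-focused ($f=1$) for
mean-vs-stability, symmetric ($f=0.5$) for which-won-where — each
overridable.

* **Discriminativeness vs representativeness.** Environment vector length
  measures discriminating power; the angle to the average-environment axis
  (AEA, the unit vector along the mean of environment score vectors)
  measures representativeness. The conventional type labels are computed
  from explicit cutoffs — type I if length < half the longest vector,
  type II if long and angle < 45°, type III if long and angle ≥ 45° — and
  the raw length and angle are always reported so users can apply their own
  cutoffs; reports in this literature use the labels qualitatively.
* **Mean vs stability.** Signed projection of each genotype score on the
  AEA orders genotypes by mean performance (in the additive limit this
  ranking provably equals the ranking of raw genotype means, a property the
  tests assert); the perpendicular distance to the AEA line measures
  instability.
* **Which won where.** The convex hull of the genotype scores is traversed
  counter-clockwise, and the outward normal of each hull edge defines a ray
  from the origin. The arc between the normals of the two edges meeting at
  a hull vertex is exactly the set of directions in which that vertex has
  the largest projection (its normal cone), so the vertex genotype wins
  every environment whose score direction falls in its arc. This
  construction is exact for any hull position — it is the polygon's normal
  fan — and is verified against an exhaustive all-projections oracle on
  random configurations. Environments exactly on a boundary ray are
  assigned to the counter-clockwise sector; environments with a zero score
  vector have no direction and get no winner. Sectors holding two or more
  environments are flagged as mega-environments.

One modelling note: descriptions of the GGE model sometimes write the
centering against a genotype-indexed mean even though the environment
effect is what remains; standard GGE centers by environment, and that is
what the package implements.

## Stability index and LER

GSI is a rank sum: trait means are ranked descending (best = 1), ASV
ascending (most stable = 1), and $GSI = rASV + rX$ with a final ascending
rank `rGSI`. All ranks use competition ("min") ties — tied values share the
minimum rank and the next distinct value skips — which is the rule that
reproduces shared first places in published tables (e.g. two hybrids both
at GSI 7 and rGSI 1). GSI therefore depends only on orderings, an
invariance the tests check under monotone transformations.

LER sums relative yields over the component crops of an intercrop,
$LER = \sum_i IC_i/C_i$; a value strictly greater than 1 is favorable
(LER = 1 exactly is not). The trial table holds only the maize side, so
`partial_ler_input()` builds maize component rows (intercrop cell mean over
matched sole-crop cell mean, within genotype × season) and companion-crop
rows can be appended from a separate table. Whether a published LER value
embeds the companion ratio or is a maize-only partial LER is generally not
recoverable from the printed numbers alone; both modes are supported and
results state which components they used (`n_crops`). Strata whose sole
crop yielded zero have no defined relative yield and are dropped with a
warning rather than aborting the analysis.

## The synthetic generator

`simulate_trial()` draws from the generative counterpart of the AMMI model:

$$Y_{ijk} = \mu + G_i + E_j + \sum_t \lambda_t \alpha_{it}\gamma_{jt} +
r_{k(j)} + \varepsilon_{ijk},$$

with centered main effects, orthonormal score matrices (QR of Gaussian
draws), Gaussian replicate effects and i.i.d. Gaussian plot noise, all
reproducible from one seed. Default dimensions mirror the motivating study:
24 genotypes × (2 seasons × 3 systems) × 3 replicates. Effect scales were
calibrated once from that study's printed ANOVA summary: grain yield uses
grand mean 4.36 t·ha⁻¹, genotype effect SD 0.30, environment effect SD
2.10, GEI singular values (8, 5) and plot noise SD 0.65 =
$\sqrt{MS_{error}}$; the biomass trait uses 7.43, 0.83, 3.13, (12, 9) and
1.48. Because yields are physically non-negative, simulated plot values are
left-censored at zero; under the default calibration this touches only the
occasional extreme low cell, and zero-noise tables — the basis of all
exactness tests — are unaffected whenever the structural means are
non-negative.

What the generator deliberately does **not** emulate: skewed or
heteroscedastic errors, spatial field trends, genetic (pedigree)
covariance between hybrids, and season-specific system effects beyond what
the drawn environment effects produce. Passing tests therefore demonstrate
correctness of the estimators under the assumed additive + low-rank model,
not robustness to those real-data features.

## Numerical choices and problem sizes

Tolerances: exactness identities (reconstruction, SS conservation,
additivity) at 1e-8 to 1e-12; noise-free parameter recovery at 1e-8
relative over 50 random specifications; spectrum-tie detection at 1e-10
relative. The test suite runs the full enumeration ANOVA oracle on designs
up to ~200 plots, 100 random which-won-where configurations against the
exhaustive projection oracle, and 300 null simulations for the F-statistic
calibration check; the whole suite completes in well under a minute on one
CPU. The acceptance script (`scripts/acceptance.R`) re-derives the
published worked values from the shipped summary-table columns and re-runs
the recovery and winner-agreement checks from a user-supplied seed.

## Limitations

* Unbalanced designs are supported only through explicit additive
  imputation at the means level; there is no REML/mixed-model path and no
  Type II/III sums of squares.
* No significance tests for AMMI components (Gollob or F-ratio style) and
  no bootstrap confidence regions on biplots.
* The GGE figure-level results of the motivating study (PC percentages,
  genotype placements) depend on its deposited raw plot data, which is not
  redistributed here; integration checks against it run only when a local
  copy is supplied.
* Alternative stability measures (Shukla, Wricke, Eberhart–Russell) and
  economic intercropping indices (ATER, monetary LER) are out of scope.
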