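---
title: "Methods: soil micro-food-web indices, footprints and networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil micro-food-web indices, footprints and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microfoodweb)
```

This vignette documents the models and procedures the package
implements, the assumptions behind them, and the design choices made
where the conventions of the field leave room.

## Data model and units

Nematode communities are genus-level count tables standardised to
individuals per 100 g dry soil:
`count * 100 / (fresh_mass_g * (1 - moisture_fraction))`. The
standardisation makes plots with different gravimetric moisture
comparable; it is linear in the raw count and undefined at
`moisture_fraction >= 1`, which is rejected. Microbial (16S/ITS) tables
enter as raw read counts or relative abundances; both units are accepted
and recorded, since correlation-based downstream stages are rank-based
and diversity indices are computed on relative abundances either way.
Chao1 is the exception — it needs integer counts and is reported as an
explicit `NA` otherwise.

Every nematode genus must be annotated with a trophic group (BF, FF, PP,
OP), a c-p value in 1–5 and a fresh body mass in µg; an unannotated
nematode genus is an error because every index below is undefined
without it. Unannotated microbial genera only lose their node label in
the network stage, so they are a warning.

## Ecological indices

Shannon `H` (natural log, in nats) and dominance `λ = Σ pᵢ²` are
computed over the relative abundances of the genera present in a sample,
with `0·ln 0 = 0`. Input vectors must sum to 1 within `1e-9`.

The maturity index is the abundance-weighted mean c-p value over
free-living taxa. Free-living is taken as BF + FF + OP — the standard
convention that omnivore-predators are part of the free-living
assemblage — while the plant-parasitic index is the same mean over PP
taxa only. Both are invariant to uniform rescaling of abundances and to
merging taxa with identical trophic group and c-p value; both are
undefined (`NA`, never 0) when their taxon set has zero abundance, which
genuinely happens in sparse samples. The same explicit-`NA` policy
applies to `NCR = BF/(BF+FF)` when both microbivore channels are empty
and to `WI = (BF+FF)/PP` when no plant parasites are present.

A note on symbols: descriptions of these indices sometimes also define a
within-trophic-group proportion that no index formula actually uses; the
implementation follows the formulas as written (proportions within the
free-living and plant-parasitic assemblages respectively).

Chao1 defaults to the classic estimator `S_obs + F₁²/(2F₂)` with the
`S_obs + F₁(F₁-1)/2` fallback when doubletons are absent, because that
is the common citation default; the bias-corrected form
`S_obs + F₁(F₁-1)/(2(F₂+1))` is available behind a flag rather than
silently substituted.

## Metabolic footprints and the faunal profile

The per-taxon footprint `N (0.1 W/m + 0.273 W^0.75)` combines a
production term (biomass turned over per unit time scales with body mass
and inversely with the c-p class's generation time) and a respiration
term (metabolic rate scales as mass to the 3/4). It is additive over
taxa and homogeneous of degree 1 in abundance, which the tests exploit
as oracles.

The enrichment, basal and structural components default to the literal
unweighted memberships `e = {BF₁, FF₂}`, `b = {BF₂, FF₂}`,
`s = {BF₃₋₅, FF₃₋₅, OP₃₋₅, PP₂₋₅}`. Two consequences are worth making
explicit: FF₂ sits in both `e` and `b`, and plant parasites contribute
to structure. The widely used weighted alternative (`weights =
"ferris2001"`: cp1 3.2, cp2 0.8, cp3 1.8, cp4 3.2, cp5 5.0, PP excluded
from `s`) is provided because many studies report EI/SI on that scheme;
the package default follows the unweighted definitions so that both
modes are available rather than guessed between. Fe and Fs always sum
*unweighted* per-taxon footprints over the same memberships — the
weights calibrate component abundances for the indices, not carbon.

`EI = 100 e/(e+b)` and `SI = 100 s/(s+b)` are undefined when their
denominator is zero; a community of only basal taxa has EI = SI = 0.
Quadrants split at 50 with ties assigned downward (EI = 50 is "not
enriched", SI = 50 "not structured"); the 50/50 split is the universal
faunal-profile convention, and the tie rule only matters on a
measure-zero boundary.

The functional footprint is the quadrilateral through
`(SI, EI − Fe/2k)`, `(SI + Fs/2k, EI)`, `(SI, EI + Fe/2k)`,
`(SI − Fs/2k, EI)` — vertex order matters, as this sequence traces a
rhombus with perpendicular diagonals `Fe/k` and `Fs/k` whose area is
`(Fe/k)(Fs/k)/2`. The implementation computes the area by the shoelace
formula after translating the vertices to their centroid: the area is
translation-invariant, and centring avoids the floating-point
cancellation that otherwise appears when a small rhombus sits far from
the origin. The closed form and the shoelace agree to `1e-9` over 10⁴
random configurations in the test suite. `k` defaults to 100 and only
rescales the drawing (area scales as `1/k²`); it is configurable.

## Carbon-flow ternary map

Channel proportions are the relative metabolic footprints of the BF, FF
and PP groups (OP sits above the channels and is excluded); the map into
the fixed triangle with vertices (0,0), (100,0), (50,86.6) is the
barycentric combination of the vertices. 86.6 is the equilateral apex
height 50√3 rounded to one decimal — the plot is a convention, not a
computation, so the package uses the conventional constant exactly. The
reference frame of seven landmarks (3 vertices, 3 side midpoints,
centroid) is emitted with the data; per-sample points and per-treatment
mean points are both produced, the latter being well-defined because the
barycentric map is affine. Which channel sits at which corner is not
standardised; the default BF→(0,0), FF→(100,0), PP→apex is recorded in
the output attributes and configurable.

## Co-occurrence networks

Spearman correlation is the default: abundance data are zero-inflated
and heavy-tailed, and rank correlation is invariant to the monotone
transformations (relative vs absolute units) the inputs may arrive in.
Pearson is available. P-values come from `stats::cor.test`; for small
untied samples the Spearman p is the exact permutation probability
(verified in the tests against exhaustive enumeration of all rank
permutations), otherwise the asymptotic approximation.

Edges require `|r| ≥ 0.6` and `p ≤ 0.05`; multiple-testing adjustment
(BH) is off by default, mirroring common co-occurrence practice, and
both thresholds plus the adjustment choice are recorded in every output.
Taxa present in fewer than 3 samples are removed first — a correlation
against a nearly-all-zero vector is noise. All thresholds are
configurable, nothing is hidden.

With the study-shaped design of 3 replicates per treatment, a
per-treatment network is statistically impossible under the package's
own ≥ 4 samples rule, so the pipeline defaults to pooling all samples
into one network; `network_grouping = "per_treatment"` exists for
designs with more replicates and fails fast otherwise. Keystone taxa are
the top-k nodes by centrality (degree by default; betweenness and
eigenvector available), with lexicographic tie-breaking so rankings are
deterministic. Node importance is read as proportional to centrality.

## Treatment comparisons

One-way ANOVA with protected LSD: pairwise t-tests on the pooled
within-group mean square are only performed when the omnibus F is
significant at `alpha` (default 0.05); otherwise all groups share the
letter "a". Compact letters use the insert-and-absorb algorithm with
groups processed in descending mean order, so the highest mean always
carries "a" and the display is deterministic. A constant response
(zero variance everywhere) short-circuits to a single shared letter
rather than producing 0/0 test statistics.

## The synthetic generator

The generator emulates the study design the package targets: a cropland
control (CK) and forage stands of 2, 9 and 18 years (Y2, Y9, Y18), three
replicates each. Counts are negative-binomial (variance
`μ + φμ²`, default overdispersion φ = 0.5 — typical for community count
data) around per-taxon log-normal baseline means (nematode genera around
20 individuals per 100 g dry soil, bacterial genera around 500 reads,
fungal around 200), scaled by per-treatment trophic-group multipliers.
The default multipliers encode the directional structure the analysis is
meant to detect: the plant-parasitic group declines along Y2→Y9→Y18
(1.2, 0.5, 0.35) while the omnivore-predator group rises (0.5, 1.2,
1.5), fungivores are highest in the control, bacterivores flat. Soil
covariates follow per-treatment means (moisture declining, organic
carbon and total nitrogen rising, available phosphorus declining along
the chronosequence, pH and bulk density flat) with 5 % log-normal noise.
Correlated taxon pairs are planted through a shared latent log-normal
factor, sign-flipped for negative pairs — the simplest mechanism that
yields controllable co-occurrence edges.

The trait fixture uses real soil genus names, but its c-p values and
body masses are synthetic fixture values at realistic magnitudes, not
measured traits; it covers every (trophic, c-p) combination the faunal
components use.

What the generator does *not* emulate: compositionality of sequencing
data (reads are drawn independently per taxon, not multinomially from a
fixed depth), spatial autocorrelation between replicate plots,
taxon–taxon interactions beyond the planted pairs, and any attempt to
match a real study's genus-level abundance profile. Passing tests
therefore demonstrate that the estimators recover known structure from
idealised community data, not that they are robust to every artefact of
real amplicon surveys.

Everything is driven by one integer seed; the generator saves and
restores the caller's RNG state, and identical configs are bit-identical.

## Problem sizes and numerical conventions

The test suite exercises the trend-recovery and ANOVA-separation
properties at 200 replicates per treatment (800 samples), moment
recovery at 400 replicates, the shoelace/closed-form identity at 10⁴
random rhombi, index identities at 10³ random communities, and exact
permutation oracles at n = 5 (120 permutations) — sizes chosen so every
stochastic check sits far from its decision boundary while the whole
suite runs in about a minute. Probability vectors are validated to
`1e-9`; integer checks tolerate `1e-8` of floating noise; delimited
writers print doubles at 17 significant digits so numeric tables
round-trip exactly.

## Known limitations

- Per-treatment networks at 3 replicates are refused rather than
  computed badly; pooled networks conflate treatment effects with
  taxon–taxon association, which is the standard but imperfect
  compromise.
- Chao1 on relative abundances is undefined and reported as `NA`;
  no rarefaction-depth standardisation is applied before it.
- The weighted and unweighted EI/SI schemes can disagree noticeably in
  enrichment-dominated samples; results should state which scheme was
  used (the bundle's `summary.json` records it).
- The LSD procedure makes no multiplicity correction beyond the omnibus
  gate; with many indices compared across treatments, letters should be
  read as descriptive, not confirmatory.
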