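---
title: "Methods: trait-variance partitioning for grazing-by-climate experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-variance partitioning for grazing-by-climate experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitpart)
```

`traitpart` implements the statistical machinery of a factorial
grazing-exclosure study replicated along a climate gradient: 3 climate
levels (arid, intermediate, mesic) x 3 herbivore treatments (all
herbivores, wildlife only, no herbivores) x 3 blocks, i.e. 27 plots with
percent-cover vegetation surveys and leaf/seed trait measurements (LA,
SLA, LDMC, LNC, seed mass).  This vignette explains each model, its
assumptions, the tunable parameters, and the design choices made where the
design was genuinely open.

## The common-species rule

Every analysis operates on the species that jointly make up at least 90%
of each plot's total cover (`threshold = 0.9`).  Species are ranked by
cover within the plot, descending, ties broken lexicographically by
species code so the retained set is deterministic; the smallest prefix
reaching the threshold is kept.  The rule is *per-plot relative*: a plot
with sparse absolute cover is filtered against its own total.  A subtlety:
re-evaluating the rule on already-filtered data would measure 90% of the
*reduced* total and could drop further species, so the filter tags its
output and re-application at the same threshold is a no-op.

## CWM conventions

The community-weighted mean uses relative-abundance weights,
$\mathrm{CWM} = \sum_i w_i t_i$ with $w_i = a_i / \sum_j a_j$ over species
with trait values.  Weight normalisation makes the result invariant to the
units and totals of the cover scale (quadrat counts, percentages);
`normalize = FALSE` provides the raw weighted sum for sensitivity checks.
Species lacking a trait value under a convention are dropped and the
weights renormalised; the lost cover fraction is reported per plot x
trait, with a warning past 20%, so degradation from incomplete trait
tables is visible rather than silent.

The ITV convention is always computed as specific minus fixed — never
independently — so the identity `itv = specific - fixed` holds to machine
precision and the variance decomposition below is exact by construction.
When trait measurements come from a subset of plots, the explicit
`trait_plot_map` argument states which plot's measurements feed which
plot's specific CWM; the package deliberately does not guess this mapping.

## Turnover/ITV decomposition

For each trait, three sequential (Type I) two-way ANOVAs
`response ~ climate + treatment + climate:treatment` are fitted to the
specific, fixed and ITV responses.  With the balanced factorial design the
ordering of terms is immaterial; unbalanced data would make the ordering
(climate first, then treatment, then interaction) visible, which matches
the scientific priority of the gradient.  Per term,

$$SS_{cov} = SS_{specific} - SS_{fixed} - SS_{ITV},$$

and all contributions are expressed as percentages of the *total specific*
sum of squares — the only normalisation under which both the rows
(turnover + ITV + covariation = total) and the columns (term contributions
sum to the total row) of the contribution table are coherent.  Positive
covariation means turnover and intraspecific shifts push community trait
values the same way; negative means they conflict.  Traits available only
as pooled records cannot separate the components and are excluded.  The
decomposition requires at least two plots per climate x treatment cell;
with one plot per cell the interaction is confounded with the residual and
is flagged.

The optional permutation mode recomputes term significance by freely
permuting the response across plots (999 permutations, seeded) and
comparing sequential F statistics; the free permutation scheme is the
simplest exchangeable-null choice for a balanced two-way design.

## Functional diversity

The default trait space is built from range-normalised Gower
dissimilarities among species (quantitative traits; zero-range traits are
uninformative and excluded from the mean), embedded by principal
coordinates with the Cailliez additive correction so all eigenvalues are
non-negative, retaining `min(S - 1, n_traits)` axes.  A z-scored Euclidean
space is available as an alternative (`geometry = "euclidean"`), with
`standardize = FALSE` exposing raw coordinates for unit-free data.

* **FRic** is the convex-hull volume of the species coordinates,
  abundance-free.  The hull volume is computed exactly in any (small)
  dimension by enumerating supporting hyperplanes and summing pyramid
  volumes over facets, recursing for facet measures (shoelace in 2-D).
  FRic is *undefined* — flagged with a reason, never fabricated — when
  the species count is at most the number of axes or the points are
  affinely dependent; a true point-community has FRic 0.
* **FEve** weighs minimum-spanning-tree branches by
  $EW_l = d_{ij}/(w_i + w_j)$, normalises to $PEW_l$, and evaluates
  $(\sum_l \min(PEW_l, \tfrac{1}{S-1}) - \tfrac{1}{S-1}) / (1 -
  \tfrac{1}{S-1})$; it needs $S \ge 3$.
* **FDiv** measures abundance-weighted deviation of species distances
  from the centroid of the *hull vertices*; it requires a defined hull.
* **FDis** is the abundance-weighted mean distance to the
  abundance-weighted centroid; it is defined for any community and is
  zero exactly when all abundance-bearing species coincide.

All four are validated against independent brute-force implementations
(direct formula evaluation, shoelace hulls, an external MST) to 1e-10 on
random communities, and against closed forms (unit square FRic = 1,
equally spaced triplet FEve = 1, equidistant-from-centre FDiv = 1,
two-point FDis = d/2).

## Dissimilarity and ANOSIM

Jaccard dissimilarity is computed on presence/absence *after* the
90%-cover filter, matching the use of a binary index on filtered survey
data.  ANOSIM ranks all pairwise dissimilarities with mid-ranks for ties
and reports $R = (\bar r_{between} - \bar r_{within}) / (M/2)$; because it
is rank-based, R is invariant to monotone transformations of the
dissimilarities.  The p-value is one-sided ($R \ge$ observed).  When the
number of distinct label arrangements is at most 10,000 the test is exact
(all arrangements enumerated — e.g. 1,680 for 9 plots in three groups of
three); otherwise 999 seeded random permutations are used, with
$p = (1 + \#\{R^* \ge R\})/(1000)$.  The study suite runs one test
grouping all plots by climate and one per climate grouping by treatment.

## Mixed models and AICc selection

Each response gets the five marginality-respecting fixed structures
(intercept; climate; treatment; climate + treatment; climate x treatment),
always with a random intercept for block (site letter).  Fits use maximum
likelihood, not REML, because REML likelihoods are not comparable across
different fixed-effect structures.  AICc = AIC + 2k(k+1)/(n−k−1), with k
counting fixed-effect coefficients plus the two variance components.  The
minimum-AICc model is selected unless a model within 2 units has fewer
parameters, in which case the most parsimonious such model supersedes it.
LA and seed-mass CWMs are right-skewed and modelled on the log scale;
their marginal means are reported back-transformed.

For inference the chosen model is *refitted by REML*: ML variance
estimates are biased low at n = 27 and a 500-run null simulation showed
Tukey-adjusted pairwise contrasts exceeding their nominal family-wise
error under ML, while the REML refit controls it.  Degrees of freedom use
the Satterthwaite approximation.  Containment df were considered and
rejected: climate varies only between the nine block letters, and
containment assigns such between-block contrasts zero denominator df,
producing undefined p-values on exactly this design.  Random-effect
variances that collapse to zero are flagged as singular and the model is
retained; non-converging candidates are flagged and excluded.

## The synthetic-community generator

`sim_community()` emulates the study design so each downstream stage has
ground truth: a full 3 x 3 x 3 factorial; per-climate species pools of 12
species with a tunable shared fraction (`pool_overlap`); per-plot relative
covers from a symmetric Dirichlet (concentration 1.5 by default — uneven,
survey-like communities) scaled to percent; lognormal species base traits
with magnitudes typical of a Mediterranean savanna understory (LA ~500
mm², SLA ~15 mm²/mg, LDMC ~250 mg/g, LNC ~20 mg/g, seed mass ~2 mg).

Two signal pathways are separable by construction:

* **Turnover** — a per-trait log-scale gradient (`turnover_strength`,
  default 0.25 per climate step) shifts each species' base trait by its
  home pool's position, so pools differ functionally.  Without such a
  gradient, pool differences would be pure sampling noise and the
  turnover component would have no predictable structure.
* **ITV** — additive plot-level shifts for climate, treatment and their
  interaction (fractions of the trait's baseline scale: 0.12, 0.08, 0.04
  by default) plus Gaussian noise (0.05).  The pooled ("fixed") record of
  a species is the mean of its realised plot-specific values, so the
  decomposition identities hold exactly whatever the parameters.

`covariation_mode` controls the alignment of the climate ITV shift:
`reinforcing` aligns it with the *realised, abundance-weighted*
between-pool base-trait differences of the draw, `opposing` anti-aligns
it, `independent` applies the plain centred-index pattern.  Alignment to
the realised (not expected) gradient matters: with uneven abundances the
realised community-level gradient of a single draw can deviate from, or
even reverse, the expected one, and a regime aligned only in expectation
would not have a predictable covariation sign seed by seed.

Trait values are floored at a tiny positive bound to respect the
positivity contract of the trait table; default effect sizes keep the
floor unreachable in practice.

### Regime presets

* `turnover_only` — all ITV fractions and noise zero; the ITV response is
  identically zero and the decomposition attributes 100% to turnover.
* `itv_only` — one shared pool (`pool_overlap = 1`), no base-trait
  gradient, abundance draws shared across climates, high Dirichlet
  concentration (50) and strong ITV shifts (0.25/0.15/0.08).  Residual
  turnover comes only from abundance noise interacting with the cover
  filter (different low-cover species dropped in different plots) and
  stays near 2% of total SS.
* `mixed_positive` / `mixed_negative` — both pathways active with
  reinforcing/opposing alignment.  These presets use 50% pool overlap
  (covariation is only expressible through species that span the
  gradient: for climate-endemic species the pooled mean absorbs the
  climate ITV shift entirely), a strong gradient (0.4 per step, so its
  realised sign is stable across seeds), fairly even communities
  (concentration 10), and ITV dominated by the aligned climate component
  (0.25 vs 0.05/0.02).  Under these conditions the opposing regime
  produces negative total covariation in ≈98% of seeds, the reinforcing
  regime positive in ≈100%.

### What the generator does not emulate

Real surveys have zero-inflated, spatially autocorrelated covers,
phylogenetically structured traits, trait-abundance correlations, and
missing trait measurements concentrated in rare species.  Passing tests on
synthetic data therefore demonstrate the *correctness of the computations
and the recoverability of known structure*, not robustness to every
property of field data.  The degradation pathways that field data exercise
(missing traits, degenerate trait spaces, confounded interactions) are
tested separately through constructed edge cases.

## Numerical choices

* Filter tie-breaks: lexicographic among equal covers; threshold boundary
  inclusive (a prefix reaching exactly the threshold stops there).
* Hull computations use relative tolerance 1e-9 for coplanarity; facet
  deduplication by rounded normal vectors.
* `itv = specific - fixed` asserted to 1e-12 in tests; decomposition
  identities to 1e-10.
* Exact ANOSIM below 10,000 arrangements; seeded sampling otherwise.
* Permutation p-values use the add-one convention, bounded below by
  1/(n_perm + 1).
* Degenerate inputs yield explicit flags (`NA` with a `reason`
  attribute, a `note` column in `fd_indices()`), never silent zeros —
  except FRic = 0 for a genuine point-community.

## Problem sizes used in the test-suite simulations

Calibration and recovery checks run at the study's own scale (27 plots):
200 random datasets for the decomposition identities, 20-seed and 50-seed
ensembles for regime recovery and covariation signs, 500 null simulations
for ANOSIM and contrast calibration, and 200 random small communities
(4–8 species, 2–3 axes) for the FD brute-force comparisons.  These sizes
give the binomial checks standard errors comfortably inside their
acceptance margins while keeping the whole suite to a few minutes.

## Known limitations

* FRic's exact hull volume enumerates `choose(S, d)` hyperplanes; it is
  intended for plot-level species counts (tens) and up to ~6 axes, not
  for hundreds of species in high dimension.
* The paper-style workflow measures traits at a subset of plots; mapping
  those measurements to surveyed plots is the user's explicit choice via
  `trait_plot_map`, and specific/ITV conventions are only as good as that
  mapping.
* PERMANOVA-style permutation p-values use free permutation; restricted
  schemes (within-block) are not implemented.
* The mixed models assume Gaussian errors; non-Gaussian families are out
  of scope.
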