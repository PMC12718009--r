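---
title: "Methods: estimating premating isolation between ecotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating premating isolation between ecotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prematingRI)
```

# The barrier model

All three premating barriers considered here — ecogeographic, phenological
and pollinator-mediated — act by reducing the chance that pollen from one
ecotype reaches another at all, i.e. they affect co-occurrence. For such
barriers a single statistic applies:

$$\mathrm{RI} = 1 - \frac{S}{S + U}$$

where $S$ is the shared and $U$ the unshared portion of occurrence. RI is 0
under complete overlap (no barrier) and 1 under complete separation. The
currency of $S$ and $U$ differs by barrier: presence cells of the binary
predicted ranges, days of the year with recorded flowering, and legitimate
functional pollinator groups.

**Directionality.** Barrier strength is directional. For gene flow from
donor $x$ into recipient $y$ we take $U$ to be the *recipient's* unshared
portion, $U_y$. Under this convention a recipient whose range (or season,
or pollinator set) is entirely contained in the donor's experiences no
barrier to incoming gene flow, while the reverse direction can be strongly
isolated — the asymmetry characteristic of a small ecotype encased within a
widespread one. The convention is applied uniformly to all three barriers.

**Sequential composition.** Barriers act in series: barrier $i$ removes the
fraction $\mathrm{RI}_i$ of the gene flow that survives barriers
$1,\dots,i-1$. Its absolute contribution is
$\mathrm{RI}_i \prod_{j<i}(1-\mathrm{RI}_j)$ and the total is

$$\mathrm{RI}_{\mathrm{total}} = 1 - \prod_i (1 - \mathrm{RI}_i),$$

which is order-invariant; the contributions are not, and are reported in
the conventional order ecogeographic → phenological → pollinator. Missing
barriers (an ecotype with no pollinator data) are *skipped*, not scored
zero: scoring them zero would assert complete overlap on no evidence.

**Uncertainty.** Confidence intervals are 2.5/97.5 percentiles over 10 000
with-replacement resamples of the barrier's raw units — grid cells for the
ecogeographic barrier, flowering records for phenology, per-population
legitimate-pollinator records for the pollinator barrier. Resampling is
implemented as multinomial draws over the distinct units, which is
distributionally identical to resampling the unit list and much faster.
Intervals for the total draw one value per barrier per replicate from the
component bootstrap distributions, treating barriers as independent, and
compose them sequentially. All resampling is seeded and bit-reproducible.

# Colour vision models

Floral reflectance spectra (percent reflectance on a common 1 nm grid,
300–700 nm) are converted to receptor quantum catches

$$P_i = R_i \int_{300}^{700} S_i(\lambda)\, I(\lambda)\, D(\lambda)\,
d\lambda$$

by the trapezoidal rule, where $S_i$ is the receptor sensitivity, $I$ the
stimulus reflectance and $D$ the illuminant. $R_i$ is the von Kries factor
fixing the adapting background's catch at exactly 1 per receptor, so the
background always maps to the model origin. Catches are hyperbolically
transformed, $E = P/(P+1)$, giving $E = 0.5$ for the background.

The bee (trichromatic) model plots loci in the colour hexagon,
$x = \sin 60^\circ\,(E_G - E_{UV})$, $y = E_B - (E_G + E_{UV})/2$ — the
standard hexagon construction, under which all loci for $E \in [0,1]$ lie
within unit distance of the origin. Euclidean distances between loci proxy
discriminability; achromatic contrast is the absolute green-receptor
excitation difference (bee model only; we do not model fly achromatic
vision, for which behavioural evidence is weak). The fly model uses
colour-opponent coding on the pale and yellow receptor pairs,
$x = E_{R7p} - E_{R8p}$, $y = E_{R7y} - E_{R8y}$; quadrant membership is
the colour category, loci on an axis are flagged rather than assigned, and
a configurable within-quadrant discrimination threshold (default off)
supports the finer discrimination reported for some hoverflies.

The packaged D65-like illuminant, green-leaf background and bee/fly
sensitivities are *synthetic* curves generated from a visual-pigment
nomogram and smooth anchor-point splines; they are adequate for
von Kries-normalized modelling, where the illuminant largely cancels, but
published analyses should substitute measured curves. Correctness of the
machinery is tested with independent Gaussian systems against 0.1 nm
fine-grid integration (1 nm trapezoid agrees within 0.5 % for smooth
curves), so nothing depends on the packaged curves.

Between-group colour distances are summarized as the distance between group
centroids with a percentile bootstrap over within-group resamples.

# Circular phenology statistics

Days of the year map to angles $2\pi d/365$; day 366 folds onto 365. The
Mardia–Watson–Wheeler test replaces pooled circular ranks by uniform
scores $\beta = 2\pi r/N$ and uses
$W = 2\sum_j (C_j^2 + S_j^2)/n_j \sim \chi^2_{2(k-1)}$ under the null.
Citizen-science flowering records are heavily tied (many observations per
day); ties are broken by a *seeded* random rank assignment recorded in the
result — a documented reproducible draw rather than an average over draws.
Group sizes below 10 trigger a warning about the asymptotic approximation.
Pairwise tests are Bonferroni-corrected by the number of pairs.

The phenological barrier uses raw binary day occupancy, not
abundance-weighted overlap: record counts from opportunistic platforms
reflect observer effort, not plant abundance. Occupancy supports optional
circular gap-filling that bridges interior gaps of at most `gap_fill`
missing days (including across the year boundary); filling never extends a
season beyond its observed extremes.

# Abiotic-niche post-processing

The package deliberately consumes suitability surfaces from any external
niche model rather than fitting one: the scientific content here is the
post-processing. Layers are pruned greedily in a user-controlled priority
order, dropping any layer with $|r| > 0.69$ against an already-retained
layer (a pair at exactly 0.69 is kept); the earlier layer in the priority
order survives. Scores are evaluated by rank-based AUC (ties one half) and
binarized at the equal sensitivity–specificity threshold: among candidate
thresholds (the unique observed scores, presence rule score ≥ t), the one
minimizing |sensitivity − specificity|, with ties resolved by maximal
sensitivity + specificity and then the smallest threshold. Overlap is
counted in grid cells over jointly valid cells; equal-area grids are
assumed and a warning is emitted for geographic (degree) grids. Occurrence
records with missing accuracy fail the quality filter (conservative), and
the accuracy rule is strict (`accuracy < 100 m`).

# Pollination networks

Visitation rate is visits per flower per hour. Pollen loads sum the head,
thorax and abdomen counts of conspecific pollen, capping each body part at
1000 grains *before* summing (counts beyond 1000 per part are not resolved
by the counting protocol); summing across parts (rather than taking the
maximum) is our documented choice. Pollinator importance is visitation rate
× mean capped load per functional group; groups observed visiting but never
caught are flagged and carry load 0.

Network specialization uses H2′, the Shannon entropy of the interaction
matrix standardized between the minimum and maximum entropy achievable
under the observed marginal totals. For count webs the extremes respect the
web's granularity: the maximum-entropy table comes from integer
proportional filling (floor of the marginal-product expectation, greedy
repair of the remaining units, then margin-preserving 2×2-transfer
hill-climbing) and the minimum from randomized multistart greedy
concentration (internally seeded, hence deterministic). The unit tests
check these extremes against exhaustive enumeration of all integer tables
with the same margins on small webs. For non-integer matrices the
continuous limits are used; the continuous index is exactly
scale-invariant, and the count-web index converges to it as the web total
grows — exact invariance under *non-integer* rescaling of a small count
web is impossible once extremes are granularity-aware, a trade-off we
accept because interaction webs are counts.

Instead of modularity detection we expose the per-row argmax "pollinator
niche" (the single most important functional group per site), with ties
flagged; on strongly specialized importance networks this reproduces the
same niche structure at a fraction of the machinery. Trait matching uses
importance-weighted mean pollinator traits per site and ordinary least
squares.

# Group statistics

A single permutational engine serves all multivariate group comparisons
(morphology, colour coordinates, realized niches): Euclidean distances on
z-scored features (scaling is the default because the feature tables mix
millimetres, counts and metres; it can be disabled), the pseudo-F from
between/within squared-distance partitions, and p-values
$(1 + \#\{F^\ast \ge F\})/(1 + n_{\mathrm{perm}})$ with 999 seeded
permutations, so the smallest attainable p is 0.001. We use the
permutational test in place of a parametric MANOVA for colour coordinates
as well — one coherent engine, no multivariate-normality assumption; the
pseudo-F is cross-checked against an independent implementation in the test
suite. PCA is column-standardized SVD; zero-variance columns are dropped
with a warning.

# The synthetic ecotype complex

The generator produces every input class the pipeline consumes, from one
master seed with per-ecotype, per-class child streams (adding a sampler
never perturbs another stream). The default scenario has seven ecotypes
qualitatively mirroring a well-studied complex: two widespread lowland
ecotypes, one widespread long-flowering ecotype, a small ecotype encased in
range and season within the widespread ones and lacking pollinator data,
and three restricted ecotypes. Ground truth is exact set arithmetic:
ranges are threshold sets of the true suitability surfaces, seasons are day
intervals (the von Mises law only shapes observation density within them),
and pollinator sets are the scenario's group lists, so `true_ri()` is an
oracle, not an approximation.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| grid | 80 × 60 unit cells | large enough that the smallest range spans ~250 cells |
| suitability edge | logistic in normalized elliptical distance, steepness k = 8 | a smooth habitat gradient; sharp (near-binary) edges make equal-sens-spec thresholding ill-conditioned because the score distribution becomes bimodal and the empirical threshold can land anywhere in the gap |
| presence threshold τ | the population-level equal-sens-spec operating point of each surface | this is the estimand the thresholding estimator is consistent for; defining the true range at any other τ would build an irreducible bias into the recovery comparison |
| flowering κ | 1 | broad within-season spread typical of opportunistic observation records |
| occupancy gap_fill | 3 days (estimation pipeline) | bridges short observation gaps within a season without bridging between seasons |
| background points | 10 000 per ecotype | the conventional background size for presence-background niche models |
| pollination | one dominant functional group per population (0.25 visits·flower⁻¹·h⁻¹), other true groups at 25 % of that rate | populations specialize on one highly effective pollinator while minor visitors still occur, so ecotype-level sets are recoverable |
| pollen counts | negative binomial (μ = 350, size = 1.2), uncapped | overdispersed loads that occasionally exceed 1000, exercising the capping rule |

The validation suite runs the full pipeline at 500 samples per ecotype per
data class on this scenario and requires every directional barrier estimate
within 0.05 of `true_ri`; bootstrap coverage is checked on the weighted
pollinator barrier (a smooth multinomial functional, where
percentile-bootstrap theory applies) with 500 replicate datasets of 500
records and 2000-rep intervals, requiring 93–97 % coverage of a true RI of
0.6. Coverage is *not* checked on the set-valued barriers: at these sample
sizes their estimators are nearly degenerate (the occupancy and range sets
are almost fully recovered every replicate), so interval coverage of a
point mass is not a meaningful calibration target.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: spatial autocorrelation and sampling bias in
occurrence records, observer-effort gradients in phenology, heterospecific
pollen loads and misidentification, between-year phenological shifts,
correlated morphological traits, and suitability surfaces with the complex
geography of real climate layers. The recovery results certify the
estimation pipeline, not the field protocols.

# Numerical choices and degenerate inputs

- Integration: trapezoid on the native 1 nm grid; curves are linearly
  interpolated to that grid on construction.
- `RI` with $S + U = 0$ is undefined and returned as `NA` with a warning,
  never coerced to 0 or 1.
- Bootstrap of a single distinct unit warns and returns a zero-width
  interval.
- Equal-sens-spec threshold ties: maximize sensitivity + specificity, then
  take the smallest threshold.
- Constant environmental layers have undefined correlation; they are
  retained and flagged rather than silently dropped.
- All-zero interaction matrices and empty groups are errors, not zeros.
- Every stochastic routine takes an explicit integer seed and restores the
  caller's RNG state.

# Known limitations

- The pollinator barrier treats functional groups as equivalent in
  effectiveness; a weighted variant (per-group weights summed in place of
  counts) is provided, but weights must be supplied by the user.
- Cell counts are the areal currency; on geographic-degree grids the
  package warns but does not reproject.
- The MWW χ² approximation is poor below ~10 observations per group; no
  exact small-sample variant is provided.
- The H2′ entropy extremes are exact only as far as the local searches
  reach; on large webs they are high-quality heuristics, as is standard for
  this index.
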