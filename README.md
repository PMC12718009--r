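# prematingRI

Quantifying premating reproductive isolation between plant ecotypes from
ecological field data.

When intraspecific forms (ecotypes) diverge in where they grow, when they
flower and who pollinates them, each axis of niche differentiation becomes a
barrier to gene flow. `prematingRI` implements the full analysis chain used
to measure these barriers in a polymorphic species complex:

- **Insect colour vision** — reflectance-spectrum handling, von
  Kries-normalized quantum catches, the trichromatic bee colour hexagon and
  the four-receptor fly colour-opponent-coding (COC) model, chromatic and
  green-receptor achromatic contrasts, and bootstrapped between-group colour
  distances.
- **Flowering phenology** — day-of-year circular statistics, the
  Mardia–Watson–Wheeler k-sample homogeneity test with Bonferroni-corrected
  pairwise comparisons, and binary flowering-day occupancy sets.
- **Abiotic niche post-processing** — Pearson pruning of correlated
  environmental layers (|r| > 0.69), rank-based AUC, equal
  sensitivity–specificity thresholding of habitat-suitability surfaces,
  binary ranges and shared/unshared overlap summaries (ESRI ASCII grid I/O).
- **Pollination networks** — visitation rates (visits·flower⁻¹·h⁻¹),
  per-part-capped pollen loads, pollinator importance (rate × load), the
  network-level specialization index H2′, legitimate functional pollinator
  sets, and importance-weighted pollinator traits with OLS trait matching.
- **Barrier strengths** — for every ordered ecotype pair and every barrier,
  the co-occurrence isolation statistic

      RI = 1 − S / (S + U)

  where `S` is the shared and `U` the *recipient's* unshared portion of
  occurrence (range cells, flowering days, or functional pollinator
  groups), sequential composition of barriers into total premating
  isolation, `RI_total = 1 − Π(1 − RI_i)`, and percentile-bootstrap
  confidence intervals over the barrier-specific raw units.
- **A synthetic ecotype-complex generator** — seven ecotypes with known
  ranges, flowering intervals, pollinator sets, spectral templates and
  morphology, whose true directed barrier table is exactly computable, so
  the whole estimation pipeline can be validated against ground truth.

Group-level statistics (distance-based permutational MANOVA with pairwise
Bonferroni comparisons, PCA utilities) are included for morphology, colour
coordinates and realized-niche tables.

## Worked example

Simulate the default seven-ecotype complex, estimate every directional
barrier from the synthetic field data, and compare with the generator's
ground truth:

```r
library(prematingRI)

scenario <- build_scenario()
dataset  <- simulate_dataset(scenario, n_occurrences = 500,
                             n_flowering = 500, n_populations = 12, seed = 7)
est <- estimate_ri_table(dataset, n_boot = 1000, seed = 7)

subset(est$table, donor == "macowanianus" & recipient == "blandus")
#>            donor recipient       barrier  S  U   RI ci_low ci_high
#> 125 macowanianus   blandus ecogeographic 84 24 0.22   0.15     0.3
#> 126 macowanianus   blandus  phenological 42  0 0.00   0.00     0.0
#> 127 macowanianus   blandus    pollinator NA NA   NA     NA      NA
#> 128 macowanianus   blandus         total NA NA 0.22   0.15     0.3

round(ri_summary(est$table), 2)
#> ecogeographic  phenological    pollinator         total
#>          0.91          0.66          0.39          0.94
```

The `macowanianus → blandus` direction shows the signature asymmetry of an
encased ecotype: `blandus` flowers entirely within the long `macowanianus`
season (phenological RI = 0) and most of its small range lies inside the
`macowanianus` range, so isolation *into* `blandus` is weak while the
reverse direction is strong. `blandus` carries no pollinator data, so its
totals compose only the ecogeographic and phenological barriers (the
`pollinator` row is `NA`, not zero). Complex-wide, ecogeographic isolation
is the strongest barrier and the three barriers together give near-complete
premating isolation. Against the generator's exact `true_ri(scenario)`
table, every estimated barrier here is within 0.01 of truth.

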