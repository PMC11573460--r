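# grazesel

Diet-selection analysis for grazing trials, from raw measurement layers
to selectivity, intake and dietary-composition statistics.

Grazing sheep on temperate steppe face grasslands dominated by grasses of
modest nutritional value; whether and how strongly animals select
scarcer, protein-rich forbs — and whether young animals learn that
selection from experienced adults in mixed groups — is the core question
this package's toolchain addresses. It takes four standard data layers:

* **vegetation quadrat surveys** (clipped dry biomass per species),
* **tri-axial accelerometer traces**,
* **marker-dosed fecal chemistry** (TiO₂, crude protein, ash),
* **fecal DNA metabarcoding read tables** (ASV counts + reference barcodes),

and turns them into availability, behaviour, intake and diet estimates,
joined by the statistics used to compare grazing strategies. A
synthetic-data generator reproduces all four layers with known ground
truth, so the entire pipeline is testable end to end.

## The quantities at its core

* **Jacobs' electivity** for food item use *r* vs availability *p*:
  `D = (r − p) / (r + p − 2rp)`, in [−1, 1], 0 at proportional use;
  departures from neutrality tested per item with an exact signed-rank
  test.
* **Marker intake chain**: `FO = dose / [TiO₂]`,
  `FOM = FO (1 − ash/100)`, `OMD = 0.899 − 0.644 e^(−0.5774 FCP/100)`,
  `OMI = FOM / (1 − OMD)`.
* **ODBA behaviour classification**:
  `ODBA = |dₓ| + |d_y| + |d_z|` after removing a running-mean static
  component; epochs above 0.1 g are grazing.
* **Diet composition (DRA)**: reads assigned by exact 100%-identity
  barcode match, summed within plant families, normalized over assigned
  reads; dietary richness by rarefaction-style bootstrap.
* **Comparative statistics**: pooled t-tests, one-way ANOVA,
  Bray–Curtis dissimilarity, multi-start NMDS, one-way permutational
  MANOVA (implemented from the distance decomposition), and
  standardized multiple regression of dietary richness on vegetation
  characteristics with Wald tests.

## Worked example

Simulate a full trial (four strategies, 3 plots per grazing unit,
3 periods, 108 diet samples) and run the main analyses:

```r
library(grazesel)

trial <- simulate_trial(collars = c(LA = 1, LM = 1, EM = 0, EA = 0),
                        depth = 20000, seed = 42)
trial
#> Simulated grazing trial: 37 species, 9 plots, 3 periods, 108 samples, 6 traces

# marker chain: fecal output, digestibility, organic-matter intake
intake <- estimate_intake(trial$fecal)
head(intake, 3)
#> # A tibble: 3 × 6
#>   animal period    fo   fom   omd   omi
#>   <chr>   <int> <dbl> <dbl> <dbl> <dbl>
#> 1 LA1_a1      1  663.  562. 0.669 1698.
#> 2 LA1_a1      2  559.  462. 0.682 1453.
#> 3 LA1_a1      3  451.  380. 0.591  930.
```

An animal producing 663 g fecal dry matter a day at 67% digestibility
ate about 1.7 kg of organic matter. Diet composition and selectivity:

```r
taxonomy <- assign_exact(attr(trial$reads, "sequences"),
                         pool_reference(trial$pool))
nut <- trial$pool[, c("species_id", "cp", "ndf", "adf")]
item_nutr <- food_item_nutrients(trial$quadrats, nut, trial$family_map) |>
  dplyr::summarise(cp = mean(cp), ndf = mean(ndf), adf = mean(adf),
                   .by = item)
diet <- diet_composition(trial$reads, taxonomy, trial$family_map,
                         item_nutr, iterations = 200, seed = 7) |>
  dplyr::left_join(trial$samples, by = "sample")

dra_long <- tidyr::pivot_longer(diet, dplyr::starts_with("dra_"),
                                names_to = "item", names_prefix = "dra_",
                                values_to = "dra")
sel <- compute_selectivity(
  dra_long[, c("sample", "plot", "period", "item", "dra")],
  availability_long(trial$vegetation)) |>
  dplyr::left_join(trial$samples[, c("sample", "strategy")], by = "sample")

selectivity_tests_by_item(sel[sel$strategy == "LM", ])
#> # A tibble: 6 × 7
#>   item               n statistic    p_value direction method      median_d
#> 1 Amaryllidaceae    27        29 0.000127          -1 normal ap…    -0.331
#> 2 Cyperaceae        27        21 0.0000572         -1 normal ap…    -0.252
#> 3 Fabaceae          27        84 0.0121            -1 normal ap…    -0.158
#> 4 forbs             27       378 0.00000593         1 normal ap…     0.479
#> 5 Poaceae           27         0 0.00000593        -1 normal ap…    -0.287
#> 6 Rosaceae          27        50 0.000876          -1 normal ap…    -0.125
```

Lambs in mixed grazing prefer forbs (median D = 0.48, p < 0.001) and use
every other item below its availability — the preference structure the
simulation was configured with. Dietary dissimilarity between lambs
alone and lambs in mixed grazing:

```r
sub <- diet[diet$strategy %in% c("LA", "LM"), ]
mat <- as.matrix(sub[, grep("^dra_", names(sub))])
rownames(mat) <- sub$sample
permanova(bray_curtis_matrix(mat), sub$strategy, seed = 9)
#> perMANOVA: pseudo-F = 204.4394 (df 1, 52), R2 = 0.7972, p = 0.001 (sampled, 999 permutations)
nmds(bray_curtis_matrix(mat), seed = 10)
#> NMDS ordination: 54 samples in 2 dimensions, stress = 0.0577

# behaviour from the first simulated collar
cls <- classify_behavior(dynamic_component(trial$accel[[1]]$trace))
daily_grazing_time(cls)
#> [1] 8.783333
```

The two lamb groups' diets separate cleanly (R² = 0.80, p = 0.001; the
simulated contrast is deliberately strong), the ordination embeds them
at low stress, and the first collared animal grazed 8.8 h of its 13 h
session. `autoplot()` methods exist for ordinations and regressions,
`plot_selectivity()`/`plot_behavior()` for the other result types, and
`run_pipeline()` drives all stages from one config with a checksum
manifest.

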