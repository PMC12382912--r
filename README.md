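# nepartition

Factorial net-energy partition analysis for growing pigs measured by
indirect calorimetry.

## The problem

The net energy (NE) system values feed by the energy an animal can
actually deposit or spend, after successive deductions from gross energy
(GE): fecal losses give digestible energy (DE), urinary and methane
losses give metabolizable energy (ME), and the heat increment of feeding
gives NE.  In growing pigs NE is further partitioned into energy retained
as body protein (PD) and as body lipid (LD), and the split depends
strongly on which nutrient supplies the energy — starch, oil and casein
behave very differently.  This package implements the full analysis chain
for substitution ("difference method") calorimetry trials:

1. **Energy and nitrogen balance** per pig: apparent total tract
   digestibility `ATTD = (intake − fecal)/intake`, nitrogen retention
   `NR = N_in − N_fecal − N_urinary`, `DE = GE_i − GE_f`,
   `ME = DE − GE_u − CH4E`, and heat production from 5-min respiration
   chamber gas traces by the Brouwer equation
   `HP = 16.18·O₂ + 5.02·CO₂ − 2.17·CH₄ − 5.99·uN` (kJ; L and g per day).
   The partition on the metabolic body-weight scale (kJ/kg BW^0.6/d) is
   then `HI = THP − FHP`, `NE = ME − HI`, `RE = ME − THP`,
   `PD = NR × 6.25 × 23.86`, `LD = RE − PD`.
2. **Single-nutrient energy values** by the difference method: for a test
   diet in which a nutrient replaces part of the basal diet's
   energy-supplying fraction (proportions r₀, r₁, r₂),
   `value_j = (value_test − value_basal/r₀·r₁)/r₂`, plus the efficiency
   ladder `dj = DE/GE`, `mj = ME/DE`, `pj = PD/ME` and `kj`, the
   efficiency of using ME for NE not deposited as protein.
3. **The nested partition model**
   `LD = kj(1−pj)·ME − K_BR·FHP + NE_PD·PD`, estimating `K_BR` (efficiency
   of using body reserves for ATP synthesis during fasting) and `NE_PD`
   (additional energy cost of protein deposition) by least squares with an
   explicit Newton–Raphson solver.
4. **Prediction equations** for PD and LD from ingredient nutrient
   characteristics (GE, CP, EE, starch, NDF, ADF, ash): Pearson
   correlation screening and forward–backward stepwise regression at
   p = 0.05 with R², RMSE, AIC, BIC and validation R² on a seeded 70/30
   split.

A synthetic-data module generates complete trials (balance records and
gas traces) with known latent parameters, so every estimator in the chain
is testable by parameter recovery; the published reference tables are
packaged as plain-CSV fixtures (`nep_fixture()`).

## Worked example

Simulate a noise-free six-diet trial (36 pigs) and run the full analysis:

```r
library(nepartition)

trial <- generate_trial(trial_spec(n_pigs_per_diet = 6, noise_sd = 0,
                                   seed = 7), traces = FALSE)
res <- analyze_trial(trial$records, trial$schemes,
                     ge_density = setNames(trial$diet_info$ge_density,
                                           trial$diet_info$diet),
                     nutrients = c(T2 = "corn_starch", T3 = "pea_starch",
                                   T4 = "tapioca_starch",
                                   T5 = "soybean_oil", T6 = "casein"))
res
#> Trial analysis: 36 pigs, 5 nutrients
#>
#>        nutrient   ge   de   me   ne    dj    mj   pj   kj
#>     corn_starch 16.1 16.0 15.8 14.0 0.994 0.984 0.05 0.88
#>      pea_starch 16.3 16.1 15.4 12.4 0.985 0.957 0.05 0.80
#>  tapioca_starch 17.0 17.1 16.3 14.2 1.003 0.957 0.05 0.86
#>     soybean_oil 38.0 36.5 36.2 32.7 0.961 0.991 0.12 0.95
#>          casein 20.2 19.2 16.9 14.2 0.950 0.881 0.51 0.68
#>
#> Nested net-energy partition fit (n = 5)
#>   K_BR  = 0.9600 (se 0.0000)
#>   NE_PD = 0.3500 (se 0.0000)
#>   converged: TRUE after 2 iteration(s); SSE = 6.592e-25
```

With measurement noise off, the analysis chain inverts the generator
exactly: the per-nutrient efficiencies `pj`/`kj` and the nested-model
coefficients come back at their latent values (here `K_BR = 0.96`,
`NE_PD = 0.35`).  With the default, SEM-matched noise the same call
returns noisy estimates whose bias and spread are characterised in the
test suite.

The regression stage works off the packaged 47-ingredient table:

```r
tab4 <- nep_fixture("table4_ingredients")
correlation_matrix(tab4)$r["cp", "pd"]
#> [1] 0.9196224

stepwise_fit(tab4, "pd", c("ge", "cp", "ee", "starch", "ndf", "adf", "ash"))
#> pd = 14.88 +28.78 x cp -18.75 x adf
#>   n = 47, R2 = 0.907, RMSE = 140.75, AIC = 467.92, BIC = 473.47
```

Crude protein is the dominant predictor of protein deposition (r = 0.92),
and the stepwise search at p = 0.05 keeps CP with a positive and ADF with
a negative coefficient.

`run_pipeline()` chains simulate → balance → difference → regress and
writes CSV outputs plus a JSON manifest of every assumed constant; a thin
command-line wrapper lives at `inst/scripts/nepartition`.

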