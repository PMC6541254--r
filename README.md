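# grapemx

Non-destructive grape ripening estimation from multi-channel
chlorophyll-fluorescence readings, and the economics of adopting the
sensor that takes them.

## The problem

Tracking berry ripening the classical way is destructive and slow:
samples are cut from the vine on repeated dates, hauled to a laboratory,
and assayed for sugars (TSS, °Brix), acids and — in red cultivars —
total anthocyanins. Hand-held fluorimeters offer an alternative: they
excite chlorophyll with red, green and UV light and read the far-red
fluorescence that escapes the berry skin. Pigments in the skin screen
specific excitation bands, so ratios of the four channels (FRF_R, FRF_G,
FRF_UV, RF_R) track skin composition without touching the fruit.

`grapemx` is aimed at viticulture researchers and technical consultants
who want to (a) turn raw channel readings into the standard indices,
(b) fit and invert the calibration curves linking those indices to wet
chemistry, and (c) decide whether buying the sensor pays off for a given
farm.

## The indices and models

Five indices are derived from the four channels (decimal logs):

| index | definition | tracks |
|---|---|---|
| `ANTH_RG` | log10(FRF_R / FRF_G) | anthocyanins (green-light screening) |
| `FERARI`  | log10(1 / FRF_R)     | anthocyanins (single signal) |
| `FLAV`    | log10(FRF_R / FRF_UV)| flavonols |
| `FLAV_UV` | log10(1 / FRF_UV)    | flavonols (UV screening) |
| `SFR_R`   | FRF_R / RF_R         | chlorophyll breakdown → sugars |

`FLAV + FERARI = FLAV_UV` holds exactly by construction. Calibration
families are linear (`y = p1 x + p2`), polynomial (quadratic for
flavonols, quartic for the non-monotone `ANTH_RG` response) and the
three-parameter sigmoid

    y = a / (1 + exp(b - c·x))

whose asymptote `a` is the anthocyanin plateau. The sugar model is
restricted to TSS ≥ 10 °Brix, below which `SFR_R` is uninformative.
Anthocyanins convert between fresh-berry and fresh-skin mass bases
through the skin-to-berry ratio (%).

The investment appraisal discounts the yearly cost saving `C` of
replacing destructive sampling (grape destroyed + sampling labor +
laboratory assays) over the sensor lifetime `T`:

    NPV = -I - Σ_m M/(1+r)^m + Σ_{t=1..T} C/(1+r)^t

with purchase price `I` = 13,900 EUR, maintenance `M` = 1,000 EUR every
3rd year, discount rate `r` = 2%. `breakeven_lifetime()` searches the
smallest `T` with NPV > 0; `monte_carlo_npv()` propagates uncertainty in
labor cost and sampling times; `sensitivity_sampling_time()` stress-tests
the timing assumptions.

A seeded synthetic-data module (`simulate_season()`,
`synthesize_fluorescence()`, `simulate_cluster_sides()`) generates
seasonal ripening trajectories for five cultivar profiles (two white,
one pink, two red) and fluorescence records consistent with the
published calibration equations, so the whole pipeline is testable
without field data.

## Worked example

```r
library(grapemx)

## a season of a deep-red cultivar, and its optical readings
profile  <- cultivar_presets()$barbera
season   <- simulate_season(profile, seed = 20)
readings <- synthesize_fluorescence(season, profile, seed = 21)
idx      <- compute_indices(readings)
head(idx[, c("doy", "frf_r", "frf_g", "ferari", "anth_rg", "sfr_r")], 3)
#>   doy     frf_r    frf_g      ferari     anth_rg     sfr_r
#> 1 190 0.8807665 1.052055  0.05513921 -0.07717783 0.9906733
#> 2 190 1.0132051 1.306857 -0.00569735 -0.11053073 0.6493159
#> 3 190 0.7444886 0.818702  0.12814195 -0.04126778 0.9712076

## refit the anthocyanin calibration from the noisy season
models <- printed_calibration_models()
keep <- season$anth_berry > predict(models$anth_ferari$barbera, 0) &
        season$anth_berry < 0.99 * 1.55
fit_sigmoid(idx$ferari[keep], season$anth_berry[keep])
#> <calibration: sigmoid>
#>   y = 1.54482 / (1 + exp(3.99039 - 5.31924 * x))
#>   R^2 = 0.9997, n = 12
```

Despite 3% channel noise and replicate chemistry noise, the refit lands
on the generating curve (a = 1.55, b = 4.005, c = 5.261). At harvest,
1.68 mg/g of anthocyanins per fresh berry at a 9.82% skin ratio is
`convert_anth_basis(1.68, 9.82)` = 17.1 mg/g of fresh skin.

```r
## is the sensor worth buying for a 2-ha farm with 3 red cultivars?
plan  <- farm_preset("two-hectare", n_cultivars = 3)
costs <- cost_parameters()
npv_report(plan, costs, lifetime = 7)
#>  scenario cash_flow_eur_y  npv_eur lifetime_y breakeven_y
#>     lower        2593.245 1053.165          7           7
#>     upper        2609.040 1155.390          7           7
#>   average        2600.231 1098.380          7           7

monte_carlo_npv(plan, costs, "average", lifetime = 7, seed = 1)
#> <NPV: 1094.07 EUR over 7 y (average scenario)>
#>   Monte Carlo: mean 1094.07, sd 129.27, n = 1000, t = 267.64, seed = 1
```

The farm saves ≈ 2,600 EUR/year (dominated by the 126 × 20 EUR
laboratory assays it avoids); over 7 years that exceeds the purchase and
maintenance cost by ≈ 1.1 k EUR, so 7 years is also the breakeven
lifetime. With 2 cultivars the breakeven stretches to 11 years; the
30-hectare estate preset (`farm_preset("mossi")`, 6 cultivars) breaks
even after 3.

A thin CLI wraps the same functions
(`inst/scripts/grapemx <simulate|indices|calibrate|econ|report>`), and
`run_pipeline()` drives everything from a YAML/JSON scenario config.

## Vignette

`vignettes/grapemx-methods.Rmd` documents the models, the generator's
assumptions, numerical choices and known limitations.
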