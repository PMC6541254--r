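---
title: "Methods: fluorescence ripening indices and the sensor-adoption appraisal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluorescence ripening indices and the sensor-adoption appraisal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapemx)
```

`grapemx` has two computational halves — optical estimation of grape
ripening and the economics of adopting the sensor — glued together by a
synthetic-data generator that makes both testable end to end. This
vignette explains the models, the defaults and why they are what they
are, the numerical choices, and what the package's tests do and do not
demonstrate about real field data.

## 1. Fluorescence indices

A hand-held fluorimeter pointed at a grape cluster excites chlorophyll
through the berry skin with red, green and UV light and records far-red
fluorescence (`frf_r`, `frf_g`, `frf_uv`) plus red fluorescence under
red excitation (`rf_r`). Skin pigments absorb specific excitation
bands before they reach the chlorophyll: anthocyanins absorb green,
flavonols absorb UV. Ratios of channels therefore carry skin
composition.

`compute_indices()` derives the five standard indices. The logarithm
base is decimal: the defining equations are written "log" without a
base in the index literature, and `log10` is the convention there; all
published calibration coefficients shipped in
`printed_calibration_models()` are interpreted on that scale. Two
algebraic facts are worth knowing and are enforced by tests:

* `flav_uv = flav + ferari` exactly, because
  `log10(frf_r/frf_uv) + log10(1/frf_r) = log10(1/frf_uv)`;
* `anth_rg` and `sfr_r` are ratios of channels and are invariant to a
  common rescaling of all channels, while `ferari`, `flav` and
  `flav_uv` are not — so the latter three depend on the normalization
  step being consistent across readings.

`normalize_signals()` applies `(raw − offset) / standard` per channel.
Its defaults are the identity because exported field data are usually
already offset-corrected and expressed relative to the fluorescence
standard; the step exists for users starting from raw electronics
counts. A corrected channel that is not strictly positive is a sensor
fault, not a value, and raises a classed error naming the channel.

## 2. Calibration families

Three families cover the published curve shapes:

* **linear** — sugar (`sfr_r` vs TSS, negative slope as chlorophyll
  degrades) and low-pigment anthocyanin responses;
* **polynomial** — quadratic for the flavonol index, quartic for the
  red/green anthocyanin index, whose response rises to a peak near
  0.5–1.0 mg/g and then falls back toward zero as dense pigment
  re-absorbs the green-excited fluorescence;
* **sigmoid** `y = a/(1 + exp(b − c·x))` — the single-signal
  anthocyanin index in deeply colored cultivars, with asymptote `a`
  the concentration plateau (≈ 1.5 mg/g fresh berry mass).

The model object stores the family, ordered coefficients, an optional
validity window, `r2` and `n`. Orientation convention: for the
anthocyanin sigmoid/linear set the predictor is the index and the
response the concentration (so the generator *inverts* them), whereas
the sugar, flavonol and red/green models are stored in forward
(chemistry → index) orientation, matching how each is used. `x_name`
and `y_name` make the orientation explicit on every object.

Numerical choices:

* Linear and polynomial fits are ordinary least squares via `stats::lm`
  on raw powers. `r2 = 1 − SSE/SST` with SST about the mean — the
  conventional definition; published polynomial `r2` values may come
  from a different software definition, so exact `r2` equality is never
  asserted, only coefficient recovery.
* The sigmoid is fitted with Levenberg–Marquardt (`minpack.lm::nlsLM`,
  `ftol = 1e-10`, ≤ 500 iterations per start). Starting values come
  from a logit linearization — `a0 = 1.05·max(y)`; regressing
  `log(y/(a0 − y))` on `x` over interior points gives `c0` (slope) and
  `b0` (−intercept) — followed by a deterministic ladder of up to 10
  jittered `a0` restarts before a classed failure. The ladder is a
  fixed sequence, not random, so identical data always yield identical
  fits.
* `invert_calibration()` is closed-form for both invertible families; a
  sigmoid requires `0 < y < a` and errors otherwise. `invert ∘ predict`
  is the identity to 1e-9 on the valid domain (property-tested).
* `select_model()` picks the candidate with the highest `r2`, breaking
  exact ties (within 1e-12) toward fewer coefficients. The original
  analysis chose families per cultivar by inspection; parsimony is the
  natural automatic tie-break.
* The sugar-domain threshold defaults to 10 °Brix (`filter_tss_domain`)
  but is an argument: the 10 °Brix inflexion is an empirical feature of
  the underlying study, not a physical constant.

Basis conversion: anthocyanins live in the skin, so concentration per
gram of fresh skin is the whole-berry concentration divided by the
skin-to-berry fresh-mass fraction. `convert_anth_basis()` and its
inverse round-trip exactly and preserve ordering.

Two published captions required editorial decisions, made once and
documented here: the Ortrugo sugar model is printed with a missing "x"
and is read as slope −0.0205; and the berry-basis quartic for the
darkest cultivar is printed with a sign pattern that evaluates negative
everywhere, contradicting its own described shape — the stored version
flips the linear term to +1.2373, which reproduces the peak-then-decline
response. The skin-basis anthocyanin models are shipped for
completeness; the generator anchors on the berry-basis set, which is
internally consistent.

## 3. The economic appraisal

The sensor does not change revenue; it changes costs. The annual net
cash flow is the cost of the destructive protocol minus the cost of
running the sensor over the same protocol, with three components
(`annual_net_cash_flow()`):

1. **grape destroyed** — ripening samples of 0.05–0.2 kg and harvest
   bunches of 0.1–0.4 kg valued at 0.45–0.60 EUR/kg. Scenario bounds
   (`lower`/`upper`/`average`) pick the corresponding bound of every
   range; only this component depends on the scenario, which is why the
   three scenarios differ by only a few EUR.
2. **labor** — destructive collection minus one optical point per
   replaced sample, at 8 EUR/h.
3. **laboratory assays** — 20 EUR per avoided anthocyanin assay. The
   5 EUR sugar assay is recorded but excluded from savings: the sensor's
   sugar estimate is not reliable enough to drop the refractometer,
   which growers own in either regime.

The protocol is 6 dates × 5 samples per cultivar plus 12 harvest
bunches (3 bunches × 4 vines) per cultivar: 126 assays/year for three
cultivars. Each harvest bunch is treated as one assay and one labor
unit, and each destructive sample is replaced by exactly one optical
point — the protocol text is ambiguous about pooling, and this reading
reproduces the published NPV table within a few percent.

`npv()` discounts end-of-year cash flows at 2% against the 13,900 EUR
purchase and 1,000 EUR maintenance. Maintenance falls at the end of
*every* 3rd year of ownership, including a final year that is a
multiple of three. The alternative (no servicing in the disposal year)
reproduces the same baseline breakevens, but it makes the breakeven
drift when all sampling times are scaled by a common factor — and
invariance of the results under exactly that scaling is a documented
property of the appraisal. Charging maintenance on schedule regardless
of disposal keeps the breakeven invariant for scalings between 0.5× and
2× and is also the contractually realistic reading of "every 3 years".

`monte_carlo_npv()` draws labor rate and the three sampling times from
uniform distributions centered on their nominal values with ±20%
relative half-width (1000 draws). The underlying study names the
stochastic variables but not their distributions; the symmetric uniform
is a deliberate stand-in, so only the *expected* NPV is comparable to
published values — spreads and significance statements are not. With
zero half-width the simulation collapses bit-for-bit onto the
deterministic NPV, which doubles as a correctness check. Every
stochastic result carries its seed.

Presets: `farm_preset("two-hectare")` (11 / 4.5 min destructive,
5 min optical — an average Italian vineyard) and `farm_preset("mossi")`
(6 red cultivars, 20 / 9 / 9.5 min — a 30-ha estate). Under defaults
the breakeven lifetimes are 11, 7 and 3 years for 2-cultivar,
3-cultivar and estate cases, with 7-year average-scenario NPVs of about
−4.5 k, +1.1 k and +18.6 k EUR.

## 4. The synthetic-data generator

The generator exists so that every analysis step has realistic,
seed-reproducible input. It emulates:

* **seasonal chemistry** (`simulate_season()`): one logistic per
  variable between onset and harvest anchors — sugar rising from
  ≈ 5 °Brix (veraison onset) to the cultivar's harvest value, acids and
  malate decaying, anthocyanins rising to the cultivar maximum,
  flavonols, phenolics and berry mass rising. The pre-veraison
  lag-phase plateau is the logistic's lower tail rather than a separate
  segment — adequate for calibration work, which only needs the
  covered concentration range, not the botanically exact time course.
  The skin-to-berry ratio drifts linearly to its harvest anchor within
  8–13% (its full seasonal table is not published; the harvest values
  are). Skin-basis anthocyanins are *derived* from the berry basis
  through the ratio, so the two bases are exactly consistent at every
  date. Replicate noise is additive Gaussian, truncated at zero.
* **fluorescence channels** (`synthesize_fluorescence()`): the
  anthocyanin index is the *inverse* of the published anthocyanin
  model at the sample's concentration; the red/green and flavonol
  indices are forward model values; the sugar ratio comes from the
  cultivar's sugar model above 10 °Brix and is drawn uniformly from the
  observed pre-threshold variability band (0.5–1.1) below it. The
  four indices determine the four channels uniquely, and channels then
  receive multiplicative log-normal noise (σ = 0.03 by default, chosen
  so refits at n = 27 land near the published fit qualities without
  asserting them). Concentrations at or above 99% of a sigmoid
  asymptote are clipped there with a warning; concentrations below the
  model's sensitivity floor (the sigmoid value at index 0) map to the
  index baseline. Both clips keep the generated point exactly on the
  curve, so zero-noise refits recover the generating coefficients to
  1e-4 — the package's central round-trip property.
* **cluster sides** (`simulate_cluster_sides()`): south-west readings
  are the published linear side-concordance relations applied to the
  north-east values, then back-converted to channels. The early-season
  side asymmetry in the sugar ratio is carried entirely by that
  relation's slope (0.718) rather than a separate bias term.
* **profiles**: five presets anchored to the published harvest table —
  two whites (no anthocyanins), one pink (0.20 mg/g), two reds (1.68
  and 1.91 mg/g), harvested at day-of-year 233 (whites) or 249. The
  default season is 9 dates × 3 replicates = 27 samples, matching the
  sample size of the published per-cultivar fits. White and pink
  profiles have no sigmoid of their own and route their (zero or low)
  anthocyanin through the pink cultivar's linear relations, which are
  defined and positive there. No sugar model was significant for the
  darkest red (its fitted slope even implies negative ratios at high
  sugar), so that profile draws its sugar ratio from the variability
  band at all sugar levels.

What the generator does *not* emulate: weather forcing, berry optics,
within-vine spatial structure, inter-season variation, or the ANOVA
block structure of the field trial. Consequently, passing tests show
that the *pipeline* is correct — indices, fits, inversions and the
economics reproduce known inputs — not that the published per-cultivar
field `r2` values (0.04–0.99) would be reproduced on new field data;
those depend on unpublished raw measurements and are out of scope.

## 5. Degenerate inputs and error contract

All user-facing failures are classed conditions
(`grapemx_invalid_signal`, `grapemx_degenerate_fit`,
`grapemx_fit_failure`, `grapemx_out_of_range`,
`grapemx_unsupported_family`, `grapemx_invalid_ratio`,
`grapemx_pairing_error`, `grapemx_selection_failure`,
`grapemx_invalid_lifetime`, `grapemx_invalid_distribution`,
`grapemx_config_error`, `grapemx_data_error`) so pipelines can branch
on the class. Notable contracts: fits require 3 (linear),
`degree + 2` (polynomial) or 5 (sigmoid) points; constant `y` is a
degenerate sigmoid input, not a convergence failure; polynomial
inversion is refused rather than approximated; a zero skin ratio is an
invalid-ratio error, never an Inf.

## 6. Reproducibility and problem sizes

Every stochastic function takes a seed and restores the caller's RNG
state, so library use never perturbs a session's random stream.
Pipeline outputs are written atomically and record their seed in a
`# seed=` header; identical config and seed give byte-identical files.
The test suite and the acceptance script run on desk-scale problems —
27-sample seasons, 200-replicate noise studies, 1000-draw Monte Carlo —
sizes chosen to match the published fits' sample sizes and to keep a
full run in seconds while leaving Monte Carlo standard errors around
4 EUR, far below the decision scale of the appraisal.

## 7. Known limitations

* Calibrations are single-site, single-season by design; no
  multi-season transfer or prediction intervals are offered.
* The skin-basis sigmoid set is stored as printed but its asymptotes
  are inconsistent with the ~15–20 mg/g skin-basis plateau narrative;
  the berry-basis set is the one the generator trusts.
* The economics model the cost side only: no revenue effects, taxes,
  inflation, financing, or farm sizes beyond the two presets plus user
  configuration.
* The Monte Carlo distribution family is an assumption (uniform,
  ±20%); conclusions about NPV spread inherit it.
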