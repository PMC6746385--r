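---
title: "Methods: a desk-scale testbed for parameterization uncertainty in EPIC-style crop model ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale testbed for parameterization uncertainty in EPIC-style crop model ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and intent

Global gridded crop models (GGCMs) that share the same process core can still
disagree substantially because of their *setups*: cultivar distributions, soil
data and its handling, coefficients for nutrient and water processes, and
management assumptions. `gridcropens` re-creates, at desk scale, the analysis
machinery used to study such parameterization-induced uncertainty: a synthetic
gridded world, a minimal EPIC-style daily crop-soil simulator whose parameters
are grouped into six switchable *setup domains*, area-weighted aggregation,
ensemble agreement metrics, benchmarking against country-level reported
yields, a full 2^6 factorial permutation of the setup domains between two
parent configurations, and driver analyses relating disagreement to
fertilizer input, climate region and cultivar choice.

The package is a *testbed*, not a crop model for forecasting. Everything runs
on synthetic inputs with known structure, so every downstream claim the test
suite makes is checkable against a planted truth.

## The simulator

The daily loop follows the classical EPIC skeleton:

* **Phenology** by heat-unit accumulation: daily heat units are
  `max(0, (Tmin+Tmax)/2 - Tbase)`, capped at `Topt - Tbase`; the season ends
  when the cumulative sum reaches the potential heat units (PHU) computed for
  each growing season from the weather climatology, or at the harvest date.
* **Potential growth** by radiation-use efficiency:
  `dB = 0.01 RUE * f_row * f_int * (0.5 * Rs)` t/ha, where `f_int` is light
  interception from a two-anchor S-curve in heat-unit time (anchors (0.15, 5%)
  and (0.50, 95%)), `0.5 Rs` is the photosynthetically active fraction of
  global radiation, and `f_row` is a row-spacing factor from the management
  domain.
* **The minimum-stress rule**: on each day only the single most limiting of
  the water, nitrogen, phosphorus and temperature factors scales the
  potential increment. Temperature stress is a linear ramp from `Tbase`
  (factor 0) to `Topt` (factor 1) -- deliberately the simplest form
  preserving the qualitative behavior; it is harsher near the margins than
  EPIC's sine response, which matters for interpreting cold-margin cells.
* **Yield formation**: the realized harvest index is
  `HI_a = HI_max - (HI_max - HI_min) * WSI`, where WSI is the mean water
  stress deficit over the days after a configurable fraction of the season
  (0.50 in most presets, 0.45 in one). Yield = aboveground biomass x `HI_a`.
* **Water balance**: curve-number runoff with the retention parameter scaled
  down by a profile soil-moisture index raised to the configured curve-number
  index coefficient; percolation above field capacity limited by saturated
  conductivity; transpiration limited by a fixed daily extractable fraction
  (0.12) of plant-available water; topsoil evaporation modulated by the soil
  evaporation coefficient. The balance closes to machine precision by
  construction, and tests require closure to 1e-6 of cumulative flux.
* **Nutrients**: first-order mineralization of organic N
  (`2e-4 d^-1` base rate x microbial decay coefficient x moisture S-curve x
  temperature factor x an oxygen-by-depth factor `1 - S(depth)`), daily
  volatilization of a fraction of surface mineral N (coefficient x 0.01),
  and a scalar first-order denitrification loss active only near saturation
  (a documented stand-in for the method-specific denitrification routines;
  rates 0.002-0.01 per day by "method" label). Crop uptake is
  demand-limited by the mineral pools; N mass is conserved across pools,
  losses and uptake.
* **Management**: automatic irrigation and fertilization are triggered when
  the previous day's stress factor falls below the configured trigger
  (e.g. 0.80 or 0.90), filling the profile to field capacity up to the
  maximum single application, or applying 25 kg N per event within the annual
  budget. One preset uses *rigid timing* instead: the annual rate in three
  calendar doses (days 1, 31, 61). Under the sufficient-nutrient scenario the
  budget is unlimited (rigid timing applies 150 kg per dose).

### Setup domains and presets

Parameters are grouped into six domains -- `cult`, `soil_d`, `soil_p`,
`coeff_n`, `coeff_w`, `manage` -- mirroring how real EPIC-based GGCM setups
differ. Five presets ship with the package. The two permutation parents are:

* `eIIASA`: Hargreaves PET (0.0023, exponent 0.6), prescribed soil hydraulics
  ("pedotransfer A": higher field capacity, lower wilting point), 10 soil
  layers, static soil profile (annual re-initialization of texture and
  organic matter; water and mineral nutrients carry over), transient
  continuity, microbial decay 0.8, N volatilization coefficient 0.700,
  triggers 0.80, max single irrigation 500 mm.
* `gGEPIC`: Hargreaves (0.0032, 0.5), online pedotransfer ("B", Rawls-like),
  5 layers, dynamic soil profile with a 0.003/yr topsoil loss, decadal
  continuity (full soil reset each decade followed by a spin-up, shortened
  to 5 years at desk scale from the 30-year original), decay 1.0,
  volatilization 0.005, triggers 0.90, max single irrigation 1000 mm, a 1.1
  row-spacing factor and higher residue removal.

`eBOKU`, `eTAMU` and `pPEPIC` complete the ensemble (all-high-yielding
cultivar map; dynamic-transient soils with stress triggers at 0.99; rigid
fertilizer timing with water-erosion topsoil loss, respectively). Members
whose real-world counterparts use Penman-Monteith PET get the textbook
Hargreaves coefficients (0.0023, 0.5) as a stand-in, since only Hargreaves is
implemented -- a deliberate scope decision, as both permutation parents use
Hargreaves.

Cultivars differ **only** in harvest-index bounds and temperature ranges
(radiation-use efficiency is a crop constant): two high-yielding types
(HI_max 0.55/0.53), one adapted cool type, and a low-yielding
drought-sensitive type (HI_max 0.40, HI_min 0.10). These values are
placeholders on the documented scale -- the authoritative per-cultivar values
live in supplementary material not reproduced here -- and are exposed as
configuration, not hard-coded truth.

## The synthetic world

`generate_world()` builds the study region: 360-day years (12 x 30 days),
cells with daily weather (seasonal sinusoid with latitude-dependent amplitude
plus AR(1) noise; gamma-distributed wet-day precipitation scaled to the
cell's mean annual precipitation), a 10-layer soil texture profile with
organic N declining with depth, rainfed/irrigated harvested areas, a
harmonized growing season, and countries with a development index.

Stated-world choices (fixed once, before the acceptance suite was frozen):

* Latitudes span -45 to 67 degrees; the climate is parameterized through the
  *warmest-month mean* (28 C at the equator, -0.26 C per degree of latitude,
  floored at 13 C so PHU stays positive for every cultivar). Climate regions
  are assigned by simple thresholds (tropical: coldest month >= 18 C and
  MAP >= 800 mm; arid: MAP < 400 mm; cold: warmest month < 15 C; else
  temperate), with boundary values following the stated comparison operators.
  Four archetype cells are pinned so every region occurs even in tiny worlds.
* Country development indices are stratified-jittered over (0,1), and the
  N application rate is `300 * dev^3` kg/ha plus noise: fertilizer
  intensification is convex in development, so low-yielding-cultivar
  countries (development < 0.65 under the "very high development" rule,
  about the top third as in reality) are also low-input. This co-location is
  a property of real agricultural systems that the driver analyses depend
  on; without it the synthetic world would place high-input cells in
  low-cultivar countries that do not exist in reality.
* Reported yields are the aggregated truth times a technology trend
  (1.5 %/yr by default) times multiplicative noise (sd 0.08, truncated at
  -0.9 to keep yields positive); a configurable fraction of countries is
  flagged as agency-estimated and a configurable subset receives harvested
  areas fluctuating by more than 100 %, to exercise the benchmarking filter.

What the generator does **not** emulate: real geography and spatial
autocorrelation between neighboring cells, multi-season cropping, climate
trends, input-data error structure, or political yield reporting artifacts
beyond the simple flag/fluctuation hooks. A green test therefore establishes
that the *analysis machinery* behaves as specified on data with the assumed
statistical structure -- not that any real-world ensemble number is
reproduced. The headline numbers of the motivating study derive from actual
multi-model archives and are out of reach by design.

## Analysis stack

* **Aggregation**: national and global yields are harvested-area-weighted
  means over cells and both water regimes, with static areas; masked
  cell-years are excluded with weights renormalized. The first simulation
  year is always excluded (wrapping seasons have no complete first season).
* **Agreement metrics**: the coefficient of variation (sample SD over mean,
  in percent) across configurations of long-term mean yields per cell
  (`cv_av`); the CV of mean-normalized series (`cv_t`, analytically equal to
  the CV and kept for protocol fidelity); the mean error; and pairwise
  Pearson correlations of yield time series per cell, summarized by the
  median over pairs (zero-variance pairs excluded). Significance uses the
  two-sided critical r, `t*/sqrt(t*^2 + n - 2)`; at n = 30 and alpha = 0.1
  this is 0.306, the conventional "r > 0.31". Two-sided is adopted precisely
  because it reproduces that printed threshold.
* **Benchmarking**: reported series are detrended by subtracting the 5-year
  centered moving mean (shrunk at the edges) and recombining with the mean
  over a reference window (central 7 years by default). Additive
  recombination is the default; the multiplicative reading is implemented as
  an option since the protocol wording admits both. Simulated series are not
  detrended -- the simulator has no technology trend. Countries are filtered
  by the estimation flag and by harvested-area fluctuation > 100 %. The best
  configuration per country is the one with the highest correlation, ties
  broken by lower absolute mean error and then label order (a deterministic
  rule the protocol leaves unstated).
* **Permutation**: all 64 combinations of the six domains spliced from the
  two parents, run under the fully harmonized rainfed protocol; per-domain
  attribution collects the 32 paired differences obtained by toggling one
  domain with the other five held fixed. Splicing is exact, so domains with
  identical parent blocks attribute exactly zero, bit for bit.
* **Drivers**: per-cell tables of `cv_av`, median r, N rate, climate region
  and the ensemble cultivar-agreement class (`all_high` if every member
  plants a high-yielding cultivar; `dominant_low` if at least n-1 members
  plant the drought-sensitive type -- the "at least four of five" rule
  generalized to arbitrary ensemble sizes; else `mixed`), with OLS of the
  metric on N rate capped at 200 kg/ha, the conventional sufficiency level.

## Numerical choices and edge cases

* The two-anchor S-curve family is `f(x) = x / (x + exp(b1 - b2 x))` with
  the coefficients solved in closed form from the anchors; anchor y values
  follow the percent convention of the parameter tables.
* Solar geometry for Hargreaves uses the standard 365-day closed form even
  though the simulation calendar has 360-day years; the small seasonal
  mismatch is irrelevant for a synthetic world and keeps the implementation
  verifiable against textbook values to 1e-9.
* The daily loop exists twice: a pure-R reference composition of the
  exported step functions, and a transcribed C++ engine used for ensemble
  runs (the 64 x cells x years x seeds workloads are infeasible in R).
  Tests assert agreement to 1e-9; observed agreement is at machine noise.
* Degenerate inputs: zero-variance series make a correlation pair missing
  (excluded from medians); a zero mean makes a CV missing; countries with
  zero harvested area are dropped with a warning; strata with fewer than
  three cells yield missing regression results, never extrapolations.
* Determinism: every generator is a pure function of its arguments and a
  seed; sub-seeds derive from the top-level seed by a domain-separated
  integer hash (`derive_seed`), so modules are independently reproducible
  and all derived seeds stay below 2^31.

## Known limitations

The temperature ramp overstates stress away from the optimum; cold-margin
cells are therefore chronically temperature-limited, and their ensemble
disagreement is dominated by cultivar temperature parameters rather than
nutrient dynamics. Phosphorus cycling is a single labile pool. The
off-season uses the harvest year's weather for wrapped days (stationary
climate approximation). Erosion is a single annual topsoil-loss fraction,
and the oxygen and denitrification formulations are acknowledged scalar
stand-ins. NetCDF interfaces were narrowed to CSV/JSON because the target
environment provides no NetCDF bindings; the I/O contracts (lossless round
trip, unit checks, named-dimension errors) are unchanged.
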