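---
title: "Modelling the beginning of the growing season: four onset models, their calibration and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the beginning of the growing season}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenospring)
library(dplyr)
```

## The problem

The beginning of the growing season (BGS) — the spring day on which
vegetation activity starts — controls the seasonal energy balance and the
net CO~2~ flux of terrestrial ecosystems, and is one of the most
climate-sensitive quantities a dynamic vegetation model must predict.
Operationally, BGS is expressed as a day of year (DOY, 1-based) and
predicted per *pixel-year* from daily mean air temperature and, for
grasses, daily precipitation. `phenospring` implements the four
temperature-driven onset models commonly embedded in dynamic vegetation
models, calibrates them per biome by error-sum-of-squares minimisation over
a random half split of pixels, and evaluates them with the standard
land-surface-phenology metrics. A synthetic climate and onset generator
stands in for the gridded reanalysis and satellite phenology products such
a study would use at hemispheric scale, so the whole pipeline is testable
on a desk.

## The four models

All models scan days of the target year in order and trigger on the first
day their criterion is met (thresholds are inclusive, ties go to the
earliest day). Each pixel-year record carries the preceding
November–December (61 days) so chilling sums never cross records.

**GDD (growing degree-days).** From a start day $t_0$ (January 1 by
default), accumulate $\max(T_d - T_{th}, 0)$; onset is the first day the
sum reaches a critical value $GDD_c$. One phase, pure forcing.

**NGD (number of growing days).** Count days with $T_d > T_{th}$; onset
when the count reaches an integer $NGD_c$.

**BBGC woody.** The Biome-BGC rule for deciduous woody plants. "Soil
temperature" is the 11-day *trailing* running mean of air temperature
(a causal proxy — onset prediction must not look at future temperatures;
the first ten days of a series average what is available). From January 1
the excess of soil temperature above $T_{th}$ is accumulated on days the
proxy exceeds the base; the critical value is
$\exp(a + b\,\bar T)$ with $\bar T$ the pixel-year's mean annual
temperature, so local thermal adaptation is built in. The crossing
additionally requires day length above 39 300 s (photoperiod gate,
evaluated on the crossing day itself), and the reported onset is 15 days
*before* the crossing day, floored at DOY 1. Day length comes from standard
solar geometry: declination
$\delta = -23.44^\circ \cos(2\pi(d+10)/365)$, sunrise hour angle
$\cos\omega = -\tan\phi\tan\delta$, day length $2\omega/15$ hours, clamped
at polar day/night.

**BBGC grass.** Grasses additionally need water: onset requires both the
accumulated soil-temperature excess to reach
$c\,\max(\bar T, 0) + d$ and accumulated precipitation (from January 1)
to reach a fraction $k$ of the annual precipitation. Both sums share the
January 1 origin; the same 15-day offset applies. A rainless pixel-year is
treated as never meeting the water criterion when $k > 0$, rather than
meeting it vacuously.

**NCD-GDD (two-phase chilling–forcing).** Chilling days are days since
November 1 with $T_d < T_{th}^{chill}$; forcing is the degree-day sum
above $T_{th}^{forc}$ since January 1. Onset is the first day $t$ with
$$GDD(t) \ge g + h\,e^{w\,NCD(t)}, \qquad w \le 0,$$
so accumulated chilling lowers the forcing requirement. With no chilling
ever ($T_{th}^{chill} = -\infty$) the model reduces exactly to a GDD model
with critical sum $g + h$ — a property the test suite checks.

The displayed functional forms for the BBGC critical sums follow the
original Biome-BGC onset rule ($\exp(4.795 + 0.129\,\bar T)$ in its
North-American calibration), whose scale matches the reference forest
coefficients bundled with this package; the grass soil-temperature
threshold is implemented as the additive form $c\,\max(\bar T,0)+d$, with
the warm/cool distinction absorbed into $d$. Minus signs in the bundled
reference parameter table are ordinary negatives.

### Reference parameters and biome classes

`default_biome_params()` ships calibrated values for 14 Northern-Hemisphere
biome classes. Four IGBP types spanning wide latitude ranges (mixed forest,
closed shrub, open shrub, woody savanna) are split into cool/warm classes
from annual climate statistics ($T_c$ = annual minimum of daily mean
temperature, $\Delta T$ = annual range): mixed forest, closed shrub and
woody savanna are *cool* iff $T_c < 0$ °C; open shrub is *cool* iff
$\Delta T > 20$ °C or $T_c < 5$ °C. Boundary values resolve to *warm*
because the cool criteria are printed as strict inequalities. When several
years are supplied, each statistic is averaged across years before
thresholding (a climatology, the natural choice when the classification
window is not prescribed). Grassland, savanna and the woody savanna
classes follow the grass scheme; forests, shrubs and permanent wetland the
woody scheme — read directly from which coefficient columns are populated
in the reference table.

## The synthetic generator

The generator emulates the two real data sources at the level of their
statistical structure, not their formats:

* **Daily temperature** — a site-specific sinusoid
  $\mu - A\cos(2\pi(d - d_{peak} + 182.5)/365)$ plus iid Gaussian noise.
  Defaults: amplitude 12 °C and daily noise sd 1 °C, typical mid-latitude
  continental values; peak DOY 200 (mid-July).
* **Daily precipitation** — gamma-distributed daily amounts (shape 0.8,
  right-skewed like daily rain) whose means follow a raised-cosine
  seasonal weight normalised so the annual sum is `annual_precip` in
  expectation.
* **Onset observations** — a chosen model's prediction plus
  integer-rounded Gaussian error clamped to [1, 365], because satellite
  phenology is reported in whole days. The default `obs_noise_sd = 3` days
  reflects validation studies that found day-scale to two-week differences
  between satellite onset and ground observation; the value is a free
  choice since no error model is prescribed, and every recovery experiment
  sets it to 0 explicitly.

A fixed 365-day no-leap calendar is used everywhere (synthetic data never
emits February 29), which removes leap-year branching from every
accumulation loop; on disk, dates are real ISO dates with February 29
skipped. The year blocks of the temperature and precipitation streams are
seeded per `(site, calendar year)`, so the November–December tail of one
pixel-year record is bit-identical to the prefix of the next, and all three
generators are bitwise reproducible given their seeds.

What the generator does *not* emulate: spatial autocorrelation between
pixels, weather persistence (daily noise is white), snow, and the
systematic (non-Gaussian) retrieval errors of satellite phenology. Passing
tests therefore demonstrate the correctness and identifiability of the
*methods*, not the field accuracy any model would achieve on real
archives.

## Calibration

Calibration minimises the error sum of squares (days²) between predicted
and observed onset over training pixel-years, pooling all pixels and years
of a biome class. Records with a missing *observation* are skipped;
records where the *model* fails to predict onset are charged
`penalty_days`² each (default 60 days — roughly two months, large enough
that "never predict" is never optimal, small enough not to dominate);
otherwise an optimiser could win by never predicting onset. The
half split is by pixel — all years of a pixel stay together — with
`ceiling(n/2)` pixels in the training half, and is performed per biome.

Predicted onset is a *piecewise-constant* function of every parameter: an
infinitesimal change in a threshold moves no onset until a day boundary is
crossed. Derivative-based nonlinear regression is therefore ill-posed
here, and the package instead uses a deterministic scheme:

1. **Coarse grid scan** over declared bounds (defaults bracket every
   reference value with margin: base temperatures −10..15 °C, $GDD_c$
   0..1500, $NGD_c$ 1..120, $g$ −500..200, $h$ 0..1500, $w$ −0.5..0).
   Ties at the minimal SSE resolve lexicographically — smallest critical
   sum / day count first, then smallest base temperature — so degenerate
   problems (e.g. a single pixel-year) have a well-defined answer.
2. **Structure-aware starts** for the two families whose critical value is
   a parametric function of site climate (woody $\exp(a+b\bar T)$,
   chilling $g + h e^{wN}$). Their zero-SSE basins are extremely narrow —
   a 1 % error in the critical sum already shifts onsets by days — so a
   coarse grid cell rarely lands inside. Regressing the accumulated
   forcing implied by each observed onset on its covariate (log-linear on
   $\bar T$; linear on $e^{wN}$ per gridded $w$, excluding day-1 onsets,
   which only bound the criterion) places a start inside or next to the
   basin. This mirrors how the woody relation was originally derived —
   a log-linear regression of accumulated soil-temperature sums on mean
   annual temperature. Starts compete with the grid winner on the same
   objective.
3. **Coordinate pattern search with step halving** from the best start:
   each sweep probes ± one step per parameter, accepts strict
   improvements, and halves all steps after a sweep with no improvement;
   integer parameters ($NGD_c$) descend by unit neighbourhood. Iteration
   stops when continuous steps fall below 10⁻⁴ of each parameter range.
   The best SSE is non-increasing by construction (asserted in tests), and
   the whole procedure is deterministic given its inputs.

A simplex method was considered for the refinement stage and rejected:
simplices collapse on the plateaus of a step function. Pattern search
with step halving is the standard derivative-free alternative for
piecewise-constant objectives.

### Recovery experiments

`recovery_experiment()` packages the identifiability checks used by
`scripts/acceptance.R` and the acceptance tests. Designs, chosen once per
family:

| family | pixels × years | climate design | free parameters |
|---|---|---|---|
| GDD | 200 × 10 | means −2..10 °C, amplitude 12, noise 1 | $T_{th}$, $GDD_c$ |
| NGD | 200 × 10 | as GDD | $T_{th}$, $NGD_c$ (integer) |
| BBGC woody | 300 × 10 | means 0..18 °C, amplitude 12, noise 0.5, lat 45 | $T_{th}$, $a$, $b$ |
| NCD-GDD | 300 × 10 | means 0..16 °C, amplitude 8 → chilling spans none to deep | $g$, $h$, $w$ (bases at truth) |
| BBGC grass | 300 × 10 | means 8..16 °C, wet-season centre 60..300, annual precip 300..700, concentration 4 | $c$, $d$, $k$ ($T_{th}$ at truth) |

The gradients are what make each parameter identifiable: the woody $b$
needs sites spanning mean annual temperature; the chilling amplitude $h$
needs sites from no-chill (critical forcing $g+h$) to deep-chill; the
grass $k$ needs warm springs with late, variable wet seasons so the
precipitation criterion binds for a large share of pixel-years. Gradient
fields beyond the first are deterministically permuted across sites so
they are not collinear. Observations are noise-free, so the truth attains
SSE 0 and recovery is a pure test of the optimiser and of
identifiability; GDD/NGD recover exactly, and the woody/chilling/grass
families recover their headline coefficients to within a few percent.

## Evaluation metrics

For paired (observed, predicted) pixel-years, after dropping pairs with a
missing side: RMSE; mean absolute error (denoted $R_A$ in the
land-surface-phenology literature); $R^2$, defined as the *squared Pearson
correlation* between predicted and observed (scatter-plot convention),
with the stricter $1 - SSE/SST$ reported separately as `r2_sse_sst`;
cumulative frequencies $100\cdot P(|\hat y - y| \le \tau)$ over a 1–30 day
threshold grid, computed over pixel-years; and the interannual Pearson $r$
between annual biome-mean series (unweighted pixel means within biome and
year, at least 3 years). Metrics are computed per biome over pooled
pixel-years. Identities asserted in tests: RMSE ≥ $R_A$ with equality iff
all absolute errors are equal; cumulative frequencies are non-decreasing
and reach 100 % at the largest absolute error; under iid Gaussian error of
sd $\sigma$, RMSE estimates $\sigma$ and $R_A$ estimates
$\sigma\sqrt{2/\pi}$.

## Numerical and design choices

* **DOY is 1-based and inclusive**; sentinel tests pin onsets at DOY 1 and
  DOY 365 through prediction and CSV round trips.
* **Thresholds are inclusive (≥)** in every criterion; "exceeds" is read
  as ≥ for consistency with the grass rule's "larger than or equal".
* **Accumulation origins**: GDD and NGD start January 1 by default (the
  conventional start; configurable via `t0`); the NCD-GDD forcing origin
  is January 1 ("midwinter") and chilling counts from November 1; the
  grass precipitation sum shares the January 1 thermal origin.
* **$\bar T$ and annual precipitation** are computed per pixel-year from
  the target calendar year of the driving data — no climatology window is
  imposed.
* **The day-length gate** is ANDed with the thermal condition day by day;
  the 15-day-earlier reported onset is not re-checked against the gate.
* **Missing onset** propagates: generators emit it, pairing drops it,
  calibration charges it, metrics never count it.
* **Problem sizes** in the shipped tests and acceptance script: recovery
  experiments at 200–300 pixels × 10 years (≈ 2–3 min each suite);
  property loops at 300 randomised series for oracle equivalence, 400
  generated years for the precipitation expectation, 6 seeded replicates
  for noisy recovery — sizes chosen so the full suite runs in minutes
  while keeping every check statistically meaningful.

## Limitations

* Only spring onset is modelled — no senescence or end of season, and the
  evergreen-broadleaf, cropland and mosaic classes are excluded by design.
* The soil-temperature proxy is an 11-day trailing mean of air
  temperature, not a heat-diffusion model.
* NetCDF input is not implemented; CSV is the canonical interchange.
* The optimiser guarantees monotone improvement and exact recovery in the
  tested designs, but like every derivative-free method it cannot certify
  a global optimum on arbitrary data.
* Real-archive headline numbers (hemispheric $R^2$, RMSE maps) require
  the satellite and reanalysis archives themselves and are out of scope;
  the package's claims are confined to what its tests and acceptance
  script compute.

## A worked run

```{r demo, eval = FALSE}
report <- run_pipeline(demo_run_config(seed = 1))
report$metrics |>
  select(biome, model, r2, rmse, r_a, n)
```

See the README for the printed output of this exact run and
`scripts/acceptance.R` for the recovery experiments.
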