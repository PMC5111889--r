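---
title: "Methods: a first-order self-seeding assessment for spawning Pocillopora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a first-order self-seeding assessment for spawning Pocillopora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefseed)
```

## The question and the model

After a catastrophic disturbance, does a coral population retain the capacity
to reseed itself? `reefseed` answers this with a deliberate first-order
approximation: measured densities plus stated assumptions, chained into an
order-of-magnitude comparison of larvae produced versus larvae required.
The calculation cannot establish that locally produced larvae recruited
locally — seawater moves freely between habitats and islands — but it can
reject or fail to reject sufficiency of local production, which is the
tractable half of the self-seeding question.

The chain, per habitat and year, is

$$
Z \;=\; \underbrace{\frac{D}{a}\,A}_{\text{colonies } N}\;
  p_{\mathrm{mat}}\;\underbrace{c\,\bar d^{\,\beta}}_{\text{tissue area}}\;
  f\;\varphi ,
$$

where \(D\) is the mean colony density per quadrat area \(a\), \(A\) the
habitat's hard-bottom area, \(p_{\mathrm{mat}}\) the mature fraction,
\(\bar d\) the mean diameter of mature colonies, \(c\,d^{\beta}\) the
diameter-to-tissue-area allometry, \(f\) the pooled fecundity (eggs cm⁻²
y⁻¹), and \(\varphi\) the pooled fertilization success. Zygotes \(Z\) stand
in for larvae because nothing is known about development rates. On the other
side of the ledger, observed recruits \(R\) (from settlement tiles, scaled
the same way) require \(R/(1-L)\) larvae under an assumed loss fraction
\(L\).

## Parameters, units, defaults

All constants live in the configuration (`moorea_config()`, or YAML via
`read_pipeline_config()`), never inside the operations, because each is an
assumption a user should be able to replace:

| parameter | default | unit | basis |
|---|---|---|---|
| back-reef hard bottom | 4.58 | km² | planimetric measurement of the ~16 km north shore |
| outer-reef hard bottom | 3.15 | km² | idem, to the 17 m isobath |
| tile scoring area | 225 | cm² | lower tile surface, where >90% of recruits settle |
| quadrat area | 0.25 | m² | 0.5 × 0.5 m frames |
| points per image | 200 | – | random-point scoring |
| grid cells | 25 | – | dominance scoring, 4% resolution |
| maturity threshold | 14 | cm | size at maturity of the congeneric Hawaiian spawner |
| allometry \(c,\beta\) | 2.493, 2.312 | cm², – | wax-dipping calibration, r² = 0.986 |
| polyp density | 66 | cm⁻² | literature value for the genus |
| fecundity | 6327 ± 1882 | eggs cm⁻² y⁻¹ | pooled from three studies (`pooled_fecundity()`) |
| fertilization | 0.15 ± 0.21 | fraction | pooled from two spawning-coral studies |
| MC draws | 20000 | – | enough for <1% relative MC standard error on the mean |
| larval loss | 0.999 | fraction | scenario assumption, swept over {0.9, 0.99, 0.999} |

Internally every area is converted to cm² at ingest (1 km² = 10¹⁰ cm²).
A single unit system makes the scaling step a bare proportionality and is
checked by a dimensional-consistency test (m² pathway agrees to 10⁻⁹
relative). Values are carried at full precision; rounding to three
significant figures happens only when report tables are rendered, because
the published chains only reconcile when intermediates are unrounded.

## Aggregation choices

Tile counts are aggregated in a fixed order: mean per site × depth × period,
periods summed to an annual density (the two deployments cover the year),
then mean across sites, then across depths. The same path serves quadrat
densities with a degenerate "annual" period. Two weightings are offered:

* `simple` (default) — mean of site means; every site counts equally.
* `pooled` — total count / total sampling units; every unit counts equally.

They coincide under balanced effort. The default is `simple` because the
published habitat means are described as averages among sites; `pooled` is
retained because at least one published site pair (juvenile densities of
0.08 and 0.30 averaging to a printed 0.26 rather than 0.19) is only
explicable by unequal per-site effort. A habitat-year observed in only one
of the two field periods is flagged `partial` rather than silently summed.

The maturity threshold is applied inclusively (d ≥ 14 cm). The population
egg output uses the mean mature diameter as a representative colony — the
published approach — with `method = "integrate"` available to average the
allometry over a full size census instead; the two differ because the
allometry is convex, and the representative form is the default purely for
comparability.

January surveys that represent the preceding season (the 2015 back-reef
census standing for the 2014 epoch) are relabelled to the epoch year before
reporting; `moorea_observations()` carries both the survey year and the
epoch.

## Monte Carlo choices

Fecundity and fertilization are drawn independently from
\(\mathcal N(6327, 1882^2)\) and \(\mathcal N(0.15, 0.21^2)\). Because the
chain is linear in \(f\varphi\) and the draws are independent, the draw mean
converges to the deterministic product — which is why negative draws are
**kept** by default: truncating at zero (available as
`truncate_negative = TRUE`, and logged in the config stamp) raises the mean
and breaks the correspondence with the deterministic chain. A
fertilization input with CV = 1.4 necessarily yields draw distributions with
CV > 1; the published MC spreads (CV ≈ 0.25) cannot be reconstructed from
the published input SDs, so this package reports SD, skewness, and kurtosis
as diagnostics of *its* simulation and asserts only the mean against the
published value.

Moments use 1/n central-moment normalisation; kurtosis is reported raw
(normal = 3), matching the convention of the classical moment diagnostics.
The KS normality check fits mean and SD from the sample and carries an
explicit "parameters estimated, p approximate" note rather than a Lilliefors
correction, since only a plain Kolmogorov–Smirnov test is specified for this
analysis. All randomness flows through seeds recorded in the outputs; a
rerun with the same configuration is bit-identical.

## The synthetic-survey generator

`simulation_scenario()` fixes ground truth and `simulate_survey()` draws:
Poisson tile and quadrat counts (counts of rare sessile individuals in small
fixed areas; a negative-binomial overdispersion hook exists but is off by
default), multinomial image scores from true cover fractions, lognormal
colony diameters (so the mature fraction has the closed form
\(1-\Phi((\ln t-\mu)/\sigma)\)), and power-law allometry pairs with
multiplicative lognormal noise. Default truths mirror the published Moorea
magnitudes (annual recruit densities 3.29/0.38 per tile in 2010, 0.88/0.47
in 2014; quadrat densities 0.02–9.08 per 0.25 m²; ~10% mature back-reef
colonies in 2014).

What the generator does **not** emulate — and hence what passing recovery
tests do not show about real data: spatial autocorrelation among quadrats,
depth gradients within a habitat, tile-versus-natural-substratum settlement
bias, taxonomic misassignment of recruits, and temporal autocorrelation
between years. Recovery tests demonstrate that the estimators are correct
for their sampling models, not that the sampling models are complete.

## Numerical and degenerate-input conventions

* SEs use the sample SD (n−1); a single-image group reports SE 0 and is
  identifiable by `n_images = 1`. A single fecundity study yields `sd = NA`
  with a warning, never 0.
* Categories unscored on an image are 0% cover, not missing — both scoring
  schemes are exhaustive.
* Zero mature colonies (or zero abundance) short-circuit the egg chain to
  exactly 0; a positive mature fraction with an undefined mean diameter is
  an error, not a guess.
* Fold changes and sufficiency ratios refuse zero baselines; survival
  fractions above 1 are flagged implausible but never clamped.
* `fit_allometry()` clamps r² into [0, 1] against floating-point overshoot
  on exact data and suppresses the "perfect fit" warning, since exact
  power-law input is a supported case, with recovery to 10⁻⁹ relative.
* Validation reports 1-based row numbers of offending records, and missing
  columns are named.

## Known inconsistencies in the published totals

Three published shore-wide totals are not reproducible from their own
printed densities and areas: the outer-reef 2010 recruit total (4.27 × 10⁸
printed vs ≈4.6 × 10⁸ from 3.29 per 225 cm² over 3.15 km²), the outer-reef
2014 colony total (1.78 × 10⁸ vs ≈1.14 × 10⁸ from 9.08 per 0.25 m²), and a
juvenile "57% less" comparison that contradicts the printed juvenile
increase. Additionally the 2010 per-habitat egg totals are consistent with
the two habitats' mature fractions having been transposed. `reefseed` does
not force agreement: `moorea_observations()$printed_totals` carries the
printed values as data with an explicit note, the scaling operation always
computes from densities, and tests assert only the self-consistent chains.
Where a printed total is used at all (the 2010 whole-shore recruit count),
it enters as an input, clearly labelled.

## Problem sizes used by the test suite

The suite favours small, targeted simulations chosen to keep estimator
standard errors well below the asserted tolerances: recovery tests use
80–200 sampling units per group and 8–25 replicates; moment-estimator checks
use 10⁵ draws; the Monte Carlo checks use the full 20,000 draws of the
production configuration; the end-to-end synthetic recovery uses 200
quadrats, 2,000 measured colonies, and a 3-site design. All are fixed-seed.

## Limitations

Beyond the generator's simplifications listed above: the assessment treats
each habitat's density as representative of all its hard bottom; it uses a
single representative mature colony per habitat-year; fecundity and
fertilization come from other regions and decades; and the loss fraction is
an assumption, which is why the report sweeps it rather than estimating it.
The sufficiency ratio should be read as an order-of-magnitude statement —
its useful content is "production exceeds requirement even at 99.9% loss",
not its second digit.
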