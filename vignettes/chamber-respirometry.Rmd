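---
title: "Reducing closed-chamber incubations to coral metabolic rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing closed-chamber incubations to coral metabolic rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chamberflux)
library(dplyr)
```

## The measurement problem

Sealed transparent chambers placed over individual benthic organisms are
the standard way to measure colony-scale metabolism in situ. A chamber is
closed for a few hours; water samples drawn at the start and end of the
sealed window record how much total alkalinity (TA) and dissolved oxygen
the enclosed water gained or lost. Three processes are read off those
drifts:

* **Calcification** `G` — precipitating one mole of CaCO~3~ removes two
  equivalents of alkalinity, so the control-corrected TA decline, halved,
  counts moles of carbonate fixed (the alkalinity-anomaly method).
* **Net photosynthesis** `P_N` — the light-phase O~2~ gain.
* **Dark respiration** `R` — the dark-phase O~2~ decline, sign-flipped so
  that respiration is reported as a positive rate; gross photosynthesis
  is then `P_G = P_N + R`.

The hourly rate equations are

$$G = \frac{\Delta TA \cdot \rho \cdot 0.5 \cdot V}{I_t \cdot SA \cdot 1000},
\qquad
P_N,\,R = \frac{\Delta O_2 \cdot V}{I_t \cdot SA \cdot 1000},$$

with `ΔTA` in µmol kg^-1^ (start − end), `ΔO2` in µmol L^-1^
(end − start), `ρ` the seawater density in kg L^-1^, `V` the chamber
water volume in L, `I_t` the sealed duration in h and `SA` the colony
surface area in m^2^; rates come out in mmol m^-2^ h^-1^. The density
term appears only in `G` because titration alkalinity is measured per
kilogram of seawater while optode oxygen is measured per litre. That
asymmetry is encoded once, in `calcification_rate()` /
`oxygen_flux_rate()`, never at call sites.

Daily rates are stepwise sums of the measured windows,
$\sum_t P(t)\,\Delta t$ (`integrate_daily()`). When the measured windows
cover less than the declared photoperiod the shortfall is *reported*
(`coverage_h`, `coverage_frac`), never extrapolated unless the caller
sets `extrapolate = TRUE`; a start/end design carries no information
about the unmeasured hours, so scaling by the mean measured rate is an
assumption the user must opt into.

## Blank correction and its consequences

Coral-free control chambers filled with the same water track microbial
activity of the enclosed water column. Every treatment drift is corrected
by subtracting the *mean* same-phase, same-cycle control drift, in
concentration units, before any volume or area scaling — controls carry
no colony and in general their own volume. A missing control is an error,
never a silent zero-correction.

One statistical consequence deserves emphasis because it is easy to miss:
all colonies corrected against the same controls share that control
mean's noise. In a multi-site campaign where each site-day deployment has
its own controls, colony rates are therefore correlated *within a
deployment*. Treating colony-days as independent — or using a
calendar-day random intercept when two sites share calendar days —
understates the uncertainty of species-site means (we measured ~87%
coverage of nominal 95% intervals in simulation). `fit_metabolic_lme()`
therefore exposes the random grouping (`random_group`): for multi-site
blank-corrected data, the site×day *deployment* is the exchangeable unit.
`deployment_mean_intervals()` complements the model-based intervals with
design-based t-intervals on per-deployment cell means, which are exactly
calibrated for balanced designs regardless of how the variance decomposes
between shared and individual components.

## Physical properties

The rate equations need `ρ`, and the oxygen-safety classifier needs the
air-equilibrium O~2~ concentration. Both are computed from documented
one-atmosphere fits, evaluated at each interval's mean salinity and
temperature:

* density: the one-atmosphere International Equation of State of
  Seawater (Millero & Poisson 1981), verified in the test suite against
  its published check values (e.g. S = 35, T = 5 °C →
  1027.67547 kg m^-3^);
* O~2~ solubility: the Garcia & Gordon (1992) combined fit
  (Benson–Krause coefficients), µmol kg^-1^ converted to µmol L^-1^ with
  the same density (check value S = 35, T = 10 °C → 274.610 µmol kg^-1^).

A constant density can be configured instead
(`reduction_config(rho = ...)`) for users who reduced historical data
with a fixed value. Pressure dependence is deliberately omitted: these
chambers sit in a few metres of water. Field salinities are treated as
practical salinity even when logged from a refractometer (±0.5), which
moves density by < 0.05% — far below the volume-driven error budget.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `precision_ta` | 2 | µmol kg^-1^ | titration accuracy/precision of the TA system |
| `precision_o2` | 0.05 | µmol L^-1^ | optode accuracy |
| `k_detect` | 3 | — | a drift counts as detectable only beyond 3× analytic precision (strict inequality; a drift exactly at the limit is not detectable) |
| `supersaturation_pct` | 200 | % of saturation | light-phase safety ceiling; photosynthesis can push tissue O~2~ past 200% saturation, fuelling reactive-oxygen stress |
| `hypoxia_pct` | 30 | % of saturation | optional stricter dark criterion |
| `anoxia_umol_l` | 5 | µmol L^-1^ | dark-phase floor (default criterion) |
| `decision_hour` | 3 | h | the flushing interval: volumes must be safe **and** informative within one sealed cycle |
| `photoperiod_h` | 12 | h | tropical daylight, used for daily-coverage reporting |

Only the 200% supersaturation anchor has a direct literature basis; the
hypoxia and anoxia defaults are package choices, exposed in
`oxygen_state_thresholds()` and stamped into outputs. The dark-phase
criterion defaults to the **anoxia floor** rather than relative hypoxia:
dark volume-ladder trials are scored on reaching anoxic conditions, and a
relative criterion would reject mid-sized volumes that such trials
accept. `dark_criterion = "hypoxia"` selects the stricter rule.

## The volume decision rule

Chamber volume trades signal against safety: a small volume concentrates
the metabolic signal but supersaturates in the light and exhausts in the
dark; a large volume stays safe but dilutes the TA drift below titration
detection. The rule implemented in `accept_volumes()` accepts a volume
when, at the decision hour, replicate consensus shows *no* unsafe oxygen
state (`-`) *and* a unanimous detectable metabolic change (`+`) in both
the light and dark tables. Detectability combines TA **and** O~2~ with
AND. Consensus codes collapse replicate flags: all-false `-`, mixed `±`,
all-true `+`.

Two paths produce a decision matrix. The packaged verbatim encoding
(`read_decision_matrix()`) reproduces a bench volume-ladder consensus
table exactly — that is the reference path. The simulator path
(`simulate_volume_series()` → `build_decision_matrix()`) exercises the
classifier on synthetic ladders; its rate preset
(`acropora_rate_preset()`: G = 1.2, P~N~ = 45, R = 42 mmol m^-2^ h^-1^)
is *illustrative*, chosen so the qualitative trade-off appears on the
250–1500 mL ladder, not a measurement of any real colony. Noise-free,
that preset reproduces the 1000–1250 mL optimum window; with analytic
noise the large-volume TA drifts sit near the 3σ detection limit and
their codes become stochastic — which is precisely why the protocol fixes
volumes from a replicated bench trial rather than one deployment.

## The forward simulator

`simulate_incubation()` inverts the rate equations: end concentrations
are start values plus `rate · I_t · SA · 1000 / V` (divided by `ρ·0.5`
for TA), plus an optional shared background drift (what controls exist to
remove), plus Gaussian analytic noise on *every* measured value — so a
drift carries √2× the single-sample sd. Rates are constant within a
window, matching what a start/end design can resolve. Chambers are
flushed between cycles. Simulated O~2~ is floored at zero and flagged
(`anoxia_events`): an exhausted chamber is a finding, and a floored
trajectory is deliberately *not* invertible, so exactness guarantees
apply to the physically valid regime.

`simulate_case_study()` layers the generative mixed model on top: cell
mean + shared day effect (`day_sd`) + colony-day residual
(`residual_sd`), then forward-simulates every colony-day as one 3 h light
and one 3 h dark cycle with three controls per site-day, volumes of
1.05 L (100 mL sample aliquot + 950 mL residual) and 0.0012 m^2^
colonies. Defaults for the cell means are the packaged two-site,
three-species field table (`reef_rate_means()`).

What the simulator does **not** emulate: within-window rate dynamics
(photoinhibition, light fluctuation), boundary-layer flow effects,
carbonate-buffering feedback on calcification, temperature-driven rate
changes (a linear in-chamber temperature drift is available as
`temp_drift_per_h`, with 0.175 °C h^-1^ reproducing the worst-case bench
warming, but rates do not respond to it), or non-Gaussian instrument
error. Passing tests therefore certify the *reduction arithmetic and
statistics*, not the field validity of any particular deployment.

## Numerical and design choices

* **Signs.** `ΔTA = start − end` (precipitation → positive G);
  `ΔO2 = end − start` (light production → positive P~N~); the dark ×(−1)
  applies after control correction. Anomalies (O~2~ rising in the dark,
  TA rising) are flagged in the output, never dropped.
* **Volume resolution.** Per-(chamber, cycle) accounting first, then a
  per-chamber default, then an error — volumes are measured per
  deployment, and controls need their own.
* **Time base.** Fractional hours since the first sample; clock times
  and ISO-8601 datetimes are converted once at ingest
  (`read_sample_log()`).
* **Degenerate comparisons.** A paired comparison with constant
  difference is reported exactly (t = 0, p = 1 when the difference is
  zero) instead of failing inside `t.test`.
* **Model selection.** REML likelihoods are not comparable across fixed
  structures, so `select_model()` refits both models under ML before the
  likelihood-ratio test; normality and residual diagnostics are emitted
  as advisory tables, not gates. Reported species-contrast tables are
  produced by refitting with rotated reference levels (`reference =`),
  which changes labels but not fitted values.
* **Problem sizes.** The test suite runs the round-trip oracle on 100
  random chamber configurations, parameter recovery on 200 replicates of
  the full 2 × 3 × 5 × 5 design, the type-I error check on 2000 null
  draws, and the LR-null calibration on 150 simulations — sizes chosen so
  the whole suite completes in about two minutes while keeping Monte
  Carlo error well inside the asserted margins.

## Known limitations

* TA values are consumed as inputs; Gran-titration curve processing and
  full carbonate-system speciation (pCO~2~, Ω) are out of scope.
* Surface area is an input; no geometry is computed here.
* The contrast tables of a historical analysis are reproducible only if
  its exact contrast coding is known; this package exposes the reference
  level explicitly rather than guessing.
* Published per-species field means are carried as packaged constants
  for simulation defaults; the raw colony data behind them were never
  deposited, so they serve as generating truth for synthetic campaigns,
  not as validation targets.
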