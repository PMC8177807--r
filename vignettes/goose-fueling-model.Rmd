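---
title: "Time budgets, energy budgets and premigratory fueling: the model behind goosefuel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time budgets, energy budgets and premigratory fueling: the model behind goosefuel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goosefuel)
```

## What the package models

Wintering Arctic-breeding geese must balance their energy budget through a
cold season with short days and poor forage, then deposit large fat stores
("premigratory fueling") before departing for the breeding grounds in May.
`goosefuel` implements the full chain from raw tracking data to inference
about that fueling process:

1. **Behavior from accelerometry.** Each GPS fix carries a 0.5-s burst of
   triaxial acceleration (10 samples at 20 Hz). Four features — overall
   dynamic body acceleration (ODBA), mean pitch, and the mean absolute time
   derivatives of the surge and sway axes — feed a random forest (50 trees,
   40/60 train/test split) that labels each burst inactive, active,
   foraging or flying. Agreement is summarized by a confusion matrix,
   per-class precision, overall accuracy and Cohen's kappa.
2. **Time budgets.** Fixes are thinned to one per 30-minute slot; the
   retained fix's behavior stands for the whole slot. Apparent foraging on
   open water (wave motion mimics grazing) is relabeled inactive. Slots are
   split day/night by an in-package implementation of the NOAA solar
   calculator, and each night's moonlit hours come from a low-precision
   lunar position series (moon above the geometric horizon, 1-minute
   resolution); an injected moonrise/moonset table can replace the
   algorithm.
3. **Energy budgets.** Existence energy is `BMR × b × t` with behavior
   multipliers (inactive 1.5, active 1.9, foraging 1.6) and BMR scaling
   proportionally with body mass (5.536 W at 1825 g; 4.853 W for a 1600-g
   bird). Thermoregulation cost rises below a lower critical temperature of
   10 °C as a function of air temperature, 10-m wind and shortwave
   radiation. Because activity heat substitutes for thermoregulation, the
   total cost of an interval is `max(Et, Ee)`; flight is costed separately
   (its existence energy is zero) from airspeed and a pluggable power
   curve.
4. **Intake.** Potential metabolizable intake rate (PI, kJ/h) is linear in
   cumulative growing degree days (GDD), fitted per habitat by ordinary
   least squares to field observations; metabolized energy is PI times
   foraging-plus-active time on forageable habitat (pastures and natural
   grassland).
5. **Body-mass trajectories (BMTs).** A per-fix recursion: surplus energy
   is stored at efficiency 0.8, deficits are burned at efficiency 1, both
   converted at 29 kJ/g. Existence energy tracks the simulated mass;
   thermoregulation stays at the fixed 1600-g parameterization — the two
   components deliberately use different masses, mirroring the asymmetric
   treatment in the underlying energetics.
6. **Counterfactual scenarios.** *no_night* sets every night slot to
   inactive; *max_foraging* replaces each night after the first January
   moon cycle with the same bird's night from that cycle, matched through
   a 30-day cycle anchored at January 1 (`((doy − 1) mod 30) + 1`). The
   four correspondences this mapping must reproduce (Jan 31/Feb 1,
   Mar 2/3, Apr 1/2 and May 1/2 all map to Jan 1/2, and the next nights to
   Jan 2/3) uniquely determine that arithmetic.
7. **Inference.** Fueling onset is the breakpoint of a continuous
   two-segment ("hinge") regression of mass (or foraging time) on
   day-of-year, chosen by profile maximum likelihood. Scenario timings are
   compared per bird with Wilcoxon signed-rank tests, and a sensitivity
   analysis re-simulates both scenarios under normal perturbations of the
   PI intercept and of the reference BMR (mean 5.54 W, SD 0.42).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `bmr_ref_w`, `w_ref_g` | 5.536, 1825 | W, g | reference point of proportional BMR scaling |
| `multipliers` | 1.5 / 1.9 / 1.6 | × BMR | inactive / active / foraging existence costs |
| `lct_c` | 10 | °C | lower critical temperature for this species |
| `bird_height_m` | 0.15 | m | wind reference height and convective length scale |
| `plumage_resistance_s_m` | 150 | s/m | coat resistance; species-specific, configurable |
| `energy_density_kj_g` | 29 | kJ/g | energy density of deposited tissue |
| `store_eff`, `burn_eff` | 0.8, 1.0 | — | storage vs mobilization efficiency |
| `flight_speed_kmh` | 20 | km/h | minimum ground speed flagging flight |
| `flight_bmr_multiple` | 12.5 | × BMR | default flight power (replaceable curve) |

The thermoregulation default is a documented biophysical parameterization,
not a published coefficient set: heat loss is a series conductance (a
wind-dependent boundary-layer resistance `307·sqrt(d/u)` s/m plus the
plumage resistance, with 10-m wind scaled to bird height by a log profile
over roughness 0.01 m), driven by the gap between the LCT and an operative
temperature that rises 0.015 K per W/m² of shortwave radiation, over a Meeh
surface area `0.1·m_kg^(2/3)`. It reproduces the dependencies that matter —
zero at thermoneutrality, monotone in temperature, wind and radiation,
linear in time — and `energetics_params(thermo_model = ...)` is the plug-in
point for any exact published model.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions: 23 birds, 30-minute
fixes from January 1 to mid-May at a Wadden Sea site (53.87° N, 7.3° E), a
calibration set of 945 bursts (796 inactive / 57 active / 44 foraging / 48
flying), daylight slots foraging with probability 0.66, and a nightly
foraging target `(45 + 3.6 · moonlit hours) · exp(−(doy−1)/60)` minutes —
the moonlight gain is the fitted coefficient scale reported for this
system, and the exponential decay encodes that the longest nocturnal
foraging happens in the first January moon cycle, the premise of the
maximum-foraging substitution. Night foraging fills each night from its
first slot; no extra night-level noise is added by default (no variance
structure is reported for it, and `night_noise_sd` exposes the knob). The
true intake lines default to 85 + 0.06·GDD kJ/h (agricultural) and 75 +
0.06·GDD (natural — deliberately below agricultural, matching consistently
lower food quality in natural habitat). These values were fixed once from
an energy-balance argument: near balance with a slight deficit in
January–February, fueling at roughly 20–30 g/day in April–May, departure
mass around 2.5 kg.

The generator deliberately omits: spatial movement (habitat is a label
stream; GPS positions only jitter around the site), weather-dependent
behavior (cold nights do not lengthen foraging), observation error in
behavior labels at fix level, and between-bird heterogeneity in intake.
Passing tests therefore show that the *pipeline machinery* is correct under
the assumed structure, not that the structure captures everything real
tracking data would show.

## Numerical choices

* All timestamps are UTC; local civil time never enters the computations.
* Day is `sunrise ≤ t < sunset` (NOAA −0.833° convention); night runs
  sunset to next sunrise, with civil twilight counted as night. A night
  belongs to the date of its sunset.
* Daily budgets attribute slots to their UTC calendar date, so classified
  plus missing minutes sum to exactly 1440 per bird-day; night-level
  bookkeeping (moonlight models, scenario substitution) uses the separate
  `nightly_budget()` keyed by the night of the sunset. These two
  attributions cannot coexist in one table because nights cross midnight.
* ODBA uses the within-burst mean as the static component (a 0.5-s burst
  precludes a longer smoothing window) and sums axis deviations; pitch sign
  follows "anterior axis up = positive", so grazing is negative pitch —
  only separability matters, not the convention.
* The published feature-selection step is not re-run; the four final
  features are fixed.
* GDD accumulates `max(0, T_mean)` (base 0 °C) from January 1, both
  configurable; PI extrapolations are floored at 0 kJ/h.
* Replacement nights in the maximum-foraging scenario copy behavior *and*
  habitat of the source night (intake is habitat-specific, and a night
  budget includes where the bird fed), but are priced at the *target*
  night's GDD: PI reflects current food quality, not January's.
* The breakpoint profile uses a Gaussian likelihood with constant variance
  (equivalent to least squares) and enforces continuity at the break; the
  optimizer is seeded from a 101-point grid plus the conventional starting
  value 4 (in day units) and refines with `optimize()`. Pure-linear data is
  flagged degenerate rather than returning an arbitrary interior break.
* The sensitivity omission rule is implemented exactly as stated: a run is
  dropped (with reason) when the PI intercept draw is below −0.5 SD and a
  baseline trajectory has its maximum on January 1.
* Mass conservation is exact by construction: final minus starting mass
  equals `(0.8·Σ surpluses − Σ deficits)/29`, and the test suite checks
  this to 1e-9 g.

## Problem sizes

The shipped tests run the full season at 2–4 birds for trajectory and
scenario properties, 23 birds for generator-level fractions, 100 seeded
half-season trajectories for the conservation identity, 100 replicates for
breakpoint recovery, and 1000 synthetic nights for the moonlit-hours
interval algebra. `run_pipeline()` at the full 23-bird default completes in
well under ten minutes on one CPU; the sensitivity stage is the only
expensive part and its run counts are configurable.

## Known limitations

* The lunar series is low-precision (a few tenths of a degree); moonlit
  hours are reliable to a few minutes, not seconds, which is far inside
  the variability that matters here.
* Flight energetics default to a flat 12.5 × BMR power; a U-shaped
  aerodynamic curve should be plugged in for any analysis where flight
  cost matters quantitatively.
* The mixed-effects analyses around foraging-duration drivers (AICc model
  selection, variance and autocorrelation structures) are reporting-level
  statistics, not re-implemented machinery; stock routines (`nlme`,
  `wilcox.test`) are the intended tools on the package's budget tables.
* Headline field numbers (minimum masses, decline rates, calendar dates of
  onset and departure) depend on the real 16-bird tracking data and are
  reproduced here only qualitatively: the synthetic defaults give winter
  decline, a late-winter minimum, spring fueling, and the expected
  scenario ordering and direction of timing shifts.
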