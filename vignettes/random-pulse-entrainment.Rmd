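---
title: "Simulating entrainment by randomly timed single daily light pulses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating entrainment by randomly timed single daily light pulses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circapulse)
```

## The problem

Subterranean rodents such as tuco-tucos (*Ctenomys* sp.) spend nearly all
their time in dark burrows and see daylight only during brief, irregularly
timed surface excursions. Field light-logger records show one or a few
short exposure episodes per day, at times that vary from day to day but
concentrate around midday. A laboratory abstraction of this exposure
pattern is a regimen with a single 1-h light pulse per day, delivered at a
time drawn uniformly at random within a fixed daytime window of length
*I* hours. The striking experimental finding this package revolves around
is that such regimens — which carry far less timing information than a
conventional light/dark cycle — still entrain the circadian activity
rhythm to 24 h, up to surprisingly wide windows (about 15 h at 1,000 lux),
and that the entrainment limit shrinks when pulse intensity *L* drops to
100 lux.

`circapulse` provides all the machinery to reproduce this programme in
silico: light-protocol construction, a forced limit-cycle oscillator,
synthetic wheel-running and light-logger data, and the standard rhythm
analyses (chi-square periodogram, entrainment classification, phase
markers, exposure statistics).

## The oscillator model

No canonical equation set exists for the tuco-tuco clock; what is required
of a model is phenomenological: a self-sustained limit cycle with a
free-running period near (but not equal to) 24 h, a *weak* (type-1) phase
response curve (PRC) to a 1-h saturating pulse with maximal shifts of
1–2 h, and finite amplitude relaxation. We use a radially relaxing
(Poincaré-type) amplitude–phase oscillator with photic forcing on one
state variable:

$$
\dot x = \gamma x (1 - r) - \frac{2\pi}{\tau} y
          + K\,\Lambda(L(t))\,\bigl(\max(0, -x) + \epsilon\bigr), \qquad
\dot y = \gamma y (1 - r) + \frac{2\pi}{\tau} x,
$$

with $r = \sqrt{x^2 + y^2}$. Unforced, the system has an attracting limit
cycle of radius 1 and period $\tau$; $\gamma$ sets the amplitude
relaxation rate. Illuminance enters through a saturating map
$\Lambda(L) = \log(1 + L/L_\mathrm{ref}) / \log(1 + L_\mathrm{sat}/L_\mathrm{ref})$,
normalised so a 1,000-lux pulse gives $\Lambda = 1$.

Two features of the forcing term deserve comment, because both were
driven by the phenomenology rather than convenience:

* **State-gated sensitivity.** The factor $\max(0, -x)$ restricts light
  action to the half-cycle where $x < 0$, which we identify with
  subjective night. This produces the canonical nocturnal-rodent PRC —
  delays in early subjective night, advances in late subjective night,
  and a dead zone through subjective day — rather than the sinusoidal PRC
  of a purely additive force. The dead zone is not cosmetic: with a
  sinusoidal PRC every daytime pulse perturbs the phase, and under wide
  dispersion windows the daily phase jitter grows until the trailing-window
  period estimate fails the 24 h ± 10 min criterion in roughly half the
  replicates. With a dead zone, pulses landing in subjective day are
  nearly silent, so at the entrained phase most of the window contributes
  no jitter and the window edges supply the systematic correction.
* **A shallow, not absolute, dead zone.** The small leak $\epsilon$ keeps
  subjective-day sensitivity at a fraction of the nocturnal peak. An
  absolutely dead zone makes capture pathological: an oscillator whose
  pulses initially fall in the dead zone must wait for its own
  free-running drift ($|\tau - 24|$ h per day) to carry the schedule into
  the sensitive half-cycle, which for a 12-h dead zone and
  $|\tau - 24| = 0.25$ h takes longer than a 40-day stage. The leak adds a
  weak continuous (parametric) drive that shortens capture to one or two
  weeks, matching the transient durations seen in the experimental
  actograms.

### Default parameters and their calibration

| parameter | default | units | meaning |
|---|---|---|---|
| `tau` | 23.75 | h | intrinsic free-running period |
| `stiffness` ($\gamma$) | 0.1 | 1/h | amplitude relaxation rate (relaxation time $\approx 1/\gamma$) |
| `coupling` (K) | 0.7 | – | forcing amplitude per unit normalised light |
| `dead_zone_leak` ($\epsilon$) | 0.25 | – | basal daytime sensitivity, fraction of nocturnal peak |
| `lux_ref` | 1000 | lux | reference of the saturating lux map |
| `lux_sat` | 1000 | lux | illuminance mapped to forcing 1 |

The calibration recipe (re-runnable via `scripts/calibrate.R`) is:
fix $\tau$, tune $K$ until the 1-h/1,000-lux PRC has maximal shifts of
1–2 h, check that 15-h windows entrain at least 9 of 10 seeded replicates
at 1,000 lux while 20-h windows do not entrain all replicates, then set
`lux_ref` so that the 100-lux mapping ($\Lambda(100) \approx 0.14$) fails
at the 15-h window. With the defaults the calibration lands at:
maximal PRC shift 1.94 h, mid-subjective-day shift −0.08 h, and (seeded
sweep, 10 replicates × 40 days per window) full entrainment through
I = 14 h, ≥ 9/10 through I = 16 h, and 4–6/10 at I = 20 h.

The choice $\tau = 23.75$ h has two reasons. First, the daily correction
an entraining regimen must deliver is $|24 - \tau|$; at 0.5 h/day
(τ = 23.5) the correction nearly exhausts what a 15-h window can supply
on average, leaving almost no basin of attraction, whereas 0.25 h/day
reproduces the observed 15-h entrainment comfortably. Second, the period
grid of the 5-min periodogram snaps estimates to multiples of 5 min: a
free-running period of, say, 23.8 h snaps to 23 h 50 min, which sits
exactly on the 24 h ± 10 min criterion boundary and would misclassify a
free-run as entrained. 23.75 h is representable exactly on the grid and
lies safely outside the criterion.

## Light protocols

Pulse start times are drawn independently each day, uniformly on a 5-min
grid (matching the recording resolution and the integer draws of the
original scheduling), spanning
$[\mathrm{window\_start},\; \mathrm{window\_start} + I - \mathrm{duration}]$,
so the entire pulse always lies inside the window. A fixed-time schedule
(the LD1:23 cycle) is the degenerate case $I = $ duration. Schedules
render to piecewise-constant illuminance series; constant darkness is the
empty schedule. The dim red background light of the laboratory is treated
as circadian-ineffective darkness (`background_lux = 0` by default, and
forcing is only applied above background). Windows are placed centred on
12:00 by default; schedules that would cross midnight wrap modulo 24 h
with each pulse attributed to the day it starts.

## Synthetic behaviour and light logs

Wheel-running counts are emitted in 5-min bins, gated to subjective night
(a phase window of width `gate_fraction`, default half the cycle, centred
on CT18). Counts are negative binomial with configurable dispersion; the
paper-style analyses do not depend on the count distribution, and exact
tests use the noiseless setting. A square-wave generator
(`synthetic_free_run()`) provides analysis fixtures with an exactly known
period. What the generator deliberately omits: masking (direct behavioural
suppression by light), period aftereffects, ultradian bouts, and
inter-individual τ variation. Passing tests therefore demonstrate the
correctness of the analysis chain and the oscillator phenomenology, not
fidelity to any individual animal.

Field logger records are simulated at 1-min resolution and downsampled to
per-5-min maxima, the dialect real loggers store. Each day has at least
one episode (zero-truncated Poisson count); episode start times follow a
von Mises distribution centred at midday (the field histograms are
unimodal around midday); episode illuminance sits at the upper detection
limit after clipping; placement is rejected until no supra-threshold
(> 1.2 lux) sample can fall outside civil twilight, with placement limits
aligned to the 5-min grid so binning cannot straddle the twilight bounds.
Episode counts and durations are order-of-magnitude choices exposed in the
generator arguments, not asserted facts.

## Rhythm analyses

The chi-square periodogram follows the Sokolove–Bushell convention:
complete cycles only, $Q_P$ referred to the $\chi^2_{P-1}$ critical value
at α = 0.05 per trial period, with no multiplicity correction (the
standard practice for this statistic). The period grid is the 5-min bin
grid from 20 to 28 h; period estimates use the trailing 15 days of a
stage; a rhythm is *entrained* when its significant peak lies within
24 h ± 10 min (boundary inclusive), *free-running* when a significant
peak lies outside, *arrhythmic* when nothing is significant. Note the
per-period α means white noise shows at least one significant period
somewhere in the scanned range far more often than 5% of records — the
5% size holds per trial period, which is what the test suite checks.

Phase markers per cycle (record folded at the reference period): the
activity bout is the longest circular run of bins whose 30-min smoothed
counts exceed half the cycle mean, with onset/offset then refined to the
first/last *raw* bins above the threshold inside that run. The two-stage
rule keeps the smoother's robustness against fragmented bouts without
letting it displace bout edges (a centred moving average alone shifts a
square-wave onset two bins early). The centre of gravity is the circular
weighted mean of all bins in the cycle, using bin-start angles. Phase
dispersion is the circular standard deviation of a marker across cycles
and is reported only for entrained records, mirroring the study
convention. Side bands are significant local maxima of
$Q_P - \mathrm{sig}$ outside an exclusion zone around the main peak.

## Numerical choices

Integration is fixed-step classical RK4 (compiled) with 10 sub-steps per
5-min regimen sample (step 1/120 h ≤ 0.01 h); the forcing is piecewise
constant and its discontinuities coincide with step boundaries, so the
scheme keeps its full order. Step halving changes a 3-day forced
trajectory's final phase by well under $10^{-3}$ h, and the integrator
matches an independent `deSolve` RK4 run to $10^{-8}$ under constant
light. Fixed-step integration was preferred over adaptive schemes for
bit-reproducibility: a configuration and seed regenerate every record and
report identically. Phase is the unwrapped angle about the cycle centroid
(the origin), scaled to 24 circadian hours per cycle; amplitude is the
radius. Degenerate inputs are defined, not special-cased away: a
zero-variance record has $Q_P = 0$ everywhere (arrhythmic), an all-zero
cycle yields `NA` markers, a constant logger record yields zero episodes
with a warning. Periodogram peak ties are broken by the maximal
$Q_P - \mathrm{sig}$ excess among significant periods.

## Problem sizes

Simulated experiments use the study's own design scales: 40-day stages
(the lab treatments ran 29–54 days), 10-day DD lead-ins, analysis on the
trailing 15 days, 10 seeded replicates per condition, and 1-h steps for
the window-length sweep (8–22 h). A full six-stage protocol integrates in
well under a second; the complete replicate sweep takes seconds.

## Worked example

```{r example, eval = FALSE}
p <- oscillator_params()
cfg <- experiment_config(
  stages = list(stage_dd(40), stage_fixed(12, 1000, 40),
                stage_random(8, 1000, 40), stage_random(8, 1000, 40, shift = 6),
                stage_random(15, 1000, 40), stage_random(20, 1000, 40)),
  oscillator = p, seed = 1)
report <- run_experiment(cfg)
report
```

## Known limitations

* A single oscillator: no coupled multi-oscillator dynamics, hence no
  statement about how coupling strength would move the entrainment range.
* No period aftereffects: τ is constant, so release into DD resumes the
  intrinsic period immediately, unlike real animals.
* No masking: light affects behaviour only through the oscillator.
* The phase of the entrained rhythm re-equilibrates with a time constant
  of one-to-two weeks after a protocol change; in a 40-day shifted-window
  stage the trailing-15-day phase therefore still carries a residual of a
  few tenths of an hour, so measured phase displacements after a 6-h
  window delay come out slightly under 6 h.
* Civil twilight is an input table, not an astronomical computation.
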