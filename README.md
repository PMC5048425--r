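# circapulse

Simulation and analysis of circadian entrainment under **irregular**
light/dark schedules: one brief light pulse per day, delivered at a random
time inside a daytime "dispersion window" of length *I* hours.

This regimen abstracts the natural light exposure of subterranean rodents
(tuco-tucos, *Ctenomys* sp.), which see daylight only during brief,
irregularly timed surface excursions. The package lets you build such
light protocols, drive a limit-cycle circadian oscillator with them,
synthesise wheel-running and field light-logger records, and run the
standard chronobiology analyses — so the whole in-silico side of the
research programme (range of entrainment in *I* and in pulse intensity
*L*, phase control by the pulse window, periodogram diagnostics, field
exposure statistics) is reproducible from a seed, with no animal data.

## The model and the analyses

The oscillator is a radially relaxing (Poincaré-type) amplitude–phase
limit cycle with state-gated photic forcing,

$$\dot x = \gamma x (1-r) - \tfrac{2\pi}{\tau} y
          + K\,\Lambda(L(t))\,(\max(0,-x) + \epsilon), \qquad
  \dot y = \gamma y (1-r) + \tfrac{2\pi}{\tau} x,$$

where $r=\sqrt{x^2+y^2}$, $\tau$ is the intrinsic free-running period,
$\gamma$ the amplitude relaxation rate, $K$ the light coupling,
$\Lambda$ a saturating lux map and $\epsilon$ a shallow dead-zone leak.
The gated forcing yields the canonical nocturnal-rodent weak (type-1)
phase response curve: delays in early subjective night, advances in late
subjective night, a dead zone through subjective day, maximal shifts of
1–2 h for a 1-h, 1,000-lux pulse.

Rhythm analysis follows standard practice: Sokolove–Bushell chi-square
periodogram ($Q_P$ against the $\chi^2_{P-1}$ critical value, α = 0.05,
5-min period precision, trailing 15 days), entrainment defined as a
significant peak within 24 h ± 10 min, activity onset/offset/centre-of-
gravity phase markers with circular phase dispersion, side-band
detection, and actogram matrices. Field logger records are analysed for
supra-basal exposure episodes, 15-min exposure histograms (release and
recapture days excluded) and supra-threshold light outside civil
twilight.

See the methods vignette
(`vignettes/random-pulse-entrainment.Rmd`) for the model rationale,
calibration procedure and numerical conventions.

## Worked example

Run the full increasing-dispersion protocol — constant darkness (DD), a
fixed daily pulse (LD1:23), then random pulses in windows of 8 h, 8 h
delayed by 6 h, 15 h and 20 h, all 1-h pulses at 1,000 lux, 40 days per
stage:

```r
library(circapulse)
p <- oscillator_params()
p
#> <oscillator_params> tau = 23.75 h, stiffness = 0.1 /h, coupling = 0.7,
#>   dead-zone leak = 0.25, lux map ref/sat = 1000/1000 lux

cfg <- experiment_config(
  stages = list(stage_dd(40), stage_fixed(12, 1000, 40),
                stage_random(8, 1000, 40), stage_random(8, 1000, 40, shift = 6),
                stage_random(15, 1000, 40), stage_random(20, 1000, 40)),
  oscillator = p, seed = 1)
report <- run_experiment(cfg)
report
#> <experiment_report>
#>   1. DD                     free_running period 23.75 h
#>   2. LD1:23                 entrained    period 24 h
#>   3. I=8h L=1000lux         entrained    period 24 h
#>   4. I=8h L=1000lux (shifted +6h) entrained    period 24 h
#>   5. I=15h L=1000lux        entrained    period 24 h
#>   6. I=20h L=1000lux        free_running period 23.75 h
```

Reading: in DD the activity rhythm free-runs at the intrinsic period
(23.75 h — note the trailing-15-day periodogram snaps to its 5-min grid).
Every pulse regimen up to the 15-h window locks the rhythm to 24 h within
the ± 10 min criterion, including the 6-h-delayed window (whose entrained
phase follows the delay — the evidence that the pulses, not some
uncontrolled cue, do the entraining). At the 20-h window this replicate
escapes and free-runs; across seeds roughly half the replicates still
entrain at 20 h, reproducing the mixed outcomes seen experimentally.

The same protocols ship as YAML configs:

```r
cfg <- read_experiment_config(system.file("extdata", "fig3.yaml", package = "circapulse"))
```

Field-side synthesis and checks:

```r
log <- synthetic_light_log(10, seed = 1)
log
#> <light_log_record> 'logger': 2880 bins @ 5 min (10.0 days),
#>   range [0.3, 19000] lux, basal 0.3
nrow(night_exposure_check(log))   # supra-1.2-lux samples outside twilight
#> [1] 0
```

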