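# dotpulse

Dissolved-oxygen pulse analysis for intermittently fed *E. coli*
minibioreactor cultivations.

Minibioreactors are fed by discrete glucose boluses, and every bolus
leaves a negative pulse in the dissolved oxygen tension (DOT) signal.
The shape of that pulse is a free physiological measurement: a steep
decline while glucose is oxidized (with the excess overflowing to
acetate), an optional plateau or small rise while the metabolism pauses
and adapts from glucose to acetate oxidation, a second shallower decline
while the acetate is burned, and an exponential transfer-driven return
to saturation.  `dotpulse` turns that shape into numbers, for
bioprocess engineers and modellers who have a DOT trace and a feed log
but few or no offline samples.

The package provides, end to end:

* **Signal conditioning** — CSV I/O, uniform resampling, Savitzky–Golay
  smoothed derivatives, and first-order sensor-lag inversion
  (`DOT = τ·dDOTm/dt + DOTm`, τ = 36 s for the emulated probes).
* **Pulse segmentation** — feed-anchored pulse windows and a trained
  slope-classification state machine labelling up to four segments
  (S1–S4) per pulse, with per-segment duration, slope and area metrics.
* **Physiology retrieval** — from the segment geometry:
  * `KLa` from the recovery segment, via the analytic solution of
    `dDOT/dt = (DOT* − DOT)·KLa`;
  * `qO2`, `OUR` and `qO2max` from first segments near biomass samples,
    via the oxygen balance `qO2 = ((DOT*−DOT)·KLa − dDOT/dt)/(H·Cx)`;
  * `YO2/S` from two-segment pulses (transfer-area integral over the
    pulse divided by the glucose mass fed);
  * `YO2/A` from four-segment pulses (transfer integral over the
    acetate-oxidation phase divided by the overflow acetate mass);
  * the overflow switching condition `qs_ox,crit = qO2max/YO2/S`.
* **An event-driven metabolic simulator** — piecewise-continuous
  overflow kinetics with four metabolic states including an explicit
  *adaptation state* whose duration scales with accumulated acetate and
  inversely with biomass (`Δt = t_max·(CA/CA_max)·(Cx_max/Cx)`), exact
  event location, oxygen balance and sensor lag.
* **A synthetic-experiment generator** reproducing the reference
  experiment (8 mL, 600 mg/mL feed, bolus plans A–H, 1 s sampling,
  0.3% sensor noise), with ground truth written alongside, so the whole
  analysis loop is testable without laboratory data.

## Worked example

Generate a synthetic reference-plan run (6.5 µL every 9 min for 11.85 h,
79 boluses, growth from 8 to ~25 mg/mL biomass) and retrieve the
physiology from its noisy measured signal:

```r
library(dotpulse)

g <- generate_experiment(experiment_spec(plan = "E", seed = 1))
g$trace
#> <dot_trace> 42661 points, 0.0-42660.0 s, DOT* = 100%, uniform dt = 1 s
#>   6612 value(s) outside [0, DOT*]

wf <- run_workflow(g$trace, g$feeds, g$samples)
wf
#> <physio_estimate>
#>  parameter estimate       lo       hi  n
#>        kla 246.7153 228.8436 264.5869 79
#>     qo2max   0.1560   0.1323   0.1517 16
#>       yo2s   0.0819   0.0816   0.0822  2
#>       yo2a   0.1255   0.1207   0.1303 77
#>        our   2.1261   1.7079   2.5443 16
#>        qo2   0.1420   0.1323   0.1517 16
#> overflow switching condition qs_ox_critical = 1.906 g/(g h)

wf$pulses
#> <pulse_set> 80 feed(s): 77 four-segment, 2 two-segment, 1 flagged
```

The run was generated with `KLa = 250` 1/h, `qO2max = 0.16` g/(g·h),
`YO2/S = 0.075` and `YO2/A = 0.15` g/g (`g$truth`), so the estimates
above are off by −1.3%, −2.5%, +9% and −16% respectively: `KLa` and
`qO2max` are recovered tightly, while the yield estimators carry the
acetate-turnover bias discussed in the methods vignette.  `lo`/`hi` are
the per-pulse mean ± one standard deviation, `n` the number of pulses
contributing to each estimate (biomass-dependent quantities use only
pulses near one of the five at-line samples; `YO2/S` uses only
two-segment pulses).

The simulator alone reproduces the feed-volume threshold at which the
adaptation segment appears:

```r
find_segment_threshold()$threshold   # 1-10 uL sweep at Cx = 10 mg/mL
#> [1] 5
```

A thin command-line front end wraps the same pipelines
(`inst/cli/dotpulse.R`):

```sh
Rscript inst/cli/dotpulse.R synth --out run1 --plan E --seed 1
Rscript inst/cli/dotpulse.R estimate --trace run1/trace.csv \
        --feeds run1/feeds.csv --samples run1/samples.csv \
        --out run1/physio.csv
```

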