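---
title: "Segmenting dissolved-oxygen pulses and retrieving cell physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting dissolved-oxygen pulses and retrieving cell physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotpulse)
```

## The signal and what it encodes

Minibioreactor cultivations of *E. coli* are fed by discrete glucose
boluses (a few microlitres every few minutes).  Each bolus triggers a
burst of oxygen consumption, and because the oxygen transfer rate of the
reactor is finite, the dissolved oxygen tension (DOT, in % air
saturation) shows a negative pulse after every injection.  Up to four
phases are distinguishable in one pulse:

* **S1** — a sharp decline while glucose is taken up at the cell's
  maximum oxidative capacity; uptake beyond that capacity is shunted to
  acetate (overflow metabolism).
* **S2** — a plateau or small rise: after glucose runs out the
  metabolism pauses briefly before the cell redirects its machinery to
  acetate oxidation.  This *adaptation state* appears only when enough
  acetate accumulated, i.e. above a feed-volume (dilution-per-biomass)
  threshold.
* **S3** — a second, shallower decline while the accumulated acetate is
  oxidized.
* **S4** — an exponential return to saturation driven purely by the
  reactor's oxygen transfer, at rate `KLa`.

Small boluses produce only S1 and S4.  The package detects the pulses,
labels the segments, and converts segment geometry into physiology:
`KLa` from S4, the specific oxygen uptake rate `qO2` (and its maximum)
from S1, the oxygen yields on glucose (`YO2/S`, from two-segment
pulses) and on acetate (`YO2/A`, from four-segment pulses).

## The mechanistic model

The simulator is an event-driven, piecewise-continuous overflow model
with four metabolic states mirroring the segments.  Within a state the
ODE system for glucose `Cs`, acetate `CA`, biomass `Cx`, actual oxygen
`DOT` and measured oxygen `DOTm` is integrated with a stiff-capable
solver (`deSolve::lsodar`), and the switching times (glucose exhaustion,
adaptation deadline, acetate exhaustion) are located by root finding,
not by stepping over them.

* State I: total uptake `qs = qs_max Cs/(Cs+Ks)`; the oxidative share is
  capped at the critical rate `qO2max/YO2S` (times an optional oxygen
  Monod factor `DOT/(DOT+KO)`); the excess becomes acetate with yield
  `YA/S`.
* State II: every uptake rate is scaled by `1 - Rt`; the shipped default
  `Rt = 1` is a complete pause.  Its duration is
  `dt = t_adap_max (CA/CA_max)(Cx_max/Cx)` (60 s at 0.5 mg/mL acetate
  and 25 mg/mL biomass) — more acetate prolongs the pause, more biomass
  shortens it.  The state is entered only when acetate exceeds
  0.1 mg/mL at glucose exhaustion.
* State III: acetate oxidation at `qa_max CA/(CA+KA)`, capped at the
  oxygen-equivalent capacity `qO2max/YO2A`.
* State IV: no metabolic activity; DOT relaxes to saturation at `KLa`.

The oxygen balance is `dDOT/dt = (DOT* - DOT) KLa - qO2 H Cx` with
`H = DOT*/C*_O2` converting oxygen mass concentration to % saturation
(`C*_O2 = 0.007` g/L at cultivation temperature, giving
`H ≈ 14286 % L/g`), and the probe reads the signal through a first-order
lag `dDOTm/dt = (DOT - DOTm)/tau` with `tau = 36` s.  Feeds are
instantaneous: glucose mixes in at the feed concentration, everything
else is diluted by `V/(V + Fs)`, and the injection duration (about a
second in the real system) is neglected.

### Parameter defaults and the threshold calibration

| parameter | default | unit | meaning |
|---|---|---|---|
| `qo2max` | 0.16 | g O2/(g h) | maximum specific oxygen uptake |
| `yo2s`, `yo2a` | 0.075, 0.15 | g/g | oxygen yields on glucose, acetate |
| `yas` | 0.667 | g/g | acetate yield on overflowed glucose |
| `qs_max` | 3.95 | g/(g h) | total glucose uptake capacity |
| `qa_max` | 0.7 | g/(g h) | acetate uptake capacity |
| `ks`, `ka` | 0.01, 0.01 | g/L | substrate Monod constants |
| `ko` | 1 | % DOT | oxygen Monod constant |
| `kla` | 250 | 1/h | reference oxygen transfer coefficient |
| `tau` | 36 | s | probe time constant |

`qo2max`, the yields and `kla` are the mid-range values retrieved from
the reference reactor run.  `qs_max` is the calibration knob for the
four-segment threshold: the acetate accumulated by a bolus is
`YA/S x (overflow fraction) x (glucose added)`, and with
`qs_max = 3.95` the 0.1 mg/mL adaptation threshold is crossed at a
5.0 uL bolus (10 mg/mL biomass, 8 mL volume) — 4.5 uL pulses stay
two-segment, 5.0 uL pulses gain S2 and S3.  This calibration was fixed
once, before the parameter-recovery analyses, and is not a fitting
parameter.

Two kinetic choices deserve explanation because they interact with the
event-driven structure:

* **Small Monod constants (`ks = ka = 0.01` g/L).**  With a large `ks`
  the glucose Monod tail lasts tens of seconds during which the oxygen
  uptake collapses *before* the acetate state engages; the DOT then
  rises and dips again, imitating a second and third segment even for
  sub-threshold boluses.  Hard, nearly zero-order depletion (values at
  the lower end of reported *E. coli* affinities) keeps the switch
  abrupt, which is exactly the regime the event-driven formulation
  assumes.  Similarly, a large `ka` would stretch acetate oxidation into
  the recovery segment and corrupt `KLa` estimates.
* **`qa_max` below the oxygen-equivalent capacity.**  If acetate were
  oxidized at the full oxygen capacity, the third segment would be as
  steep as the first, contradicting the observation that the first
  decline is always the steeper one.  The default 0.7 g/(g h) makes the
  third-segment oxygen uptake about two thirds of `qO2max`.

## Segmentation

The detector anchors one candidate window on every feed event: the
window opens at the last sample before the post-feed decline onset and
closes at the start of the *final* period in which the (smoothed) signal
stays above 95% of its pre-pulse value — searching backwards from the
next feed, because on the delay-corrected signal the adaptation bump
itself can graze the recovery band and would otherwise end the window
prematurely.  Windows cut short by the next feed are flagged truncated
and excluded from `KLa` estimation.

Within a window every sample is classified by its Savitzky-Golay
smoothed slope (window 11 samples, order 2 at 1 s sampling) into steep
decline, moderate decline, flat, or rise.  The steep/moderate boundary
is trained per run: each window contributes its steepest smoothed
decline, and half the median of those becomes the boundary; the flat
band is 15% of it, symmetric around zero so that slightly negative
plateaus still count as flat (second segments drift from positive to
slightly negative slopes over a cultivation).  Runs shorter than 4 s are
merged into their longer neighbour, the runs are collapsed into
down/neutral blocks, and the block pattern maps onto the segments:
leading declines are S1, a neutral block followed by more decline makes
S2 and S3, the trailing rise is S4.

Class transitions are smeared by half the smoothing window, so each
boundary is then sharpened to the intersection of straight lines fitted
to the interiors of the adjacent segments; a boundary is only moved when
the propagated uncertainty of that intersection is below about 1.5
samples.  On noise-free piecewise-linear pulses the refined boundaries
are exact; at 0.2% added noise they stay within 3 samples.

## Parameter retrieval

The workflow (`run_workflow()`) corrects the sensor lag
(`DOT = tau dDOTm/dt + DOTm`, with the same Savitzky-Golay derivative),
segments the corrected trace, and then walks the estimation chain:

1. **`KLa`** per untruncated pulse.  The default estimator least-squares
   fits `DOT* - A exp(-KLa t)` to the recovery, anchored where a
   smoothed copy first passes 87% of saturation (below that level
   residual acetate oxidation still consumes oxygen) and extending five
   recovery time constants into the inter-pulse tail, stopping one
   filter window before the next feed (the acausal smoothing filter
   anticipates the crash).  The two-point closed form over the fourth
   segment is available as `method = "endpoints"` and supplies the
   fit's initial rate.
2. **`qO2`, `OUR`, `qO2max`** from first segments of pulses within
   15 min of a biomass sample, via the rearranged oxygen balance
   `qO2 = ((DOT* - DOT) KLa - dDOT/dt)/(H Cx)` using the segment-mean
   DOT (10% of the samples at each boundary are trimmed because the
   metabolic transition is not resolved exactly).  `qO2max` is the
   maximum across pulses.
3. **`YO2/S`** from two-segment pulses: the transfer integral
   `V KLa ∫(DOT* - DOT) dt / H` divided by the glucose mass fed, with an
   analytic completion term for the last 5% of the recovery outside the
   window.
4. **`YO2/A`** from four-segment pulses: the transfer integral from the
   start of S3 until the signal regains its S3-start level, divided by
   the acetate mass.  The default route obtains the oxidized glucose
   from the pulse's own oxygen book-keeping,
   `(O2_total - O2_acetate)/YO2S`, which stays valid when oxygen
   limitation throttles the uptake in deep pulses; the printed
   kinetic form `qs_ox_max Cx V dT1` is available as
   `method = "kinetic"` but inherits the bias of the measured first
   segment duration, which slope-based segmentation cannot pin down
   once the DOT rides its quasi-steady floor.

The ratio `qO2max/YO2S` is reported as the overflow switching condition.
Estimated `KLa` outside 20-1440 1/h (the envelope of comparable stirred
minibioreactor systems) raises a warning, not an error.

## The synthetic-experiment generator

`generate_experiment()` emulates the reference cultivation: 8 mL initial
volume, 600 mg/mL glucose feed, one of the eight bolus plans (the
reference plan delivers 6.5 uL every 9 min; 79 boluses over the 11.85 h
production phase), about 1 s DOT sampling, additive Gaussian sensor
noise of 0.3%, a 36 s probe lag, growth enabled, and five at-line
biomass/glucose/acetate samples spread over the horizon.  Real schedules
deviate from the plan because feeding competes with sampling and
titration tasks; the generator emulates that with a 15% relative
standard deviation on the bolus volumes (truncated at 2.5 sd and 1 uL).
This amplitude jitter is also what makes a run contain both
two-segment and four-segment pulses, as the real runs do.  The initial
biomass of 8 mg/mL grows to about 25 mg/mL by the end of the reference
plan, so late pulses reach oxygen-limited conditions — deliberately, as
the heavier feeding plans do in reality.

What the generator does *not* emulate: slow KLa drift from rising
viscosity, pH and temperature dynamics, induction effects, measurement
error on the at-line samples, and interval jitter (available but off by
default).  Passing recovery tests on this data therefore shows that the
estimators invert the model that generated the data under realistic
noise and sampling; it cannot certify behaviour under real-world
systematic drifts.

## Numerical choices and verification scale

* Solver tolerances `rtol = 1e-8`, `atol = 1e-10`; switching events
  located by `lsodar` root finding.  Residual substrate zeroed at a
  switch (the root is placed at 1e-6 mg/mL to keep the depletion abrupt)
  is charged to the cumulative totals, so mass and oxygen balances close
  to machine precision.
* Simulator state lives in hours internally (rate constants are per
  hour); all user-facing times are seconds.
* Integrals over sampled signals use the composite trapezoid on the
  sampling grid; tolerance statements assume 1 s sampling.
* The degenerate transition with `0 < CA <= 0.1` mg/mL at glucose
  exhaustion goes directly to acetate oxidation, so mass is conserved
  and the resulting short, shallow third phase stays invisible to the
  segmentation — consistent with observed two-segment pulses.
* Verification runs use single pulses of 3-9 uL at 10 mg/mL biomass
  (several hundred simulated seconds each), a 19-point volume sweep for
  the threshold, and five full reference-plan runs (79 pulses, 11.85 h)
  for parameter recovery; the complete test suite runs in about a
  minute on one core.

## Known limitations

* The yield estimators carry a structural bias wherever acetate turnover
  overlaps the windows they integrate: a "two-segment" pulse still
  oxidizes up to 0.1 mg/mL of acetate inside its window, which inflates
  `YO2/S` by up to ~10% at the calibrated overflow fraction, and `YO2/A`
  inherits that bias with opposite sign through the workflow chain.
  The recovery tests measure both effects explicitly.
* `qO2` estimates in oxygen-limited pulses report the transfer-limited
  uptake — physically correct, but `qO2max` then relies on the early,
  unlimited pulses near a biomass sample.
* The segmentation reconstruction is one of several defensible designs;
  every threshold lives in `segmentation_config()` so alternatives can
  be plugged in.
* Runs in which no pulse qualifies for a stage (no two-segment pulses,
  no biomass samples) return that stage as missing rather than guessing;
  pooling across replicate runs is the intended remedy.
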