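---
title: "Modelling oxytocin neuron spiking, secretion and plasma concentration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxytocin neuron spiking, secretion and plasma concentration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(oxysim)
```

Magnocellular oxytocin neurons of the supraoptic nucleus translate synaptic
input into pituitary hormone release. This package implements the full chain
from a stochastic spiking model of a single neuron, through spike-pattern
statistics and model fitting, to a population secretion model and a
two-compartment plasma pharmacokinetic model that predicts circulating
oxytocin concentrations during a gavage feeding stimulus. This vignette
documents the models, the parameters that matter, the numerical choices, and
the limits of what the tests demonstrate.

## The spiking model

Each neuron is a modified integrate-and-fire unit,

$$V = V_{rest} + V_{syn} - HAP - AHP + DAP,$$

where $V_{syn}$ is a summed synaptic perturbation and the three
afterpotentials are single variables, each incremented by a fixed amount $k$
(mV) at every spike and decaying exponentially with half-life $\lambda$
(ms):

* the **HAP** (hyperpolarising afterpotential; default 50 mV, 8 ms) produces
  relative refractoriness for a few tens of milliseconds — there is no
  explicit membrane reset, the HAP alone silences the cell after a spike;
* the fast **DAP** (depolarising afterpotential; 3 mV, 50 ms) transiently
  raises excitability, favouring short interspike intervals;
* the medium **AHP** (afterhyperpolarisation; 0.5 mV, 600 ms) accumulates
  over successive spikes and shapes patterning on the seconds scale.

Excitatory and inhibitory PSPs arrive as independent Poisson counts per
integration step, with the inhibitory arrival rate a fixed fraction
`I_ratio` (default 0.5) of the excitatory rate `I_re`. Each PSP has a fixed
amplitude of ±2 mV, and the summed perturbation decays with a 7.5-ms
half-life. The resting potential is −62 mV and the threshold −50 mV; these
and the PSP shape are held constant across all cells. The defaults of
`neuron_params()` are the consensus ("typical oxytocin cell") values.

### Integration scheme

`simulate_neuron()` integrates with a fixed 1-ms step (compiled kernel; the
pure-R `step_neuron()` implements the identical update and the two are
asserted to agree spike-for-spike). All decays are applied as exact
per-step half-life factors $2^{-dt/\lambda}$ rather than Euler
approximations, so half-life arithmetic is exact. Within a step the order
is:

1. decay the accumulated $V_{syn}$, then add this step's PSPs at full
   amplitude;
2. decay the afterpotentials;
3. test $V$ against threshold;
4. on a spike, increment the afterpotentials.

The placement of the threshold test relative to the PSP decay is a genuine
convention choice in a discrete-time implementation. We add the current
step's PSPs before testing, i.e. a PSP contributes its full amplitude at the
moment of the test, and decay applies only to prior accumulation. This
convention reproduces the observed basal firing rate of ~3.26 spikes/s at
`I_re` = 370 Hz with the consensus parameters; decaying this step's PSPs
before the test systematically underestimates the membrane excursion at the
test instant and yields a basal rate far below the observed one at the same
published parameters.

The descriptions of the synaptic input are ambiguous about whether
inhibitory events arrive at the full excitatory rate or at the tabulated
ratio of 0.5; the tabulated ratio is used, and equal rates with ±2-mV
amplitudes can be recovered by setting `I_ratio = 1` (they produce a
mean-zero drive and near-silence at these parameters).

```{r}
tr <- simulate_neuron(consensus_neuron_params(),
                      constant_protocol(370, 600), seed = 1)
mean_rate(tr)
```

## Pattern statistics

`summarise_train()` bundles the three statistics used to characterise (and
fit) a cell, all computed from the same record:

* **ISI histogram** (`isi_histogram()`): interspike intervals in 5-ms
  left-closed bins up to 1000 ms. The analysis window is our own default
  (the sources do not state one); intervals beyond it are kept in an
  overflow bin so that totals are conserved.
* **Hazard function** (`hazard()`): per bin, the number of ISIs in
  $[t, t+5)$ divided by the number of ISIs longer than $t$. Bins whose
  denominator reaches zero are marked undefined rather than zero-filled.
* **Index of dispersion** (`iod_profile()`): variance/mean of spike counts
  at bin widths from 0.5 to 10 s (grid
  $\{0.5, 1, \dots, 10\}$ s, our choice within the stated range). Widths
  with fewer than 10 whole bins are flagged unreliable.

Firing-rate responses use 30-s bins (`binned_rate()`), baseline-subtracted
against a 10-min pre-stimulus window (`normalise_to_baseline()`), and the
gavage response is summarised by a straight line constrained through zero at
a fixed onset (`fit_ramp()`, default onset +3.5 min after gavage start). The
slope is reported in spikes/s per minute; the units of the corresponding
published slope are ambiguous (spikes/s versus spikes per 30-s bin), which
is one reason the ramp slope is not used as a quantitative target. The
$R^2$ of the constrained fit is computed against the mean of the post-onset
data and truncated at zero (a convention the sources leave open).

Interval statistics are invariant to a global time shift of the record;
binned statistics shift with their reporting axis (`t0`), which is how
series are aligned to stimulus onset. Because fixed-step simulation places
spikes on a 1-ms grid, bin boundaries are snapped at nanosecond precision so
that shifted copies of a train bin identically.

## Fitting: score, genetic algorithm, consensus

`fit_score()` compares a candidate pattern summary against a target as a
weighted sum of RMSE measures over the ISI histogram (as per-bin
probabilities), the hazard function, and the IoD profile — smaller is
better. Two numerical choices matter:

* Each statistic's RMSE is divided by the range of the target's statistic
  (equal weights after unit-range scaling), since no relative weighting is
  published. `scale = "none"` gives raw RMSEs.
* The hazard RMSE is precision-weighted: each bin is weighted by the smaller
  of the two surviving-interval counts, the binomial information behind that
  bin's estimate. Unweighted RMSE lets tail bins estimated from a handful of
  long intervals dominate the comparison with pure sampling noise; the
  weighting reduces that noise floor by more than an order of magnitude and
  reduces to plain RMSE when denominators are equal. Undefined bins are
  excluded, never zero-filled.

`ga_fit()` searches the free parameters of a model variant (`I_re` plus the
$k/\lambda$ pair of each afterpotential present; at most seven) with a
real-coded genetic algorithm: tournament selection (size 3), uniform
crossover (rate 0.7), Gaussian mutation (per-gene rate 0.2, SD 5% of the
bound width), one elite per generation. Box bounds envelope the published
per-cell fits with margin. Each candidate is scored by simulating a 600-s
train at a per-run fixed seed, so scores are comparable within a run and the
elite trajectory is non-increasing; the best of `runs` restarts is returned.
The full replication setting is 100 restarts per variant; the test suite
uses reduced populations and restarts (problem sizes are stated in the test
code) since the GA operators, not the budget, are what the tests verify.
`fit_all_variants()` fits all four afterpotential configurations (HAP only,
HAP+AHP, HAP+DAP, HAP+AHP+DAP) and keeps the best score, breaking ties
toward fewer free parameters.

`consensus_params()` builds a "typical cell" from a table of per-cell fits:
the HAP pair is the point on the $\lambda_{HAP}$-on-$k_{HAP}$ regression
line nearest the per-parameter medians (the two are strongly negatively
correlated across cells); AHP and DAP parameters are medians over the fits
containing them; the input rate is the median rate. Medians are rounded —
$k$ to 0.1 mV, $\lambda_{AHP}$ to 100 ms, $\lambda_{DAP}$ to 10 ms, `I_re`
to 10 Hz — which reproduces the published rounded values from the published
per-cell table (shipped as `oxytocin_fits()`).

```{r}
consensus_params(oxytocin_fits())
```

### Identifiability of the HAP pair

The HAP amplitude and half-life are only weakly identified jointly: raising
$k_{HAP}$ while shortening $\lambda_{HAP}$ leaves the post-spike suppression
window — and with it the ISI histogram, hazard and IoD — almost unchanged.
Quantitatively, the expected hazard difference between a true pair and a
±20% amplitude-compensated pair is an order of magnitude below the sampling
noise of a 10-min record, so no fitting algorithm can resolve the amplitude
to ±20% from such records; what the data constrain is the trade-off line.
This is consistent with the strong anti-correlation of the two parameters
across the published per-cell fits and with defining the consensus as a
point *on* that line. The closed-loop recovery experiment in the test suite
records this honestly: the input rate is recovered to within 10%, while the
HAP amplitude lands anywhere along the trade-off line.

## Secretion and plasma

`secretion_from_spikes()` converts a train into a release-rate signal: a
facilitation variable $f$ is incremented by `facil_gain` at each spike
(capped at `facil_max` = 20) and decays with a 60-s half-life; a spike
arriving with facilitation $f$ releases
$\mathrm{base} \cdot (1+f)^{p}$ units, with $p = 2$ by default. The
supralinear exponent stands in for the cooperative calcium dependence of
neurohypophysial exocytosis, and it is load-bearing: the measured plasma
concentration rises ~3.5-fold from basal to 40 min while the model firing
rate rises only ~1.5-fold. With release *linear* in a rate-proportional
facilitation variable, steady-state secretion can scale at most with the
square of the rate ratio (≈2.2), so no gain setting can reach the measured
40-min concentration; with $p = 2$ the calibration problem has a root. The
secretion equations of the original coupled model are not published in the
source we reproduce; this facilitation form is this package's own committed
surrogate, all of whose parameters are exposed.

`plasma_dynamics()` integrates a linear two-compartment system in
concentration units: secretion (scaled by the population factor and the
plasma volume) enters the plasma compartment, exchanges with an
extravascular compartment ($k_{pe}, k_{ep}$ = 0.5/min), and is cleared from
plasma only ($k_{clear}$ = 1.2/min, plasma volume 10 mL — a typical adult
rat). These defaults give a fast distribution phase and a dominant half-life
of roughly two minutes, consistent with oxytocin clearance measured in
minutes; they are package defaults, not published values. The update is an
exact exponential integrator (the 2×2 matrix exponential applied per step in
the eigenbasis, input held constant over each 0.1-s step), which is
unconditionally stable and conserves mass to rounding error; the mass ledger
(inflow = cleared + stored) is checked to 1e−6 in the tests. After a bolus
the model decays biexponentially with the eigenvalues of the rate matrix,
verified against an independent ODE solver.

### Calibration policy

The chain has two free constants: the population `scaling` (one model
neuron's secretion to whole-gland output) and the facilitation gain.
`calibrate_secretion()` fixes them from two measured anchors of the
sweetened-condensed-milk group: scaling is set analytically so the
steady-state basal concentration equals the measured basal mean (65 pg/mL;
exact because the plasma model is linear in scaling), and the gain is found
by bounded root-finding so the simulated 40-min concentration equals the
measured 40-min mean (229 pg/mL), re-deriving the scaling inside every
evaluation since gain changes basal secretion too. The 20-min concentration
is then a genuine out-of-sample prediction — nothing in the calibration
uses it. `predict_gavage()` runs the full pipeline: 100 neurons (seeds
`seed + i`), 6000 s each under the gavage protocol (40-min control at
370 Hz, 3.5-min delay, 0.037 Hz/s ramp for 35 min, plateau at 447.7 Hz),
secretion signals averaged into the plasma model.

## Synthetic data

The recordings behind the published fits are not deposited, so every stage
is exercised on generated data with the structure the analysis assumes:
`gen_cell()` produces stationary baseline trains from known parameters
(with the truth record retained for closed-loop tests),
`gen_gavage_recording()` produces trains whose 30-s rates rise
approximately linearly after the protocol delay, and
`gen_measurement_cohort()` draws per-animal plasma values from a
zero-truncated normal and reports sample means and SEMs. What these
generators do **not** emulate: correlated or bursty synaptic input,
non-stationary baselines, electrode artefacts, spike-sorting errors, or
assay noise. Tests passing on synthetic data therefore demonstrate the
internal consistency of the pipeline — statistics, fitting, calibration,
prediction — not robustness to the failure modes of real recordings.

## Problem sizes and determinism

Simulation is deterministic given a seed everywhere (population members use
`seed + index`; GA restarts derive per-run streams from the configured
seed), and every population run carries a manifest sufficient to reproduce
it exactly. The replication script uses 20 seeds for the firing-rate ramp
and 100 neurons for the plasma prediction; the test suite uses 25 neurons
for the calibrated prediction (the averaging properties it relies on are
themselves tested) and a reduced GA. These sizes are the package's own
choices and are stated where they are used.

## Known limitations

* The HAP amplitude/half-life pair is structurally degenerate (above); fits
  constrain the trade-off line, not the point.
* The secretion model is a surrogate with a committed functional form; its
  adequacy is established only through the calibrated plasma predictions.
* Plasma kinetic constants are defaults consistent with a minutes-scale
  half-life, not fitted values; the calibration absorbs their overall scale
  (only the shape of the response tests them).
* The printed ramp-fit slope is not reproduced as a target because its units
  are ambiguous in the source material.
* The 1-ms integration step aliases PSP arrival times within a step; all
  published comparisons were made at the same step size.
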