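---
title: "Decomposing phase variability in a switching rhythmic motor system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing phase variability in a switching rhythmic motor system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasevar)
```

## The system and the question

The leech heartbeat system is a strictly feedforward rhythmic motor system:
a central pattern generator (CPG) of bilaterally paired heart interneurons
(HN) drives segmental heart motor neurons (HE), which drive the two lateral
heart tubes. At any moment one body side runs a rear-to-front *peristaltic*
coordination while the other runs a near-simultaneous *synchronous* one,
and the two sides switch states together every few minutes, so a recording
is a sequence of alternating coordination episodes of roughly 15–60 beat
cycles at periods of a few seconds.

The output characteristic of interest is the intersegmental phase
difference $\Delta\phi$: the timing offset between the activity markers of
a front and a rear segment, expressed as a fraction of the beat period.
`phasevar` quantifies *where the variability of $\Delta\phi$ comes from*,
separating four nested sources:

1. **cycle-to-cycle** — dispersion across beats within one episode,
2. **repetition** — drift between two repetitions of the same coordination
   on the same side (consecutive switch cycles),
3. **bilateral** — differences between the genetically identical left and
   right homologs within one animal,
4. **population** — differences between animals.

## Phase extraction

Spike trains are grouped into bursts wherever the interspike gap reaches
the interburst threshold (1 s by default); groups below `min_spikes`
(default 3) are discarded as stray spikes. The phase marker of a burst is
its middle spike by count, `ceiling(n/2)`, and the cycle period $T_r$ is
the middle-spike-to-middle-spike interval of the reference channel. The
phase of an event at $t_i$ in the reference cycle starting at $t_r$ is
$\phi = (t_i - t_r)/T_r$, reduced modulo 1. Each reference cycle is the
half-open interval to the next marker, so every instant belongs to exactly
one cycle; a cycle containing zero or several target markers is flagged and
skipped rather than guessed at. For optically recorded heart constrictions
the marker is the maximum rate of rise (MRR) of the smoothed signal; the
marker time is refined by a derivative-weighted centroid of the
supra-threshold rise, which is exact for symmetric constriction waveforms
and insensitive to sample-level noise on the flat top of the derivative.

Phase differences are reported in the centered convention $(-0.5, 0.5]$, so
small leads and lags around synchrony keep their sign; all arithmetic is
circular internally.

## Circular statistics

All dispersion measures derive from vector summation: phases become unit
vectors at angle $2\pi\phi$, the mean vector has length $r \in [0, 1]$, and
the angular variance is $s^2 = 2(1 - r)$ in rad², divided by $4\pi^2$ for
phase-fraction units (angular SD: $\sqrt{s^2}$, divided by $2\pi$). The
implementation is checked against a brute-force accumulation oracle to
$10^{-12}$.

Linear t tests (used for level comparisons) are run on phases linearized
around the pooled circular mean — each value is represented as its centered
circular deviation from that mean — which avoids wrap artifacts while
preserving group differences; with the small dispersions of these data the
linearization is essentially exact, and the result is rotation invariant.

## Episode segmentation

In the animal, coordination identity is defined by which switch interneuron
is silent — a channel that is not part of the analyzed recordings. The
package therefore classifies coordination from the phase differences
themselves, using three structural facts: the two sides are always in
opposite states, all levels switch simultaneously, and peristalsis is a
*signed* rear-to-front lead while synchrony sits near zero.

Per cycle we form the signed score
$\mathrm{score} = \Delta\phi_L - \Delta\phi_R$, summed over all
simultaneously recorded levels. The score alternates between two states
(left-peristaltic high, right-peristaltic low). A two-cluster k-means with
deterministic extreme-value initialization assigns each cycle to a state;
the higher-score cluster is left-peristaltic. Label changes are accepted
only when sustained for at least `hysteresis` cycles (default 3), so
single-cycle excursions never create a switch; the starting label is taken
from the first sustained run. The resulting contiguous segmentation is kept
only if it explains at least 40% of the score variance — genuine
alternation explains far more, while clustering artifacts on a recording
without switches do not, in which case the whole recording is one episode
labelled by the score's sign. Cycles within `exclude` cycles (default: the
hysteresis width) of an accepted switch are marked transitional and do not
enter any statistic, so coordinations are never mixed within an episode.

An absolute magnitude threshold (e.g. the midpoint of the two
coordinations' nominal means) can be supplied; it is then enforced per
episode and a sustained violation raises an ambiguity error. It is not the
default because per-animal offsets of realistic size routinely cross any
fixed threshold, which would misclassify or discard a substantial fraction
of animals; the relative rule is insensitive to such offsets.

A *switch cycle* is one pass of a side through both coordinations.
Episodes are paired consecutively without overlap, so five observed
switches (four complete delimited episodes) yield exactly two complete
switch cycles and a trailing unpaired episode is flagged.

**Known limitation.** If an animal's peristaltic $\Delta\phi$ draws happen
to lie below its synchronous ones (a genuinely possible configuration in
the overlap of the two distributions, a few percent of animals under
realistic variances), no classifier using $\Delta\phi$ alone can label it
correctly. Such animals either collapse to a single episode (and are
excluded, with a log entry) or enter the population strata mislabeled,
where the 1.5×IQR outlier screen removes them. This is why outlier
screening is on by default in the pipeline.

## The variance decomposition

Per animal, side, level, coordination, and switch cycle, the episode's
usable cycles give a circular mean $\Delta\phi$ and a cycle-to-cycle
angular variance. The four components are then recovered by method of
moments on the wrapped-normal $\sigma^2$ scale, where independent
components add exactly ($s^2_{phase}$ and $\sigma^2$ are related by
$4\pi^2 s^2_{phase} = 2(1 - e^{-\sigma^2/2})$):

* cycle-to-cycle: the median across episodes of the within-episode
  variance (median, not mean, so one badly segmented episode cannot
  dominate), with the $n/(n-1)$ small-sample correction;
* repetition: $\mathrm{Var}(\Delta\phi_1 - \Delta\phi_2)/2$ across
  animal–sides, minus the averaged cycle-noise term $\sigma^2_{cyc}/\bar n$;
* bilateral: $\mathrm{Var}(\Delta\phi_L - \Delta\phi_R)/2$ minus the
  repetition and noise terms;
* population: the across-animal variance of the per-animal means (averaged
  over side × switch-cycle strata) minus all lower components.

All sample angular variances carry the first-order $n/(n-1)$ bias
correction, subtractions are floored at zero, and results are reported in
phase² units.

Inference follows two resampling routes:

* **Population variance CIs** resample animals with replacement. The
  default interval is studentized (bootstrap-t with jackknife standard
  errors). The plain percentile interval is provided as an option but is
  *not* the default: for a variance-type statistic at n ≈ 25 animals its
  coverage is around 86% at a nominal 95% (we verified this by simulation,
  along with BCa at ~89%), while the studentized interval covers at ~94%.
* **Repetition and bilateral tests** compare the observed variance of
  $\Delta\Delta\phi$ (the centered circular difference of paired
  $\Delta\phi$ means) with the variances of 10,000 scrambled populations in
  which the pairing is re-drawn across animals. The default scramble is a
  fixed-point-free permutation per iteration ("derangement"), which uses
  every animal exactly once like the observed pairing does; under an
  exchangeable null its z-score p values are uniform to within
  Kolmogorov distance ~0.04, whereas independent re-pairing is measurably
  conservative. The p value is the lower-tail normal probability of the
  observed variance's z score against the scrambled distribution (the
  hypothesis being that within-animal structure is *tighter* than the
  population); the two-sided value is reported alongside.

No multiple-testing adjustment is applied; all p values are reported raw.

## The synthetic-data generator

`generate_population()` draws the hierarchy the analysis assumes: per
animal, level, and coordination an animal offset (variance
`var_population`), per side an independent side offset (`var_bilateral`),
per switch cycle a repetition offset (`var_repetition`), and per cycle
wrapped-normal noise (`var_cycle`), all parameterized directly by angular
variances in phase² and added on the $\sigma^2$ scale. Episode lengths are
uniform on 15–60 cycles, two switch cycles (four episodes) per recording,
sides always complementary and switching simultaneously. Periods are
independent per cycle at CV 3% (within the "< 5%" regime reported for this system); period
autocorrelation within a recording is not modeled (configurable
assumption). Default mean $\Delta\phi$ values are 0.23 (CPG), 0.13 (motor
pattern) and 0.21 (beat pattern) for peristaltic and 0.02 for synchronous
coordination; default variance components are 0.004 (population), 0.005
(bilateral), 0.001 (repetition), and 0.001 (cycle) phase² — magnitudes in
the range reported for this system. Defaults of 26 animals match the
reference bilateral CPG data set.

Bursts place `spikes_per_burst` (odd, default 9) spikes symmetrically
around the middle spike so middle-spike recovery is exact; burst width is
30% of the period, and bursts adjacent to unusually close markers (large
phase jumps at switches) are shortened so the 1 s interburst gap is
preserved. Target markers are placed with the *unwrapped* phase, which is
continuous across cycles; in the noise-free limit the full chain
burst-grouping → pairing → segmentation reproduces the configured phases
exactly, which the test suite asserts.

Constriction traces are raised-cosine pulses whose maximum slope falls
exactly on the target marker; voltage-clamp traces sum an alpha-function
IPSC kernel (peak at `tau`, default 10 ms) scaled by $g(V_{hold}-E_{rev})$
with $E_{rev} = -62$ mV, so a 2 nS input at −42 mV holding gives exactly a
40 pA unitary peak.

What the generator does *not* emulate: period autocorrelation, burst-shape
variability, spike detection noise, electrode artifacts, gradual drifts
within an episode, and any dependence of synaptic strength on coordination
state. Passing tests therefore validate the statistical machinery under
the stated hierarchical model, not robustness to every feature of real
recordings.

## Numerical choices and scales

Wrapped-normal sampling requires each angular variance below
$1/(2\pi^2) \approx 0.0507$ phase² and the summed dispersion to stay
unimodal (phase SD ≤ 0.15); violations are rejected with a diagnostic.
Episodes with fewer than 7 usable cycles are excluded (the smallest episode
size in the reference analyses). The spike-triggered average uses a 50 ms
pre-trigger baseline and a 200 ms post-trigger window, requires 10 trigger
bursts (overridable), and reports the signed extremum; holding-potential
accuracy of ±5 mV is propagated into a conductance uncertainty band.

Validation problem sizes, chosen to pin estimates while keeping the suite
quick: parameter recovery uses 100 animals × 20 seeds (mean estimates of
all four components land within a few percent of truth); scrambling
calibration uses 1,000 replicates at 1,000 scrambles; bootstrap coverage
uses 500 replicates of 25 animals at 2,000 resamples; production analyses
default to the full 10,000 resamples and scrambles.

Every resampling stage derives its own substream seed from the root seed
and a stage tag, so any single report table can be reproduced in isolation
and two runs of the same configuration are byte-identical.
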