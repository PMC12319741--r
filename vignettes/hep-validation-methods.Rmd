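---
title: "Validating heartbeat-evoked potential effects: models, controls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating heartbeat-evoked potential effects: models, controls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepvalid)
```

## The problem

Heartbeat-evoked potentials (HEPs) are EEG deflections time-locked to the
cardiac R-peak. When HEPs are compared between task conditions — for example
between trials later sorted into high and low P300 amplitude, or fast and
slow reaction times — the pre-stimulus interval that hosts the HEPs also
hosts heartbeat-*independent* activity: slow anticipatory potentials such as
the contingent negative variation (CNV), arbitrary slow fluctuations of the
ongoing EEG, and regression-to-the-mean structure introduced by the sorting
itself. Any of these can masquerade as a "HEP effect", and conversely can
mask a genuine one. `hepvalid` implements the two control procedures that
address this, the statistics around them, and a simulation framework to
study their operating characteristics.

## The statistical engine

Condition contrasts are tested with cluster-based permutation t tests.
Per channel–time sample a t statistic is computed (paired over subjects with
`df = n − 1`, or pooled-variance two-sample over trials for within-dataset
designs); samples with two-tailed `p < 0.05` that are adjacent in space
(neighbouring channels, supplied as an explicit edge list or derived from
montage coordinates) and time are merged into clusters, each scored by its
summed t. The null distribution records, per permutation of the condition
labels, the maximum |summed t| across all clusters of either polarity — a
max-statistic construction that controls the family-wise error across the
whole channel–time grid and both tails. With `B` permutations a cluster's
Monte-Carlo p is `max(count(null ≥ |sum t|), 1) / B`, so its attainable
floor is exactly `1/B` (0.001 at the default 1000). For paired designs with
`n ≤ 12` subjects the full set of `2^n` sign assignments can be enumerated
(`exact = TRUE`); ties between the observed statistic and a null assignment
(the identity flip is always in the exhaustive null) are counted at a
`1e-9` relative tolerance. Samples with zero difference variance get
`t = 0` rather than an infinite statistic, so degenerate synthetic inputs
cannot spawn artificial clusters.

Two polarity conventions were genuinely open. The null pools both polarities
into one max distribution and each observed cluster — positive or negative —
is compared against that pooled null; this is the stricter variant and keeps
the two-tailed family-wise error at its nominal level.

## Surrogate heartbeat analysis

The cluster permutation answers "do the conditions differ?", not "is the
difference heartbeat-locked?". The surrogate control answers the second
question: within each condition, the multiset of R-peak latencies relative
to their parent stimuli is permuted across trials
(`shuffle_rpeaks_within_condition()`). Every trial keeps its stimulus and
regains its original number of R-peaks, so per-condition latency multisets —
and hence mean heart rate and inter-beat intervals — are preserved exactly,
while the temporal alignment between heartbeat and EEG is destroyed.
Repeating the full analysis on many shuffles (100 by default, configurable
upward) yields a null distribution of maximum |summed t| values; a genuine
heartbeat-locked effect must exceed the 95th percentile of that null.
Trials contributing several eligible R-peaks pool all their latencies and
are refilled to their original counts — descriptions of the procedure in
the field leave this case open, and this choice is the only one that
preserves both the multiset and the per-trial counts.

We implement the shuffle as a latency permutation rather than random
re-jitter because only the permutation preserves the latency multiset
exactly; a jitter variant would additionally perturb the marginal latency
distribution and could move R-peaks outside the eligibility window.

## Pseudotrial correction

Where the surrogate analysis *gates* (it can only prevent false positives),
pseudotrial correction *removes* heartbeat-independent activity so genuine
effects hidden underneath can surface. For each trial a pseudo-R-peak is
inserted at a uniformly random latency in the pre-stimulus window of
interest; pseudo epochs are extracted and processed through the *identical*
rejection and baseline pipeline as the real HEP epochs (any asymmetry would
itself be a confound), averaged per condition, and the per-condition average
is subtracted sample-wise from every real HEP epoch of that condition.
Activity that is present in the pre-stimulus window regardless of heartbeat
timing — CNV ramps, sorting-related slow offsets — cancels in expectation;
heartbeat-locked activity survives because the pseudo onsets are unrelated
to the real R-peak times. The correction commutes with baseline correction
(both are linear), which the test suite verifies.

Because the correction subtracts a *noisy average*, it adds a shared offset
(variance `σ²/m` for `m` pseudo epochs) to every corrected epoch of a
condition. That offset moves the group mean coherently without entering the
per-trial variance estimate, so corrected data have heavier cluster
statistics under the null than uncorrected data. The adapted surrogate
below exists precisely to calibrate against this.

## The adapted surrogate for corrected data

To control for structure introduced by the correction itself, the pseudo
triggers are exchanged twice per condition, producing two independent
pseudotrial sets; the first set's epochs are corrected by the second set's
per-condition average and passed through the same cluster test
(`surrogate_for_corrected()`; in the simulation arm the two sets are
latency re-shuffles of the pseudo candidates, which live on the trials
*without* simulated HEPs). Because no heartbeat-locked signal can enter
either pseudotrial set, this null isolates exactly the noise that the
correction adds — the subtracted noisy average — and a genuine effect in
the corrected data must beat its 95th percentile.

One calibration property of this null deserves attention. In the simulation
design the corrected data subtract a pseudo average computed on a
*disjoint* trial subset (the non-HEP trials), while both surrogate
pseudotrial sets live on the same subset. When the background carries heavy
sub-Hz power, the slow-activity difference between the two trial subsets is
a real noise source of the corrected data that the surrogate cannot see,
and the gate becomes anti-conservative: at zero coupling we measure ~35%
nominally-significant corrected outcomes under the default `1/f`
background, roughly 10–20% when the spectrum is flattened below 1 Hz, and
the nominal ~5% once the background carries no excess slow power at all
(white noise). The gate is therefore exactly calibrated only when slow
activity does not differ between the HEP-bearing and pseudo-bearing trial
subsets; the type-I property test in the suite runs under that setting,
and users analysing slow-rich data should read corrected-arm gate decisions
with this in mind.
We deliberately did not "repair" the null (for instance by shuffling the
real triggers into it): any variant that epochs the HEP-bearing trials
retains the genuine pulse at a random lag inside the epoch, contaminating
the null with a smeared copy of the very effect under test and inverting
the power ordering the correction exists to deliver.

## The synthetic-session generator

Cohort EEG suitable for phase-randomized backgrounds is rarely shareable,
so the generator builds the study conditions fully synthetically
(`sim_config()` defaults):

| parameter | default | meaning |
|---|---|---|
| `sampling_rate` | 250 Hz | analysis rate of the emulated preprocessing |
| `session_length`, `isi` | 1688 s, 4 s | 422 task triggers per session |
| `erp_mean`, `erp_sd` | 7, 2 µV | simulated ERP peak amplitudes (normal) |
| `hep_mean`, `hep_sd` | 1.5, 0.8 µV | simulated HEP peak amplitudes |
| `erp_onset`, `erp_duration` | 300, 600 ms | ERP Gaussian deflection |
| `hep_duration`, `hep_latency` | 400, 200 ms | HEP deflection; peak 200 ms after its trigger |
| `hep_placement_window` | [−1500, −600] ms | uniform trigger placement, half the trials |
| `erp_snr_db`, `hep_snr_db` | +3.3, −9.3 dB | calibration targets |
| `k` | in [−1, 1] | ERP–HEP amplitude coupling |

Amplitude coupling standardises both amplitude vectors by their *population*
parameters, mixes with weights `(k, √(1−k²))` and rescales by the HEP
population moments. Population (not sample) moments make `k = 0` an exact
identity and give the mixture unit variance for every `k`; the empirical
correlation between coupled HEP and ERP amplitudes converges to `k`.

Gaussian deflections use `σ = duration/6` and are truncated to the stated
duration, so >99.7% of the pulse mass lies inside its window; the peak falls
exactly on the centre sample. The stated 200 ms "start" of the pre-stimulus
deflection is interpreted as the pulse-peak latency after its own inserted
trigger — the HEP-like latency — because the trigger itself is placed
uniformly in the pre-stimulus window and a fixed post-stimulus start would
contradict that placement.

SNR is defined as `10·log10` of the mean power of the pulse waveforms (mean
squared amplitude over each pulse's duration, averaged over pulses) over the
mean background power, and calibration applies one multiplicative factor per
pulse set. The two stated targets are mutually consistent with the stated
amplitude distributions — both imply a background power near 7.3 µV² — so
calibrating each set independently preserves the amplitude ratios exactly.

The background is synthetic `1/f` noise (`generate_background()`), shaped to
the bandwidth of typical preprocessed EEG: flat below 0.3 Hz (emulating the
high-pass used for slow-component-preserving pipelines) and rolled off with
a 4th-order Butterworth magnitude at 45 Hz. `phase_randomize()` is retained
for users who want to build the background from their own recordings —
it preserves the amplitude spectrum bin-by-bin (hence all oscillatory
power and the total variance) while destroying evoked structure.

### What the generator does and does not emulate

It emulates: trigger structure, amplitude distributions, coupling, SNR, the
spectral *bandwidth* of preprocessed EEG, and (for the multichannel
validation fixtures) R-peak trains at realistic RR variability, a
two-component ECG template, CNV-like condition-specific ramps and genuine
heartbeat-locked condition effects. It does not emulate: volume-conducted
topographies, the cardiac field artifact, non-stationarities, or the true
spectral *composition* of any particular cohort's EEG — the synthetic
spectrum has no rhythmic peaks.

That last simplification has a quantitative consequence worth stating
plainly. The power of the whole pipeline is governed by the sorting
fidelity `ρ = cor(window-mean sorting amplitude, true ERP amplitude)`,
which depends on how much background power survives averaging over the
350 ms sorting window — essentially the sub-1.5 Hz power fraction. A `1/f`
spectrum concentrates ~40% of its power there, giving `ρ ≈ 0.34` and a
corrected-pipeline detection power of roughly 26–28% at `|k| = 1` under the
calibrated SNRs, where a background with a real cohort's spectrum can sit
substantially higher. Passing simulation tests therefore demonstrate the
*logic* of the controls (type-I control at `k = 0` in every arm, surrogate
gating of confounds, recovery of masked effects after correction, power
monotone in `|k|`), not the exact detection percentages any particular
dataset would give.

## The power study

`run_power_study()` sweeps coupling strengths and signs. Each repetition
assembles a fresh session, sorts trials by the 250–600 ms post-stimulus
window mean into high/low halves (median split; ties alternate into the
currently smaller group, so group sizes never differ by more than one),
and runs four arms: observed uncorrected, shuffled-trigger surrogate,
pseudotrial-corrected, and corrected surrogate. Detection power of an arm
is the fraction of repetitions whose maximum cluster statistic strictly
exceeds the 95th percentile of its surrogate arm's statistics — one
surrogate draw of each kind per repetition, so observed and surrogate
vectors are paired and equally long.

Problem sizes are configurable; the shipped analyses use 100 repetitions
per coupling cell (200 at `|k| = 1`) with 200 permutations per cluster
test on full-scale 422-trial sessions, and the group-level validation
studies use 8 subjects × 40 trials with 50 surrogate iterations and 100
permutations. Binomial 95% confidence intervals accompany every rate.

## Equivalence testing

For non-significant contrasts, `tost_equivalence()` runs two one-sided
paired t tests against ±SESOI, the smallest effect size of interest,
expressed as a standardised effect (default Hedges' g = 0.19, the lower
bound of meta-analytic HEP effects) and converted to raw units via the SD
of the differences. Equivalence is declared only when both one-sided tests
reject at α = 0.05; an observed effect exactly at the bound is declared in
~5% of runs (the boundary property the suite checks). `cohens_d()` and
`hedges_g()` (with the `1 − 3/(4·df − 1)` small-sample correction) report
the effect sizes themselves.

## Numerical and degenerate-input policy

Epoch windows are half-open in samples (`[tmin, tmax)`), so 800 ms at
250 Hz is exactly 200 samples and the locking event maps onto sample
`−tmin·fs`. Selection windows (R-peak eligibility, baseline, sorting
windows) are closed on both ends. An R-peak eligible for two stimuli is
assigned to the earlier one. Onsets are stored as 0-based integer samples;
conversions to ms always round half away from zero through one helper.
Rejection masks are never destructive and every average excludes rejected
trials. Subjects falling below the minimum-trial rule (default 20 epochs)
are excluded per comparison, never imputed. All randomness flows from one
master seed through named substreams, so sessions, shuffles and permutation
nulls are bit-reproducible; `--seed` on the command line reaches every
draw.

## Known limitations

The surrogate heartbeat gate itself has a second-order bias worth knowing
about: shuffling R-peak latencies smears any genuine heartbeat-locked
energy — including condition-*unspecific* HEPs — across the surrogate
epochs, where it raises the per-trial variance and slightly deflates the
surrogate t statistics. When heartbeat-locked amplitudes are large relative
to the background noise the gate therefore runs somewhat above its nominal
5% level. At realistic HEP-to-noise ratios (a microvolt or two against
10–20 µV EEG) the bias is negligible; in compact synthetic fixtures with
favourable ratios it can reach a few extra percentage points.

Neither control can address artifacts inherently time-locked to the
heartbeat (cardiac field artifact, pulse artifact): the surrogate shuffle
destroys their locking too, and the pseudotrial average does not contain
them. The Spearman-cluster ΔECG–ΔEEG correlation analysis
(`spearman_cluster_corr()`, minimum two neighbouring channels per cluster,
subject-permutation null) is the complementary check for such artifacts.
The LDA spatial filter uses an analytically shrunk within-class covariance
(Ledoit–Wolf-style intensity toward a scaled identity), which is the
standard remedy when channels outnumber what the trial count can estimate;
with very few trials the filter is still only as good as its class means.
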