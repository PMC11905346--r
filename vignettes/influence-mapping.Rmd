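---
title: "Influence mapping: model, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Influence mapping: model, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbmap)
```

# The measurement problem

Two-photon single-neuron photostimulation combined with population calcium
imaging asks a causal question of a cortical circuit: when one excitatory
neuron fires, what happens to the activity of every other imaged neuron?
The answer — the stimulated neuron's *influence map* — is the net,
network-level result of all direct and polysynaptic pathways leaving that
neuron. In layer 2/3, single-cell stimulation typically produces a narrow
central zone of positive influence on close neighbors and a broader, weaker
zone of negative influence ("suppressive surround") on more distant
neurons, and the relative spatial scales of these two zones differ between
sensory-level and association-level areas.

`perturbmap` implements the full analysis path for such experiments, and a
synthetic-session generator with known ground truth so that every stage can
be validated end to end.

# From fluorescence to activity

Raw somatic fluorescence is contaminated by surrounding neuropil; the
corrected trace is `f_raw - 0.7 * f_neu` (`neuropil_correct()`, scale
configurable). dF/F uses a slow percentile baseline: at each frame, the
baseline is the 8th percentile of the corrected trace over a window of 450
frames (about 15 s at 30 Hz) before and after that frame
(`delta_f_over_f()`). Two conventions are fixed for reproducibility:

* percentiles interpolate linearly between order statistics (R's type 7);
* baseline windows are truncated at the trace edges, not reflected —
  truncation never manufactures values that do not exist in the data.

A rolling-window percentile is quadratic if recomputed naively, so the
baseline is computed in C++ with an incrementally maintained sorted window
(one insertion and one removal per frame).

Deconvolution inverts the indicator's AR1 impulse response with coefficient
`exp(-1/(frame_rate * tau))` and zeroes events below 0.05 a.u.
(`deconvolve_ar1()`). This is a direct sparse inversion with a global decay
constant; per-neuron kernel optimization is deliberately out of scope. All
downstream analyses accept either trace and default to dF/F; the event
trace is used for tone responses, where fast onsets matter.

# The influence statistic

For each stimulation trial, a neuron's pre- and post-stimulus responses are
the mean activity over the 10 frames (333 ms) before the onset and the 10
frames after it (`align_trials()`). The onset frame itself — which contains
the 100 ms stimulation artifact — belongs to neither window. Influence is

> mean over trials of (post − pre), divided by the sample standard
> deviation (n − 1) of that difference across trials.

A zero standard deviation never produces a division by zero: the value is 0
when the mean difference is also 0, and the pair is flagged degenerate (and
excluded) otherwise.

Two windowing conventions circulate for the post-stimulus response — the
333 ms window matching the pre window, and a 1 s window. We default to the
symmetric 333 ms pair (it limits baseline noise and captures the bulk of
the evoked transient at 30 Hz) and expose `post_len` for the 1 s variant.

## Significance: the trial-shuffle null

Each (target, neuron) pair gets its own null distribution: the target's
onset set is replaced by an equal-size draw, without replacement, from the
pooled onsets of all *other* targets, and the statistic is recomputed
(`shuffle_null()`, 1000 shuffles by default). Resampling real stimulation
onsets — rather than arbitrary time points — preserves slow drift and the
temporal density of stimulation in the null. A pair is *positive* if its
observed influence strictly exceeds the 99th percentile of its null,
*negative* if below the 1st percentile. We use per-pair (not pooled) nulls,
since response variance differs strongly across neurons.

Two properties of this construction are worth knowing:

* With 1000 shuffles the estimated 99th percentile is itself noisy, so the
  realized false-positive rate is ~1.1% rather than exactly 1% (the usual
  order-statistic effect); the specificity check tolerates this.
* When influence is dense (a strong surround covering much of the field of
  view), the null for a given pair is shifted by the *other* targets' real
  effects on that neuron. On null sessions the pool is exchangeable and
  the rule calibrates exactly; on strongly suppressive synthetic sessions
  positive calls are mildly inflated. Real sparse data sits close to the
  calibrated regime.

## Target success and exclusions

A target counts as *successfully stimulated* when its own influence
statistic (its self pre/post response) is classified positive against its
own shuffle null — no success criterion is standard in this literature, so
this documented rule keeps success and significance on the same footing.
Only successful, non-control targets contribute records. Neurons within
25 µm of the target are flagged excluded (direct activation by the
stimulation spiral cannot be ruled out there) and carry no significance
class.

# Spatial structure

`centered_influence_map()` translates every target to the origin and
accumulates the relative positions of its significantly influenced
neighbors into 20 µm bins, normalized per targeted neuron; the map total
equals (influenced neurons)/(targets) exactly. Distance analyses use 50 µm
bins with edges at 25, 75, 125, ... µm, matching the exclusion radius;
`distance_binned_influence()` averages *all* retained pairs per bin, not
only the significant ones, so the profile estimates the underlying kernel
rather than a thresholded version of it.

`fit_center_surround()` fits a difference of Gaussians

\[
K(d) = A_c e^{-d^2/2\sigma_c^2} - A_s e^{-d^2/2\sigma_s^2}
\]

to a binned profile by weighted least squares (bin counts as weights,
multi-start L-BFGS-B under box constraints). The DoG is also the
generator's ground-truth kernel — the minimal two-scale family exhibiting a
center/surround structure — which makes parameter recovery a well-posed
test of the whole pipeline. In practice \(\sigma_c\) is recovered with a
modest (+15–25%) upward bias: the exclusion zone removes the innermost
samples, and normalizing by the trial SD compresses the largest responses
(stimulated spiking adds Poisson variance), flattening the measured center.
The surround width of a *weak* surround is poorly identified (its
amplitude is estimated far more stably), so cross-regime comparisons of
surround strength should use the fitted amplitude or far-distance mean
influence, not \(\sigma_s\).

When comparing the distance distributions of positively influenced neurons
between regimes with different positive-call rates, note that false
positives are uniform over the field of view (mean distance ≈ 230 µm in a
500 µm field) and dilute the group *mean* toward that value at different
strengths in the two regimes; the *median* tracks the true-positive mass
and is the robust ordering statistic.

# The population stimulus axis

For each target, the stimulus axis is the unit vector from the
population's trial-averaged prestimulus activity to its trial-averaged
response (`stimulus_axis()`), over all SOM and Non-SOM neurons at least
25 µm from the target. Unit normalization is our choice — no normalization
is standard — and makes weights comparable across targets and sessions.
Projections (`project_axis()`) subtract the prestimulus mean first, so
baseline activity projects to zero. `weights_by_distance()` summarizes the
positively and negatively weighted subsets by distance bin; these mirror
the single-pair influence analysis at the population level.

# Behavioral state

Locomotion is summarized per trial as the mean running speed over the 20
frames (660 ms) before each onset (`prestim_speed()`), split into
within-session quartiles (`assign_quartiles()`; cut points at the type-7
25/50/75 percentiles, boundary ties to the lower quartile). In sessions
where the animal is stationary half the time, quartile 1 is the stationary
set and interior quartiles can be empty — this is faithful to the
within-session definition, and comparisons use quartiles 1 and 4.
`influence_by_quartile()` recomputes the statistic on each quartile's trial
subset for pairs that were significantly positive over all trials;
significance is not re-assessed per quartile (quartile means are compared
with permutation tests instead).

# Noise correlations

Residual responses subtract each neuron's trial-averaged response to the
aligning target (`stim_aligned_residuals()`), removing every deterministic
target-locked component. A pair's noise correlation is the Pearson
correlation of the two neurons' residuals over all events on which that
target was *not* stimulated, so the direct stimulation response never
enters. The influence–noise-correlation relation is summarized per cell
type and distance class (near/far of 125 µm).

# Sound-frequency tuning

Tone responses are computed on z-scored activity (1 s tone window minus a
10-frame baseline, averaged per frequency over 4–32 kHz). Responsiveness
uses a sign-flip permutation test of the pooled per-trial differences at
α = 0.05 — the criterion is not standardized in the literature, so ours is
explicit and configurable. Tuning curves are Gaussians in log2 frequency
with the center bounded to the tested range [2, 5] log2-kHz and width to
[0.1, 4] octaves; 6-point fits need those bounds to stay sane. The best
frequency (BF) is the fitted center; `delta_bf()` is the octave distance.

`tuning_shuffle_test()` asks whether influence depends on tuning
similarity: the observed Pearson correlation between influence and ΔBF is
compared with 500 shuffles of the BF labels. Labels are permuted among the
neurons that *have* a BF, which preserves both the BF multiset and the pair
set in every shuffle. p is the fraction of shuffles at least as negative as
observed, floored at 1/500; negative correlations mean like-to-like
coupling.

# Statistical machinery

`permutation_test()` implements two-sided randomization tests for
differences in means: label permutation (unpaired) or sign flips of paired
differences, p = max(count, 1)/iterations, so the smallest reportable p at
the conventional 10,000 iterations is 0.0001. The effect size is Cohen's d
with the pooled SD — the literature this package serves reports an
unnamed standardized difference, and d is the conventional reading.
`bonferroni()` applies the family-wise threshold α/m.

# The synthetic-session generator

`generate_session()` emulates one field of view of the emulated protocol:
~200 Non-SOM and ~15 SOM neurons placed uniformly in a 500 µm square, 30
opsin targets plus 5 non-opsin controls drawn from the Non-SOM pool, every
target stimulated once per repeat block in pseudorandom order at a 1 s
interstimulus interval for 100 repeats, 30 Hz imaging. Spiking is Poisson;
rates multiply a baseline by a running-state gain and (1 + shared latent),
with one slow AR1 latent per cell type inducing noise correlations.
Stimulation adds, for 3 frames (100 ms), a direct drive to the target and
the DoG kernel to everyone else. Calcium is the AR1 convolution of spikes;
fluorescence adds per-neuron gain, Gaussian noise, and a 0.7 neuropil
fraction, so the preprocessing stage has real work to do. Running is a
two-state Markov process (mean bouts ~15 s stationary / ~12 s running,
log-normal bout speeds), which reproduces the bimodal stationary/locomotion
structure the quartile analysis assumes.

Magnitudes the underlying experiments do not publish are free parameters
with calibrated defaults, chosen once by pilot simulation and then frozen:

* `baseline_rate = 1` events/s — a typical spontaneous rate for layer 2/3;
* `direct_amp = 25` events/s for 100 ms — drives unambiguous target
  success, as the real protocol's power calibration does;
* `center_amp = 15`, `center_sigma = 50` µm, `surround_amp = 1`,
  `surround_sigma = 250` µm — at the protocol's trial counts these give a
  positive-call fraction near 8% (the sparse regime such experiments
  report) and make the pair-level kernel recoverable (Spearman correlation
  between ground-truth effect and measured influence ≈ 0.52–0.54). The
  cost of a *recoverable* surround is a negative-call fraction (~15%)
  well above the few percent seen in real data, where suppression sits
  closer to the detection floor: passing recovery tests here demonstrates
  correctness of the machinery, not that real surrounds are this strong.

Two preset regimes encode the qualitative area contrast the analysis is
designed to resolve: `ac_like_params()` (narrow center σc = 35 µm, wide
strong surround σs = 220 µm, state-independent, tone block with strong
like-to-like coupling 0.9 — weaker coupling is undetectable at desk-scale
pair counts, ~6k pairs vs ~70k in a real dataset) and `ppc_like_params()`
(wide center σc = 70 µm, narrow weak surround σs = 140 µm, running gains
1.3/1.8 for Non-SOM/SOM, network effects scaled by 0.35 during running).
Both presets couple the *center* amplitude to the product of the two
neurons' latent loadings (`corr_coupling = 1`), which produces the
empirical pattern that influence and noise correlation are related for
nearby pairs; coupling the surround as well would invert that relation.

What the generator does **not** emulate: optics and point-spread functions,
motion artifacts, plasticity across trials, spatial clustering of cell
types, pupil-linked arousal beyond locomotion, and realistic sparsity of
the suppressive surround (see above). Passing tests on synthetic sessions
therefore validates the estimators and their calibration — not any claim
about biology.

# Problem sizes and reproducibility

All randomness flows from explicit integer seeds: the generator seed fixes
the session bit-for-bit, and analysis seeds fix the shuffle and permutation
draws, so every pipeline run is exactly reproducible. The test suite
exercises the full protocol scale where the property demands it (null
specificity: 200 neurons × 35 targets × 100 repeats with 1000 shuffles;
parameter recovery: one AC-like and one PPC-like session at the same
scale) and small sessions everywhere else; statistical calibration uses
2000 null permutation runs and 200 shuffle-test replicates. The
`scripts/acceptance.R` entry point re-derives the specificity benchmark
from scratch for any seed.

# Known limitations

* The AR1 deconvolution uses one global decay constant; per-neuron kernel
  estimation would change event magnitudes (dF/F analyses are unaffected).
* σc recovery carries the systematic +15–25% bias described above; the fit
  is a comparative tool, not an unbiased kernel estimator.
* The shuffle null inherits each session's real stimulation density; with
  very few targets the pool is small and thresholds are coarse.
* Quartile analyses require enough trials per quartile per target (< 2 are
  skipped); heavily locomoting sessions can starve quartile 1.
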