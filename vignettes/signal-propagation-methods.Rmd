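---
title: "Methods: from stimulation-response calcium imaging to a signal-propagation atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from stimulation-response calcium imaging to a signal-propagation atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sigprop` turns single-neuron stimulation experiments with whole-brain
calcium imaging into a statistical atlas of functional connectivity, fitted
signal-propagation kernels, and network-level simulations that can be
compared against connectome-constrained predictions. This vignette explains
the models and procedures, the tunable parameters, and the design choices
made where the methodology was genuinely open.

## The experimental design being modelled

One neuron at a time is optogenetically stimulated (one randomly chosen
target every 30 s, stimuli of 0.3-0.5 s) while nuclear calcium indicator
fluorescence is recorded across the brain at 2 volumes/s. An ordered neuron
pair (j, i) is characterized by the responses of downstream neuron i in the
30 s after stimulations of j. Control recordings without any stimulation
provide empirical null distributions. Because downstream responses reflect
propagation over *all* network paths, the measured connections are
*effective*, not monosynaptic.

## Calcium pre-processing

Five fixed stages, in order:

1. **Missing-value interpolation** (`interpolate_missing`). Interior gaps
   linear, edge gaps held at the nearest present value. This is the only
   non-causal stage.
2. **Photobleach correction** (`correct_photobleach`). A double exponential
   `b(t) = a1 e^(-t/tau1) + a2 e^(-t/tau2)` is fitted to each trace's
   baseline and divided out, preserving the initial value. The baseline is
   isolated by iteratively reweighted least squares that down-weights
   samples more than one residual SD above the running fit (weight 0.02),
   because calcium transients are positive excursions. Four reweighting
   iterations are used; a failed fit falls back to a single exponential and
   is flagged. The outlier SD of stage 3 is computed *after* this stage
   because bleaching inflates the raw SD.
3. **Outlier removal** (`remove_outliers`). Samples more than 5 SD from the
   per-trace mean are marked missing and re-interpolated, with one
   re-estimation pass. Constant traces pass through untouched.
4. **Causal smoothing** (`smooth_causal`). Savitzky-Golay, window 13
   samples (6.5 s at 0.5-s sampling), polynomial order 1, evaluated at the
   window's final position so the filter is entirely "in the past" and
   cannot smear response onsets earlier in time. The first 12 samples use
   shrunken causal windows of the same form rather than being discarded.
   Smoothed traces serve display and statistics; all kernel fits run on the
   unsmoothed output of stage 3.
5. **Windowed dF/F0** (`response_window`). F0 is the mean fluorescence over
   the 30 s before the stimulus; dF/F0 = (F - F0)/F0 over t in [-30, +30) s.

The temporal second derivative used by the classifier and the statistics is
estimated with the same causal 13-sample window at polynomial order 2
(`second_derivative`), exact on quadratics, in units of 1/s^2.

## Inclusion criteria

A stimulation event enters the analysis only if the stimulated neuron shows
an *autoresponse*: dF/F0 above an amplitude threshold **and** |second
derivative| above a derivative threshold, jointly, for a contiguous 4 s of
the post-stimulus window (`detect_autoresponse`). The two-threshold rule is
read as *jointly* contiguous — the stricter of the two possible readings.
Published descriptions of such classifiers set thresholds "to match human
perception" without numeric values; here the defaults are amplitude 0.1
(dF/F0) and derivative 0.002 s^-2, the latter chosen as three times the
null SD of the causal second-derivative statistic under the generator's
default noise; `calibrate_thresholds()` recomputes it for any control set.
Downstream traces are excluded when a contiguous missing segment exceeds 5%
of the response window, or when unlabeled. A special override for
stimulation targets too dim to yield their own trace admits downstream
windows without an upstream trace but excludes dF/F0 > 2 (numerical
baseline artifacts).

## Statistical framework

Per observation, two summaries are computed over the post-stimulus window:
the mean dF/F0 and the maximum |second derivative|. Working with
per-observation summaries rather than pooled time points keeps the
Kolmogorov-Smirnov test calibrated (pooled samples are autocorrelated and
anticonservative).

- **Null distributions** (`build_null`): pseudo-stimulation times on the
  real schedule (every 30 s) applied to control recordings; summaries
  pooled across neurons and pseudo-events. Their SDs are the sigma of the
  equivalence margin.
- **Connection test**: two-sided two-sample KS tests of the pair's
  summaries against the null samples, one per summary
  (`ks_pair_pvalues`); the two p-values are fused by Fisher's method with
  4 degrees of freedom (`fisher_combine`; the independence assumption is
  inherited and documented, not corrected), and q-values are computed with
  the Storey-Tibshirani estimator (`storey_qvalues`): pi0 from the lambda
  grid 0, 0.05, ..., 0.90 with a cubic smoother (`smooth.spline`, df = 3)
  evaluated at lambda = 0.90, clipped to (0, 1].
- **Equivalence test** (`tost_pair_pvalue`): two one-sided Welch t-tests of
  the pair mean against the null with margin epsilon = 1.2 sigma per
  summary (p_eq = max of the two one-sided p-values), the two summaries
  fused by Fisher, and q_eq again by Storey-Tibshirani. The 1.2-sigma
  margin is deliberately conservative; with n_obs < 2 equivalence is never
  claimed (p_eq = 1).
- **Labels** (`classify_pairs`): *connected* iff q < 0.05;
  *non-connected* iff q_eq < 0.05 and q >= 0.05; otherwise *undetermined*.
  The two labels are mutually exclusive by construction.
- **Extrasynaptic screen** (`extrasynaptic_screen`): pairs connected in the
  wild-type atlas (q < 0.05), equivalent to null in the
  dense-core-vesicle-release-deficient mutant (q_eq < 0.05), with the
  additional guard q(mutant) > 0.05 to exclude small-but-significant
  mutant responses.

## Kernel algebra and fitting

A propagation kernel k(t) maps upstream to downstream activity by
convolution. It is parametrized as a sum of at most two chains of convolved
causal decaying exponentials; convolutions are carried out *symbolically*
using four closed-form rules on terms of the form a θ(t) t^n e^(-γt), so
evaluation is exact (verified against trapezoid numerical convolution to
better than 1e-6 relative error). Two chains of opposite sign represent
saturating transmission. Equal rates are detected by exact comparison:
equal-rate and distinct-rate chains are distinct model classes during
fitting, which avoids the numerically unstable limit of the distinct-rate
rule.

`fit_kernel` minimizes squared error of `downstream - k * upstream` on the
raw post-stimulus window, with chain counts 1-2 and chain lengths 1-3
compared by AICc, rates bounded in [1/60, 10] s^-1 (set by the 30-s window
and 0.5-s sampling), L-BFGS-B from log-spaced rate initializations, and no
regularization. Chain-length increases cannot worsen the training fit;
overfitting is controlled only through the number of summed chains. When
the downstream neuron fails response detection the kernel is zero by
convention; the zero model also competes in selection.

**Rise time** (`rise_time`): saturation terms (chains whose integral
opposes the dominant chain's sign) are removed first, because a saturating
second term shifts the apparent peak later and masks instantaneous
transmission; the rise time is then the interval from the earliest time |k|
reaches 1/e of its peak to the peak, zero if the peak is at t = 0.

**Stereotypy** (`stereotypy`): all round-robin pairs of a connection's
single-trial kernels are convolved with common stimulus inputs; the mean
Pearson correlation of the outputs over pairs and stimuli measures
trial-to-trial consistency.

## Kernel-based and anatomy-based network simulation

`predict_correlations` drives one neuron at a time with an activity
transient, computes every other neuron's response through the
trial-averaged kernels (pairs with q > 0.05 carry the zero kernel),
correlates the resulting activities, and averages the per-drive correlation
matrices over the drive set. `select_top_n` chooses drivers by greedy
forward selection against a target matrix (ties broken by label order); the
greedy choice is one of several reasonable readings of "top-n" selection
and is deterministic and O(n N) in evaluations.

The anatomy route (`biophys_simulate`) integrates a standard
leaky-integrator model: C dV_i/dt = -G_l(V_i - E_l) - Σ_j g_gap Gap_ij (V_i
- V_j) - Σ_j g_syn Chem_ij s_j (V_i - E_rev(sign_ij)) + I_i, with graded
synaptic activation ds/dt = a_r φ(V)(1 - s) - a_d s and logistic φ.
Defaults (all exposed in `biophys_params`): capacitance 1 pF, leak 10 pS at
-35 mV, 100 pS per gap contact and per synapse, a_r = 1 s^-1, a_d = 5
s^-1, slope 0.125 mV^-1, excitatory/inhibitory reversals 0/-70 mV, and the
sigmoid midpoint solved per neuron so activation is half-maximal at rest —
conventional values for small-nervous-system modelling. The resting state
is solved algebraically (linear system at φ = 0.5), so simulations start
exactly at equilibrium; integration uses lsoda with tight tolerances
(1e-10) because gap junctions make small circuits stiff. Peak |ΔV| with its
excursion sign forms the response matrix (`dv_response_matrix`); 0.1 V is
exposed as the "large response" threshold. `fit_weights` re-optimizes
signed edge weights against measured amplitudes under the wiring mask
(absent edges stay zero), and `r2_agreement` reports the through-origin
slope and R^2 (which may be negative). Polarity tables are aggregated
across bilateral subtype members by majority with ties and absences
excitatory (`assign_polarities`). Multiple connectomes are combined by
arithmetic mean after per-dataset total-count normalization — a minimal
reading of "scaled average" (`average_connectomes`).

Hop distances (`hop_distances`) compose the binarized union of chemical and
gap edges iteratively — a pair is connected at n hops if unconnected at
fewer but connected through an intermediate — which equals
breadth-first-search distance and is tested against an independent graph
library on exhaustive 3-node digraphs (all 64) and randomized larger ones.
Exhaustive enumeration much beyond n = 3 is combinatorially impossible
(2^(n(n-1)) digraphs), so coverage above that is randomized.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested:

- **Schedule and acquisition**: dt = 0.5 s, one target per 30-s interval,
  0.5-s stimuli (0.3 s in the mutant-like condition), 30-min default
  recordings.
- **Autoresponse**: a double-exponential transient (rise 1 s, decay 8 s)
  normalized to peak dF/F0 = 1 — "modest" responses of
  calcium-indicator phenomenology, and a shape that keeps kernels
  identifiable.
- **Edges**: random directed graph of configurable density; kernels with
  rates log-uniform in [0.05, 1] s^-1, 25% saturating, 11% inhibitory by
  default (the measured inhibitory fraction among connected pairs);
  inhibition is negative-going dF/F0 on a tonic baseline, since inhibition
  is only observable in tonically active neurons. Edge DC gains are drawn
  uniformly from a configurable band; the generator *rejects* networks
  whose DC-gain spectral radius reaches 1 (unstable as linear systems).
  The pipeline-level default band (0.3-0.7) makes downstream responses
  comparable in amplitude to autoresponses, as observed for connected
  pairs; small desk-scale networks remain stable at that strength.
- **Trial variability**: each edge transmits per stimulation with
  probability `response_probability` (default 0.7), emulating downstream
  neurons that respond to some upstream stimulations but not others.
- **Nuisances**: multiplicative double-exponential photobleaching,
  i.i.d. Gaussian sensor noise (default SD 1 on a baseline of 100, i.e.
  1% dF/F0), 2% randomly missing samples.
- **Propagation**: by default downstream responses come from direct
  ground-truth kernels only (no recursive re-propagation), keeping
  per-pair ground truth interpretable for recovery tests; an optional
  linear-network mode propagates recursively and realizes effective
  (all-paths) semantics.
- **Controls**: identical generative model with an empty stimulation log.
  How many control recordings an experiment needs is a configuration
  choice, not an empirical fact; defaults use two 30-min controls.
- **Connectome**: wired (non-extrasynaptic) functional edges receive
  synapse counts 1 + Poisson(3) *independent* of kernel gain — bare
  anatomical weights are empirically poor predictors of functional
  strength, and the generator reproduces that property — plus
  configurable anatomical-only edges and symmetric gap junctions.
  Extrasynaptic functional edges are absent from the connectome by
  construction.
- **Spontaneous activity** (`simulate_spontaneous`): the linear kernel
  network driven by independent Gaussian drive, with a small set of
  intrinsically active driver neurons (default 3) and weak background
  drive elsewhere — spontaneous dynamics dominated by a few neurons, the
  same property that makes top-n driver selection effective.

What passing tests on this generator do *not* show: robustness to motion
and segmentation artifacts, non-Gaussian sensor noise, nonlinear dendritic
integration, state-dependent kernels, or neuron-identification errors —
none of which the generator emulates.

## Problem sizes and numerical choices

Tests and the acceptance script run at desk scale chosen for statistical
interpretability: null distributions from 20-neuron control recordings
(several thousand pseudo-observation summaries), 500-600 simulated pairs
with 10 observations each for calibration checks, 12-neuron networks with
20 seeded replicates for the end-to-end ordering comparison, 100 random
kernels for the symbolic-numeric equivalence bound (1e-6 relative on a
1-ms grid), and 30-neuron digraphs for the hop-distance checks. Stage
tolerances: deterministic pre-processing stages are idempotent to 1e-9;
ODE integration at 1e-10; kernel-fit convergence is bounded by 300
L-BFGS-B iterations per start.

On the end-to-end ordering comparison (fitted-kernel prediction vs
biophysical anatomy model vs bare counts): at 12 neurons the agreement
statistic is computed from 66 matrix entries and has a sampling SD of
roughly 0.1; the kernel route wins in the clear majority of replicates,
but the strict double ordering in 90% of replicates is at the edge of what
these network sizes support. The atlas-scale margins rest on hundreds of
neurons and tens of thousands of pairs, which desk-scale replicates cannot
reproduce; the test records the realized frequency honestly rather than
relaxing the comparison.

## Known limitations

- In small dense synthetic networks a neuron's own recent responses often
  overlap the 30-s pre-stimulus baseline of a later event; the inflated F0
  produces negative dF/F0 windows that the KS machinery correctly flags as
  departures from the no-stimulation null. This baseline carry-over is a
  property of rapid revisiting schedules, mild at atlas scale where a given
  neuron is revisited rarely, and visible at desk scale.

- Fisher's fusion assumes independence of the amplitude and derivative
  p-values; the two summaries are correlated in practice, making the fused
  p mildly anticonservative. The q-value calibration test bounds the
  realized false-discovery proportion under the study conditions.
- The TOST margin 1.2 sigma is a convention; equivalence calls are only
  meaningful relative to it.
- Kernel fitting assumes linear time-invariant transmission per trial;
  saturation is representable, but slow adaptation across trials is not.
- The biophysical model is point-neuron and graded; it is a comparison
  baseline, not a biophysically complete simulation.
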