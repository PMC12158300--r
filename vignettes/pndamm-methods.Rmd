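---
title: "Modeling neurofeedback brain-state dynamics with pndamm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neurofeedback brain-state dynamics with pndamm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Alpha-suppression neurofeedback training (NFT) asks a participant to
hold their Pz alpha-band (8–12 Hz) power below 60% of a resting
reference across 10 runs of 134 s per session. `pndamm` models the
per-run brain state as a discrete linear dynamical system,

$$x_k = A_{k-1}\,x_{k-1} + w_{k-1}, \qquad z_k = H\,x_k + v_k,$$

under the working assumption that within one session the task is
constant, so $A_k \equiv A$. The state $x_k$ is a structured object:
four Spearman-correlation blocks over seven harmonized channels — the
motor-cortex subnetwork `mc` (C3, Cz, C4), the left-occipital subnetwork
`loc` (P7, Pz, PO3, Oz), the cross block `mc_loc`, and the mesoscale
network `mnet` over region-pooled series (LMC = mean of C3 and Cz,
RMC = mean of C4 and Cz, LOC = mean of P7, Pz and Oz). Every block of
$A$ left-multiplies the matching state block, so the `mc_loc` transition
is a 3×3 map acting on the 3×4 cross block; its linearized layout
(row-major `mc`, `loc`, `mc_loc`, `mnet`; 9+16+9+9 = 43 weights) is the
coordinate system for all losses and statistics.

The measurement side ($H$, $v_k$) is not materialized as a matrix:
ICA-based artifact removal followed by network construction plays its
role. The control-input terms of the general form are fixed at zero
(the protocol never changes within a session).

Two documented montage asymmetries are worth stating: the LOC
*subnetwork* carries four channels (Pz–PO3 weights are part of the
statistics) while LOC *pooling* for the mesoscale network uses only
P7, Pz and Oz; both sets live in `region_scheme()` and are
configurable. "Pooling" is the sample-wise arithmetic mean; one
network is computed per full run (no sliding windows).

## Noise adaptation

The per-transition least-squares estimates
$\hat A_k = x_k\,\mathrm{pinv}(x_{k-1})$ disagree across $k$ when
process noise is present; the covariance loss

$$f_1 = \frac{1}{43}\sum_{p=1}^{43}\operatorname{Var}_k\!\big(\mathrm{vec}(\hat A_k)_p\big)$$

(the trace of the 43×43 covariance divided by 43 — order-free and
shape-agnostic) measures that disagreement. `pnda_fit_session()`
iterates:

1. denoise: $\tilde x_k = x_k - b_0 - \hat w_{k-1}$;
2. re-estimate all transitions and the joint (consensus) least-squares
   transition over the chain;
3. propose the fuzzy update
   $\hat w(j{+}1) = \theta_1(\Delta f_1)\,\hat w_{\mathrm{cand}}(j)$,
   where the candidate direction is the residual of each state against
   the consensus prediction from the *corrected* previous state
   (residuals propagated sequentially, so a full step makes the
   denoised chain exactly consistent with the consensus transition —
   one-step residuals frequently increase $f_1$, which is why they are
   not used);
4. accept only if $f_1$ does not increase; otherwise halve the gain
   and retry once, then stop.

$\theta_1$ is a minimal triangular-membership fuzzy rule over the
relative loss change: categories improving / flat / worsening with
default gains 1.2 / 1.0 / 0.7, membership half-width `delta_width`
(default 1e-3 on the relative scale), defuzzified by the
membership-weighted mean and clamped to `theta_bounds` (default
[0.5, 1.5] ⊂ (0, 2)). The functional form is a design choice — the
source method states only that an adaptive weight function exists — and
the defaults were fixed once, before any acceptance measurement.
Accepted $f_1$ trajectories are non-increasing by construction; a
numerical floor of 1e-24 marks already-consistent (noiseless) chains as
converged immediately; a fit aborts with a diagnostic if $f_1$ exceeds
ten times its initial value.

The session bias $b_0$ enters the model additively in the update rule.
A literal re-addition of $b_0$ inside every $w$ update would accumulate
it across iterations, so it is treated as a session-level state offset
subtracted once at denoising ($\tilde x_1 = x_1 - b_0$ included).

## Session alignment

Across sessions, $f_2$ is the mean pairwise Euclidean distance between
per-session mean linearized transitions. A shared additive offset
between groups of sessions appears in the per-session mean-state
deviations from the grand mean. Estimating each session's bias from
these deviations is delicate: the deviations are dominated by
session-specific random structure (mostly the random initial state),
and subtracting that structure *increases* $f_2$ — we verified this
empirically for the raw deviation, its leading-PC projection, and a
regression-intercept estimate $(I-A)^{+}C$ (the last explodes because
$I-A$ is nearly singular for near-identity dynamics).
`align_sessions()` therefore (1) clusters sessions by the sign of their
score on the dominant deviation mode, (2) takes each session's
*cluster-mean* deviation as its bias direction (the shared-offset
estimate; session-specific structure stays untouched), (3) runs a
greedy per-session backtracking line search over scales (1, 0.5, 0.25,
0.1) accepting only strict $f_2$ decreases, and (4) rescales the
accepted biases jointly by $\theta_2(\Delta f_2)$ while $f_2$ keeps
falling. The line search exists because the bias-to-$f_2$ map is steep
and nonlinear: a full-scale correction can overshoot even along a
helpful direction.

## Synthetic data: the stated world

The clinical recordings behind the source study are not deposited, so
the generator emulates the stated paradigm at two levels.

*Network level* (`simulate_network_chain`): exact dynamics
$x_k = A x_{k-1} + w_{k-1}$, $w$ i.i.d. Gaussian per entry
(`process_noise_sd`, default 0.01), $x_1$ a shrunk-Wishart random
correlation structure, stored states clipped to $[-1, 1]$ *after*
noise injection with the pre-clip truth recorded. The default
ground-truth transitions are fixed constants, not random draws: resting
is a near-identity contraction (diagonal 0.95 plus a small fixed
non-symmetric mixing); NFT scales the MC diagonal by 0.5 (exactly half
the resting weights), the LOC diagonal by 0.7, and the mesoscale
diagonal by (0.6, 0.5, 0.7) for (LMC, RMC, LOC) — suppression strongest
in RMC — while the MC–LOC cross block is identical across conditions
(no training effect there). The `separation` knob scales all of this;
it is a free parameter of the stated world, not calibrated to any
clinical effect size, because no effect size is reported for how
strongly training alters $A$.

*Signal level* (`simulate_eeg_run`): seven independent unit-variance
temporal processes — a broadband AR(1) ($\phi = 0.9$) mixed with a
resonant alpha AR(2) (poles at 10 Hz, radius 0.97) — are coupled
through a square root of the Pearson-warped target network
($r = 2\sin(\pi\rho_s/6)$, so the *Spearman* network converges to the
target without the Gaussian-copula bias). Because all channels share
one spectrum, the alpha mix does not perturb the cross-channel
correlations. The alpha variance fraction drops from 0.5 (resting) to
0.15 (NFT), which puts the Pz alpha-power ratio near 0.4–0.5, safely
below the 0.6 feedback threshold — emulating *successful* regulation;
per-channel alpha topography, eye/muscle artifact waveforms, device
filters and nonstationarity are deliberately not modeled. A green
signal-level test therefore establishes that the pipeline recovers
correlation structure and alpha suppression from stationary Gaussian
surrogates — not that it handles real EEG artifacts.

A note on chain decay: with contraction dynamics the states shrink
geometrically, and NFT chains (spectral radius ≈ 0.5 in MC) approach
the noise floor within a session. Raw per-transition estimates on such
states are wildly unstable (initial $f_1$ in the hundreds); the
consensus estimate, which weights transitions by state magnitude, stays
accurate. Parameter-recovery acceptance is measured on
resting-condition chains for this reason — they keep signal throughout
the chain; NFT recovery at the same noise level is additionally
exercised in unit tests.

## Preprocessing

Fixed stage order, recorded in provenance: polyphase resample to 250 Hz
(Kaiser-windowed sinc, β = 5) → zero-phase 8th-order Butterworth
bandpass 0.5–38 Hz (analog prototype, prewarped bilinear transform,
second-order sections; forward–backward with odd-reflection padding
sized to the slowest pole's decay, 9/(1−r) samples) → common average
reference over the seven electrodes, optionally retaining an explicit
zero reference channel to preserve matrix rank → FastICA artifact
removal → channel alignment (8-channel montage: PO3 := mean(P3, O1)) →
134-s segmentation (half-open intervals, seconds in files, invalid
annotations dropped) → 0.5-s baseline correction → per-channel
z-scoring pooled within session. Only the harmonization filter is
applied in-pipeline; device-native filters are treated as properties of
the input.

ICA is FastICA (tanh contrast, symmetric decorrelation, seeded
initialization) rather than extended infomax: it is deterministic for a
fixed seed, a few dozen lines, and the automated rejection rules —
ocular if the below-4 Hz power fraction exceeds 0.6, muscular if the
above-20 Hz fraction exceeds 0.6 — depend only on the recovered
sources, not on the contrast function. The thresholds are exposed in
`ica_criteria()`; the source study does not report its values.
`n_components = "full"` errors on rank-deficient input (naming the
rank); the pipeline default is `"auto"` because reference-retaining CAR
deliberately produces an (n+1)-channel rank-n matrix.

## Classification and statistics

Transitions become 4-channel 4×4 tensors (blocks zero-padded
bottom-right; packing is lossless). The CNN is the smallest
architecture honoring the stated 2-conv/2-pool/2-FC structure on 4×4
inputs: 2×2 kernels with same padding, 8 then 16 channels, 2×2 max
pooling (4×4 → 2×2 → 1×1), a 32-unit hidden layer and a 2-way softmax,
trained with Adam (lr 0.01, batch 64, early stopping on validation
loss, patience 25), implemented with im2col matrix algebra and verified
against numerical gradients. Splits are session-level 7:1:2 with the
floor-remainder rule (test = ⌊0.2n⌋, val = ⌊0.1n⌋, train = rest), and
the partition-disjointness (no-leakage) property is asserted in tests.

The shuffled-label control deserves a note. Naively shuffling *training*
labels does not produce chance-level test accuracy here: the synthetic
feature space forms two tight clusters, and a flexible model aligns
them with whichever majority a finite shuffle leaves, making test
accuracy bimodal near 0 and 1 rather than binomial around 0.5.
`shuffled_label_control()` instead permutes the chain labels globally
*before* the split and evaluates against the permuted test labels — the
standard permutation test — under which accuracy is binomial around 0.5
whatever the classifier does.

Weight statistics use Welch's two-tailed t-test per linearized position
(pooled-variance mode available), one observation per transition per
session, with Shapiro–Wilk and Levene assumption checks, step-up BH-FDR
at q < 0.05, and NFT/resting mean-weight ratios at significant
positions. Ratio confidence intervals come from a *cluster* bootstrap
that resamples sessions, since transitions within a session are
dependent (a row-level bootstrap yields CIs narrow enough that a 0.1%
estimator bias excludes the true ratio). Presentation matrices follow
the zero-fill convention: 0 marks "no significant difference".

## Numerical choices and degenerate inputs

* Pseudoinverse tolerance: singular values below 100·eps relative to
  the largest are dropped; an all-zero previous-state block is an
  unidentifiable transition and errors.
* Spearman ties use average ranks (bit-reproducibility).
* JSON archives serialize doubles with 17 significant digits so
  round-trips are bit-exact.
* Degenerate t-test positions (zero variance in both groups) are
  flagged: p = 1 when the means agree, undefined otherwise; NA p-values
  pass through BH unrejected.
* Zero-amplitude signal configurations and unstable (spectral radius
  ≥ 1) AR generators error before generating anything.
* All randomness is seed-derived; chains, fits, splits, training and
  bootstraps are reproducible bit-for-bit under a fixed seed and BLAS
  configuration.

## Known limitations

The dynamics model is linear with a constant per-session transition;
nonlinear or time-varying effects are out of scope by design. The
generator's stationary Gaussian signals cannot probe robustness to real
artifacts, and its effect size is a stated constant rather than a
clinically calibrated one — end-to-end accuracies near 1.0 on synthetic
data say the pipeline is correct, not that the method would reach the
source study's clinical accuracy. EDF input is not supported (no EDF
library in the supported dependency set); recordings exchange as CSV
with a JSON sidecar.
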