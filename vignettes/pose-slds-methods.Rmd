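---
title: "Segmenting animal pose trajectories into behavioral syllables: model and methods"
author: "poseSLDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting animal pose trajectories into behavioral syllables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Markerless pose trackers turn behavioral video into per-frame coordinates of
a handful of anatomical keypoints, each with a detector confidence. Rodent
behavior is organized into brief, stereotyped motifs ("syllables") that
recur with sub-second cadence, but keypoint time series mix three things:
the animal's pose, its location and heading, and tracker noise whose
magnitude varies wildly from frame to frame. Naive clustering of keypoint
features confuses all three. poseSLDS implements a switching linear
dynamical system (SLDS) that separates them explicitly and segments the
pose dynamics into syllables by Gibbs sampling.

## The generative model

Observed coordinates $Y_t \in \mathbb{R}^{K\times D}$ ($K$ keypoints,
$D\in\{2,3\}$) are a rigid transform of a centered, oriented pose:
$$Y_t = \tilde Y_t R(h_t) + \mathbf{1}_K v_t^\top, \qquad
\operatorname{vec}(\tilde Y_t) \sim
\mathcal N\big((\Gamma \otimes I_D)(C x_t + d),\, S_t\big),$$
where $v_t$ is the centroid (Gaussian random walk with per-frame variance
$\sigma^2_{\mathrm{loc}}$), $h_t$ the heading (uniform prior), and
$\Gamma \in \mathbb{R}^{K\times(K-1)}$ an orthonormal basis of the
zero-mean subspace, so the expected pose is always centered. The latent
pose $x_t \in \mathbb{R}^M$ follows a lag-$L$ vector autoregression whose
parameters $(A_i, b_i, Q_i)$ switch with a discrete syllable label
$z_t \in \{1..N\}$:
$$x_t \mid z_t \sim \mathcal N\!\big(A_{z_t} x_{t-L:t-1} + b_{z_t},
Q_{z_t}\big),$$
with a matrix-normal inverse-Wishart (MNIW) prior on $[A_i|b_i], Q_i$. The
syllable sequence is a sticky HDP-HMM in the weak-limit approximation:
$$\beta \sim \mathrm{Dir}(\gamma/N, \ldots), \qquad
\pi_i \mid \beta \sim \mathrm{Dir}(\alpha\beta_1, \ldots,
\alpha\beta_i + \kappa, \ldots, \alpha\beta_N),$$
where $\kappa$ (the "stickiness") controls syllable durations. Keypoint
noise is heavy-tailed: the observation covariance
$S_t = \mathrm{diag}(\sigma_1^2 s_{t,1}, \ldots, \sigma_K^2 s_{t,K})
\otimes I_D$ combines a per-keypoint baseline $\sigma_k^2 \sim
\chi^{-2}(\nu_\sigma, \sigma_0^2)$ with a per-frame scale
$s_{t,k} \sim \chi^{-2}(\nu_s, s_{0,t,k})$ — a Student-t observation model
in disguise. The prior scale $s_0$ is tied to the detector confidence by
the logistic curve $s_0(c) = 1 + 100(1 + e^{20(c-0.4)})^{-1}$, so
low-confidence detections are automatically down-weighted and effectively
re-inferred from the model.

## Hyperparameters

Defaults (see `defaultHyperparams()`): $N = 100$, $\gamma = 1000$,
$\alpha = 100$, $L = 3$, $\nu_0 = M + 2$, $S_0 = 0.01 I_M$,
$M_0 = [\,0 \mid I_M \mid \mathbf 1\,]$ ("copy the last pose"),
$K_0 = 10 I_{LM+1}$, $\sigma_0^2 = 1$, $\nu_\sigma = 10^5$ (pinning
$\sigma_k^2 \approx 1$ by design), $\nu_s = 5$,
$\sigma^2_{\mathrm{loc}} = 0.4$ squared length units per frame. $M$ is
chosen by the PCA explained-variance criterion (90%). $\kappa$ has no
universal default: it is calibrated per dataset so the median syllable
duration is 400 ms (`calibrateKappa()`), the characteristic sub-second
timescale of rodent behavior. Two conventions needed pinning down: the prior-mean dimensions only make sense as
$M_0 = [0_{M\times M(L-1)} \mid I_M \mid \mathbf 1_{M\times 1}]$ with
$K_0 = 10 I_{LM+1}$, and the prior variance $\sigma_C^2$ of the loading
$(C, d)$ is never given a value — we default to 10, which is immaterial
because $(C, d)$ stay fixed at their PCA initialization (the protocol's
default).

## Fitting protocol

Phase 1 (`fitARHMM()`): coordinates below confidence 0.5 are interpolated
linearly, jittered with Uniform($-0.1, 0.1$) noise to avoid degeneracy on
interpolated stretches, egocentrically aligned (centroid = unweighted
keypoint mean; heading = posterior-to-anterior axis angle), and projected
with whitened PCA. An AR-HMM is Gibbs-sampled on this *fixed* trajectory:
states, transitions, and AR parameters only. Phase 2
(`fitKeypointSLDS()`): the full model — including $x$, $v$, $h$, $s$,
$\sigma^2$ — is initialized from phase 1 and fit on the *original*
(uninterpolated, unjittered) coordinates for a fixed number of sweeps
(500 by default; convergence is monitored via the log joint, never
auto-detected). `applyModel()` re-infers latents on new or ablated data
with all parameters frozen, which keeps syllable labels comparable across
runs. Ensembles of fits are ranked by the expected marginal likelihood
score (`emlScores()`): the average log marginal density of the other
fits' pose trajectories under each fit's dynamics, discrete states summed
out by the forward algorithm. We define the prefactor of this score as $1/(N-1)$, so that consensus-like fits
score *highest* — the stated semantics.

## Gibbs sampler: design choices

All conditionals are standard conjugate or linear-Gaussian updates; the
order of one sweep is $z \to (\pi,\beta) \to (A,b,Q) \to x \to h \to v
\to s \to \sigma$. Implementation choices that matter numerically:

* **Discrete states.** Forward filtering–backward sampling per recording,
  with per-step normalization (equivalent to log-space message passing but
  cheaper); implemented in C++. The initial state of each recording is
  uniform.
* **Continuous trajectories ($x$ and $v$).** Both conditionals are joint
  Gaussians with block-banded precision. Rather than running a stacked-state
  Kalman filter–smoother — whose companion-form noise matrix is singular by
  construction and needs special-casing — we assemble the banded precision
  (AR factors couple each window $x_{t-L:t}$; emissions add
  $\sum_k w_{tk} B_k^\top B_k$ per frame) and draw exactly via sparse
  Cholesky. This is the same conditional, avoids the singular blocks
  entirely, and is validated against dense joint-Gaussian oracles in the
  test suite.
* **Headings.** Exact von Mises conditional per frame (Best–Fisher
  rejection sampler); zero concentration falls back to a uniform draw.
* **Scales and variances.** Scaled inverse-chi-squared conditionals, drawn
  through the inverse-gamma equivalence.
* **Transitions.** The weak-limit auxiliary table-count (Chinese
  restaurant) scheme with the binomial stickiness-override correction,
  then Dirichlet draws for $\beta$ and each row of $\pi$. $\gamma$ and
  $\alpha$ stay fixed at their defaults; we do not resample them.
* **Boundary convention.** The AR history is zero-padded at recording
  starts — this is the model definition, used consistently by the $x$
  sampler, the likelihood table, and the simulator, which is what makes
  the suite's getting-it-right (Geweke) test exact. The user-facing AR-HMM
  fit instead masks the first $L$ frames of each recording in the state
  likelihood (uniform across states), so arbitrarily initialized pose
  histories cannot bias the segmentation.
* **State indices** are 1-based everywhere (R convention), including
  reports.
* $\Gamma$ is built as the sub-Helmert orthonormal basis rather than via a
  numerical SVD of the centering matrix: all its nonzero singular values
  equal 1, so an SVD's column order and signs are solver-dependent, while
  the Helmert construction is exactly reproducible and satisfies the same
  identities ($\Gamma^\top\Gamma = I$, $\Gamma^\top \mathbf 1 = 0$,
  $\Gamma\Gamma^\top = I - \mathbf{1}\mathbf{1}^\top/K$).
* The derivation of the centroid update nominally assumes a flat prior on
  $v_t$; we use the generative model's random walk (which the Kalman-style
  update requires anyway) plus a proper $\mathcal N(0, \sigma^2_{v_1})$
  prior on the first frame ($\sigma^2_{v_1} = 100$), needed for a proper
  joint density.

## The simulator and what it does (not) emulate

`simulateKeypointSLDS()` draws from the generative model itself: sticky
Markov syllables (mean duration 12 frames at 30 Hz ≈ 400 ms), per-state
damped-rotation AR dynamics with state-specific angular velocities and
drifts (stable by construction; alternatively MNIW prior draws with a
spectral-radius rejection), a random-walk centroid
($\sigma^2_{\mathrm{loc}} = 0.4$), heavy-tailed keypoint noise with
confidences emitted through the inverse of the $s_0$ logistic, and a
rodent-like elongated base pose (body length 60 length units, pose
variation ≈ 8 units per latent dimension against ≈ 1 unit of tracker
noise — the regime in which 4 principal components explain 90% of
variance, as reported for overhead-camera data). Two deliberate
departures from the literal prior: headings follow a wrapped random walk
with uniform start by default (i.i.d. uniform headings — the model prior —
are unphysical at 30 Hz and make linear interpolation of world
coordinates meaningless; the `headings = "iid"` option restores the
prior), and the single-state LDS null (`simulateLDSNull()`) uses separate
per-axis noise variances, matching its role as a negative control.

What passing tests on simulated data do **not** show: real tracker errors
are not conditionally Gaussian given a scale, real syllable durations are
not geometric, real pose dynamics are only locally linear, and real
confidences are imperfect proxies for error size. Recovery rates measured
here are upper bounds on what to expect from video-derived keypoints.

## Test and validation scales

The suite validates every closed-form conditional against moment, KS, or
dense-oracle checks (10^5 draws where the check is a scalar moment; dense
Gaussian comparisons on T ≤ 5 toys), runs a getting-it-right test on a
tiny model (T = 30, K = 4, M = 2, N = 3; 800 independent short
successive-conditional chains compared to forward draws), and exercises
parameter recovery, the single-state negative control, and ablation
robustness on simulations of 2,000–10,000 frames with 3–4 true states —
sizes chosen so the full suite completes on one desktop CPU in well under
half an hour. The stickiness calibration is additionally exercised at the
protocol's full scale (20,000 frames, N = 100, 50-sweep pilots) by
`scripts/acceptance.R`.

## The single-state negative control

`simulateLDSNull()` generates keypoint data with no syllable structure.
At desk scale (thousands of frames) the fitted model collapses onto one
dominant syllable — the correct answer — rather than retaining many
interchangeable states. As a consequence, the cross-syllable-likelihood
summary of this control (off-diagonals near 1, signalling
indistinguishable dynamics among the reported syllables) is only
informative for fits in which several comparably sized states survive,
which requires much longer recordings and the slow state-merging of a
large-N chain. On short simulations the collapse itself is the
negative-control evidence; the few surviving rare states act as outlier
catchers with idiosyncratic noise estimates, and their likelihood ratios
say nothing about behavioral structure.

## Known limitations

* Point estimates only: a single Gibbs chain is not a posterior; the
  ensemble score ranks chains but does not average them.
* The number of effective syllables depends on $\kappa$ and the HDP
  concentrations; the 400 ms calibration target is a modeling choice, not
  an estimate.
* $(C, d)$ fixed at PCA values means the latent basis never adapts to the
  robust noise model (the protocol's own choice; `updateCd = TRUE`
  enables the conjugate update).
* No 3D camera geometry, no skeleton constraints, no video I/O.
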