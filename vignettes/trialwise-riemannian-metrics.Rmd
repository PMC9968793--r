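---
title: "Trial-wise Riemannian performance metrics for SMR-BCI training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-wise Riemannian performance metrics for SMR-BCI training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A substantial fraction of would-be users of sensorimotor-rhythm (SMR)
brain-computer interfaces cannot produce brain-signal patterns that a
classifier can decode — the "BCI inefficiency" problem. One response is
better user training, which requires feedback that (i) describes the current
level of performance, (ii) reflects *change* in performance, and (iii) is
available immediately after every trial. Conventional classifier feedback
(the predicted task label) satisfies only the last requirement: for a poorly
performing user the classifier output is near random even while the user's
signals are in fact becoming more separable.

`riembci` implements classifier-independent performance metrics defined on
the manifold of symmetric positive-definite (SPD) matrices, trial-wise
engines that update them after every trial, a classifier baseline, a
synthetic SMR session simulator, and the statistical battery used to judge
how faithfully the trial-wise signals track slower block-wise performance
changes.

## The metrics

Each trial is summarized by the spatial covariance matrix of its
band-filtered EEG epoch, an SPD matrix. Distances are measured with the
affine-invariant Riemannian metric,
$$\delta_R(A, B) = \Big(\sum_i \log^2 \lambda_i(A^{-1}B)\Big)^{1/2},$$
which is invariant under any common full-rank spatial remixing of the
channels — so the metrics do not depend on reference choice or linear
channel transformations. Class means are Fréchet (geometric) means,
computed by a fixed-point iteration in the tangent space (initialized at the
arithmetic mean, tolerance $10^{-8}$ on the tangent-gradient norm, at most
50 iterations; non-convergence returns the best iterate with a warning).

With $\bar\Gamma_c$ the class-$c$ mean and
$\Phi_c = N_c^{-1}\sum_i \delta_R(\bar\Gamma_c, \Gamma_{c,i})$ the
intra-class dispersion:

* **classDistinct** $= \delta_R(\bar\Gamma_1, \bar\Gamma_2)/(\Phi_1 + \Phi_2)$ —
  separability of the two task classes;
* **classStability** $= 1/(1 + \Phi_c)$ per class — within-class
  consistency, averaged over the two classes for a session-level value.

A *subset dispersion* $\Phi^*$ replaces $\Phi$ in the weighted-average
engine: trials are split chronologically into subsets of $N_t$ trials
(default 5) and the per-subset dispersions are averaged, damping slow
non-stationarities that would otherwise inflate the dispersion of a long
trial sequence. Within a running block, when the trial count is not
divisible by $N_t$, the final subset is the most recent $N_t$ trials and may
overlap its predecessor; for completed blocks subsets are disjoint. If a
static trial set is not divisible by $N_t$ and overlap is not requested, the
remainder forms a smaller final subset (all trials are used).

## Trial-wise engines

All three engines emit, after every trial $i$ of block $k \ge 2$, the
reinforcement signal $M'_{k,i} - M_{k-1}$, where $M_{k-1}$ is the static
metric of the previous block (the $\Phi^*$-based version for the
weighted-average engine). The block start, rather than the previous trial,
is the reference so that the signal reflects gradual trends rather than
trial-to-trial volatility. Block 1 is warm-up only.

* **running** — recompute the metrics on all trials observed so far. This is
  the anchor oracle: the engine's output is tested to equal a from-scratch
  static recomputation at every trial.
* **sliding window** — per-class FIFO queues of the most recent
  `queue_length` trials (default 20, one block's class count, so at a block
  boundary the queue holds exactly the previous block); metrics are
  recomputed on queue contents.
* **weighted average** — per class, the post-trial mean moves along the
  geodesic from the previous block's mean $\bar\Gamma_{k-1,c}$ toward the
  queue mean $\gamma_{i,c}$:
  $\bar\Gamma^{1/2}(\bar\Gamma^{-1/2}\gamma\,\bar\Gamma^{-1/2})^{\alpha_1}\bar\Gamma^{1/2}$,
  the Riemannian analogue of the convex sum $(1-\alpha_1)\bar\Gamma +
  \alpha_1\gamma$; the post-trial dispersion is
  $(1-\alpha_2)\Phi^*_{k-1,c} + \alpha_2\,\phi^*_{k,c}$ with $\phi^*_{k,c}$
  computed from current-block trials only. Both weights default to 0.9.

Design choices where the procedure was genuinely open:

* *Queue length* defaults to 20 trials per class so the queue spans exactly
  one block's worth of evidence; it is configurable.
* *Queue mean* $\gamma_{i,c}$ is the Fréchet mean of the queue — the only
  mean consistent with the geodesic update's geometry.
* *Early-block dispersion (weighted engine)*: with fewer than two
  current-block trials of a class, $\phi^*_{k,c}$ is not yet meaningful (a
  single trial has dispersion 0 by construction, which would spike the
  stability), so the $\alpha_2$ update is deferred and the previous block's
  $\Phi^*$ is carried until two trials are available.
* *Weighted classDistinct denominator* uses the $\alpha_2$-updated
  dispersions for internal consistency with the stability metric.
* Degenerate inputs: identical trials in both classes make the
  classDistinct denominator zero; the value is flagged (Inf/NaN) with a
  warning rather than an error so batch evaluation continues.

## Classifier baseline

The baseline reinforcement is the conventional $\pm 1$ reward/punishment
from a CSP + regularized-LDA classifier trained on blocks $1..k-1$ and
applied to each block-$k$ trial. CSP uses 4 filters (2 per eigenvalue
extreme) and log-variance features; LDA shrinks the pooled covariance toward
a scaled identity with an analytic (Ledoit–Wolf-style) intensity. The
temporal sub-band (8–11, 9–13, 11–19, 17–30 or 8–30 Hz) is chosen per block
by stratified 3-fold cross-validation on the training data; folds are
assigned deterministically (round-robin within class) and ties break toward
the widest band. Block-wise ground-truth performance additionally includes
RWCA, the leave-one-trial-out CSP-rLDA accuracy within a single block.

## Preprocessing

Trials are zero-phase filtered with an order-4 Butterworth band-pass
(8–30 Hz default), cropped to the central 2 s, and summarized by sample
covariances (divisor $n-1$, symmetrized, with diagonal jitter only if an
epoch is rank-deficient). Epoch indices are 0-based and half-open. The
Riemannian potato field for artifact rejection comprises five contact-loss
detectors on channel pairs (F3-C3, P3-Pz, Fz-F4, Cz-C4, C4-P4; band-passed
1–20 Hz) and three general detectors on channel quadruples (F3-C3-P3-Pz,
Fz-F4-Cz-C4, P4-Pz-Fz-F4; band-stopped 8–38 Hz). Each potato is calibrated
once on the subject's full trial set; a trial is rejected when any potato's
distance z-score exceeds 2.5. Both the 5+3 detector list and the band-stop
setting of the general detectors are configurable.

## The session simulator

`sim_session()` generates two-block sessions (40 trials per block, 20 per
class, interleaved order) from a 9-channel linear mixing model: two
band-limited SMR sources (8–13 Hz carrier plus a weaker beta harmonic) with
Gaussian spatial profiles centered at C3 and C4, a broadly projecting 1/f
background source, per-channel 1/f noise and white sensor noise. An
event-related desynchronization (ERD) multiplies the desynchronizing
source's amplitude by `erd_gain` (default 0.5). User-performance levels
differ only in their lateralization rule:

* **low** — both tasks desynchronize the right motor cortex;
* **moderate** — left-hand trials are consistent; right-hand trials are
  contralateral on exactly half the trials (a Bernoulli mode is available);
* **high** — consistently contralateral ERD.

Session types pair block levels: LM, LH, ML, MH, HL, HM, and NC (one level
drawn uniformly, used for both blocks).

Two stochastic features were calibrated once and then frozen. A per-trial
lognormal SMR amplitude fluctuation (log-sd 0.3) keeps single-block
CSP-rLDA accuracy of high-level blocks around 0.9 rather than saturating at
1.0 — without it the spatial contrast is unrealistically clean. A
block-level lognormal drift of the SMR and background amplitudes (log-sd
0.25) reproduces the slow between-block covariate shifts that are well
documented in EEG and that drive the characteristic negative bias of the
running and sliding-window classStability reinforcement sums.

What the simulator does *not* emulate: volume-conduction from an anatomical
leadfield, ocular or movement artifacts, realistic inter-subject
variability, or gradual within-block learning. Passing corpus-level tests
therefore demonstrates that the metrics respond correctly to controlled
covariance-structure changes, not that effect sizes match any particular
real recording.

## Evaluation battery

For every block transition the block-wise metric change (ground truth) is
paired with each method's reinforcement sum. Agreement is quantified by
Spearman correlation (simulated corpora) or repeated-measures correlation
(multi-subject data; implemented via the subject-intercept ANCOVA
formulation, df $= N - k - 1$), bootstrap percentile CIs for correlation
differences (resampling whole sessions/subjects; Bonferroni-adjusted level
within a comparison family), ROC/AUC on the sign of the change (DeLong's
paired test for AUC differences), and zero-threshold sign agreement
(exact McNemar tests on discordant pairs), with Holm adjustment within each
family. Records with exactly zero deltas or sums are excluded from sign
analyses with a logged count.

## Problem sizes and numerical choices

The corpus analyses in the tests and the acceptance script use 30 sessions
per type (210 sessions, 16,800 trials), which gives stable sign-share and
correlation estimates while keeping a full run in the minutes range on one
core. Geometry tolerances are $10^{-8}$; congruence invariance holds to
$10^{-8}$ on random triples. The Fréchet mean is warm-started from the
previous iterate inside the engines, which does not change the fixed point.
Zero-phase filtering applies `signal::butter` coefficients forward and
backward with reflective padding in compiled code.

## Limitations

Only two-class sessions are supported. Absolute metric values are not
interpretable across montages or epoch lengths — more channels or shorter
epochs inflate distances — so only within-session changes should be fed
back to users. The sliding-window classStability is known to inflate
dispersion estimates when the window straddles a distribution shift; the
weighted-average variant is the more robust default.
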