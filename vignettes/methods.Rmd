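---
title: "Confidence-weighted group decisions from EEG and response times: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted group decisions from EEG and response times: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Groups of observers usually outperform individuals in rapid perceptual
decisions, but only if votes are aggregated well. Plain majority voting
treats every member alike and resolves even-split ties by chance. If one
can estimate, trial by trial, how likely each member's decision is to be
correct, votes can be weighted by that estimate and even-sized groups
stop wasting their ties. This package implements such a hybrid
brain-computer interface (hBCI): it estimates per-trial decision
confidence from EEG features and response times, and aggregates
individual binary decisions with a confidence-weighted majority rule.

Because no recorded human dataset ships with the package, a first-class
synthetic-cohort simulator reproduces the statistical structure the
pipeline relies on, and the whole evaluation runs end to end on
simulated cohorts.

## The decision model

For participant $p$ and trial $i$, let $d_{p,i} \in \{+1, -1\}$ be the
individual decision (target present / absent) and $w_{p,i} \in [0, 1]$
its confidence weight. The group decision of $m$ members is

$$G_i = \mathrm{sign}\Big(\sum_{p=1}^m w_{p,i}\, d_{p,i}\Big),$$

with an exactly zero sum declared a tie and resolved by a fair coin
flip. Methods differ only in the weight source: all ones (standard
majority), a logistic model on response time only (RTCI), on the two
CSP neural features only (nf-BCI), on all three (hBCI), the raw
reported 0-100 confidence (confidence majority), or unit weights over
the post-communication second responses (second-response majority).

## Confidence estimation

The confidence model is trained on decision *correctness*, which is
available in a training set, on the premise that observers are on
average less confident when wrong: correct trials form the "confident"
class (label $-1$), incorrect trials the "non-confident" class (label
$+1$), and $w$ is the predicted probability of the confident class.

Three features describe each trial:

* **Stimulus-locked neural feature.** Conditioned epochs (below) are
  spatially filtered with Common Spatial Patterns fitted on the
  training trials' correctness labels; the feature is the natural log
  of the variance of the first CSP component. Only the first component
  is used; per-trial covariances are trace-normalised before averaging
  within class, and both class estimates are shrunk toward a scaled
  identity with a Ledoit-Wolf style analytic intensity when the
  composite covariance is ill-conditioned.
* **Response-locked neural feature.** Same construction on
  response-locked epochs, with its own CSP transformation.
* **Response time** in seconds.

The logistic layer is L2-penalised with the regularisation strength $C$
selected from $\{10^{-4},\dots,10^{4}\}$ by stratified 3-fold inner
cross-validation on the training set (with 288 training trials: 192 fit
/ 96 validate per fold), scoring by held-out logistic loss with
fold-specific feature standardisation so no inner-fold statistics leak.
Ties in mean validation loss go to the smallest $C$. Features are
z-scored on training statistics before the final refit. The
standardisation step, the tie rule and the analytic shrinkage are not
dictated by the protocol; they are this package's own design choices,
stated as such. The optimiser is a
damped Newton iteration on the strictly convex penalised loss
(intercept unpenalised); tests verify it against an independent grid
minimisation to three decimals.

Degenerate training sets are handled explicitly: a single-class fold
raises a typed error that the pipeline converts into a constant weight
of 1 (so the method gracefully degrades to majority for that
participant-fold), and a minority class below 2 trials skips the inner
CV and fixes $C = 1$, flagged in the fitted model.

## EEG preprocessing

The conditioning chain maps a continuous recording to stimulus-locked
and response-locked epochs on a common 48-sample grid:

1. **Re-referencing** to the average of the two earlobe electrodes;
   the earlobe rows are zeroed and excluded downstream, which makes the
   operation idempotent.
2. **Band-pass filtering** 0.15-40 Hz with a linear-phase FIR of 14677
   taps at 2048 Hz (scaled proportionally at other rates), applied
   forward with the group delay compensated so latencies are preserved.
   At realistic lengths the 0.15 Hz edge sits inside the window design's
   transition band, so the design is DC-nulled by subtracting the
   coefficient mean: the symmetric structure is preserved, $H(0)$
   becomes exactly zero, and the pass band moves by less than 0.2%
   (verified numerically in the tests).
3. **Ocular artefact removal** by regression on the proxy
   $o(t) = \tfrac12[(\mathrm{Fp1}-\mathrm{F1}) + (\mathrm{Fp2}-\mathrm{F2})]$:
   each channel has its least-squares projection on $o$ subtracted,
   leaving all channels empirically decorrelated from the proxy. A
   zero-variance proxy leaves the recording unchanged with a warning.
4. **Epoching.** Nominal 1900 ms windows: $[-200, +1700)$ ms around
   stimulus onset and $[-1200, +700)$ ms around the response, half-open
   in sample indices, the event sample included. 1900 ms is not an
   integer number of samples at 2048 Hz; windows are therefore cut as
   $48 \cdot f_s/32$ retained samples plus a $\mathrm{round}(0.2 f_s)$
   margin per side (3892 samples at 2048 Hz), which makes the final
   counts exact. Windows crossing the recording edge exclude the trial,
   logged.
5. **Conditioning.** Per channel: linear least-squares detrend; an
   equiripple low-pass (pass edge 14 Hz, stop edge 16 Hz) designed with
   the Remez exchange algorithm and applied with zero net delay;
   trimming of the 200 ms margins; decimation to 32 Hz by keeping every
   $f_s/32$-th sample. The 14/16 Hz edges sit below the 16 Hz Nyquist
   of the target rate, so the mandated low-pass doubles as the
   anti-alias stage and no extra filter is added. Every conditioned
   epoch is exactly 48 samples per channel (1.5 s); 64 channels give
   3072 values.

The default low-pass order is $\min(1200, 0.75 f_s)$: the Remez
exchange iteration in the available implementation becomes numerically
unstable for very narrow normalised transition bands (orders above
about 1200 at 2048 Hz), and order 1200 already attenuates the stop band
by more than 95% at every supported rate. The order remains a user
parameter, and the tests use shorter designs meeting the same band
edges at reduced rates. Whether filtering should be zero-phase is a
design choice (it preserves ERP latencies); so is the exact form of the
ocular "standard subtraction" (least-squares projection), and both are
documented here rather than asserted as the only possibility.

## Evaluation design

An outer 10-fold cross-validation partitions the 320 trials into 288
training / 32 test per fold, stratified by stimulus class so every test
fold keeps the 25% target prevalence. Folds are shared across
participants, which is what makes group evaluation on common test
trials possible. Within each fold, CSP and the logistic layer are fit
on training trials only; a dedicated test perturbs held-out epochs and
checks that no fitted parameter moves. Test-trial weights are
concatenated across folds so every trial is predicted exactly once.

Groups are enumerated exhaustively: all $\binom{n}{m}$ subsets for
independent cohorts (45 pairs, 120 triplets, ... for $n = 10$), or all
$\binom{7}{k}$ unions of whole pairs for communicating cohorts (21
groups of size 4, 35 of size 6, ...), never splitting a pair and never
forming odd sizes. Tie-break draws come from one seeded generator per
evaluation run with draw order fixed by (group, trial) — one draw per
trial whether used or not — so runs are bit-reproducible and different
weighting methods face identical tie-break randomness.

Method contrasts use the one-sided Wilcoxon signed-rank test over
paired per-group error rates (exact distribution at 25 or fewer pairs,
normal approximation above); distribution contrasts between the correct
set $D_c$ and the incorrect set $D_i$ (response times, reported
confidence, estimated $w$, per-sample ERP voltage) use the
Kruskal-Wallis test, which with two groups is the tie-corrected
rank-sum test and is kept under that name deliberately. ERP contrasts
report grand averages and a per-channel, per-sample p-value map with no
multiple-testing correction, flagging only the conventional 5% level;
scalp-map values are exported at 600 and 900 ms post-stimulus and
±200 ms around the response. Error and tie dynamics use a simple moving
average over 40 consecutive trials (overlapping windows advancing one
trial) with an ordinary least-squares trend, its correlation
coefficient and two-sided p-value; the trend is fit to the smoothed
series.

## What the simulator emulates

Each synthetic session reproduces the experimental design: 8 blocks of
40 trials with exactly 25% targets per block, one shared stimulus
sequence across participants, 64 scalp channels (plus two earlobe
references) at 2048 Hz by default — both reducible for tractable
studies. Per trial:

* **Correctness** is Bernoulli with the configured per-participant
  error rate (default 0.2, matching the error level of isolated
  observers in the motivating experiments; communicating cohorts use
  0.337).
* **Response times** are log-normal — positive support and right skew
  typical of RTs — with medians 0.8 s (correct) and 1.1 s (incorrect)
  and log-scale SD 0.3; draws that would not fit the 4 s inter-trial
  window are resampled and counted. The fixed 4 s spacing guarantees
  response-locked epochs never overlap neighbouring trials.
* **EEG** is white Gaussian background noise (10 µV SD; 1/f optional)
  plus a biphasic template — a positive Gaussian peak with a shallower
  negative rebound, controllable latency/width/amplitude — injected at
  stimulus onset (peak 450 ms, width 120 ms) and around the response
  (peak 100 ms before it), on the midline centro-parietal channels
  (Cz, CPz, Pz, POz) at 5 µV. On incorrect trials the amplitude is
  multiplied by 0.5. A single scalar attenuation keeps the
  correct/incorrect ERP effect size interpretable; the true ERP
  difference shape is not characterised quantitatively anywhere, so the
  simulator exposes it as a free parameter rather than claiming
  waveform fidelity.
* **Ocular blinks** (4/min, 40 µV, frontal topography dominated by
  Fp1/Fp2) exercise the regression-based artefact removal.
* **Reported confidence** is a quantised (10-point steps, 0-100) noisy
  monotone function of correctness — means 75 vs 45, SD 15 — when
  observers are isolated. In communication mode it becomes
  correctness-independent (mean 60), the incorrect-trial attenuation is
  pulled toward 1 (the correct/incorrect ERP difference shrinks by
  60%), overall ERP amplitude drops by 20%, and pairs produce second
  responses: on a disagreement trial, with the configured conformity
  probability (default 0.5) the member reporting lower confidence
  adopts the partner's decision. This convergence rule — rather than
  both members independently switching, which would merely swap a
  disagreement — makes conformity 0 a no-op and conformity 1 forced
  agreement.

What the simulator does *not* model: realistic ERP topographies and
component mixtures, non-stationary noise, learning/fatigue trends,
eye movements beyond the blink proxy, or any coupling between stimulus
content and difficulty. Passing tests on simulation therefore
demonstrate that the pipeline recovers the structure it assumes
(correctness-dependent RTs and ERP amplitudes, confidence-correctness
coupling and its communication-induced decoupling) — not that it would
achieve any particular accuracy on recorded human data.

## Numerical choices and problem sizes

Variances are floored at $10^{-12}$ before logs; eigenvalues below
$10^{-12}$ of the maximum are dropped when whitening; the degenerate
all-equal input to the rank tests short-circuits to $H = 0$, $p = 1$.
Epoch-grid arithmetic is integral by construction (sampling rates must
be multiples of 32 Hz). All stochastic steps — trial sampling, fold
assignment, inner CV splits, tie breaks — derive from explicit integer
seeds, and identical configuration plus seed reproduces sessions
bit-identically.

Simulation studies in the tests and the acceptance script run at a
reduced montage of 8 channels sampled at 128 Hz with all other
generator parameters at their defaults; this keeps a full 10-participant
cross-validated evaluation around ten seconds while leaving every
pipeline stage (filtering, epoching, CSP, inner/outer CV, enumeration)
fully exercised. Parameter-recovery claims are Monte-Carlo statements
over 50 seeds at those conditions.

## Known limitations

* The CSP layer uses only the first component per lock type; richer
  feature banks (first and last components, band-specific CSP,
  Riemannian features) are deliberately out of scope.
* Reported confidences enter the confidence-majority rule raw on the
  0-100 scale; a member reporting 0 abstains, and an all-zero group
  falls to the coin flip.
* The Wilcoxon implementation follows the standard practice of
  switching to the normal approximation in the presence of ties, which
  paired error rates over small trial counts often produce.
* No EDF/BDF reader or writer is bundled; recordings travel as
  in-memory matrices or a CSV + JSON sidecar container, and large
  sessions are best regenerated from their configuration seed.
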