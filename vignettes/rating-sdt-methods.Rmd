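---
title: "Modelling graded responses from confidence ratings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling graded responses from confidence ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratingsdt)
```

## The question and the model

When listeners rate their perception of a near-threshold tone on a
six-point scale, is the underlying perceptual state graded or
dichotomous?  The package's core idea is that a signal detection
model fitted to the *behavior alone* makes a quantitative prediction
about *physiology*: if a measured response amplitude tracks the
internal evidence variable, then the mean amplitude for trials given
rating $i$ should equal the mean of the evidence distribution
truncated to that rating's criterion bin,

$$A_i \;=\; \frac{\int_{c_{i-1}}^{c_i} x\, g(x)\,dx}
                 {\int_{c_{i-1}}^{c_i} g(x)\,dx},$$

with $c_0 = -\infty$, $c_6 = +\infty$, and $g$ the class density.
For a Gaussian component this is closed form,
$\mu + \sigma\,(\varphi(\alpha)-\varphi(\beta))/(\Phi(\beta)-\Phi(\alpha))$
with $\alpha,\beta$ the standardized bin edges; the test suite checks
the closed form against direct quadrature to $10^{-8}$.

Three generative accounts are compared on the same normalized
amplitude profile:

* **Unequal-variance SDT** — signal $N(\mu_s, \sigma_s)$, noise
  $N(0,1)$; perception is graded.
* **Bifurcation** — signal evidence is a mixture
  $(1-\beta)N(0,1) + \beta N(\mu_{high},1)$; trials from the lower
  mode are perceptually empty.  $\beta$ is not fitted but fixed at
  the dichotomized detection rate (ratings 4–6 as hits).
* **Threshold** — the SDT fit's predictions with the amplitudes of
  ratings 1–3 set to zero; sub-threshold trials evoke nothing.

## Estimation procedure

1. **Scale.** $\sigma_s$ comes from the z-transformed rating ROC:
   under the Gaussian model $z(H_k) = \mu_s/\sigma_s + (1/\sigma_s)
   z(FA_k)$, so the OLS slope of $z(H)$ on $z(FA)$ estimates
   $1/\sigma_s$.  OLS on the z-ROC is the textbook estimator; no
   weighting is attempted because the five points come from the same
   multinomial table and their errors are correlated anyway.
2. **Location.** $\mu_s$ minimizes
   $\sum_{i=1}^5 |c_i^{noise} - c_i^{signal}(\mu_s)|$, where each
   criterion is obtained by inverting the corresponding cumulative
   tail probability (closed form for Gaussians, bisection for the
   mixture).  The objective is piecewise-linear in $\mu_s$ and
   unimodal in practice; a 101-point grid prescan over $[0,5]$
   followed by Brent minimization (tolerance $10^{-6}$) guards
   against flat stretches.
3. **Grand average first.** The distribution parameters are fitted
   once on probabilities pooled across participants; criteria are
   then re-fitted per participant by minimizing
   $|P_{noise}(X>c_i) - p_{FA,i}| + |P_{signal}(X>c_i) - p_{H,i}|$
   independently per criterion over $[-6, 6]$.  Ties are broken
   toward the noise-only solution.  If sampling noise makes the five
   solutions non-monotone they are repaired by pooling adjacent
   violators and the result is flagged — the model assumes ordered
   criteria but observed tables need not.
4. **Extreme rates.** Observed proportions of exactly 0 or 1 are
   clipped to $[1/(2N), 1 - 1/(2N)]$ with $N$ the backing trial
   count before any z-transform, the standard log-linear correction.
   Zero-mass rating bins yield a flagged midpoint sentinel instead
   of a NaN and are excluded from $R^2$.

## Normalization and the $A_{H1}$ divisor

Before averaging across participants, all amplitude profiles are
shifted by the across-participant mean of the noise-class rating-1
amplitude (so the lowest rating sits at 0) and divided by a
normalization constant, the criterion-1 hit amplitude.  The divisor
deserves a note, because the reporting convention is genuinely open:
a literal "signal-class rating-1 amplitude after shifting" is the
truncated mean of the signal distribution *below* the most liberal
criterion, which for the fitted model is numerically within a few
hundredths of the shift itself.  Dividing by it is unstable — under
per-participant criterion variation it crosses zero — and produces
profiles scaled by factors of tens.  The package therefore uses the
mean evidence of criterion-1 *hits*, $E[X \mid X > c_1, signal]$,
which is large, positive, and stable; `normalize_profiles()` accepts
any explicit divisor for users who prefer another convention.
Monotonicity of the profile and the ranking of model $R^2$ values do
not depend on this choice (any positive constant preserves both).

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
under which the pipeline is exercised.

* **Design**: 17 participants, 500 signal-present and 100
  signal-absent trials each (two parts of 250 + 50); the sparser
  first-experiment design (150 near-threshold + 50 absent + 50
  modulated-noise trials per run) can be configured.
* **Evidence**: signal $N(1.385, 1.344)$ vs noise $N(0,1)$ — the
  published grand-average fit — or any bimodal variant.
* **Criteria**: group criteria $(0.254, 0.692, 1.065, 1.831, 2.590)$,
  obtained by inverting the signal distribution at cumulative
  response rates $0.80, 0.697, 0.594, 0.37, 0.185$.  These anchors
  reproduce the reported dichotomized detection rate (59.4% at the
  3/4 split), the 37% rate at the 4/5 split, and the reported
  response pattern (ratings 4–6 and rating 1 roughly equally
  frequent, 2–3 rarer).  The implied false-alarm rate at the 3/4
  split is 0.143 where 9.9% was observed — a single-Gaussian model
  cannot match both printed rates exactly, and the signal side is
  anchored because signal trials dominate the design 5:1.
* **Heterogeneity**: per-participant criteria are the group criteria
  plus i.i.d. $N(0, 0.4^2)$ jitter, re-sorted, matching the reported
  between-participant criterion spread (SD $\approx 0.4$).
* **Amplitudes**: measured amplitude = evidence + $N(0, 0.5^2)$
  measurement noise; the identity link is the weakest assumption
  under which the truncated-mean predictions are exact.
* **Pupil**: 1000-Hz traces as baseline + slow drift + event-locked
  gamma kernels (onset $\approx$ 500 ms, peak $\approx$ 1000 ms
  post-stimulus) with gain increasing in trial evidence, white
  noise, and annotated blink dropouts.
* **Waveforms**: a negative-going early template (150–700 ms) scaled
  by condition-mean evidence plus a late positive template (400–600
  ms) for high ratings; continuous streams with 3-s onset spacing
  feed the stimulus-free reference-epoch builder (1.9–3.0 s
  post-onset, re-referenced so 2.0 s maps to $t=0$).

All generators are pure functions of (config, seed); child seeds per
stream are derived deterministically from the master seed.

What the generator does *not* emulate: real pupil traces have
non-Gaussian noise, slow autocorrelated drifts, and gaze-dependent
area artifacts; real source waveforms have correlated sensor noise
and participant-specific latencies; real observers drift in
criterion over time.  Passing tests therefore certify the
*estimators* under the model's own assumptions, not robustness to
every feature of real recordings.

## A known limit of grand-average fitting

Pooling rating probabilities across participants with heterogeneous
criteria flattens the grand-average ROC (each pooled point is an
average of points along the participant-level curves), so the pooled
estimator is attenuated: at the default criterion spread (SD 0.4)
the recovered $\mu_s$ underestimates the generating 1.385 by roughly
0.08 on average, with $\sigma_s$ attenuated less.  With homogeneous
criteria the estimator is unbiased (errors $\sim$0.02 at the default
design size, shrinking with $n$), and on exact analytic
probabilities it recovers the generating parameters to better than
$10^{-3}$.  This attenuation is a property of the grand-average
procedure itself — which is retained deliberately, because it is the
procedure whose outputs the downstream amplitude predictions use —
and is why the full simulated-experiment recovery check is reported
with its bias rather than hidden by reducing the heterogeneity the
generator is meant to emulate.

## Pupillometry pipeline choices

* **Blink interpolation**: linear, from 100 ms before to 100 ms
  after each annotated blink; pads truncated at a trace edge hold
  the nearest valid sample (with a warning).  Epochs with more than
  20% interpolated samples are rejected; the rule is exact
  ($>0.20$, not $\geq$).
* **Filter**: the 4-Hz low-pass is realized as a 2nd-order
  Butterworth applied forward-backward (zero-phase).  A causal
  filter would delay the pupil dilation derivative's onset and peak
  — exactly the latencies the derivative analysis is meant to
  resolve — so zero-phase is the defensible realization even though
  causality of the original is unknowable from the description.
* **Derivative**: first difference of the *raw* epoch (divisive
  baselining first would rescale the derivative by the baseline),
  smoothed by a centered 200-sample moving mean with shrinking edge
  windows (preserving epoch length), optionally corrected by
  subtracting the baseline-window mean of the derivative — which
  removes a linear rising trend such as a noise-onset ramp.
* **Units**: per-sample differences (a.u./ms at 1000 Hz), reported
  as-is.

## Statistics

The temporal cluster permutation test thresholds pointwise paired
$t$ statistics two-sided at the cluster-forming alpha (0.05),
scores contiguous supra-threshold runs by summed $t$, and compares
observed cluster masses against the permutation distribution of the
maximum absolute mass under within-participant sign flips —
family-wise control over the analysis window.  Sign flipping (rather
than condition-label exchange) matches the paired and test-against-
zero designs; positive and negative clusters are pooled by absolute
mass, a conservative two-sided choice.  The permutation count
defaults to 10,000 and is configurable; p-values use the
$(b+1)/(m+1)$ convention so a significant result is never claimed
beyond the resolution of the permutation count.  Analysis windows
are fixed constants per modality (100–400 ms auditory cortex,
300–800 ms RSC/PCC, 500–1000 ms pupil derivative).

Polynomial contrasts use orthonormal `contr.poly` weights; the
contrast score is tested against zero per participant, $F = t^2$
with df $(1, n-1)$.  The one-way repeated-measures ANOVA computes
the Greenhouse–Geisser $\varepsilon$ from the double-centered
condition covariance and multiplies both degrees of freedom by it;
$\varepsilon$ is clamped to $[1/(k-1), 1]$.

## Problem sizes used in the checks

The calibration of the cluster test uses 1000 simulated null
experiments of 14 participants × 40 time samples with 1000
permutations each; the quadrature comparison uses 1000 random
model/criterion pairs; the simulated-experiment recovery uses the
default 17 × 600 design.  These sizes give Monte-Carlo error well
below the tolerances being checked while keeping the whole suite
fast enough to run routinely.
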