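# ratingsdt

Signal-detection modelling of six-point confidence ratings and the
graded physiological responses they predict.

In near-threshold auditory detection, listeners rate their perception
of a faint tone on a six-point scale while neural (MEG/EEG
source-level) and pupil responses are recorded.  `ratingsdt`
implements the analysis chain that links the two: an unequal-variance
Gaussian signal detection (SDT) model is fitted to the rating
frequencies alone, and the fitted model predicts the mean response
amplitude for each rating as a truncated-Gaussian conditional mean.
If perception is graded, measured amplitudes should follow these
predictions; two competitor models embodying dichotomous perception —
a bimodal-signal "bifurcation" model and a discrete threshold model —
make contrasting predictions that can be compared by R².

## The model

Evidence on a trial is a draw from one of two Gaussians,

    noise:  X ~ N(0, 1)           (location and scale fixed by convention)
    signal: X ~ N(mu_s, sigma_s)

and a rating r in 1..6 is produced by five ordered criteria
c_1 < ... < c_5: r = 1 + #{i : c_i < X}.  The package estimates:

- criterion from rates: c = −(z(H) + z(FA)) / 2, and d′ = z(H) − z(FA);
- sigma_s from the z-ROC: the slope of the least-squares line through
  (z(FA_k), z(H_k)) over the five cumulative rating criteria equals
  1/sigma_s (with sigma_noise = 1);
- mu_s by criterion consistency: the value that minimizes the summed
  absolute difference between the five criteria implied by the noise
  distribution and by the signal distribution (grand-average data);
- per-participant criteria c_i minimizing
  |P_noise(X > c_i) − p_FA,i| + |P_signal(X > c_i) − p_H,i|;
- predicted amplitude per rating: the mean of the class distribution
  truncated to the rating's criterion bin,
  A_i = mu + sigma (phi(a_i−1) − phi(a_i)) / (Phi(a_i) − Phi(a_i−1)),
  normalized by shifting the noise-class rating-1 amplitude to 0 and
  dividing by the criterion-1 hit amplitude.

The bifurcation competitor replaces the signal distribution with
(1−β) N(0,1) + β N(mu_high, 1), β fixed at the dichotomized detection
rate; the threshold competitor zeroes the predicted amplitudes of
ratings 1–3.

Around the core model the package provides the behavioral summaries
(per-rating positive/negative predictive values, pupil-baseline
quintile detection rates, chronological splits), a pupillometry
pipeline (blink interpolation, 4-Hz zero-phase low-pass, epoching,
divisive baseline, smoothed pupil-dilation derivative), temporal
cluster-based permutation tests, polynomial contrasts, a one-way
repeated-measures ANOVA with Greenhouse–Geisser correction, and a
synthetic-data generator that emulates the full experimental design
(17 participants × 500 signal-present + 100 signal-absent trials)
so that every stage can be exercised end to end.

## Worked example

```r
library(ratingsdt)

cfg    <- simulation_config(seed = 1)          # the default design
sim    <- simulate_rating_experiment(cfg)
trials <- simulate_trial_amplitudes(sim)
counts <- rating_counts_from_trials(trials)
report <- fit_report(counts, measured = measured_profile_from_trials(trials))
report
#> Rating-SDT fit report
#>   mu_signal = 1.269, sigma_signal = 1.259, delta-mu/delta-sigma = 4.90
#>   bimodal: beta = 0.56, mu_high = 2.033
#>   signal-density similarity (unimodal vs bimodal) r = 0.972
#>   R^2 vs measured profile:
#>     sdt       0.999
#>     bimodal   0.994
#>     threshold 0.591
```

The first line is the unequal-variance model recovered from the
simulated rating table alone (generated from mu_s = 1.385,
sigma_s = 1.344; the shortfall reflects the between-participant
criterion spread in the generator — see the methods vignette).  The
R² rows compare each model's predicted per-rating amplitude profile
with the simulated "measured" profile: data generated under graded
perception are explained best by the graded SDT model and worst by
the threshold model.

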