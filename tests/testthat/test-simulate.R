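test_that("ratings are the count of criteria below the evidence", {
  cfg <- simulation_config(n_participants = 2, n_signal = 50,
                           n_absent = 20,
                           criteria = criterion_set(rep(-10, 5) +
                                                      (0:4) * 1e-6),
                           criterion_jitter_sd = 0, seed = 4)
  sim <- simulate_rating_experiment(cfg)
  expect_true(all(sim$trials$rating == 6))

  # signal identical to noise: rating distributions indistinguishable
  cfg2 <- simulation_config(model = sdt_model(0, 1),
                            n_participants = 1, n_signal = 50000,
                            n_absent = 50000, criterion_jitter_sd = 0,
                            seed = 5)
  sim2 <- simulate_rating_experiment(cfg2)
  ps <- tabulate(sim2$trials$rating[sim2$trials$condition == "signal"],
                 6) / 50000
  pn <- tabulate(sim2$trials$rating[sim2$trials$condition == "absent"],
                 6) / 50000
  se <- sqrt(pmax(ps * (1 - ps), 1e-6) / 50000 +
               pmax(pn * (1 - pn), 1e-6) / 50000)
  expect_true(all(abs(ps - pn) < 3.5 * se))
})

test_that("empirical rating frequencies match analytic bin masses", {
  cfg <- simulation_config(n_participants = 1, n_signal = 200000,
                           n_absent = 50000, criterion_jitter_sd = 0,
                           seed = 6)
  sim <- simulate_rating_experiment(cfg)
  pr <- analytic_rating_probabilities(cfg$model, cfg$criteria)
  emp <- tabulate(sim$trials$rating[sim$trials$condition == "signal"],
                  6) / 200000
  se <- sqrt(pr$signal$probs * (1 - pr$signal$probs) / 200000)
  expect_true(all(abs(emp - pr$signal$probs) < 3.5 * se))
})

test_that("trial amplitudes track the latent evidence", {
  cfg <- simulation_config(n_participants = 1, n_signal = 100000,
                           n_absent = 100, criterion_jitter_sd = 0,
                           seed = 8)
  sim <- simulate_rating_experiment(cfg)
  tr0 <- simulate_trial_amplitudes(sim, noise_sd = 0)
  expect_equal(tr0$amplitude, tr0$evidence)

  # within-rating means converge to the truncated-Gaussian predictions
  pred <- predicted_amplitudes(cfg$model, cfg$criteria, "signal")
  sig <- tr0[tr0$condition == "signal", ]
  for (r in 1:6) {
    a <- sig$amplitude[sig$rating == r]
    if (length(a) > 50) {
      se <- sd(a) / sqrt(length(a))
      expect_lt(abs(mean(a) - pred$amplitudes[r]), 3.5 * se)
    }
  }
  expect_gt(mean(sig$amplitude[sig$rating == 6]),
            mean(sig$amplitude[sig$rating == 1]))
  sim_bad <- sim
  sim_bad$trials$evidence <- NULL
  expect_error(simulate_trial_amplitudes(sim_bad), "evidence")
})

test_that("pupil traces carry event-locked kernels coupled to evidence", {
  cfg <- simulation_config(
    n_participants = 1, n_signal = 30, n_absent = 10,
    criterion_jitter_sd = 0, seed = 10,
    pupil = list(noise_sd = 0, blink_rate_hz = 0, drift_amplitude = 0,
                 evidence_coupling = 0, gain = 50))
  out <- simulate_pupil_traces(simulate_rating_experiment(cfg))
  tr <- out$traces[[1]]
  expect_s3_class(tr, "pupil_trace")
  expect_equal(nrow(tr$blinks), 0)
  # single-event check: epoch around the first onset shows the kernel
  ep <- preprocess_and_epoch(tr)[[1]]
  expect_gt(max(ep$samples) - min(ep$samples), 10)
  # baseline pupil recorded per trial
  expect_true(all(is.finite(out$trials$baseline_pupil)))

  # gain 0, no noise: flat trace at drift level
  cfg0 <- simulation_config(
    n_participants = 1, n_signal = 5, n_absent = 2,
    criterion_jitter_sd = 0, seed = 10,
    pupil = list(noise_sd = 0, blink_rate_hz = 0, drift_amplitude = 0,
                 evidence_coupling = 0, gain = 0))
  out0 <- simulate_pupil_traces(simulate_rating_experiment(cfg0))
  expect_equal(diff(range(out0$traces[[1]]$samples)), 0)
})

test_that("PDR' of a noiseless simulated event matches the kernel analytics", {
  cfg <- simulation_config(
    n_participants = 1, n_signal = 3, n_absent = 1,
    criterion_jitter_sd = 0, seed = 12,
    pupil = list(noise_sd = 0, blink_rate_hz = 0, drift_amplitude = 0,
                 evidence_coupling = 0, gain = 50, iti_ms = 4000))
  out <- simulate_pupil_traces(simulate_rating_experiment(cfg))
  ep <- preprocess_and_epoch(out$traces[[1]])[[1]]
  d <- pdr_derivative(ep)
  peak_ms <- d$time_ms[which.max(d$samples)]
  pp <- cfg$pupil
  # windowed-difference oracle for the smoothed derivative (the 4-Hz
  # low-pass leaves the slow kernel essentially untouched)
  K <- function(t) {
    tt <- pmax(t - pp$kernel_latency_ms, 0)
    (tt / pp$kernel_scale_ms)^(pp$kernel_shape - 1) *
      exp(-tt / pp$kernel_scale_ms)
  }
  fine <- seq(0, 2500, by = 0.1)
  analytic_peak <- fine[which.max(K(fine + 100) - K(fine - 100))]
  expect_lt(abs(peak_ms - analytic_peak), 20)
})

test_that("group waveforms order amplitudes by rating and repeat exactly", {
  cfg <- simulation_config(n_participants = 8, n_signal = 400,
                           n_absent = 80, seed = 14,
                           waveform = list(noise_sd = 0.01))
  sim <- simulate_rating_experiment(cfg)
  wf <- simulate_group_waveforms(sim)
  amps <- vapply(wf$by_rating, function(ws)
    mean(window_mean(ws, c(150, 700))), numeric(1))
  # negative-going component scales with evidence: more negative with
  # higher rating
  expect_true(all(diff(amps) < 0))

  # determinism: identical seeds give identical output
  wf2 <- simulate_group_waveforms(simulate_rating_experiment(cfg))
  expect_identical(wf$by_rating[[3]]$data, wf2$by_rating[[3]]$data)

  # streams feed the reference-epoch builder
  ref <- build_reference_epochs(wf$streams, wf$onsets)
  expect_equal(nrow(ref$data), 8)
})

test_that("full-loop: pooled fit is consistent under shared criteria", {
  # conservative upper criteria leave few extreme-rating counts, so
  # the z-ROC estimate is noisy at single-experiment size; at a
  # larger design the sampled fit converges on the generating model
  cfg <- simulation_config(seed = 20, criterion_jitter_sd = 0,
                           n_participants = 40, n_signal = 2500,
                           n_absent = 500)
  sim <- simulate_rating_experiment(cfg)
  counts <- rating_counts_from_trials(sim$trials)
  pooled <- ratingsdt:::pool_rating_counts(counts)
  fit <- fit_signal_distribution(pooled$signal, pooled$noise)
  expect_equal(fit$mu_signal, 1.385, tolerance = 0.05)
  expect_equal(fit$sigma_signal, 1.344, tolerance = 0.05)
})

test_that("criterion heterogeneity attenuates the pooled fit only mildly", {
  # pooling rating probabilities across participants with different
  # criteria flattens the grand-average ROC, biasing the pooled
  # estimator towards smaller separation; the effect stays bounded at
  # the default between-participant spread
  cfg <- simulation_config(seed = 20, n_participants = 40,
                           n_signal = 2500, n_absent = 500)
  sim <- simulate_rating_experiment(cfg)   # jitter SD 0.4
  pooled <- ratingsdt:::pool_rating_counts(
    rating_counts_from_trials(sim$trials))
  fit <- fit_signal_distribution(pooled$signal, pooled$noise)
  expect_lt(fit$mu_signal, 1.385 + 0.05)      # attenuation, not inflation
  expect_gt(fit$mu_signal, 1.385 - 0.25)
  expect_gt(fit$sigma_signal, 1.344 - 0.25)
})
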