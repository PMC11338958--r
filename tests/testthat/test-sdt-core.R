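test_that("criterion from rates matches the z-average definition", {
  expect_equal(criterion_from_rates(0.5, 0.5), 0)
  expect_equal(criterion_from_rates(0.841, 0.159), 0, tolerance = 1e-3)
  # oracle: root-finding on the quadrature CDF, independent of qnorm
  expect_equal(criterion_from_rates(0.594, 0.099),
               -(oracle_qnorm(0.594) + oracle_qnorm(0.099)) / 2,
               tolerance = 1e-8)
  expect_error(criterion_from_rates(1.2, 0.5), "outside")
  expect_warning(criterion_from_rates(1, 0.5, n_hit_trials = 100),
                 "clipped")
})

test_that("criterion is antisymmetric under rate complementation", {
  for (h in c(0.3, 0.6, 0.9)) for (f in c(0.05, 0.2, 0.4)) {
    expect_equal(criterion_from_rates(h, f),
                 -criterion_from_rates(1 - f, 1 - h))
  }
})

test_that("cumulative ROC points pool ratings above each criterion", {
  sig <- rating_probabilities(rep(1 / 6, 6), "signal")
  noi <- rating_probabilities(c(0.5, 0.2, 0.1, 0.1, 0.05, 0.05), "noise")
  roc <- cumulative_response_rates(sig, noi)
  expect_equal(roc$hit_rate, (5:1) / 6)

  sig2 <- rating_probabilities(c(0.2, 0.1, 0.1, 0.1, 0.2, 0.3), "signal")
  roc2 <- cumulative_response_rates(sig2, noi)
  expect_equal(roc2$hit_rate, c(0.8, 0.7, 0.6, 0.5, 0.3))

  # all mass on rating 6: every cumulative rate is 1
  sig3 <- rating_probabilities(c(0, 0, 0, 0, 0, 1), "signal")
  expect_equal(cumulative_response_rates(sig3, noi)$hit_rate, rep(1, 5))

  # conservation: consecutive differences reproduce the input p_i
  expect_equal(-diff(c(1, roc2$hit_rate, 0)), sig2$probs)
  expect_error(rating_probabilities(rep(0.2, 5), "signal"), "6")
})

test_that("criterion tail inversion is exact", {
  m <- paper_model()
  expect_equal(solve_criterion(0.5, m, "noise"), 0)
  expect_equal(solve_criterion(0.5, m, "signal"), 1.385)
  # Phi(1) by quadrature: upper tail 1 - Phi(1)
  expect_equal(solve_criterion(1 - oracle_pnorm(1), m, "noise"), 1,
               tolerance = 1e-8)
  expect_error(solve_criterion(0, m, "noise"), "strictly inside")
})

test_that("z-ROC slope recovers the SD ratio from analytic ROCs", {
  cs <- default_criteria()
  eq <- analytic_rating_probabilities(sdt_model(1, 1), cs)
  roc_eq <- cumulative_response_rates(eq$signal, eq$noise)
  expect_equal(estimate_sigma_ratio(roc_eq), 1, tolerance = 1e-6)

  uv <- analytic_rating_probabilities(paper_model(), cs)
  roc_uv <- cumulative_response_rates(uv$signal, uv$noise)
  expect_equal(estimate_sigma_ratio(roc_uv), 1 / 1.344,
               tolerance = 1e-6)

  degenerate <- roc_uv
  degenerate$fa_rate <- rep(0.2, 5)
  expect_error(estimate_sigma_ratio(degenerate), "underdetermined")
})

test_that("grand-average fit recovers generating parameters", {
  cs <- default_criteria()
  pr <- analytic_rating_probabilities(paper_model(), cs)
  fit <- fit_signal_distribution(pr$signal, pr$noise)
  expect_equal(fit$mu_signal, 1.385, tolerance = 0.01)
  expect_equal(fit$sigma_signal, 1.344, tolerance = 0.01)
  expect_equal(delta_ratio(fit), 1.385 / 0.344, tolerance = 0.01)

  pr_eq <- analytic_rating_probabilities(sdt_model(1, 1), cs)
  fit_eq <- fit_signal_distribution(pr_eq$signal, pr_eq$noise)
  expect_equal(fit_eq$mu_signal, 1, tolerance = 0.01)
  expect_equal(fit_eq$sigma_signal, 1, tolerance = 0.01)
})

test_that("parameter recovery holds across the unequal-variance range", {
  cs <- default_criteria()
  for (mu in c(0.5, 1.2, 2.1, 3)) for (s in c(1, 1.4, 2)) {
    pr <- analytic_rating_probabilities(sdt_model(mu, s), cs)
    fit <- fit_signal_distribution(pr$signal, pr$noise)
    expect_equal(fit$mu_signal, mu, tolerance = 0.01)
    expect_equal(fit$sigma_signal, s, tolerance = 0.01)
  }
})

test_that("participant criteria round-trip through analytic rates", {
  m <- paper_model()
  for (crit in list(c(-0.4, 0.1, 0.6, 1.1, 1.8),
                    c(-1, -0.3, 0.2, 0.9, 2.2))) {
    cs <- criterion_set(crit)
    pr <- analytic_rating_probabilities(m, cs)
    rec <- fit_participant_criteria(pr$signal, pr$noise, m)
    expect_equal(rec$criteria, crit, tolerance = 1e-4)
    expect_length(rec$flags, 0)
  }
})

test_that("coincident distributions fall back to the noise-only criteria", {
  m <- sdt_model(0, 1)  # signal identical to noise
  p <- rating_probabilities(c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1), "signal",
                            n_trials = 500)
  n <- rating_probabilities(c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1), "noise",
                            n_trials = 500)
  cc <- fit_participant_criteria(p, n, m)
  noise_only <- qnorm(1 - rev(cumsum(rev(n$probs)))[-1])
  expect_equal(cc$criteria, noise_only, tolerance = 1e-6)
})

test_that("degenerate all-or-nothing ratings hit the bounds and get flagged", {
  m <- paper_model()
  p <- rating_probabilities(c(0, 0, 0, 0, 0, 1), "signal", n_trials = 10)
  n <- rating_probabilities(c(1, 0, 0, 0, 0, 0), "noise", n_trials = 10)
  cc <- fit_participant_criteria(p, n, m)
  expect_true("clipped" %in% cc$flags || "repaired" %in% cc$flags)
  expect_true(all(diff(cc$criteria) > 0))
})

test_that("closed-form truncated means match quadrature", {
  m <- paper_model()
  cs <- default_criteria()
  prof <- predicted_amplitudes(m, cs, "signal")
  edges <- bin_edges(cs)
  for (i in 1:6) {
    lo <- max(edges[i], -30); hi <- min(edges[i + 1], 30)
    expect_equal(prof$amplitudes[i],
                 oracle_truncated_mean(1.385, 1.344, lo, hi),
                 tolerance = 1e-8)
  }
  # symmetric and half-open sanity points
  one_bin <- predicted_amplitudes(sdt_model(0, 1),
                                  criterion_set(c(-1, -0.5, 0, 0.5, 1)),
                                  "noise")
  expect_equal(one_bin$amplitudes[1],
               oracle_truncated_mean(0, 1, -30, -1), tolerance = 1e-8)
  expect_equal(oracle_truncated_mean(0, 1, 0, 30),
               dnorm(0) / 0.5, tolerance = 1e-8)
})

test_that("raw predicted amplitudes increase with rating", {
  for (mu in c(0.8, 1.385, 2.5)) for (s in c(1, 1.344, 1.8)) {
    prof <- predicted_amplitudes(sdt_model(mu, s), default_criteria(),
                                 "signal")
    expect_true(all(diff(prof$amplitudes) > 0))
  }
})

test_that("zero-mass bins get a flagged midpoint sentinel", {
  cs <- criterion_set(c(-20, -19.5, 0.5, 1, 19))
  expect_warning(prof <- predicted_amplitudes(sdt_model(0, 1), cs,
                                              "noise"),
                 "no probability mass")
  expect_true(prof$degenerate[2])      # bin (-20, -19.5]
  expect_equal(prof$amplitudes[2], -19.75)
  expect_false(any(prof$degenerate[3:5]))
})

test_that("normalization shifts the noise floor to 0 and scales by A_H1", {
  noise <- amplitude_profile(c(1, 2, 3, 4, 5, 6), "noise")
  sig <- amplitude_profile(c(1, 2, 3, 4, 5, 6), "signal")
  out <- normalize_profiles(noise, sig, shift = 1, divisor = 5)
  expect_equal(out$noise$amplitudes, c(0, 0.2, 0.4, 0.6, 0.8, 1.0))
  expect_equal(out$signal$state, "shifted_and_scaled")

  # profile equal to its own shift everywhere maps to all zeros
  flat <- amplitude_profile(rep(2, 6), "noise")
  out2 <- normalize_profiles(flat, sig, shift = 2, divisor = 1)
  expect_equal(out2$noise$amplitudes, rep(0, 6))

  # default divisor is the shifted signal-class rating-1 amplitude
  out3 <- normalize_profiles(noise, sig, shift = 0.5)
  expect_equal(out3$signal$amplitudes[1], 1)
  expect_error(normalize_profiles(noise, sig, shift = Inf), "finite")
  expect_error(normalize_profiles(noise, sig, shift = 10), "divisor")
})

test_that("R-squared follows the SS decomposition and its edge cases", {
  meas <- amplitude_profile(0:5, "signal", state = "shifted_and_scaled")
  expect_equal(goodness_of_fit(meas, meas), 1)
  pred_mean <- amplitude_profile(rep(2.5, 6), "signal",
                                 state = "shifted_and_scaled")
  expect_equal(goodness_of_fit(pred_mean, meas), 0)
  pred <- amplitude_profile(c(0, 0, 0, 3, 4, 5), "signal",
                            state = "shifted_and_scaled")
  expect_equal(goodness_of_fit(pred, meas), 1 - 5 / 17.5)
  flat <- amplitude_profile(rep(1, 6), "signal",
                            state = "shifted_and_scaled")
  expect_error(goodness_of_fit(meas, flat), "zero variance")
  raw <- amplitude_profile(0:5, "signal", state = "raw")
  expect_error(goodness_of_fit(raw, meas), "state")
})
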