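test_that("window means average the right samples", {
  t_ms <- seq(0, 995, by = 5)
  ws <- waveform_set(matrix(2, nrow = 3, ncol = length(t_ms)), t_ms)
  expect_equal(window_mean(ws, c(100, 400)), rep(2, 3))
  # single-sample window returns that sample
  ws2 <- waveform_set(matrix(seq_along(t_ms), nrow = 1,
                             ncol = length(t_ms), byrow = TRUE), t_ms)
  expect_equal(window_mean(ws2, c(500, 500)), 101)
  # ramp 0..1 across the window averages to ~0.5
  ramp <- matrix(seq(0, 1, length.out = length(t_ms)), nrow = 1,
                 byrow = TRUE)
  expect_equal(window_mean(waveform_set(ramp, t_ms), c(0, 995)), 0.5,
               tolerance = 1 / length(t_ms))
  expect_error(window_mean(ws, c(2000, 3000)), "window")
})

test_that("cluster test finds obvious effects and ignores identical data", {
  t_ms <- seq(0, 390, by = 10)
  set.seed(5)
  base <- matrix(rnorm(14 * 40), 14)
  ws <- waveform_set(base, t_ms)
  same <- cluster_permutation_test(ws, waveform_set(base, t_ms),
                                   n_permutations = 200, seed = 1)
  expect_equal(nrow(same$clusters), 0)

  # huge common offset: one cluster spanning the window, minimal p
  big <- waveform_set(base + 10, t_ms)
  res <- cluster_permutation_test(big, waveform_set(base, t_ms),
                                  n_permutations = 500, seed = 2)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$start_ms, 0)
  expect_equal(res$clusters$end_ms, 390)
  expect_lte(res$clusters$p_value, 1 / 500 + 1e-9)

  expect_warning(cluster_permutation_test(big, NULL,
                                          n_permutations = 50, seed = 1),
                 "coarse")
  expect_error(cluster_permutation_test(
    big, waveform_set(base[1:10, ], t_ms)), "matching")
})

test_that("seeded cluster tests are bit-reproducible", {
  t_ms <- seq(0, 195, by = 5)
  set.seed(9)
  ws <- waveform_set(matrix(rnorm(12 * 40, 0.3), 12), t_ms)
  a <- cluster_permutation_test(ws, NULL, n_permutations = 300, seed = 7)
  b <- cluster_permutation_test(ws, NULL, n_permutations = 300, seed = 7)
  expect_identical(a$clusters, b$clusters)
})

test_that("polynomial contrasts separate linear and quadratic shapes", {
  n <- 20
  set.seed(41)
  subj <- rnorm(n)  # participant offsets do not load on any contrast
  lin <- outer(subj, rep(1, 5)) + outer(rep(1, n), 1:5)
  ct <- polynomial_contrast_test(lin)
  expect_equal(ct$F[ct$contrast == "quadratic"], 0)
  expect_lt(ct$p_value[ct$contrast == "linear"], 1e-10)

  # symmetric inverted U: no linear component at all
  quad <- outer(subj, rep(1, 5)) + outer(rep(1, n), -(1:5 - 3)^2)
  ct2 <- polynomial_contrast_test(quad)
  expect_equal(ct2$F[ct2$contrast == "linear"], 0)
  expect_lt(ct2$p_value[ct2$contrast == "quadratic"], 1e-10)
  expect_error(polynomial_contrast_test(lin[1:2, ]), "3")
})

test_that("contrast scores are orthogonal on balanced noise", {
  set.seed(21)
  y <- matrix(rnorm(10000 * 5), ncol = 5)
  w <- contr.poly(5)[, 1:2]
  scores <- y %*% w
  expect_lt(abs(cor(scores[, 1], scores[, 2])), 0.05)
})

test_that("simulated linear effects reach the analytic power", {
  # slope d per bin with unit noise: contrast score ~ N(d * ||w||_t, 1)
  # where w_t are the polytomous trend weights applied to bin indices
  set.seed(31)
  n <- 17; k <- 5; slope <- 0.8
  w <- contr.poly(k)[, 1]
  ncp_per_subj <- sum(w * slope * (1:k))
  n_rep <- 400
  hits <- 0
  for (r in seq_len(n_rep)) {
    y <- outer(rep(1, n), slope * (1:k)) + matrix(rnorm(n * k), n)
    ct <- polynomial_contrast_test(y)
    if (ct$p_value[ct$contrast == "linear"] < 0.05) hits <- hits + 1
  }
  # analytic power of the one-sample t with noncentrality
  # sqrt(n) * ncp / sd(score); score sd = ||w|| = 1
  ncp <- sqrt(n) * ncp_per_subj
  crit <- qt(0.975, n - 1)
  power <- 1 - pt(crit, n - 1, ncp) + pt(-crit, n - 1, ncp)
  se <- sqrt(power * (1 - power) / n_rep)
  expect_lt(abs(hits / n_rep - power), 4 * max(se, 1e-3))
})

test_that("repeated-measures ANOVA with GG correction behaves", {
  y0 <- matrix(rep(1:10, 4), ncol = 4)
  out <- rm_anova_oneway(y0)
  expect_equal(out$F, 0)
  # two conditions: sphericity trivially holds, epsilon = 1
  set.seed(13)
  y2 <- matrix(rnorm(40), ncol = 2)
  expect_equal(rm_anova_oneway(y2)$epsilon, 1)
  # uncorrected p matches aov on the same layout
  y <- matrix(rnorm(60, mean = rep(c(0, 0.5, 1), each = 20)), ncol = 3)
  out3 <- rm_anova_oneway(y)
  df <- data.frame(y = as.vector(y),
                   cond = factor(rep(1:3, each = 20)),
                   subj = factor(rep(1:20, 3)))
  fit <- summary(aov(y ~ cond + Error(subj / cond), data = df))
  f_aov <- fit[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(out3$F, f_aov, tolerance = 1e-10)
  expect_lte(out3$p_value, 1)
  expect_gte(out3$p_value, out3$p_uncorrected)
})

test_that("GG epsilon is recovered from a known covariance structure", {
  set.seed(17)
  k <- 4
  # heterogeneous AR-like covariance with known epsilon
  sigma <- outer(1:k, 1:k, function(i, j) 0.9^abs(i - j)) *
    outer(sqrt(seq(0.5, 2, length.out = k)),
          sqrt(seq(0.5, 2, length.out = k)))
  ctr <- diag(k) - 1 / k
  sd_c <- ctr %*% sigma %*% ctr
  eps_true <- sum(diag(sd_c))^2 / ((k - 1) * sum(sd_c^2))
  ch <- chol(sigma)
  y <- matrix(rnorm(200 * k), ncol = k) %*% ch
  out <- rm_anova_oneway(y)
  expect_lt(abs(out$epsilon - eps_true), 0.1)
})

test_that("reference epochs come from the quiet late interval", {
  # zero streams give zero-valued reference epochs with t = 0 at 2 s
  streams <- list(rep(0, 20000), rep(0, 20000))
  onsets <- list(c(1000, 4000, 7000), c(2000, 5000))
  ws <- build_reference_epochs(streams, onsets)
  expect_equal(unname(ws$data), matrix(0, 2, 1100))
  expect_equal(ws$time_ms[1], -100)
  expect_equal(ws$time_ms[1100], 999)

  # onset too close to the stream end is skipped
  expect_warning(
    ws2 <- build_reference_epochs(list(rep(0, 10000)),
                                  list(c(1000, 8000))),
    "skipped")
  expect_equal(nrow(ws2$data), 1)

  # decaying evoked response (tau 300 ms) leaves < 2% of peak
  resp_t <- 0:2999
  evoked <- exp(-resp_t / 300)
  st <- rep(0, 30000)
  ons <- seq(1000, 25000, by = 3000)
  for (on in ons) st[on + resp_t] <- st[on + resp_t] + evoked
  ws3 <- build_reference_epochs(list(st), list(ons))
  expect_lt(max(abs(ws3$data)), 0.02 * max(evoked))
})
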