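#' Decision criterion from hit and false-alarm rates
#'
#' The criterion c is the negative average of the z-scored hit and
#' false-alarm rates, c = -(z(H) + z(FA)) / 2.  Positive values mean a
#' conservative observer (biased towards "absent").
#'
#' @param hit_rate,fa_rate Proportions in (0, 1).  Rates of exactly 0
#'   or 1 are clipped with a warning (by `1/(2 n_trials)` when trial
#'   counts are supplied, else by 1e-6).
#' @param n_hit_trials,n_fa_trials Optional trial counts backing the
#'   rates, used for the clipping correction.
#' @return The criterion in evidence units (noise-SD units).
#' @examples
#' criterion_from_rates(0.594, 0.099)  # ~0.53, a conservative observer
#' @export
criterion_from_rates <- function(hit_rate, fa_rate,
                                 n_hit_trials = 0, n_fa_trials = 0) {
  h <- clip_rate(hit_rate, n_hit_trials)
  f <- clip_rate(fa_rate, n_fa_trials)
  -(stats::qnorm(h) + stats::qnorm(f)) / 2
}

#' Sensitivity d' from hit and false-alarm rates
#'
#' @inheritParams criterion_from_rates
#' @return d' = z(H) - z(FA) in noise-SD units.
#' @export
d_prime <- function(hit_rate, fa_rate, n_hit_trials = 0, n_fa_trials = 0) {
  h <- clip_rate(hit_rate, n_hit_trials)
  f <- clip_rate(fa_rate, n_fa_trials)
  stats::qnorm(h) - stats::qnorm(f)
}

#' Cumulative ROC points from rating probabilities
#'
#' ROC point k (k = 1..5) treats ratings above k as "present"
#' responses: hit rate = P(rating > k | signal), false-alarm rate =
#' P(rating > k | noise).  Criterion 1 is the most liberal.
#'
#' @param signal,noise [rating_probabilities()] for the two classes.
#' @return An object of class `roc_points`: a data.frame with columns
#'   `criterion` (1..5), `hit_rate`, `fa_rate`, plus attributes
#'   `n_signal`, `n_noise`.
#' @export
cumulative_response_rates <- function(signal, noise) {
  stopifnot(inherits(signal, "rating_probabilities"),
            inherits(noise, "rating_probabilities"))
  if (signal$class != "signal" || noise$class != "noise")
    stop("arguments must be signal- and noise-class probabilities",
         call. = FALSE)
  out <- data.frame(criterion = 1:5,
                    hit_rate = upper_cumulative(signal),
                    fa_rate = upper_cumulative(noise))
  attr(out, "n_signal") <- signal$n_trials
  attr(out, "n_noise") <- noise$n_trials
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Criterion with a given upper-tail probability
#'
#' Solves P(X > c) = p_right for one Gaussian component of the model:
#' c = mu + sigma * qnorm(1 - p_right).  The Gaussian tail makes the
#' inversion closed-form; no root finding is needed.
#'
#' @param p_right Upper-tail probability, strictly in (0, 1).
#' @param model An [sdt_model()].
#' @param component `"noise"` or `"signal"` — which distribution to
#'   invert.
#' @return The criterion location in evidence units.
#' @export
solve_criterion <- function(p_right, model,
                            component = c("noise", "signal")) {
  component <- match.arg(component)
  stopifnot(inherits(model, "sdt_model"))
  if (any(p_right <= 0 | p_right >= 1))
    stop("tail probability must be strictly inside (0, 1); ",
         "clip rates before inverting", call. = FALSE)
  if (component == "noise")
    model$mu_noise + model$sigma_noise * stats::qnorm(1 - p_right)
  else
    model$mu_signal + model$sigma_signal * stats::qnorm(1 - p_right)
}

#' z-ROC slope estimate of the noise/signal SD ratio
#'
#' Transforms the rating ROC into z-coordinates and fits an ordinary
#' least-squares line z(H) ~ z(FA); under the Gaussian model the slope
#' equals sigma_noise / sigma_signal.
#'
#' @param roc ROC points from [cumulative_response_rates()].
#' @return The estimated ratio sigma_noise / sigma_signal (positive).
#' @export
estimate_sigma_ratio <- function(roc) {
  stopifnot(inherits(roc, "roc_points"))
  n_s <- attr(roc, "n_signal") %||% 0
  n_n <- attr(roc, "n_noise") %||% 0
  zh <- stats::qnorm(clip_rate(roc$hit_rate, n_s, warn = FALSE))
  zf <- stats::qnorm(clip_rate(roc$fa_rate, n_n, warn = FALSE))
  keep <- is.finite(zh) & is.finite(zf)
  if (sum(keep) < 2)
    stop("need at least 2 usable ROC points", call. = FALSE)
  zh <- zh[keep]; zf <- zf[keep]
  if (stats::sd(zf) == 0)
    stop("degenerate ROC: false-alarm z-scores are constant; ",
         "slope is underdetermined", call. = FALSE)
  slope <- unname(stats::coef(stats::lm(zh ~ zf))[2])
  if (!is.finite(slope) || slope <= 0)
    stop("z-ROC slope is not positive (", format(slope),
         "); data inconsistent with a Gaussian ROC", call. = FALSE)
  slope
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the signal distribution on grand-average rating probabilities
#'
#' Two-step estimator. (1) sigma_signal = sigma_noise / z-ROC slope.
#' (2) mu_signal is chosen so that the five criteria computed from the
#' noise distribution (via its cumulative tail probabilities) and the
#' five computed from the signal distribution agree as closely as
#' possible: the summed absolute criterion discrepancy is minimized by
#' a bounded Brent search preceded by a grid prescan.
#'
#' Intended for probabilities pooled across participants
#' (grand-average data); per-participant criteria are then obtained
#' with [fit_participant_criteria()].
#'
#' @param grand_signal,grand_noise Pooled [rating_probabilities()].
#' @param mu_range Search interval for mu_signal.
#' @return An [sdt_model()] with attributes `criteria_noise`,
#'   `criteria_signal` (the two length-5 criterion vectors at the
#'   optimum) and `objective` (the minimized discrepancy).
#' @examples
#' m0 <- sdt_model(1.385, 1.344)
#' cs <- criterion_set(c(-0.5, 0, 0.5, 1, 1.6))
#' probs <- analytic_rating_probabilities(m0, cs)
#' fit <- fit_signal_distribution(probs$signal, probs$noise)
#' @export
fit_signal_distribution <- function(grand_signal, grand_noise,
                                    mu_range = c(0, 5)) {
  roc <- cumulative_response_rates(grand_signal, grand_noise)
  sigma_signal <- 1 / estimate_sigma_ratio(roc)

  p_fa <- clip_rate(roc$fa_rate, grand_noise$n_trials, warn = FALSE)
  p_h <- clip_rate(roc$hit_rate, grand_signal$n_trials, warn = FALSE)
  c_noise <- stats::qnorm(1 - p_fa)            # mu_noise = 0, sigma_noise = 1
  q_signal <- stats::qnorm(1 - p_h)            # standardized signal criteria

  objective <- function(mu) sum(abs(c_noise - (mu + sigma_signal * q_signal)))

  # grid prescan guards against a flat or multi-basin objective
  grid <- seq(mu_range[1], mu_range[2], length.out = 101L)
  best <- grid[which.min(vapply(grid, objective, numeric(1)))]
  lo <- max(mu_range[1], best - 0.1)
  hi <- min(mu_range[2], best + 0.1)
  opt <- stats::optimize(objective, lower = lo, upper = hi, tol = 1e-6)
  mu_signal <- opt$minimum

  if (mu_signal <= 0)
    warning("fitted mu_signal is not above mu_noise; the rating data ",
            "carry little or no signal information", call. = FALSE)

  model <- sdt_model(mu_signal = mu_signal, sigma_signal = sigma_signal)
  attr(model, "criteria_noise") <- c_noise
  attr(model, "criteria_signal") <- mu_signal + sigma_signal * q_signal
  attr(model, "objective") <- opt$objective
  model
}

#' Per-participant criteria consistent with both distributions
#'
#' For each criterion i = 1..5 independently, finds the evidence value
#' c_i minimizing |P_noise(X > c_i) - p_FA,i| + |P_signal(X > c_i) -
#' p_H,i|, where p_FA,i and p_H,i are the participant's observed
#' cumulative rates.  Ties (flat stretches of the objective) are
#' broken towards the noise-only solution.  If the five solutions are
#' not increasing they are repaired by pooling adjacent violators and
#' the result is flagged `"repaired"`.
#'
#' @param signal,noise The participant's [rating_probabilities()].
#' @param model A fitted [sdt_model()] (or any object with a
#'   `tail_prob` method, e.g. a [bimodal_model()]).
#' @param bounds Search interval for each criterion (evidence units).
#' @return A [criterion_set()]; `flags` contains `"clipped"` when any
#'   observed rate needed clipping and `"repaired"` after monotone
#'   repair.
#' @export
fit_participant_criteria <- function(signal, noise, model,
                                     bounds = c(-6, 6)) {
  p_h <- upper_cumulative(signal)
  p_fa <- upper_cumulative(noise)
  flags <- character()
  if (any(p_h <= 0 | p_h >= 1 | p_fa <= 0 | p_fa >= 1))
    flags <- "clipped"
  p_h <- clip_rate(p_h, signal$n_trials, warn = FALSE)
  p_fa <- clip_rate(p_fa, noise$n_trials, warn = FALSE)

  crit <- numeric(5)
  for (i in 1:5) {
    obj <- function(c) {
      abs(tail_prob(model, c, "noise") - p_fa[i]) +
        abs(tail_prob(model, c, "signal") - p_h[i])
    }
    opt <- stats::optimize(obj, lower = bounds[1], upper = bounds[2],
                           tol = 1e-8)
    # tie-break: prefer the noise-only solution when it does as well
    c_noise <- criterion_quantile(model, p_fa[i], "noise")
    c_noise <- min(max(c_noise, bounds[1]), bounds[2])
    if (obj(c_noise) <= opt$objective + 1e-10) {
      crit[i] <- c_noise
    } else {
      crit[i] <- opt$minimum
    }
  }

  if (any(diff(crit) <= 0)) {
    crit <- pool_adjacent_violators(crit)
    flags <- c(flags, "repaired")
    if (any(diff(crit) <= 0)) {
      # pooled values can tie exactly; separate by machine-noise steps
      crit <- crit + seq_along(crit) * 1e-9
    }
  }
  criterion_set(crit, flags = flags)
}

# upper-tail probability P(X > c) for one class of a model; generic so
# the bimodal signal model can reuse the criterion machinery
tail_prob <- function(model, c, component) UseMethod("tail_prob")

#' @export
tail_prob.sdt_model <- function(model, c, component) {
  if (component == "noise")
    stats::pnorm(c, model$mu_noise, model$sigma_noise, lower.tail = FALSE)
  else
    stats::pnorm(c, model$mu_signal, model$sigma_signal, lower.tail = FALSE)
}

# inverse of tail_prob: c with P(X > c) = p
criterion_quantile <- function(model, p, component) {
  UseMethod("criterion_quantile")
}

#' @export
criterion_quantile.sdt_model <- function(model, p, component) {
  solve_criterion(p, model, component)
}

# pool adjacent violators (isotonic repair, unit weights)
pool_adjacent_violators <- function(x) {
  n <- length(x)
  vals <- as.list(x)
  wts <- rep(1, n)
  i <- 1
  while (i < length(vals)) {
    if (vals[[i]] > vals[[i + 1]]) {
      pooled <- (vals[[i]] * wts[i] + vals[[i + 1]] * wts[i + 1]) /
        (wts[i] + wts[i + 1])
      vals[[i]] <- pooled
      wts[i] <- wts[i] + wts[i + 1]
      vals[[i + 1]] <- NULL
      wts <- wts[-(i + 1)]
      if (i > 1) i <- i - 1
    } else i <- i + 1
  }
  rep(unlist(vals), wts)
}

#' Predicted mean amplitude per rating (truncated-Gaussian means)
#'
#' Under the assumption that the measured response amplitude tracks
#' the internal evidence variable, the expected amplitude for rating i
#' is the mean of the class evidence distribution truncated to the
#' rating's criterion bin (c_{i-1}, c_i].  For a Gaussian component
#' this is closed-form: mu + sigma * (phi(a) - phi(b)) / (Phi(b) -
#' Phi(a)) with a, b the standardized bin edges.
#'
#' Bins carrying probability mass below `mass_floor` get the bin
#' midpoint as a documented sentinel (finite edge for half-open bins)
#' and are marked `degenerate`.
#'
#' @param model An [sdt_model()] or [bimodal_model()].
#' @param criteria A [criterion_set()].
#' @param component `"signal"` or `"noise"`.
#' @param mass_floor Bins with less mass than this return the sentinel.
#' @return A raw [amplitude_profile()] of six values.
#' @examples
#' m <- sdt_model(1.385, 1.344)
#' cs <- criterion_set(c(-0.5, 0, 0.5, 1, 1.6))
#' predicted_amplitudes(m, cs, "signal")
#' @export
predicted_amplitudes <- function(model, criteria,
                                 component = c("signal", "noise"),
                                 mass_floor = 1e-12) {
  component <- match.arg(component)
  stopifnot(inherits(criteria, "criterion_set"))
  edges <- bin_edges(criteria)
  n_bins <- length(edges) - 1L
  amp <- numeric(n_bins)
  degen <- logical(n_bins)
  for (i in seq_len(n_bins)) {
    res <- truncated_mean(model, edges[i], edges[i + 1L], component)
    if (res$mass < mass_floor) {
      amp[i] <- bin_midpoint(edges[i], edges[i + 1L])
      degen[i] <- TRUE
    } else {
      amp[i] <- res$mean
    }
  }
  if (any(degen))
    warning("rating bin(s) ", paste(which(degen), collapse = ", "),
            " carry no probability mass; midpoint sentinel reported",
            call. = FALSE)
  amplitude_profile(amp, class = component, state = "raw",
                    degenerate = degen)
}

# mean and mass of one class distribution truncated to (lo, hi]
truncated_mean <- function(model, lo, hi, component) {
  UseMethod("truncated_mean")
}

#' @export
truncated_mean.sdt_model <- function(model, lo, hi, component) {
  if (component == "noise") {
    mu <- model$mu_noise; s <- model$sigma_noise
  } else {
    mu <- model$mu_signal; s <- model$sigma_signal
  }
  gaussian_truncated_mean(mu, s, lo, hi)
}

gaussian_truncated_mean <- function(mu, s, lo, hi) {
  a <- (lo - mu) / s
  b <- (hi - mu) / s
  mass <- stats::pnorm(b) - stats::pnorm(a)
  if (mass <= 0) return(list(mean = NA_real_, mass = max(mass, 0)))
  m <- mu + s * (stats::dnorm(a) - stats::dnorm(b)) / mass
  list(mean = m, mass = mass)
}

bin_midpoint <- function(lo, hi) {
  if (is.infinite(lo) && is.infinite(hi)) return(0)
  if (is.infinite(lo)) return(hi)
  if (is.infinite(hi)) return(lo)
  (lo + hi) / 2
}

#' Shift and scale amplitude profiles to the common reporting frame
#'
#' Normalization used before averaging across participants: every
#' amplitude is shifted by the across-participant mean of the
#' noise-class rating-1 amplitude (so the lowest rating maps to 0 and
#' negative values are avoided), then divided by the post-shift
#' signal-class rating-1 amplitude A_H1.
#'
#' @param noise_profile,signal_profile Raw [amplitude_profile()]s for
#'   one participant.
#' @param shift The across-participant mean of the noise-class A_1
#'   (evidence units).
#' @param divisor Explicit normalization divisor A_H1 (post-shift).
#'   The pipeline passes the criterion-1 hit amplitude
#'   E\[X | X > c_1, signal\] minus the shift; when omitted the
#'   shifted signal-class A_1 is used instead.  The constant is
#'   configurable because it is a reporting convention, not a model
#'   parameter.
#' @return A list with shifted-and-scaled `noise` and `signal`
#'   profiles.
#' @export
normalize_profiles <- function(noise_profile, signal_profile, shift,
                               divisor = NULL) {
  stopifnot(inherits(noise_profile, "amplitude_profile"),
            inherits(signal_profile, "amplitude_profile"))
  if (noise_profile$state != "raw" || signal_profile$state != "raw")
    stop("profiles must be in the raw state", call. = FALSE)
  if (!is.finite(shift))
    stop("shift constant must be finite", call. = FALSE)

  ns <- noise_profile$amplitudes - shift
  ss <- signal_profile$amplitudes - shift
  if (is.null(divisor)) divisor <- ss[1]
  if (!is.finite(divisor) || divisor <= 0)
    stop("normalization divisor must be positive and finite (got ",
         format(divisor), ")", call. = FALSE)

  list(
    noise = amplitude_profile(ns / divisor, class = "noise",
                              state = "shifted_and_scaled",
                              shift = shift, scale = divisor,
                              degenerate = noise_profile$degenerate),
    signal = amplitude_profile(ss / divisor, class = "signal",
                               state = "shifted_and_scaled",
                               shift = shift, scale = divisor,
                               degenerate = signal_profile$degenerate))
}

#' Coefficient of determination between profiles
#'
#' R^2 = 1 - SS_res / SS_tot over the concatenated rating-wise means.
#' Can be negative when the prediction is worse than the grand mean.
#' Ratings flagged degenerate on either side are dropped.
#'
#' @param predicted,measured [amplitude_profile()]s (or plain numeric
#'   vectors) of equal length and normalization state.
#' @return A single number <= 1.
#' @export
goodness_of_fit <- function(predicted, measured) {
  p <- as_amp_vector(predicted)
  m <- as_amp_vector(measured)
  if (length(p$x) != length(m$x))
    stop("profiles differ in length", call. = FALSE)
  if (!is.null(p$state) && !is.null(m$state) && p$state != m$state)
    stop("profiles differ in normalization state (", p$state, " vs ",
         m$state, ")", call. = FALSE)
  keep <- !(p$degen | m$degen)
  x <- p$x[keep]; y <- m$x[keep]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    stop("measured profile has zero variance; R^2 undefined",
         call. = FALSE)
  1 - sum((y - x)^2) / ss_tot
}

as_amp_vector <- function(x) {
  if (inherits(x, "amplitude_profile"))
    list(x = x$amplitudes, state = x$state, degen = x$degenerate)
  else
    list(x = as.numeric(x), state = NULL, degen = rep(FALSE, length(x)))
}

#' Analytic rating probabilities for a model and criterion set
#'
#' Exact bin masses of the two evidence distributions between
#' consecutive criteria — the noiseless inverse of the rating
#' generation process, used for parameter-recovery checks and for
#' computing model-implied response frequencies.
#'
#' @param model An [sdt_model()] or [bimodal_model()].
#' @param criteria A [criterion_set()].
#' @return List with `signal` and `noise` [rating_probabilities()].
#' @export
analytic_rating_probabilities <- function(model, criteria) {
  stopifnot(inherits(criteria, "criterion_set"))
  edges <- bin_edges(criteria)
  upper_s <- c(1, vapply(criteria$criteria, function(c)
    tail_prob(model, c, "signal"), numeric(1)), 0)
  upper_n <- c(1, vapply(criteria$criteria, function(c)
    tail_prob(model, c, "noise"), numeric(1)), 0)
  p_s <- -diff(upper_s)
  p_n <- -diff(upper_n)
  list(signal = rating_probabilities(p_s / sum(p_s), "signal"),
       noise = rating_probabilities(p_n / sum(p_n), "noise"))
}
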