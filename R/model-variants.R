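#' Bimodal-signal (bifurcation) detection model
#'
#' Competitor model in which perception is dichotomous: the signal
#' evidence distribution is a two-component Gaussian mixture — a lower
#' "undetected" mode and an upper "detected" mode — sharing one
#' standard deviation with the noise distribution.  The mixture weight
#' `beta` of the upper mode is fixed externally from the dichotomized
#' detection rate (ratings 4-6 counted as hits).
#'
#' @param beta Weight of the upper (detected) mode, in \[0, 1\].
#' @param mu_high Mean of the upper mode (evidence units).
#' @param mu_low Mean of the lower mode; defaults to the noise mean 0,
#'   mirroring the bifurcation account where undetected signals fall
#'   back to a noise-like state.
#' @param sigma_common SD shared by the noise distribution and both
#'   signal modes.
#' @return An object of class `bimodal_model`.
#' @export
bimodal_model <- function(beta, mu_high, mu_low = 0, sigma_common = 1) {
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]", call. = FALSE)
  if (mu_low > mu_high) stop("mu_low must not exceed mu_high", call. = FALSE)
  if (sigma_common <= 0) stop("sigma_common must be positive", call. = FALSE)
  structure(list(beta = beta, mu_low = mu_low, mu_high = mu_high,
                 mu_noise = 0, sigma_common = sigma_common),
            class = "bimodal_model")
}

#' @export
print.bimodal_model <- function(x, ...) {
  cat("Bimodal-signal (bifurcation) model\n")
  cat(sprintf("  signal: %.2f N(%.3f, %.2f) + %.2f N(%.3f, %.2f)\n",
              1 - x$beta, x$mu_low, x$sigma_common,
              x$beta, x$mu_high, x$sigma_common))
  cat(sprintf("  noise : N(%.3f, %.2f)\n", x$mu_noise, x$sigma_common))
  invisible(x)
}

#' Mixture weight of the bifurcation model from detection performance
#'
#' The weight of the upper ("detected") mode is set to the group-mean
#' dichotomized detection rate — ratings 4-6 counted as hits — rounded
#' to two decimals, the convention used when fixing beta externally
#' rather than fitting it.
#'
#' @param x Either the group-mean dichotomized hit rate (a single
#'   proportion) or the output of [dichotomize_ratings()], whose
#'   participant hit rates are averaged first.
#' @return beta, a proportion rounded to two decimals.
#' @export
bifurcation_weight <- function(x) {
  rate <- if (is.data.frame(x)) mean(x$hit_rate) else as.numeric(x)
  if (rate < 0 || rate > 1) stop("hit rate outside [0, 1]", call. = FALSE)
  round(rate, 2)
}

#' Density of the bimodal signal distribution
#'
#' (1 - beta) N(x; mu_low, sigma) + beta N(x; mu_high, sigma).
#'
#' @param x Evidence values.
#' @param model A [bimodal_model()].
#' @return Density values (per evidence unit).
#' @export
bimodal_density <- function(x, model) {
  stopifnot(inherits(model, "bimodal_model"))
  (1 - model$beta) * stats::dnorm(x, model$mu_low, model$sigma_common) +
    model$beta * stats::dnorm(x, model$mu_high, model$sigma_common)
}

#' @export
tail_prob.bimodal_model <- function(model, c, component) {
  if (component == "noise")
    stats::pnorm(c, model$mu_noise, model$sigma_common, lower.tail = FALSE)
  else
    (1 - model$beta) *
      stats::pnorm(c, model$mu_low, model$sigma_common, lower.tail = FALSE) +
      model$beta *
      stats::pnorm(c, model$mu_high, model$sigma_common, lower.tail = FALSE)
}

# numeric tail inversion: the mixture upper tail is strictly
# decreasing in c, so bisection has a unique root
#' @export
criterion_quantile.bimodal_model <- function(model, p, component) {
  if (component == "noise")
    return(model$mu_noise + model$sigma_common * stats::qnorm(1 - p))
  lo <- model$mu_low - 6 * model$sigma_common
  hi <- model$mu_high + 6 * model$sigma_common
  stats::uniroot(function(c) tail_prob(model, c, "signal") - p,
                 lower = lo, upper = hi, tol = 1e-8)$root
}

#' @export
truncated_mean.bimodal_model <- function(model, lo, hi, component) {
  if (component == "noise")
    return(gaussian_truncated_mean(model$mu_noise, model$sigma_common,
                                   lo, hi))
  lo_part <- gaussian_truncated_mean(model$mu_low, model$sigma_common,
                                     lo, hi)
  hi_part <- gaussian_truncated_mean(model$mu_high, model$sigma_common,
                                     lo, hi)
  w_lo <- (1 - model$beta) * lo_part$mass
  w_hi <- model$beta * hi_part$mass
  mass <- w_lo + w_hi
  if (mass <= 0) return(list(mean = NA_real_, mass = 0))
  m_lo <- if (w_lo > 0) lo_part$mean else 0
  m_hi <- if (w_hi > 0) hi_part$mean else 0
  list(mean = (w_lo * m_lo + w_hi * m_hi) / mass, mass = mass)
}

#' Fit the bimodal model on grand-average rating probabilities
#'
#' Same criterion-consistency search as [fit_signal_distribution()]
#' but with the bimodal signal tail: mu_low is pinned at the noise
#' mean, sigma_common = 1, and only mu_high is searched.  The signal
#' criteria are obtained by numeric inversion of the mixture tail.
#'
#' @param grand_signal,grand_noise Pooled [rating_probabilities()].
#' @param beta Externally supplied mixture weight (the dichotomized
#'   group detection rate).
#' @param mu_range Search interval for mu_high.
#' @return A [bimodal_model()] with an `objective` attribute.  When
#'   `beta = 0` the signal distribution coincides with noise and the
#'   fit is flagged unidentifiable (`attr(. , "unidentifiable")`).
#' @export
fit_bimodal_model <- function(grand_signal, grand_noise, beta,
                              mu_range = c(0, 6)) {
  roc <- cumulative_response_rates(grand_signal, grand_noise)
  p_fa <- clip_rate(roc$fa_rate, grand_noise$n_trials, warn = FALSE)
  p_h <- clip_rate(roc$hit_rate, grand_signal$n_trials, warn = FALSE)
  c_noise <- stats::qnorm(1 - p_fa)

  if (beta == 0) {
    m <- bimodal_model(0, mu_high = 0)
    attr(m, "unidentifiable") <- TRUE
    warning("beta = 0: signal distribution identical to noise; ",
            "mu_high is unidentifiable", call. = FALSE)
    return(m)
  }

  objective <- function(mu_high) {
    m <- bimodal_model(beta, mu_high = mu_high)
    c_signal <- vapply(p_h, function(p)
      criterion_quantile(m, p, "signal"), numeric(1))
    sum(abs(c_noise - c_signal))
  }
  grid <- seq(mu_range[1] + 1e-3, mu_range[2], length.out = 61L)
  best <- grid[which.min(vapply(grid, objective, numeric(1)))]
  opt <- stats::optimize(objective,
                         lower = max(mu_range[1], best - 0.15),
                         upper = min(mu_range[2], best + 0.15),
                         tol = 1e-6)
  m <- bimodal_model(beta, mu_high = opt$minimum)
  attr(m, "objective") <- opt$objective
  m
}

#' Zero out sub-threshold predicted amplitudes
#'
#' Threshold-model prediction: ratings at or below the threshold
#' correspond to trials that evoked no awareness-related activity, so
#' their amplitudes are set to zero; above-threshold amplitudes are
#' untouched.  Applied to normalized profiles only, so that "zero"
#' means the signal-absent baseline.
#'
#' @param profile A normalized (`shifted_and_scaled`)
#'   [amplitude_profile()].
#' @param threshold_rating Highest rating considered sub-threshold
#'   (default 3, i.e. the threshold sits between ratings 3 and 4);
#'   0 leaves the profile unchanged.
#' @return The thresholded [amplitude_profile()].
#' @export
threshold_amplitudes <- function(profile, threshold_rating = 3L) {
  stopifnot(inherits(profile, "amplitude_profile"))
  if (profile$state != "shifted_and_scaled")
    stop("threshold model applies to normalized profiles; got state '",
         profile$state, "'", call. = FALSE)
  if (threshold_rating < 0 || threshold_rating > 6)
    stop("threshold_rating must be in 0..6", call. = FALSE)
  amps <- profile$amplitudes
  if (threshold_rating >= 1)
    amps[seq_len(threshold_rating)] <- 0
  amplitude_profile(amps, class = profile$class, state = profile$state,
                    shift = profile$shift, scale = profile$scale,
                    degenerate = profile$degenerate)
}

#' Pearson similarity of two evidence densities
#'
#' Correlates two signal-distribution densities evaluated on a common
#' evidence grid — used to quantify how similar the fitted unimodal
#' and bimodal signal distributions are.
#'
#' @param density_a,density_b Functions of one numeric argument
#'   returning densities (e.g. `function(x) bimodal_density(x, m)`).
#' @param grid Evidence-axis sample points (>= 10, spanning the
#'   support of both densities).
#' @return Pearson's r in \[-1, 1\].
#' @export
distribution_similarity <- function(density_a, density_b, grid) {
  if (length(grid) < 10)
    stop("grid must have at least 10 points", call. = FALSE)
  da <- density_a(grid)
  db <- density_b(grid)
  if (stats::sd(da) == 0 || stats::sd(db) == 0)
    stop("density constant on grid; correlation undefined",
         call. = FALSE)
  stats::cor(da, db)
}
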