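#' Simulation configuration for the rating-experiment generator
#'
#' Bundles the generative model, group criteria, design counts and
#' nuisance parameters.  Defaults reproduce the rating experiment's
#' design: 17 participants, 500 signal-present and 100 signal-absent
#' trials each (two parts of 250 + 50), six ratings produced by five
#' ordered criteria, signal evidence N(1.385, 1.344) vs noise N(0, 1),
#' and between-participant criterion jitter with SD 0.4 (matching the
#' reported spread of the decision criterion).  The default group
#' criteria are anchored on the reported signal-side response rates —
#' cumulative rates 0.80, 0.697, 0.594, 0.37, 0.185 above criteria
#' 1..5 — so the generator reproduces the 59.4% dichotomized
#' detection rate at the ratings-3/4 split and the 37% rate at the
#' 4/5 split.
#'
#' @param model Generative [sdt_model()] or [bimodal_model()].
#' @param criteria Group-level [criterion_set()].
#' @param n_participants Number of participants.
#' @param n_signal,n_absent Trials per participant and class.
#' @param criterion_jitter_sd SD of i.i.d. Gaussian jitter added to
#'   each participant's criteria (re-sorted afterwards).
#' @param amplitude_noise_sd SD of the measurement noise added to
#'   evidence to obtain trial amplitudes.
#' @param pupil List of pupil-trace parameters: `kernel_latency_ms`,
#'   `kernel_shape`, `kernel_scale_ms` (gamma-kernel timing; the
#'   default peaks near 1 s after onset), `gain`, `evidence_coupling`
#'   (added gain per unit evidence), `baseline`, `drift_amplitude`,
#'   `noise_sd`, `blink_rate_hz`, `blink_ms`, `iti_ms`.
#' @param waveform List of waveform-template parameters: `aan_window_ms`
#'   (negative-going auditory component), `p3_window_ms`, `aan_gain`,
#'   `p3_gain`, `noise_sd`, `time_ms`.
#' @param seed Master seed; all child streams derive from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(model = sdt_model(1.385, 1.344),
                              criteria = criterion_set(
                                c(0.254, 0.692, 1.065, 1.831, 2.590)),
                              n_participants = 17L,
                              n_signal = 500L,
                              n_absent = 100L,
                              criterion_jitter_sd = 0.4,
                              amplitude_noise_sd = 0.5,
                              pupil = list(),
                              waveform = list(),
                              seed = 1L) {
  pupil_def <- list(kernel_latency_ms = 500, kernel_shape = 3,
                    kernel_scale_ms = 250, gain = 60,
                    evidence_coupling = 20, baseline = 800,
                    drift_amplitude = 20, noise_sd = 3,
                    blink_rate_hz = 0.1, blink_ms = 120, iti_ms = 3000)
  wave_def <- list(aan_window_ms = c(150, 700), p3_window_ms = c(400, 600),
                   aan_gain = 1, p3_gain = 0.5, noise_sd = 0.3,
                   time_ms = seq(-200, 995, by = 5))
  pupil <- utils::modifyList(pupil_def, pupil)
  waveform <- utils::modifyList(wave_def, waveform)
  if (n_participants <= 0 || n_signal <= 0 || n_absent <= 0)
    stop("counts must be positive", call. = FALSE)
  if (criterion_jitter_sd < 0 || amplitude_noise_sd < 0)
    stop("SDs must be non-negative", call. = FALSE)
  structure(list(model = model, criteria = criteria,
                 n_participants = as.integer(n_participants),
                 n_signal = as.integer(n_signal),
                 n_absent = as.integer(n_absent),
                 criterion_jitter_sd = criterion_jitter_sd,
                 amplitude_noise_sd = amplitude_noise_sd,
                 pupil = pupil, waveform = waveform,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# deterministic child seed per stream, kept under 2^31
child_seed <- function(config, stream) {
  (config$seed * 1009L + stream * 9973L) %% 2147483647L
}

draw_evidence <- function(model, n, class) UseMethod("draw_evidence")

#' @export
draw_evidence.sdt_model <- function(model, n, class) {
  if (class == "signal")
    stats::rnorm(n, model$mu_signal, model$sigma_signal)
  else
    stats::rnorm(n, model$mu_noise, model$sigma_noise)
}

#' @export
draw_evidence.bimodal_model <- function(model, n, class) {
  if (class == "noise")
    return(stats::rnorm(n, model$mu_noise, model$sigma_common))
  hi <- stats::runif(n) < model$beta
  mu <- ifelse(hi, model$mu_high, model$mu_low)
  stats::rnorm(n, mu, model$sigma_common)
}

#' Simulate a six-point rating experiment
#'
#' Per trial, internal evidence is drawn from the class distribution
#' and the rating is 1 plus the number of the participant's criteria
#' below the evidence.  Per-participant criteria are the group
#' criteria plus i.i.d. Gaussian jitter, re-sorted.  The latent
#' evidence is kept in the output so that trial amplitudes and pupil
#' gain can be coupled to it.
#'
#' @param config A [simulation_config()].
#' @return A list: `trials` (trial table per [trial-tables], with
#'   extra columns `evidence` and `rating`), `participant_criteria`
#'   (participants x 5 matrix), `config`.
#' @export
simulate_rating_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(child_seed(config, 1L))
  np <- config$n_participants
  crit0 <- config$criteria$criteria
  pc <- t(vapply(seq_len(np), function(p) {
    sort(crit0 + stats::rnorm(5, 0, config$criterion_jitter_sd))
  }, numeric(5)))
  rows <- vector("list", np)
  for (p in seq_len(np)) {
    n_s <- config$n_signal; n_a <- config$n_absent
    ev <- c(draw_evidence(config$model, n_s, "signal"),
            draw_evidence(config$model, n_a, "noise"))
    cond <- c(rep("signal", n_s), rep("absent", n_a))
    # trials interleaved chronologically across the two parts
    ord <- sample.int(n_s + n_a)
    ev <- ev[ord]; cond <- cond[ord]
    rating <- 1L + rowSums(outer(ev, pc[p, ], ">"))
    n_tot <- n_s + n_a
    rows[[p]] <- data.frame(
      participant_id = p,
      condition = cond,
      response = rating,
      rating = rating,
      run = rep(1:2, each = ceiling(n_tot / 2))[seq_len(n_tot)],
      trial_index = seq_len(n_tot),
      evidence = ev)
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(trials = trials, participant_criteria = pc, config = config)
}

#' Add measurement noise to latent evidence to get trial amplitudes
#'
#' The linking assumption of the amplitude model is that the measured
#' single-trial response amplitude tracks the internal evidence; the
#' generator implements it as identity plus additive Gaussian noise.
#' Within-rating mean amplitudes then converge to the truncated-
#' Gaussian predictions as the trial count grows.
#'
#' @param sim Output of [simulate_rating_experiment()].
#' @param noise_sd Measurement noise SD; defaults to the config value.
#' @return The trial table with an `amplitude` column added.
#' @export
simulate_trial_amplitudes <- function(sim, noise_sd = NULL) {
  trials <- sim$trials
  if (is.null(trials$evidence))
    stop("trial table lacks latent evidence", call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- sim$config$amplitude_noise_sd
  set.seed(child_seed(sim$config, 2L))
  trials$amplitude <- trials$evidence +
    stats::rnorm(nrow(trials), 0, noise_sd)
  trials
}

# gamma-shaped dilation kernel, unit peak, zero before latency
pupil_kernel <- function(t_ms, latency_ms, shape, scale_ms) {
  tt <- pmax(t_ms - latency_ms, 0)
  k <- (tt / scale_ms)^(shape - 1) * exp(-tt / scale_ms)
  pk <- max(k)
  if (pk > 0) k / pk else k
}

#' Simulate continuous pupil traces for each participant
#'
#' Trace = baseline + slow sinusoidal drift + event-locked gamma-like
#' dilation kernels whose gain increases with trial evidence + white
#' noise, with blinks (dropouts to near zero) injected at random and
#' annotated.  The per-trial baseline pupil (mean over the 200 ms
#' before onset) is written back into the trial table.
#'
#' @param sim Output of [simulate_rating_experiment()].
#' @return List of per-participant [pupil_trace()]s plus the updated
#'   trial table (`$trials`, with `baseline_pupil`).
#' @export
simulate_pupil_traces <- function(sim) {
  cfg <- sim$config
  pp <- cfg$pupil
  set.seed(child_seed(cfg, 3L))
  trials <- sim$trials
  trials$baseline_pupil <- NA_real_
  traces <- vector("list", cfg$n_participants)
  fs <- 1000
  for (p in seq_len(cfg$n_participants)) {
    tp <- trials[trials$participant_id == p, , drop = FALSE]
    n_tr <- nrow(tp)
    iti <- pp$iti_ms
    onsets <- 1000 + (seq_len(n_tr) - 1L) * iti
    n_samp <- onsets[n_tr] + iti + 2000
    t_ms <- seq_len(n_samp)
    x <- pp$baseline +
      pp$drift_amplitude * sin(2 * pi * t_ms / (60 * fs)) +
      stats::rnorm(n_samp, 0, pp$noise_sd)
    kern_t <- seq(0, iti + 1500)
    kern <- pupil_kernel(kern_t, pp$kernel_latency_ms, pp$kernel_shape,
                         pp$kernel_scale_ms)
    for (i in seq_len(n_tr)) {
      gain <- pp$gain + pp$evidence_coupling * tp$evidence[i]
      idx <- onsets[i] + kern_t
      ok <- idx <= n_samp
      x[idx[ok]] <- x[idx[ok]] + gain * kern[ok]
    }
    # blinks: poisson process, annotated, pupil drops to ~0
    n_blinks <- stats::rpois(1, pp$blink_rate_hz * n_samp / fs)
    blinks <- NULL
    if (n_blinks > 0) {
      starts <- sort(sample.int(n_samp - pp$blink_ms - 500, n_blinks)) + 200
      blinks <- cbind(starts, starts + pp$blink_ms - 1)
      for (b in seq_len(nrow(blinks)))
        x[blinks[b, 1]:blinks[b, 2]] <- 0
    }
    base_idx <- lapply(onsets, function(on) (on - 200):(on - 1))
    trials$baseline_pupil[trials$participant_id == p] <-
      vapply(base_idx, function(ii) mean(x[ii]), numeric(1))
    traces[[p]] <- pupil_trace(x, blinks = blinks, onsets = onsets, fs = fs)
  }
  list(traces = traces, trials = trials)
}

#' Simulate per-condition group waveforms
#'
#' Per participant and rating, the condition-mean waveform is a
#' negative-going early component (an awareness-negativity template
#' in the 150-700 ms range) scaled by the mean evidence in the
#' condition, plus a late positive component for high ratings, plus
#' participant noise.  Also returns continuous streams with the same
#' evoked responses embedded at 3-s spaced onsets, suitable for
#' [build_reference_epochs()].
#'
#' @param sim Output of [simulate_rating_experiment()].
#' @return List: `by_rating` (list of [waveform_set()] per rating),
#'   `streams`, `onsets`, `time_ms`.
#' @export
simulate_group_waveforms <- function(sim) {
  cfg <- sim$config
  wf <- cfg$waveform
  set.seed(child_seed(cfg, 4L))
  t_ms <- wf$time_ms
  aan <- -template_bump(t_ms, wf$aan_window_ms)
  p3 <- template_bump(t_ms, wf$p3_window_ms)
  np <- cfg$n_participants
  trials <- sim$trials

  by_rating <- lapply(1:6, function(r) {
    mat <- t(vapply(seq_len(np), function(p) {
      ev <- trials$evidence[trials$participant_id == p &
                              trials$rating == r &
                              trials$condition == "signal"]
      mean_ev <- if (length(ev)) mean(ev) else 0
      w <- wf$aan_gain * mean_ev * aan +
        (if (r >= 5) wf$p3_gain * p3 else 0)
      w + stats::rnorm(length(t_ms), 0, wf$noise_sd)
    }, numeric(length(t_ms))))
    waveform_set(mat, t_ms)
  })

  # continuous streams: decaying evoked bump at each onset, quiet after
  fs <- 1000
  n_onsets <- 20L
  onset_list <- vector("list", np)
  streams <- vector("list", np)
  for (p in seq_len(np)) {
    onsets <- 500 + (seq_len(n_onsets) - 1L) * 3000
    n_samp <- onsets[n_onsets] + 3500
    st <- stats::rnorm(n_samp, 0, wf$noise_sd)
    resp_t <- 0:1499
    resp <- -exp(-resp_t / 300) * sin(2 * pi * resp_t / 600)
    for (on in onsets) st[on + resp_t] <- st[on + resp_t] + resp
    streams[[p]] <- st
    onset_list[[p]] <- onsets
  }
  list(by_rating = by_rating, streams = streams, onsets = onset_list,
       time_ms = t_ms)
}

# smooth raised-cosine bump supported on window_ms, unit peak
template_bump <- function(t_ms, window_ms) {
  out <- numeric(length(t_ms))
  inside <- t_ms >= window_ms[1] & t_ms <= window_ms[2]
  phase <- (t_ms[inside] - window_ms[1]) / diff(window_ms)
  out[inside] <- 0.5 * (1 - cos(2 * pi * phase))
  out
}
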