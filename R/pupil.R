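#' Continuous pupil trace container
#'
#' @param samples Pupil area samples (arbitrary units) at 1000 Hz.
#' @param blinks Two-column matrix or data.frame of blink start/end
#'   sample indices (1-based, inclusive).
#' @param onsets Stimulus-onset sample indices.
#' @param fs Sampling rate in Hz; the pipeline assumes 1000.
#' @return An object of class `pupil_trace`.
#' @export
pupil_trace <- function(samples, blinks = NULL, onsets = integer(),
                        fs = 1000) {
  samples <- as.numeric(samples)
  if (is.null(blinks)) blinks <- matrix(numeric(0), ncol = 2)
  blinks <- as.matrix(blinks)
  if (ncol(blinks) != 2 && nrow(blinks) > 0)
    stop("blinks must have two columns (start, end)", call. = FALSE)
  if (nrow(blinks) > 0 &&
      (any(blinks < 1) || any(blinks > length(samples))))
    stop("blink interval outside trace bounds", call. = FALSE)
  structure(list(samples = samples, blinks = blinks,
                 onsets = as.integer(onsets), fs = fs,
                 interpolated = rep(FALSE, length(samples))),
            class = "pupil_trace")
}

#' Linear interpolation across blinks
#'
#' Replaces samples from 100 ms before each annotated blink to 100 ms
#' after it by the straight line between the two boundary samples.
#' Pads truncated at a trace edge fall back to holding the nearest
#' valid value, with a warning.
#'
#' @param trace A [pupil_trace()].
#' @param pad_ms Padding around each blink in ms (default 100).
#' @return The trace with blinks interpolated and the per-sample
#'   logical `interpolated` mask updated.
#' @export
interpolate_blinks <- function(trace, pad_ms = 100) {
  stopifnot(inherits(trace, "pupil_trace"))
  n <- length(trace$samples)
  pad <- round(pad_ms * trace$fs / 1000)
  x <- trace$samples
  mask <- trace$interpolated
  if (nrow(trace$blinks) > 0) {
    for (b in seq_len(nrow(trace$blinks))) {
      i0 <- trace$blinks[b, 1] - pad
      i1 <- trace$blinks[b, 2] + pad
      lo <- i0 - 1  # boundary samples just outside the padded gap
      hi <- i1 + 1
      if (lo < 1 || hi > n) {
        warning("blink pad extends past trace edge; holding boundary value",
                call. = FALSE)
        i0 <- max(i0, 1); i1 <- min(i1, n)
        lo <- max(lo, 1); hi <- min(hi, n)
        if (lo >= i0) x[i0:i1] <- x[hi] else if (hi <= i1)
          x[i0:i1] <- x[lo]
        else x[i0:i1] <- stats::approx(c(lo, hi), x[c(lo, hi)],
                                       xout = i0:i1)$y
      } else {
        x[i0:i1] <- stats::approx(c(lo, hi), x[c(lo, hi)],
                                  xout = i0:i1)$y
      }
      mask[max(i0, 1):min(i1, n)] <- TRUE
    }
  }
  trace$samples <- x
  trace$interpolated <- mask
  trace
}

#' Event-locked pupil epoch
#'
#' Window -500..+3000 ms relative to stimulus onset (3500 samples at
#' 1000 Hz; t = 0 is the first post-onset sample).
#'
#' @param samples Epoch samples.
#' @param time_ms Time axis in ms.
#' @param interpolated_fraction Fraction of samples that were blink
#'   interpolated.
#' @param state Processing state.
#' @param fs Sampling rate (Hz).
#' @return An object of class `pupil_epoch`; `rejected` is TRUE iff
#'   `interpolated_fraction > 0.20`.
#' @export
pupil_epoch <- function(samples, time_ms, interpolated_fraction = 0,
                        state = c("raw", "divisive_baselined",
                                  "derivative"),
                        fs = 1000) {
  state <- match.arg(state)
  structure(list(samples = as.numeric(samples),
                 time_ms = as.numeric(time_ms),
                 interpolated_fraction = interpolated_fraction,
                 rejected = interpolated_fraction > 0.20,
                 state = state, fs = fs),
            class = "pupil_epoch")
}

#' Low-pass filter and epoch a pupil trace
#'
#' Applies a zero-phase (forward-backward) 2nd-order Butterworth
#' low-pass at `cutoff_hz` to the continuous blink-interpolated
#' trace, then cuts epochs from 500 ms before to 3000 ms after each
#' stimulus onset.  Epochs with more than 20% interpolated samples
#' are marked rejected; onsets too close to the trace edge are
#' dropped with a warning.
#'
#' @param trace A blink-interpolated [pupil_trace()].
#' @param cutoff_hz Low-pass cut-off (default 4 Hz).
#' @param window_ms Epoch window relative to onset, default
#'   `c(-500, 3000)`.
#' @return A list of [pupil_epoch()]s.
#' @export
preprocess_and_epoch <- function(trace, cutoff_hz = 4,
                                 window_ms = c(-500, 3000)) {
  stopifnot(inherits(trace, "pupil_trace"))
  bf <- signal::butter(2, cutoff_hz / (trace$fs / 2), type = "low")
  filtered <- as.numeric(signal::filtfilt(bf, trace$samples))
  n <- length(filtered)
  w0 <- round(window_ms[1] * trace$fs / 1000)
  w1 <- round(window_ms[2] * trace$fs / 1000)
  time_ms <- seq(w0, w1 - 1) * 1000 / trace$fs
  epochs <- list()
  for (onset in trace$onsets) {
    i0 <- onset + w0
    i1 <- onset + w1 - 1
    if (i0 < 1 || i1 > n) {
      warning("onset at sample ", onset,
              " too close to trace edge; epoch dropped", call. = FALSE)
      next
    }
    frac <- mean(trace$interpolated[i0:i1])
    epochs[[length(epochs) + 1L]] <-
      pupil_epoch(filtered[i0:i1], time_ms, interpolated_fraction = frac,
                  state = "raw", fs = trace$fs)
  }
  epochs
}

baseline_indices <- function(epoch, window_ms = c(-200, 0)) {
  which(epoch$time_ms >= window_ms[1] & epoch$time_ms < window_ms[2])
}

#' Divisive baseline correction of a pupil epoch
#'
#' Divides every sample by the mean pupil size in the 200 ms before
#' stimulus onset, turning the epoch into a relative change signal
#' whose baseline-window mean is exactly 1.
#'
#' @param epoch A raw [pupil_epoch()].
#' @param baseline_ms Baseline window in ms relative to onset.
#' @return The baselined epoch (`state = "divisive_baselined"`, with
#'   `baseline_value` recorded).
#' @export
divisive_baseline <- function(epoch, baseline_ms = c(-200, 0)) {
  stopifnot(inherits(epoch, "pupil_epoch"))
  if (epoch$state != "raw")
    stop("divisive baseline applies to raw epochs; got '",
         epoch$state, "'", call. = FALSE)
  idx <- baseline_indices(epoch, baseline_ms)
  b <- mean(epoch$samples[idx])
  if (!is.finite(b) || b <= 0)
    stop("baseline mean not positive (", format(b),
         "); epoch rejected", call. = FALSE)
  epoch$samples <- epoch$samples / b
  epoch$baseline_value <- b
  epoch$state <- "divisive_baselined"
  epoch
}

#' Pupil dilation response derivative (PDR')
#'
#' First difference of the raw (not divisively baselined) epoch,
#' smoothed with a centered 200-sample moving mean (a non-causal
#' ~5 Hz low-pass at 1000 Hz).  With `subtract_baseline = TRUE` the
#' mean derivative in the baseline window is subtracted, which
#' linearly removes slow rising activity (e.g. a noise-onset driven
#' ramp) based on the slope in the baseline interval.
#'
#' @param epoch A raw [pupil_epoch()].
#' @param subtract_baseline Subtract the baseline-window mean of the
#'   smoothed derivative.
#' @param smooth_samples Moving-mean length (samples); windows shrink
#'   symmetrically at the epoch edges.
#' @param baseline_ms Baseline window in ms.
#' @return A `derivative`-state [pupil_epoch()]; units are a.u. per
#'   sample (a.u./ms at 1000 Hz).  The time axis drops the first
#'   sample of the input epoch.
#' @export
pdr_derivative <- function(epoch, subtract_baseline = FALSE,
                           smooth_samples = 200,
                           baseline_ms = c(-200, 0)) {
  stopifnot(inherits(epoch, "pupil_epoch"))
  if (epoch$state != "raw")
    stop("PDR' is computed from raw epochs; got '", epoch$state, "'",
         call. = FALSE)
  d <- diff(epoch$samples)
  d <- moving_mean(d, smooth_samples)
  out <- pupil_epoch(d, epoch$time_ms[-1],
                     interpolated_fraction = epoch$interpolated_fraction,
                     state = "derivative", fs = epoch$fs)
  if (subtract_baseline) {
    idx <- baseline_indices(out, baseline_ms)
    out$samples <- out$samples - mean(out$samples[idx])
  }
  out
}

# centered moving mean with symmetric shrinking windows at the edges
moving_mean <- function(x, k) {
  n <- length(x)
  half <- k %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
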