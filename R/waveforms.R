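#' Participant-by-time waveform set
#'
#' @param data Numeric matrix, one row per participant, one column
#'   per time sample (condition-mean waveforms).
#' @param time_ms Time axis in ms, one entry per column.
#' @return An object of class `waveform_set`.
#' @export
waveform_set <- function(data, time_ms) {
  data <- as.matrix(data)
  if (ncol(data) != length(time_ms))
    stop("time axis length must match the number of columns",
         call. = FALSE)
  structure(list(data = data, time_ms = as.numeric(time_ms)),
            class = "waveform_set")
}

window_columns <- function(ws, window_ms) {
  idx <- which(ws$time_ms >= window_ms[1] & ws$time_ms <= window_ms[2])
  if (length(idx) == 0)
    stop("analysis window [", window_ms[1], ", ", window_ms[2],
         "] ms contains no samples", call. = FALSE)
  idx
}

#' Mean amplitude in an analysis window
#'
#' Per-participant average of the waveform inside a time window, e.g.
#' 100-400 ms for auditory cortex, 300-800 ms for RSC/PCC, 500-1000 ms
#' for the pupil derivative.
#'
#' @param waveforms A [waveform_set()].
#' @param window_ms Two-element window (start, end) in ms, inclusive.
#' @return Numeric vector, one scalar amplitude per participant.
#' @export
window_mean <- function(waveforms, window_ms) {
  stopifnot(inherits(waveforms, "waveform_set"))
  idx <- window_columns(waveforms, window_ms)
  rowMeans(waveforms$data[, idx, drop = FALSE])
}

#' Temporal cluster-based permutation test
#'
#' Tests a condition against a reference (paired by participant; the
#' reference may be zeros to test against 0).  Pointwise paired
#' t-statistics inside the analysis window are thresholded two-sided
#' at the cluster-forming alpha; contiguous supra-threshold runs form
#' clusters scored by their summed t (mass).  The null distribution
#' is built from random within-participant sign flips of the paired
#' differences; each permutation contributes its maximum absolute
#' cluster mass, giving family-wise control across the window.
#' Positive and negative clusters are pooled by |mass|.
#'
#' @param condition A [waveform_set()].
#' @param reference A [waveform_set()] with matching participants and
#'   time axis, or `NULL` to test against zero.
#' @param window_ms Analysis window; default spans the full axis.
#' @param n_permutations Number of sign-flip permutations.
#' @param cluster_alpha Cluster-forming (pointwise) alpha, two-sided.
#' @param seed Optional integer seed for reproducible permutations.
#' @return An object of class `cluster_result`: list with `clusters`
#'   (data.frame: start_ms, end_ms, mass, p_value), `threshold`,
#'   `n_permutations`.
#' @export
cluster_permutation_test <- function(condition, reference = NULL,
                                     window_ms = NULL,
                                     n_permutations = 10000L,
                                     cluster_alpha = 0.05,
                                     seed = NULL) {
  stopifnot(inherits(condition, "waveform_set"))
  if (is.null(reference)) {
    diffs <- condition$data
  } else {
    stopifnot(inherits(reference, "waveform_set"))
    if (!identical(dim(condition$data), dim(reference$data)))
      stop("condition and reference must have matching participants ",
           "and time axes", call. = FALSE)
    diffs <- condition$data - reference$data
  }
  if (n_permutations < 100)
    warning("fewer than 100 permutations gives a coarse p-value",
            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(window_ms))
    window_ms <- range(condition$time_ms)
  idx <- window_columns(condition, window_ms)
  x <- diffs[, idx, drop = FALSE]
  time_w <- condition$time_ms[idx]
  n <- nrow(x)
  t_crit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)

  obs_t <- col_t_stats(x)
  obs_clusters <- find_clusters(obs_t, t_crit)

  # vectorized sign-flip null: flipping signs leaves per-column sums of
  # squares unchanged, so all permutation t-curves come from one
  # matrix product
  flips <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  nrow = n_permutations)
  perm_means <- (flips %*% x) / n
  q <- colSums(x^2) / n
  perm_var <- sweep(-perm_means^2, 2, q, "+") * n / (n - 1)
  perm_var[perm_var < .Machine$double.eps] <- .Machine$double.eps
  perm_t <- perm_means / sqrt(perm_var / n)
  max_mass <- apply(perm_t, 1, function(tt) {
    cl <- find_clusters(tt, t_crit)
    if (nrow(cl) == 0) 0 else max(abs(cl$mass))
  })

  if (nrow(obs_clusters) > 0) {
    obs_clusters$p_value <- vapply(abs(obs_clusters$mass), function(m)
      (sum(max_mass >= m) + 1) / (n_permutations + 1), numeric(1))
    obs_clusters$start_ms <- time_w[obs_clusters$start]
    obs_clusters$end_ms <- time_w[obs_clusters$end]
    obs_clusters <- obs_clusters[, c("start_ms", "end_ms", "mass",
                                     "p_value")]
  } else {
    obs_clusters <- data.frame(start_ms = numeric(0),
                               end_ms = numeric(0),
                               mass = numeric(0), p_value = numeric(0))
  }
  structure(list(clusters = obs_clusters, threshold = t_crit,
                 n_permutations = n_permutations,
                 cluster_alpha = cluster_alpha,
                 window_ms = window_ms),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "Temporal cluster permutation test (%d permutations, |t| > %.2f)\n",
    x$n_permutations, x$threshold))
  if (nrow(x$clusters) == 0) cat("  no clusters\n") else
    print(format(x$clusters, digits = 4), row.names = FALSE)
  invisible(x)
}

col_t_stats <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  v <- (colSums(x^2) / n - m^2) * n / (n - 1)
  v[v < .Machine$double.eps] <- .Machine$double.eps
  m / sqrt(v / n)
}

# contiguous runs with |t| above threshold and constant sign
find_clusters <- function(t_vals, t_crit) {
  supra <- abs(t_vals) > t_crit
  signs <- sign(t_vals) * supra
  r <- rle(signs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(which(keep), function(k)
               sum(t_vals[starts[k]:ends[k]]), numeric(1)))
}

#' Linear and quadratic polynomial contrasts on binned means
#'
#' Applies orthogonal polynomial contrast weights across bins to each
#' participant's means, then tests the contrast scores against zero
#' with a one-sample t-test; F = t^2 with df (1, n-1).
#'
#' @param bin_values Participants x bins numeric matrix with no
#'   missing cells (e.g. quintile detection rates or per-rating
#'   amplitudes).
#' @return A data.frame with one row per contrast (`linear`,
#'   `quadratic`): `F`, `df1`, `df2`, `p_value`.
#' @export
polynomial_contrast_test <- function(bin_values) {
  bin_values <- as.matrix(bin_values)
  n <- nrow(bin_values); k <- ncol(bin_values)
  if (n < 3 || k < 3)
    stop("need at least 3 participants and 3 bins", call. = FALSE)
  if (anyNA(bin_values)) stop("missing cells not allowed", call. = FALSE)
  w <- stats::contr.poly(k)[, 1:2, drop = FALSE]
  scores <- bin_values %*% w
  scale <- max(abs(bin_values), 1)
  out <- do.call(rbind, lapply(1:2, function(j) {
    s <- scores[, j]
    if (stats::sd(s) <= 1e-10 * scale) {
      # contrast scores constant across participants: F degenerates
      zero <- abs(mean(s)) <= 1e-10 * scale
      f_val <- if (zero) 0 else Inf
      p <- if (zero) 1 else 0
    } else {
      tt <- stats::t.test(s)
      f_val <- unname(tt$statistic)^2
      p <- tt$p.value
    }
    data.frame(contrast = c("linear", "quadratic")[j],
               F = f_val, df1 = 1, df2 = n - 1, p_value = p)
  }))
  rownames(out) <- NULL
  out
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject one-way ANOVA on a participants x conditions matrix.
#' The sphericity correction multiplies both degrees of freedom by the
#' Greenhouse-Geisser epsilon estimated from the double-centered
#' condition covariance matrix.
#'
#' @param bin_values Participants x conditions matrix, no missing
#'   cells.
#' @return List with `F`, `df` (uncorrected), `epsilon`, `df_gg`,
#'   `p_value` (GG-corrected), `p_uncorrected`.
#' @export
rm_anova_oneway <- function(bin_values) {
  y <- as.matrix(bin_values)
  n <- nrow(y); k <- ncol(y)
  if (n < 3 || k < 2) stop("need >= 3 participants and >= 2 conditions",
                           call. = FALSE)
  if (anyNA(y)) stop("missing cells not allowed", call. = FALSE)
  cond_means <- colMeans(y)
  subj_means <- rowMeans(y)
  grand <- mean(y)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_err <- sum((y - outer(subj_means, rep(1, k)) -
                   outer(rep(1, n), cond_means) + grand)^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  f_val <- if (ss_err == 0) {
    if (ss_cond == 0) 0 else Inf
  } else (ss_cond / df1) / (ss_err / df2)

  # GG epsilon from the double-centered covariance of conditions
  s <- stats::cov(y)
  s_dc <- sweep(sweep(s, 1, rowMeans(s)), 2, colMeans(s)) + mean(s)
  denom <- (k - 1) * sum(s_dc^2)
  eps <- if (denom == 0) 1 else sum(diag(s_dc))^2 / denom
  eps <- min(max(eps, 1 / (k - 1)), 1)

  list(F = f_val, df = c(df1, df2), epsilon = eps,
       df_gg = c(df1 * eps, df2 * eps),
       p_value = stats::pf(f_val, df1 * eps, df2 * eps,
                           lower.tail = FALSE),
       p_uncorrected = stats::pf(f_val, df1, df2, lower.tail = FALSE))
}

#' Stimulus-free reference epochs from continuous streams
#'
#' Builds artificial signal-absent "trials" by cutting 1.9-3.0 s
#' post-onset segments of each participant's continuous stream, a
#' period late enough that event-related activity has decayed.  The
#' cut is re-referenced so that 2.0 s after the original onset maps
#' to t = 0 in the output epochs.  Onsets whose segment would run
#' past the end of the stream are skipped with a warning.
#'
#' @param streams List of numeric vectors (one continuous stream per
#'   participant), all sampled at `fs`.
#' @param onsets List of onset sample indices per participant.
#' @param fs Sampling rate in Hz.
#' @param segment_s Segment relative to onset in seconds, default
#'   `c(1.9, 3.0)`.
#' @param zero_s Time (s after onset) mapped to t = 0, default 2.0.
#' @return A [waveform_set()] of per-participant mean reference
#'   epochs.
#' @export
build_reference_epochs <- function(streams, onsets, fs = 1000,
                                   segment_s = c(1.9, 3.0),
                                   zero_s = 2.0) {
  stopifnot(length(streams) == length(onsets))
  i0 <- round(segment_s[1] * fs)
  i1 <- round(segment_s[2] * fs) - 1L
  len <- i1 - i0 + 1L
  time_ms <- (seq(i0, i1) - zero_s * fs) * 1000 / fs
  mat <- t(vapply(seq_along(streams), function(p) {
    st <- streams[[p]]
    eps <- list()
    for (on in onsets[[p]]) {
      a <- on + i0; b <- on + i1
      if (a < 1 || b > length(st)) {
        warning("onset at sample ", on,
                " leaves no room for a reference epoch; skipped",
                call. = FALSE)
        next
      }
      eps[[length(eps) + 1L]] <- st[a:b]
    }
    if (length(eps) == 0)
      stop("participant ", p, " has no usable reference epochs",
           call. = FALSE)
    colMeans(do.call(rbind, eps))
  }, numeric(len)))
  waveform_set(mat, time_ms)
}
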