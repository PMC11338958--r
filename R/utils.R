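# internal helpers shared across modules

# clip a proportion away from 0/1 before a z-transform; the correction
# 1/(2N) is the usual log-linear rule. N = 0 falls back to a fixed eps.
clip_rate <- function(p, n_trials = 0, warn = TRUE) {
  if (any(p < 0 | p > 1)) stop("rate outside [0, 1]", call. = FALSE)
  eps <- if (n_trials > 0) 1 / (2 * n_trials) else 1e-6
  lo <- p < eps
  hi <- p > 1 - eps
  if (warn && any(lo | hi))
    warning("extreme rate clipped to [", format(eps), ", ",
            format(1 - eps), "]", call. = FALSE)
  pmin(pmax(p, eps), 1 - eps)
}

# cumulative upper-tail probabilities P(rating > k), k = 1..5
upper_cumulative <- function(rp) {
  stopifnot(inherits(rp, "rating_probabilities"))
  rev(cumsum(rev(rp$probs)))[-1L]
}
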