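# Independent numerical oracles used across test files.  These go
# through stats::integrate / uniroot on the raw density, never through
# the closed forms under test.

# standard-normal CDF by quadrature
oracle_pnorm <- function(q) {
  vapply(q, function(z)
    stats::integrate(function(x) exp(-x^2 / 2) / sqrt(2 * pi),
                     -Inf, z, rel.tol = 1e-12)$value, numeric(1))
}

# standard-normal quantile by root finding on the quadrature CDF
oracle_qnorm <- function(p) {
  vapply(p, function(pp)
    stats::uniroot(function(z) oracle_pnorm(z) - pp, c(-10, 10),
                   tol = 1e-10)$root, numeric(1))
}

# truncated-Gaussian mean on (lo, hi] by quadrature of x g(x)
oracle_truncated_mean <- function(mu, s, lo, hi) {
  g <- function(x) stats::dnorm(x, mu, s)
  num <- stats::integrate(function(x) x * g(x), lo, hi,
                          rel.tol = 1e-12)$value
  den <- stats::integrate(g, lo, hi, rel.tol = 1e-12)$value
  num / den
}

# default grouping used throughout: the printed fitted model plus a
# plausible spread of criteria
paper_model <- function() sdt_model(1.385, 1.344)
default_criteria <- function() criterion_set(c(-0.4, 0.1, 0.6, 1.1, 1.8))

# small rating-count table built from analytic probabilities (exact,
# no sampling noise); counts scaled to n trials and rounded
analytic_count_table <- function(model, criteria, ids = 1:4,
                                 n_signal = 5000, n_absent = 1000) {
  pr <- analytic_rating_probabilities(model, criteria)
  do.call(rbind, lapply(ids, function(id) {
    rbind(
      stats::setNames(data.frame(id, "signal",
                                 t(round(pr$signal$probs * n_signal))),
                      c("participant_id", "class", paste0("n_r", 1:6))),
      stats::setNames(data.frame(id, "noise",
                                 t(round(pr$noise$probs * n_absent))),
                      c("participant_id", "class", paste0("n_r", 1:6))))
  }))
}
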