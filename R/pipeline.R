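#' Read a rating-count table
#'
#' Expected CSV schema: one row per participant x class with columns
#' `participant_id`, `class` (`signal` or `noise`), `n_r1`..`n_r6`
#' (non-negative response counts for ratings 1..6).
#'
#' @param path CSV file path.
#' @return A data.frame in the same schema, validated.
#' @export
read_rating_counts <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "class", paste0("n_r", 1:6))
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("rating-count file lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(x$class %in% c("signal", "noise")))
    stop("class must be 'signal' or 'noise'", call. = FALSE)
  cnt <- as.matrix(x[, paste0("n_r", 1:6)])
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers", call. = FALSE)
  x
}

#' Rating-count table from a trial table
#'
#' @param trials Trial table (see [trial-tables]) with ratings.
#' @return Rating-count data.frame as read by [read_rating_counts()].
#' @export
rating_counts_from_trials <- function(trials) {
  check_trials(trials)
  ids <- sort(unique(trials$participant_id))
  do.call(rbind, lapply(ids, function(id) {
    do.call(rbind, lapply(c(signal = "signal", noise = "absent"),
                          function(cond) {
      r <- trials$response[trials$participant_id == id &
                             trials$condition == cond]
      cls <- if (cond == "signal") "signal" else "noise"
      cnt <- tabulate(r, nbins = 6)
      stats::setNames(
        data.frame(id, cls, t(cnt)),
        c("participant_id", "class", paste0("n_r", 1:6)))
    }))
  }))
}

# pooled grand-average probabilities from a rating-count table
pool_rating_counts <- function(counts) {
  sig <- colSums(counts[counts$class == "signal", paste0("n_r", 1:6)])
  noi <- colSums(counts[counts$class == "noise", paste0("n_r", 1:6)])
  list(signal = rating_probabilities_from_counts(sig, "signal"),
       noise = rating_probabilities_from_counts(noi, "noise"))
}

#' Full SDT / bifurcation / threshold model comparison
#'
#' Runs the complete modelling pipeline on a rating-count table and a
#' measured per-rating amplitude profile: grand-average
#' unequal-variance fit, per-participant criteria, predicted
#' amplitudes, normalization (shift by the across-participant mean of
#' the noise-class rating-1 amplitude, then division by the shifted
#' signal-class rating-1 amplitude A_H1), the bimodal competitor with
#' weight `beta` taken from the dichotomized group detection rate,
#' the threshold competitor (ratings 1-3 zeroed), and R-squared of
#' each model against the measured profile.
#'
#' @param counts Rating-count data.frame ([read_rating_counts()]).
#' @param measured Optional measured normalized signal-class
#'   amplitude profile (numeric length 6 or [amplitude_profile()]);
#'   when supplied, R-squared values are computed against it.
#' @param beta Bimodal mixture weight; default computed from the
#'   pooled dichotomized detection rate (ratings 4-6 as hits).
#' @param threshold_rating Sub-threshold boundary for the threshold
#'   model.
#' @return An object of class `fit_report`: list with `model`,
#'   `bimodal`, `beta`, `criteria` (participants x 5), `predicted`
#'   (per-model normalized signal profiles), `r_squared` (named
#'   vector, NA-free only when `measured` given), `similarity`
#'   (Pearson r between the unimodal and bimodal fitted signal
#'   densities).
#' @export
fit_report <- function(counts, measured = NULL, beta = NULL,
                       threshold_rating = 3L) {
  pooled <- pool_rating_counts(counts)
  model <- fit_signal_distribution(pooled$signal, pooled$noise)

  if (is.null(beta)) {
    # dichotomized group detection rate, ratings 4-6 as hits
    beta <- sum(pooled$signal$probs[4:6])
  }
  bimodal <- fit_bimodal_model(pooled$signal, pooled$noise, beta = beta)

  ids <- sort(unique(counts$participant_id))
  crit <- t(vapply(ids, function(id) {
    s <- rating_probabilities_from_counts(
      unlist(counts[counts$participant_id == id &
                      counts$class == "signal", paste0("n_r", 1:6)]),
      "signal")
    n <- rating_probabilities_from_counts(
      unlist(counts[counts$participant_id == id &
                      counts$class == "noise", paste0("n_r", 1:6)]),
      "noise")
    fit_participant_criteria(s, n, model)$criteria
  }, numeric(5)))
  rownames(crit) <- ids

  profiles <- function(m) {
    per <- lapply(seq_along(ids), function(k) {
      cs <- criterion_set(crit[k, ])
      list(noise = predicted_amplitudes(m, cs, "noise"),
           signal = predicted_amplitudes(m, cs, "signal"),
           # normalization constant A_H1: mean amplitude of the hits
           # under the most liberal criterion, E[X | X > c_1, signal]
           a_h1 = truncated_mean(m, cs$criteria[1], Inf, "signal")$mean)
    })
    shift <- mean(vapply(per, function(x) x$noise$amplitudes[1],
                         numeric(1)))
    norm <- lapply(per, function(x)
      normalize_profiles(x$noise, x$signal, shift,
                         divisor = x$a_h1 - shift))
    sig_mat <- t(vapply(norm, function(x) x$signal$amplitudes,
                        numeric(6)))
    amplitude_profile(colMeans(sig_mat), "signal",
                      state = "shifted_and_scaled", shift = shift)
  }
  pred_sdt <- profiles(model)
  pred_bimodal <- profiles(bimodal)
  pred_threshold <- threshold_amplitudes(pred_sdt, threshold_rating)

  r2 <- c(sdt = NA_real_, bimodal = NA_real_, threshold = NA_real_)
  if (!is.null(measured)) {
    meas <- if (inherits(measured, "amplitude_profile")) measured else
      amplitude_profile(measured, "signal", state = "shifted_and_scaled")
    r2["sdt"] <- goodness_of_fit(pred_sdt, meas)
    r2["bimodal"] <- goodness_of_fit(pred_bimodal, meas)
    r2["threshold"] <- goodness_of_fit(pred_threshold, meas)
  }

  grid <- seq(-4, model$mu_signal + 4 * model$sigma_signal,
              length.out = 512)
  sim <- distribution_similarity(
    function(x) stats::dnorm(x, model$mu_signal, model$sigma_signal),
    function(x) bimodal_density(x, bimodal), grid)

  structure(list(model = model, bimodal = bimodal, beta = beta,
                 threshold_rating = threshold_rating,
                 criteria = crit,
                 predicted = list(sdt = pred_sdt, bimodal = pred_bimodal,
                                  threshold = pred_threshold),
                 r_squared = r2, similarity = sim),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Rating-SDT fit report\n")
  cat(sprintf("  mu_signal = %.3f, sigma_signal = %.3f, ",
              x$model$mu_signal, x$model$sigma_signal))
  cat(sprintf("delta-mu/delta-sigma = %.2f\n", delta_ratio(x$model)))
  cat(sprintf("  bimodal: beta = %.2f, mu_high = %.3f\n",
              x$beta, x$bimodal$mu_high))
  cat(sprintf("  signal-density similarity (unimodal vs bimodal) r = %.3f\n",
              x$similarity))
  if (!all(is.na(x$r_squared))) {
    cat("  R^2 vs measured profile:\n")
    for (m in names(x$r_squared))
      cat(sprintf("    %-9s %.3f\n", m, x$r_squared[m]))
  }
  invisible(x)
}

#' Serialize a fit report to JSON
#'
#' @param report A [fit_report()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fit_report <- function(report, path) {
  stopifnot(inherits(report, "fit_report"))
  out <- list(
    model = list(mu_noise = report$model$mu_noise,
                 sigma_noise = report$model$sigma_noise,
                 mu_signal = report$model$mu_signal,
                 sigma_signal = report$model$sigma_signal,
                 delta_ratio = delta_ratio(report$model)),
    bimodal = list(beta = report$bimodal$beta,
                   mu_low = report$bimodal$mu_low,
                   mu_high = report$bimodal$mu_high,
                   sigma_common = report$bimodal$sigma_common),
    threshold_rating = report$threshold_rating,
    criteria = report$criteria,
    predicted = lapply(report$predicted, function(p) p$amplitudes),
    r_squared = as.list(report$r_squared),
    similarity = report$similarity)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Two layouts are accepted.  A block `simulate:` holds
#' [simulation_config()] arguments (`model: {mu_signal, sigma_signal}`
#' is expanded to an [sdt_model()], `criteria:` to a
#' [criterion_set()]); alternatively `trials_csv:` names an existing
#' trial table.  Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @return A [simulation_config()] or a list with `trials_csv`,
#'   ready for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("simulate", "trials_csv")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(y$simulate)) {
    s <- y$simulate
    ok <- names(formals(simulation_config))
    bad <- setdiff(names(s), ok)
    if (length(bad))
      stop("unknown simulate key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (!is.null(s$model))
      s$model <- do.call(sdt_model, s$model)
    if (!is.null(s$criteria))
      s$criteria <- criterion_set(unlist(s$criteria))
    return(do.call(simulation_config, s))
  }
  if (!is.null(y$trials_csv)) return(list(trials_csv = y$trials_csv))
  stop("config must contain either 'simulate' or 'trials_csv'",
       call. = FALSE)
}

#' Run the end-to-end pipeline
#'
#' Simulation (or CSV input) -> behavioral metrics -> grand-average
#' SDT fit and competitor models -> report files.  All outputs are
#' written into `out_dir` and listed in a manifest with MD5
#' checksums; runs are idempotent for a fixed seed.
#'
#' @param config Either a [simulation_config()] (simulated inputs) or
#'   a list with element `trials_csv` naming a trial table CSV.
#' @param out_dir Output directory, created if needed.
#' @param measured Optional measured amplitude profile passed to
#'   [fit_report()].
#' @return The [fit_report()], invisibly; side effects are the files
#'   listed in `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, out_dir, measured = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }

  if (inherits(config, "simulation_config")) {
    sim <- simulate_rating_experiment(config)
    trials <- simulate_trial_amplitudes(sim)
    emit("trials.csv", function(p) utils::write.csv(trials, p,
                                                    row.names = FALSE))
  } else if (!is.null(config$trials_csv)) {
    if (!file.exists(config$trials_csv))
      stop("[input] trial file not found: ", config$trials_csv,
           call. = FALSE)
    trials <- utils::read.csv(config$trials_csv)
    check_trials(trials)
  } else {
    stop("[input] config must be a simulation_config or name a ",
         "trials_csv", call. = FALSE)
  }

  behav <- dichotomize_ratings(trials)
  emit("behavior.csv", function(p) utils::write.csv(behav, p,
                                                    row.names = FALSE))
  pv <- predictive_values(trials)
  emit("predictive_values.csv",
       function(p) utils::write.csv(pv, p, row.names = FALSE))

  counts <- rating_counts_from_trials(trials)
  emit("rating_counts.csv",
       function(p) utils::write.csv(counts, p, row.names = FALSE))

  if (is.null(measured) && !is.null(trials$amplitude))
    measured <- measured_profile_from_trials(trials)
  report <- fit_report(counts, measured = measured)
  emit("fit_report.json", function(p) write_fit_report(report, p))

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Measured normalized amplitude profile from trial amplitudes
#'
#' Applies the same normalization as the model predictions to the
#' empirical within-rating mean amplitudes: per participant, the
#' rating-wise mean amplitude per class is computed; every value is
#' shifted by the across-participant mean of the noise-class rating-1
#' amplitude and divided by the shifted criterion-1 hit amplitude
#' (the mean amplitude of signal trials rated above 1), then averaged
#' across participants.
#'
#' @param trials Trial table with `amplitude` and `rating` columns.
#' @return A normalized signal-class [amplitude_profile()].
#' @export
measured_profile_from_trials <- function(trials) {
  check_trials(trials, c("participant_id", "condition", "response",
                         "amplitude"))
  ids <- sort(unique(trials$participant_id))
  per <- lapply(ids, function(id) {
    t1 <- trials[trials$participant_id == id, , drop = FALSE]
    m <- function(cond) vapply(1:6, function(r) {
      a <- t1$amplitude[t1$condition == cond & t1$response == r]
      if (length(a)) mean(a) else NA_real_
    }, numeric(1))
    list(signal = m("signal"), noise = m("absent"),
         a_h1 = mean(t1$amplitude[t1$condition == "signal" &
                                    t1$response > 1]))
  })
  shift <- mean(vapply(per, function(x) x$noise[1], numeric(1)),
                na.rm = TRUE)
  sig <- t(vapply(per, function(x) {
    (x$signal - shift) / (x$a_h1 - shift)
  }, numeric(6)))
  amplitude_profile(colMeans(sig, na.rm = TRUE), "signal",
                    state = "shifted_and_scaled", shift = shift,
                    degenerate = apply(sig, 2, function(col)
                      all(is.na(col))))
}

#' Plain-text summary of a pipeline run
#'
#' @param report A [fit_report()].
#' @param behavior Output of [dichotomize_ratings()] (optional).
#' @param path Optional file; when NULL the summary is returned as a
#'   character vector.
#' @return The summary lines, invisibly when written to a file.
#' @export
write_report <- function(report, behavior = NULL, path = NULL) {
  stopifnot(inherits(report, "fit_report"))
  lines <- c(
    "Rating-SDT pipeline summary",
    "===========================",
    sprintf("mu_signal      %.4f", report$model$mu_signal),
    sprintf("sigma_signal   %.4f", report$model$sigma_signal),
    sprintf("delta-ratio    %.3f", delta_ratio(report$model)),
    sprintf("beta           %.3f", report$beta),
    sprintf("bimodal mu_high %.4f", report$bimodal$mu_high),
    sprintf("density similarity r = %.3f", report$similarity))
  if (!all(is.na(report$r_squared)))
    lines <- c(lines, "R^2:",
               sprintf("  %-9s %.3f", names(report$r_squared),
                       report$r_squared))
  if (!is.null(behavior)) {
    lines <- c(lines,
               sprintf("group hit rate %.3f, FA rate %.3f, criterion %.3f",
                       mean(behavior$hit_rate), mean(behavior$fa_rate),
                       mean(behavior$criterion)))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
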