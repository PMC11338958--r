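#' Behavioral summaries for rating-scale detection data
#'
#' Trial tables are plain data.frames with one row per trial and
#' columns `participant_id`, `condition` (`"signal"`, `"absent"`, or
#' `"am_noise"`), `response` (rating 1..6 in the rating experiment, or
#' 0/1 button press), and optionally `run`, `trial_index`
#' (chronological order within participant), `baseline_pupil` (mean
#' pupil size in the 200 ms before onset) and `valid`.
#'
#' @name trial-tables
NULL

check_trials <- function(trials, need = c("participant_id", "condition",
                                          "response")) {
  if (!is.data.frame(trials)) stop("trials must be a data.frame",
                                   call. = FALSE)
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(trials)
}

# drop trials flagged invalid (e.g. responses outside the 1.3-s window)
drop_invalid <- function(trials) {
  if ("valid" %in% names(trials)) trials[as.logical(trials$valid), ,
                                         drop = FALSE]
  else trials
}

#' Dichotomize six-point ratings into hits and false alarms
#'
#' Ratings above `cut` count as "present" responses.  The hit rate is
#' taken over signal trials, the false-alarm rate over signal-absent
#' trials; criterion c and d' follow from the z-transformed rates.
#'
#' @param trials Trial table (see [trial-tables]) with ratings 1..6.
#' @param cut Rating boundary in 1..5 (default 3: ratings 4-6 are
#'   hits, matching the dichotomization used for the mixture weight of
#'   the bifurcation model).
#' @return A one-row data.frame per participant with `hit_rate`,
#'   `fa_rate`, `criterion`, `d_prime`, `n_signal`, `n_absent`.
#' @export
dichotomize_ratings <- function(trials, cut = 3L) {
  check_trials(trials)
  if (!cut %in% 1:5) stop("cut must be in 1..5", call. = FALSE)
  trials <- drop_invalid(trials)
  sig <- trials[trials$condition == "signal", , drop = FALSE]
  abs_ <- trials[trials$condition == "absent", , drop = FALSE]
  if (nrow(sig) == 0 || nrow(abs_) == 0)
    stop("need both signal and signal-absent trials", call. = FALSE)
  ids <- sort(unique(trials$participant_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    s <- sig$response[sig$participant_id == id]
    a <- abs_$response[abs_$participant_id == id]
    if (length(s) == 0 || length(a) == 0)
      stop("participant ", id, " lacks signal or absent trials",
           call. = FALSE)
    h <- mean(s > cut)
    f <- mean(a > cut)
    hc <- clip_rate(h, length(s), warn = FALSE)
    fc <- clip_rate(f, length(a), warn = FALSE)
    if (hc != h || fc != f)
      warning("extreme rate(s) clipped for participant ", id,
              call. = FALSE)
    data.frame(participant_id = id,
               hit_rate = h, fa_rate = f,
               criterion = criterion_from_rates(hc, fc),
               d_prime = d_prime(hc, fc),
               n_signal = length(s), n_absent = length(a))
  }))
  rownames(out) <- NULL
  out
}

#' Per-rating positive and negative predictive values
#'
#' For each rating r the per-rating response rates are computed as the
#' number of responses with that rating divided by the total number of
#' signal-present (HR_r, MR_r) or signal-absent (FAR_r, CRR_r) trials.
#' PPV treats a response with rating r as a "present" call (threshold
#' below the rating): PPV_r = HR_r / (HR_r + FAR_r).  NPV treats it as
#' an "absent" call (threshold above the rating): NPV_r = CRR_r /
#' (CRR_r + MR_r).  With this convention the values do not depend on
#' where an overall threshold is placed.  Ratings never used get NA
#' (undefined), never zero.
#'
#' Rates are pooled over participants by default; set `by_participant`
#' for per-participant tables.
#'
#' @param trials Trial table with ratings 1..6.
#' @param by_participant Return one table per participant instead of
#'   the pooled table.
#' @return A data.frame with columns `rating`, `HR`, `FAR`, `CRR`,
#'   `MR`, `PPV`, `NPV` (and `participant_id` if `by_participant`).
#' @export
predictive_values <- function(trials, by_participant = FALSE) {
  check_trials(trials)
  trials <- drop_invalid(trials)
  one <- function(tr) {
    s <- tr$response[tr$condition == "signal"]
    a <- tr$response[tr$condition == "absent"]
    if (length(s) == 0 || length(a) == 0)
      stop("need both signal and signal-absent trials", call. = FALSE)
    hr <- tabulate(s, nbins = 6) / length(s)
    far <- tabulate(a, nbins = 6) / length(a)
    crr <- far  # a rating on an absent trial is a correct "absent" call
    mr <- hr    # and on a signal trial a miss, when read as "absent"
    ppv <- ifelse(hr + far > 0, hr / (hr + far), NA_real_)
    npv <- ifelse(crr + mr > 0, crr / (crr + mr), NA_real_)
    data.frame(rating = 1:6, HR = hr, FAR = far, CRR = crr, MR = mr,
               PPV = ppv, NPV = npv)
  }
  if (!by_participant) return(one(trials))
  ids <- sort(unique(trials$participant_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    cbind(participant_id = id,
          one(trials[trials$participant_id == id, , drop = FALSE]))
  }))
  rownames(out) <- NULL
  out
}

#' Detection rate by pre-stimulus pupil-size quintile
#'
#' Within each participant, trials are sorted by baseline pupil size
#' (chronological index breaks ties) and split into five equal-count
#' bins; remainder trials go one each to the lowest bins.  The
#' detection rate per bin is computed per participant and then
#' averaged across participants.
#'
#' @param trials Trial table with `baseline_pupil` (and optionally
#'   `trial_index` for deterministic ties).  Detection is `response >
#'   cut` for rating data or `response == 1` for binary data.
#' @param cut Rating cut (default 3); ignored for binary responses.
#' @param conditions Conditions whose trials enter the analysis
#'   (default signal trials only).
#' @return List with `group` (length-5 mean detection rate per
#'   quintile) and `by_participant` (participants x 5 matrix).
#' @export
pupil_quintile_rates <- function(trials, cut = 3L,
                                 conditions = "signal") {
  check_trials(trials, c("participant_id", "condition", "response",
                         "baseline_pupil"))
  trials <- drop_invalid(trials)
  tr <- trials[trials$condition %in% conditions, , drop = FALSE]
  ids <- sort(unique(tr$participant_id))
  per <- t(vapply(ids, function(id) {
    t1 <- tr[tr$participant_id == id, , drop = FALSE]
    n <- nrow(t1)
    if (n < 5) stop("participant ", id, " has fewer than 5 trials",
                    call. = FALSE)
    tie <- if ("trial_index" %in% names(t1)) t1$trial_index else seq_len(n)
    ord <- order(t1$baseline_pupil, tie)
    det <- detected(t1$response[ord], cut)
    bins <- quintile_bins(n)
    vapply(1:5, function(b) mean(det[bins == b]), numeric(1))
  }, numeric(5)))
  rownames(per) <- ids
  list(group = colMeans(per), by_participant = per)
}

detected <- function(response, cut) {
  if (all(response %in% 0:1)) response == 1 else response > cut
}

# equal-count bins; n mod 5 remainder trials assigned one each to the
# lowest bins
quintile_bins <- function(n) {
  base <- n %/% 5
  extra <- n %% 5
  sizes <- rep(base, 5) + c(rep(1, extra), rep(0, 5 - extra))
  rep(1:5, times = sizes)
}

#' Detection rate across consecutive parts of the session
#'
#' Trials are kept in chronological order per participant and split
#' into `n_parts` equally large consecutive parts; detection rates per
#' part are averaged across participants.  Used to examine vigilance
#' changes over a run.
#'
#' @param trials Trial table with `trial_index`.
#' @param n_parts Number of consecutive parts (default 5).
#' @inheritParams pupil_quintile_rates
#' @return List with `group` and `by_participant` as in
#'   [pupil_quintile_rates()].
#' @export
chronological_split_rates <- function(trials, n_parts = 5L, cut = 3L,
                                      conditions = "signal") {
  check_trials(trials, c("participant_id", "condition", "response",
                         "trial_index"))
  trials <- drop_invalid(trials)
  tr <- trials[trials$condition %in% conditions, , drop = FALSE]
  ids <- sort(unique(tr$participant_id))
  per <- t(vapply(ids, function(id) {
    t1 <- tr[tr$participant_id == id, , drop = FALSE]
    n <- nrow(t1)
    if (n_parts > n)
      stop("n_parts exceeds trial count for participant ", id,
           call. = FALSE)
    ord <- order(t1$trial_index)
    det <- detected(t1$response[ord], cut)
    part <- ceiling(seq_len(n) / (n / n_parts))
    vapply(seq_len(n_parts), function(b) mean(det[part == b]), numeric(1))
  }, numeric(n_parts)))
  rownames(per) <- ids
  list(group = colMeans(per), by_participant = per)
}
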