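## Synthetic detector prediction-score streams with planted true and false
## positives, and re-simulation of weekly false-positive rates.

#' Species score-stream profile
#'
#' Describes the generative process behind hourly detector prediction-score
#' streams: true calls arrive in an hour as a Poisson process and each call
#' yields one or more high-scoring predictions; false-positive predictions
#' arrive independently at `fp_rate` per hour with scores drawn from a
#' rescaled Beta distribution supported on `[fp_min, fp_max]`. The bounded
#' false-positive score support reflects how an overfit detector behaves:
#' spurious predictions concentrate at low confidence and essentially never
#' reach the top of the score range.
#'
#' @param true_rate True calls per hour (Poisson rate, >= 0; default 0.08).
#' @param preds_per_call Mean extra predictions per true call; each call
#'   yields `1 + Poisson(preds_per_call)` predictions (default 1.5).
#' @param tp_shape Length-2 Beta shape for true-positive scores
#'   (default `c(4, 2)`: high on average but dispersed, so validated
#'   true-positive hours span the whole count range at any threshold).
#' @param fp_rate False predictions per hour (Poisson rate, >= 0; default 6).
#' @param fp_shape Length-2 Beta shape for false-positive scores
#'   (default `c(1.2, 8)`).
#' @param fp_min,fp_max Support of the false-positive score distribution
#'   (defaults 0.1 and 0.35).
#' @return A list of class `owl_profile`.
#' @export
species_profile <- function(true_rate = 0.08, preds_per_call = 1.5,
                            tp_shape = c(4, 2), fp_rate = 6,
                            fp_shape = c(1.2, 8), fp_min = 0.1,
                            fp_max = 0.35) {
  if (true_rate < 0 || fp_rate < 0) stop("rates must be non-negative")
  stopifnot(fp_min >= 0, fp_max <= 1, fp_min <= fp_max)
  structure(list(true_rate = true_rate, preds_per_call = preds_per_call,
                 tp_shape = tp_shape, fp_rate = fp_rate, fp_shape = fp_shape,
                 fp_min = fp_min, fp_max = fp_max), class = "owl_profile")
}

r_fp_score <- function(n, profile) {
  profile$fp_min + (profile$fp_max - profile$fp_min) *
    stats::rbeta(n, profile$fp_shape[1], profile$fp_shape[2])
}

r_tp_score <- function(n, profile) {
  stats::rbeta(n, profile$tp_shape[1], profile$tp_shape[2])
}

#' Simulate hourly detector score streams for validation
#'
#' Generates the manual-review validation sample: hour-long samples, each
#' labelled 1 if it contains at least one planted true call and 0 otherwise,
#' together with the prediction scores in that hour. Only hours containing
#' at least one prediction with score >= 0.1 enter the sample, matching how
#' review hours are chosen. The default sample size of 200 hours mirrors the
#' minimum amount of audio manually validated per species and year.
#'
#' @param profile An [species_profile()].
#' @param n_hours Number of validation hours to produce (default 200).
#' @param survey Optional `owl_survey` supplying ARU ids; synthetic ids are
#'   used otherwise.
#' @param seed Integer RNG seed.
#' @return An object of class `owl_scores`: list with `hours` (data.frame:
#'   `sample_id`, `aru_id`, `hour_start`, `label`) and `scores` (list of
#'   numeric score vectors, one per hour, values in `[0, 1]`).
#' @export
simulate_scores <- function(profile, n_hours = 200, survey = NULL, seed = 1) {
  stopifnot(inherits(profile, "owl_profile"), n_hours >= 1)
  set.seed(seed)
  aru_pool <- if (!is.null(survey)) survey$arus$aru_id else
    sprintf("S%03dA", 1:50)
  hours <- list(); scores <- list()
  t0 <- as.POSIXct("2021-05-07 20:00:00", tz = "UTC")
  tries <- 0L
  while (length(scores) < n_hours) {
    tries <- tries + 1L
    if (tries > 1000L * n_hours)
      stop("cannot generate enough validation hours; raise the rates")
    n_calls <- stats::rpois(1, profile$true_rate)
    n_tp <- if (n_calls > 0)
      n_calls + sum(stats::rpois(n_calls, profile$preds_per_call)) else 0L
    n_fp <- stats::rpois(1, profile$fp_rate)
    sc <- c(if (n_tp > 0) r_tp_score(n_tp, profile),
            if (n_fp > 0) r_fp_score(n_fp, profile))
    if (!length(sc) || max(sc) < 0.1) next # not a reviewable hour
    i <- length(scores) + 1L
    scores[[i]] <- sc
    hours[[i]] <- data.frame(
      sample_id = i, aru_id = sample(aru_pool, 1),
      hour_start = t0 + (i - 1) * 3600, label = as.integer(n_calls > 0),
      stringsAsFactors = FALSE)
  }
  structure(list(hours = do.call(rbind, hours), scores = scores),
            class = "owl_scores")
}

#' Realized weekly false-positive rate at a threshold, by re-simulation
#'
#' Draws `n_weeks` independent weeks of `hours_per_week` recording hours
#' from the profile's false-positive process and reports the fraction of
#' weeks containing at least one false-positive prediction with score at or
#' above `threshold`. This is the operational quantity the calibration
#' procedure is meant to bound.
#'
#' @param profile An [species_profile()].
#' @param threshold Score threshold in `[0, 1]`.
#' @param n_weeks Number of weeks to simulate (default 1000).
#' @param hours_per_week Survey hours per secondary sampling period
#'   (default 84, i.e. 12 nocturnal hours x 7 nights).
#' @param seed Integer RNG seed.
#' @return Fraction of weeks with at least one false positive, in `[0, 1]`.
#' @export
simulate_weekly_fp <- function(profile, threshold, n_weeks = 1000,
                               hours_per_week = 84, seed = 1) {
  stopifnot(inherits(profile, "owl_profile"), threshold >= 0, threshold <= 1)
  set.seed(seed)
  n_fp <- stats::rpois(n_weeks, hours_per_week * profile$fp_rate)
  if (threshold <= profile$fp_min) return(mean(n_fp > 0))
  if (threshold > profile$fp_max) return(0)
  week <- rep(seq_len(n_weeks), n_fp)
  sc <- r_fp_score(sum(n_fp), profile)
  flagged <- unique(week[sc >= threshold])
  length(flagged) / n_weeks
}
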