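## Detector score-threshold calibration against a weekly false-positive
## target: per-threshold prediction counts, an hour-level logistic
## false-positive model, 1-(1-FP)^n scaling, and threshold selection.

#' Candidate score-threshold ladder
#'
#' The standard 18-step ladder: 0.1 to 0.9 by 0.1, then 0.91 to 0.99 by
#' 0.01, densifying near the top of the score range where selection
#' typically happens.
#' @return Strictly increasing numeric vector of length 18.
#' @export
score_threshold_ladder <- function() {
  round(c(seq(0.1, 0.9, by = 0.1), seq(0.91, 0.99, by = 0.01)), 2)
}

#' Count predictions at or above each threshold
#'
#' @param scores Numeric vector of prediction scores in `[0, 1]`.
#' @param thresholds Strictly increasing, non-empty numeric vector.
#' @return Integer vector of counts, non-increasing in the threshold.
#' @examples
#' count_above(c(0.15, 0.85), c(0.1, 0.9)) # 2, 0
#' @export
count_above <- function(scores, thresholds) {
  if (!length(thresholds)) stop("thresholds must be non-empty")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (length(scores) && (min(scores) < 0 || max(scores) > 1))
    stop("scores must lie in [0, 1]")
  vapply(thresholds, function(th) sum(scores >= th), integer(1))
}

#' Ridge-penalized logistic fit (fallback under complete separation)
#'
#' Newton iterations on the penalized log-likelihood
#' `sum(y * eta - log(1 + exp(eta))) - lambda/2 * |b|^2`. The penalty is
#' small, so in separated data the slope is allowed to grow until fitted
#' probabilities are numerically 0/1 in the separated region, which is the
#' honest answer there, while remaining finite and reproducible.
#' @noRd
ridge_logistic <- function(X, y, lambda = 1e-5, max_iter = 500) {
  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(pmin(eta, 30))) - pmax(eta - 30, 0)) -
      lambda / 2 * sum(b^2)
  }
  b <- rep(0, ncol(X))
  ll <- pen_ll(b)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- invlogit(eta)
    g <- drop(crossprod(X, y - p)) - lambda * b
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * w, X) + diag(lambda, ncol(X))
    step <- solve(H, g)
    # step halving keeps the penalized log-likelihood monotone
    for (h in 1:30) {
      ll_new <- pen_ll(b + step)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
    }
    b <- b + step
    if (ll_new - ll < 1e-10 && max(abs(step)) < 1e-6) { ll <- ll_new; break }
    ll <- ll_new
  }
  b
}

#' Hour-level logistic false-positive model at one threshold
#'
#' Treats the hour's status as a binary response (false positive = 1, true
#' positive = 0) with the number of predictions at or above the threshold
#' as the predictor, and evaluates the fitted false-positive probability at
#' a reference count. The reference defaults to `count = 1`, the minimal
#' hour that produces a detection at the threshold; `ref = "mean"` uses the
#' mean observed count instead.
#'
#' Complete or quasi-complete separation (no false-positive hour has any
#' prediction above the threshold) makes the unpenalized fit diverge; in
#' that case a lightly ridge-penalized fit is used and the result flagged.
#'
#' @param samples Either an `owl_scores` object, or a data.frame with
#'   columns `label` (1 = hour contains a confirmed true positive) and
#'   `count` (predictions at or above the threshold).
#' @param threshold Score threshold (used to derive counts from
#'   `owl_scores`; ignored when counts are supplied directly).
#' @param ref `"one"` (default) or `"mean"`: reference count at which the
#'   hourly false-positive probability is evaluated.
#' @param constrain_slope If `TRUE`, fixes the slope at zero, so the
#'   estimate reduces to the observed false-positive fraction.
#' @return List with `intercept`, `slope`, `fp_hourly` (probability at the
#'   reference count), `ref_count`, and `flagged` (`TRUE` when the
#'   penalized fallback was used).
#' @export
fit_hourly_fp <- function(samples, threshold = NULL, ref = c("one", "mean"),
                          constrain_slope = FALSE) {
  ref <- match.arg(ref)
  if (inherits(samples, "owl_scores")) {
    if (is.null(threshold)) stop("threshold required with an owl_scores input")
    samples <- data.frame(
      label = samples$hours$label,
      count = vapply(samples$scores, function(s) sum(s >= threshold),
                     integer(1)))
  }
  stopifnot(all(c("label", "count") %in% names(samples)))
  fp <- 1L - samples$label
  if (length(unique(fp)) < 2)
    stop("degenerate validation sample: both true- and false-positive hours ",
         "are required")
  ref_count <- if (ref == "one") 1 else mean(samples$count)

  if (constrain_slope) {
    b0 <- logit(mean(fp))
    return(list(intercept = b0, slope = 0, fp_hourly = mean(fp),
                ref_count = ref_count, flagged = FALSE))
  }

  fit <- suppressWarnings(stats::glm(fp ~ count, data = samples,
                                     family = stats::binomial()))
  b <- stats::coef(fit)
  fv <- fit$fitted.values
  flagged <- !fit$converged || any(!is.finite(b)) || any(abs(b) > 10) ||
    any(fv < 1e-8 | fv > 1 - 1e-8)
  if (flagged) {
    X <- cbind(1, samples$count)
    b <- ridge_logistic(X, fp)
  }
  list(intercept = unname(b[1]), slope = unname(b[2]),
       fp_hourly = unname(invlogit(b[1] + b[2] * ref_count)),
       ref_count = ref_count, flagged = flagged)
}

#' Scale an hourly false-positive rate to a secondary sampling period
#'
#' `1 - (1 - FP)^n`: the probability of at least one false positive across
#' `n` independent survey hours, with `n = 84` the typical nocturnal hours
#' in a 1-week secondary sampling period.
#'
#' @param hourly_fp Hourly false-positive probability in `[0, 1]`.
#' @param n_hours Number of hours per period (>= 1; default 84).
#' @return Weekly false-positive rate.
#' @examples
#' weekly_fp(1e-4, 84) # ~0.008365
#' @export
weekly_fp <- function(hourly_fp, n_hours = 84) {
  stopifnot(all(hourly_fp >= 0), all(hourly_fp <= 1), all(n_hours >= 1))
  1 - (1 - hourly_fp)^n_hours
}

#' Calibrate score thresholds against a weekly false-positive target
#'
#' Fits the hour-level logistic false-positive model at every candidate
#' threshold, scales each hourly estimate to the weekly secondary sampling
#' period with `1 - (1 - FP)^n`, and selects the smallest threshold whose
#' expected weekly false-positive rate is below the target (maximizing
#' retained detections subject to the bound).
#'
#' @param stream An `owl_scores` validation sample.
#' @param thresholds Candidate thresholds (default
#'   [score_threshold_ladder()]).
#' @param target Weekly false-positive target (default 0.01, i.e. <1%).
#' @param n_hours Hours per secondary sampling period (default 84).
#' @param ref Reference count convention, see [fit_hourly_fp()].
#' @return An object of class `owl_calibration`: list with `table`
#'   (data.frame: threshold, fp_hourly, fp_weekly, flagged), `selected`
#'   (threshold), `target`, `n_hours`.
#' @export
calibrate <- function(stream, thresholds = score_threshold_ladder(),
                      target = 0.01, n_hours = 84, ref = "one") {
  stopifnot(inherits(stream, "owl_scores"))
  counts <- t(vapply(stream$scores, count_above, numeric(length(thresholds)),
                     thresholds = thresholds))
  tab <- do.call(rbind, lapply(seq_along(thresholds), function(j) {
    f <- fit_hourly_fp(data.frame(label = stream$hours$label,
                                  count = counts[, j]), ref = ref)
    data.frame(threshold = thresholds[j], fp_hourly = f$fp_hourly,
               fp_weekly = weekly_fp(f$fp_hourly, n_hours),
               flagged = f$flagged)
  }))
  structure(list(table = tab,
                 selected = select_threshold(tab, target),
                 target = target, n_hours = n_hours),
            class = "owl_calibration")
}

#' Select the smallest threshold meeting the weekly false-positive target
#'
#' @param calibration An `owl_calibration` or its per-threshold table
#'   (data.frame with `threshold` and `fp_weekly`).
#' @param target Weekly false-positive target (default 0.01).
#' @return The selected threshold (smallest with `fp_weekly < target`).
#'   Errors, naming the best achievable rate, when no threshold qualifies.
#' @export
select_threshold <- function(calibration, target = 0.01) {
  tab <- if (inherits(calibration, "owl_calibration")) calibration$table
         else calibration
  ok <- tab$fp_weekly < target
  if (!any(ok))
    stop(sprintf(
      "no threshold meets the %.3g weekly false-positive target (best achievable: %.4g at threshold %.2f)",
      target, min(tab$fp_weekly), tab$threshold[which.min(tab$fp_weekly)]))
  min(tab$threshold[ok])
}

#' @export
print.owl_calibration <- function(x, ...) {
  cat(sprintf(
    "<owl_calibration> %d thresholds, target %.3g/week (n = %d h): selected %.2f\n",
    nrow(x$table), x$target, x$n_hours, x$selected))
  invisible(x)
}
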