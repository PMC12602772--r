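## Generative twins of the BACI occupancy models: a design-level simulator
## with known ground truth (for parameter recovery and diagnostics), and a
## full landscape/survey-level detection-event simulator.

#' Default generating parameters for the synthetic study
#'
#' The occupancy coefficients put baseline occupancy near 0.27
#' (`invlogit(-1)`), a weak positive association with merely-burned sites,
#' and a strong negative effect of near-complete high-severity fire; removal
#' sites start below controls and roughly double in occupancy post-removal.
#' Year and site random-effect SDs default to 0.3 on the logit scale.
#' Detection covariate effects give seasonally declining, effort-increasing
#' weekly detection around 0.5 at average conditions.
#'
#' @param model_id BACI model id; selects the occupancy coefficient vector.
#' @return List of class `owl_truth` with `beta` (named, aligned with
#'   [model_psi_terms()]), `sigma_year`, `sigma_site`, and `alpha` (named
#'   detection coefficients: intercept, date, ruggedness, effort, invader;
#'   per-season year offsets are zero by default).
#' @export
default_truth <- function(model_id = "fire_tc") {
  model_id <- match.arg(model_id, OWL_MODELS)
  beta <- switch(model_id,
    fire_tc = c(-1, 0.5, -3),
    fire_td = c(-1, 0.5, -3, -2.5, -2),
    bo_tc   = c(-1, -0.6, 0.9),
    bo_td   = c(-1, -0.6, 0.8, 0.9, 1.0),
    int_tc  = c(-1, -0.6, 0.3, -0.5),
    int_td  = c(-1, -0.6, 0.3, -0.5, -0.5, -0.4))
  names(beta) <- model_psi_terms(model_id)
  structure(list(beta = beta, sigma_year = 0.3, sigma_site = 0.3,
                 alpha = c("(Intercept)" = 0, date = -0.6, ruggedness = 0.25,
                           effort = 0.5, invader = 0.3)),
            class = "owl_truth")
}

#' Simulate a stacked occupancy dataset directly at the design level
#'
#' Draws site-year covariates, latent occupancy states and weekly detection
#' histories from the generative process behind one BACI model, returning a
#' ready-to-fit `owl_design` together with the complete ground truth. This
#' is the workhorse for parameter-recovery and goodness-of-fit calibration
#' testing: it shares the likelihood's covariate conventions but none of its
#' code path.
#'
#' Disturbance structure: a site is burned with probability `p_burn` (fire
#' in the calendar year of the first season, so later seasons are 1, 2, ...
#' years postfire) with a high-severity fraction drawn uniformly; removal
#' sites (probability `p_removal`) have removals after the first season.
#'
#' @param model_id BACI model id.
#' @param truth An `owl_truth` (default [default_truth()] for the model).
#' @param n_sites Number of physical sites.
#' @param n_seasons Number of stacked seasons (default 2; rows =
#'   `n_sites * n_seasons`).
#' @param n_periods Weekly periods per season (default 11).
#' @param p_burn,p_removal Disturbance exposure probabilities.
#' @param p_missing Probability a period is unsurveyed (effort 0).
#' @param p_extra_sd Optional extra site-year detection heterogeneity SD on
#'   the logit scale, *not* represented in the fitted model (default 0).
#'   Positive values create unmodeled heterogeneity for power studies.
#' @param p_slope_sd Optional SD of site-year random slopes on the
#'   standardized date (default 0). Positive values make some sites
#'   detectable early and others late in the season — site heterogeneity
#'   that the shared seasonal detection trend cannot absorb.
#' @param seed Integer RNG seed.
#' @return List with `design` (an `owl_design`), and `truth` (the input
#'   truth augmented with the realized `z`, `psi`, `u_year`, `u_site`).
#' @export
simulate_occupancy_data <- function(model_id = "fire_tc", truth = NULL,
                                    n_sites = 250, n_seasons = 2,
                                    n_periods = 11, p_burn = 0.45,
                                    p_removal = 0.45, p_missing = 0.1,
                                    p_extra_sd = 0, p_slope_sd = 0,
                                    seed = 1) {
  model_id <- match.arg(model_id, OWL_MODELS)
  truth <- truth %||% default_truth(model_id)
  set.seed(seed)
  seasons <- 2020 + seq_len(n_seasons)
  sites <- sprintf("S%04d", seq_len(n_sites))

  burned <- stats::runif(n_sites) < p_burn
  frac <- ifelse(burned, stats::runif(n_sites, 0.05, 1), 0)
  fire_year <- ifelse(burned, seasons[1], NA)
  removed <- stats::runif(n_sites) < p_removal
  removal_year <- ifelse(removed, seasons[1], NA)

  cov_rows <- do.call(rbind, lapply(seasons, function(yr) {
    codes <- t(vapply(seq_len(n_sites), function(i)
      time_since_codings(yr, fire_year[i], removal_year[i], frac[i]),
      numeric(13)))
    data.frame(unit = sites, season = yr, site_type = as.integer(removed),
               codes, stringsAsFactors = FALSE)
  }))
  n <- nrow(cov_rows)
  year_index <- match(cov_rows$season, seasons)
  site_index <- match(cov_rows$unit, sites)

  terms <- model_psi_terms(model_id)
  X_psi <- cbind(1, as.matrix(cov_rows[, setdiff(terms, "(Intercept)"),
                                       drop = FALSE]))
  colnames(X_psi) <- terms

  u_year <- stats::rnorm(n_seasons, 0, truth$sigma_year)
  u_site <- stats::rnorm(n_sites, 0, truth$sigma_site)
  psi <- invlogit(drop(X_psi %*% truth$beta) + u_year[year_index] +
                    u_site[site_index])
  z <- stats::rbinom(n, 1, psi)

  # detection design: standardized date per period, year dummies, standardized
  # ruggedness and effort, invader flag
  rug <- stats::rnorm(n_sites)
  invader <- stats::rbinom(n_sites, 1, 0.2)
  obs <- matrix(stats::runif(n * n_periods) >= p_missing, n, n_periods)
  effort_h <- matrix(ifelse(stats::runif(n * n_periods) < 0.2,
                            stats::runif(n * n_periods, 20, 84), 84),
                     n, n_periods)
  date_raw <- period_ordinal_dates(n_periods)
  date_std <- (date_raw - mean(date_raw)) / stats::sd(date_raw)
  eff_std <- (effort_h - mean(effort_h[obs])) /
    max(stats::sd(effort_h[obs]), 1e-12)

  p_terms <- c("(Intercept)", "date",
               if (n_seasons > 1) paste0("year", seasons[-1]),
               "ruggedness", "effort", "invader")
  alpha <- c(truth$alpha["(Intercept)"], truth$alpha["date"],
             if (n_seasons > 1) rep(0, n_seasons - 1),
             truth$alpha["ruggedness"], truth$alpha["effort"],
             truth$alpha["invader"])
  names(alpha) <- p_terms

  X_p <- array(0, c(n, n_periods, length(p_terms)),
               dimnames = list(NULL, NULL, p_terms))
  X_p[, , "(Intercept)"] <- 1
  X_p[, , "date"] <- matrix(date_std, n, n_periods, byrow = TRUE)
  if (n_seasons > 1)
    for (s in seasons[-1])
      X_p[, , paste0("year", s)] <- as.numeric(cov_rows$season == s)
  X_p[, , "ruggedness"] <- matrix(rug[site_index], n, n_periods)
  X_p[, , "effort"] <- eff_std
  X_p[, , "invader"] <- matrix(invader[site_index], n, n_periods)

  eta_p <- matrix(0, n, n_periods)
  for (k in seq_along(p_terms)) eta_p <- eta_p + X_p[, , k] * alpha[k]
  if (p_extra_sd > 0)
    eta_p <- eta_p + stats::rnorm(n, 0, p_extra_sd) # unmodeled heterogeneity
  if (p_slope_sd > 0) # unmodeled site-level seasonal detection phase
    eta_p <- eta_p + stats::rnorm(n, 0, p_slope_sd) *
      matrix(date_std, n, n_periods, byrow = TRUE)
  p <- invlogit(eta_p)

  y <- matrix(NA_integer_, n, n_periods)
  y[obs] <- stats::rbinom(sum(obs), 1, (z * p)[obs])
  for (k in seq_along(p_terms)) { Xk <- X_p[, , k]; Xk[!obs] <- 0; X_p[, , k] <- Xk }

  design <- new_owl_design(y, X_psi, X_p, year_index, site_index, seasons,
                           sites, terms, p_terms, model_id)
  truth$alpha_full <- alpha
  truth$z <- z; truth$psi <- psi
  truth$u_year <- u_year; truth$u_site <- u_site
  list(design = design, truth = truth)
}

#' Simulate detection events from the survey- and landscape-level twin
#'
#' The full generative counterpart of the pipeline: computes site-year
#' covariates from the landscape and survey design, draws latent occupancy
#' states once per unit-season from the chosen BACI model, draws weekly
#' detections from the five-predictor detection model wherever recording
#' effort is positive, and materializes detection events as nocturnal
#' timestamps inside deployment intervals.
#'
#' @param survey An `owl_survey`.
#' @param landscape An `owl_landscape`.
#' @param truth An `owl_truth`.
#' @param model_id BACI model id.
#' @param covariates Optional precomputed [build_site_covariates()] table.
#' @param invader Optional invader covariate table (`unit`, `season`,
#'   `invader`).
#' @param species Species label stamped on the events.
#' @param level `"aru"` or `"hexagon"` sampling units.
#' @param buffer_ha Home-range buffer area for covariates (ha).
#' @param mean_events Mean number of extra events per detected week
#'   (each detected unit-week yields `1 + Poisson(mean_events)` events).
#' @param seed Integer RNG seed.
#' @return List with `events` (data.frame: `aru_id`, `timestamp`,
#'   `species`, `score`), `truth` (data.frame: `unit`, `season`, `psi`,
#'   `z`), and `weekly` (the latent weekly detection matrix, for tests).
#' @export
simulate_detections <- function(survey, landscape, truth = NULL,
                                model_id = "fire_tc", covariates = NULL,
                                invader = NULL, species = "flammulated",
                                level = c("aru", "hexagon"), buffer_ha = 50,
                                mean_events = 1.5, seed = 1) {
  model_id <- match.arg(model_id, OWL_MODELS)
  level <- match.arg(level)
  truth <- truth %||% default_truth(model_id)
  covariates <- covariates %||%
    build_site_covariates(survey, landscape, removals = NULL,
                          buffer_ha = buffer_ha, level = level)
  set.seed(seed)

  # empty history supplies the effort structure and missingness pattern
  empty <- data.frame(aru_id = character(0), timestamp = as.POSIXct(character(0)),
                      species = character(0), stringsAsFactors = FALSE)
  hist0 <- build_history(empty, survey$deployments, survey, level = level)
  design <- build_design(model_id, hist0, covariates, invader = invader)

  n <- nrow(design$y)
  beta <- truth$beta[design$psi_terms]
  if (any(is.na(beta)))
    stop("truth$beta does not cover the model terms: ",
         paste(design$psi_terms[is.na(beta)], collapse = ", "))
  u_year <- stats::rnorm(length(design$seasons), 0, truth$sigma_year)
  u_site <- stats::rnorm(length(design$units), 0, truth$sigma_site)
  psi <- invlogit(drop(design$X_psi %*% beta) + u_year[design$year_index] +
                    u_site[design$site_index])
  z <- stats::rbinom(n, 1, psi)

  alpha <- stats::setNames(rep(0, length(design$p_terms)), design$p_terms)
  shared <- intersect(names(truth$alpha), design$p_terms)
  alpha[shared] <- truth$alpha[shared]
  eta_p <- matrix(0, n, ncol(design$y))
  for (k in seq_along(design$p_terms))
    eta_p <- eta_p + design$X_p[, , k] * alpha[k]
  p <- invlogit(eta_p)

  obs <- !is.na(design$y)
  w <- matrix(NA_integer_, n, ncol(design$y))
  w[obs] <- stats::rbinom(sum(obs), 1, (z * p)[obs])

  row_unit <- design$units[design$site_index]
  row_season <- design$seasons[design$year_index]
  aru_of_unit <- if (level == "aru") stats::setNames(row_unit, row_unit) else NULL

  events <- list()
  dep <- survey$deployments
  for (i in seq_len(n)) {
    ks <- which(!is.na(w[i, ]) & w[i, ] == 1)
    for (k in ks) {
      yr <- row_season[i]
      ws <- season_start(yr) + (k - 1) * 7 * 86400
      we <- ws + 7 * 86400
      arus_here <- if (level == "aru") row_unit[i] else
        survey$arus$aru_id[survey$arus$hex_id == row_unit[i]]
      di <- dep[dep$aru_id %in% arus_here & dep$season == yr &
                  dep$start < we & dep$end > ws, , drop = FALSE]
      if (!nrow(di)) next
      n_ev <- 1 + stats::rpois(1, mean_events)
      for (e in seq_len(n_ev)) {
        j <- sample(nrow(di), 1)
        lo <- max(as.numeric(di$start[j]), as.numeric(ws))
        hi <- min(as.numeric(di$end[j]), as.numeric(we))
        for (try in 1:50) {
          ts <- as.POSIXct(stats::runif(1, lo, hi),
                           origin = "1970-01-01", tz = "UTC")
          if (is_nocturnal(ts)) break
        }
        if (!is_nocturnal(ts)) next
        events[[length(events) + 1]] <- data.frame(
          aru_id = di$aru_id[j], timestamp = ts, species = species,
          score = round(stats::rbeta(1, 12, 2), 4), stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(aru_id = character(0), timestamp = as.POSIXct(character(0), tz = "UTC"),
               species = character(0), score = numeric(0),
               stringsAsFactors = FALSE)
  events <- events[order(events$timestamp), , drop = FALSE]
  rownames(events) <- NULL

  list(events = events,
       truth = data.frame(unit = row_unit, season = row_season,
                          psi = psi, z = z, stringsAsFactors = FALSE),
       weekly = w)
}
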