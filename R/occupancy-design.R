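## Stacked single-season occupancy designs: one row per unit-season, an
## occupancy design matrix per BACI model, and per-row-period detection
## design arrays.

OWL_MODELS <- c("fire_tc", "fire_td", "bo_tc", "bo_td", "int_tc", "int_td")

#' Occupancy predictor columns of each BACI model
#'
#' The six models test severe-fire effects (time-constant and
#' time-dependent), removal effects (time-constant and time-dependent), and
#' fire-by-removal interactions (time-constant and time-dependent). All six
#' add year and site random effects on top of the listed fixed effects.
#'
#' @param model_id One of `"fire_tc"`, `"fire_td"`, `"bo_tc"`, `"bo_td"`,
#'   `"int_tc"`, `"int_td"`.
#' @return Character vector of occupancy design columns (intercept first).
#' @export
model_psi_terms <- function(model_id) {
  switch(match.arg(model_id, OWL_MODELS),
    fire_tc = c("(Intercept)", "burn", "allpostburn"),
    fire_td = c("(Intercept)", "burn", "burn1", "burn2", "burn3"),
    bo_tc   = c("(Intercept)", "site_type", "allpostlethal"),
    bo_td   = c("(Intercept)", "site_type", "lethal1", "lethal2",
                "lethal3plus"),
    int_tc  = c("(Intercept)", "site_type", "burn", "apl_burnyrs"),
    int_td  = c("(Intercept)", "site_type", "burn", "apl_burn1", "apl_burn2",
                "apl_burn3"))
}

#' Internal design constructor
#' @noRd
new_owl_design <- function(y, X_psi, X_p, year_index, site_index, seasons,
                           units, psi_terms, p_terms, model_id,
                           scale_info = list()) {
  stopifnot(nrow(y) == nrow(X_psi), dim(X_p)[1] == nrow(y),
            dim(X_p)[2] == ncol(y), length(year_index) == nrow(y),
            length(site_index) == nrow(y))
  structure(list(y = y, X_psi = X_psi, X_p = X_p, year_index = year_index,
                 site_index = site_index, seasons = seasons, units = units,
                 psi_terms = psi_terms, p_terms = p_terms,
                 model_id = model_id, scale_info = scale_info),
            class = "owl_design")
}

#' @export
print.owl_design <- function(x, ...) {
  cat(sprintf(
    "<owl_design> model %s: %d unit-season rows x %d periods, %d sites, %d years\n",
    x$model_id, nrow(x$y), ncol(x$y), length(x$units), length(x$seasons)))
  cat("  psi terms:", paste(x$psi_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Period midpoint ordinal dates for the 11 weekly periods
#' @noRd
period_ordinal_dates <- function(n_periods = N_PERIODS) {
  # May 7 of a non-leap year is ordinal day 127; midpoints at +3.5-day steps
  127 + (seq_len(n_periods) - 1) * 7 + 3.5
}

#' Build the stacked occupancy design for one BACI model
#'
#' Joins weekly encounter histories with the site-year covariate table and
#' the invader detection covariate, and assembles: the detection matrix `y`
#' (0/1/`NA`), the occupancy design matrix with exactly the model's
#' predictor columns, and the per-row-period detection design array with
#' five predictors — standardized ordinal date, survey-year category,
#' standardized terrain ruggedness, standardized weekly recording hours,
#' and the invader detection flag. Detection covariates are defined only
#' where `y` is non-missing.
#'
#' @param model_id One of the six BACI model ids, see [model_psi_terms()].
#' @param histories An `owl_history` (from [build_history()]).
#' @param covariates Site-year covariate table (from
#'   [build_site_covariates()]).
#' @param invader Data frame `unit`, `season`, `invader` (from
#'   [invader_covariate()]); `NULL` sets the flag to 0 everywhere.
#' @return An object of class `owl_design`.
#' @export
build_design <- function(model_id, histories, covariates, invader = NULL) {
  model_id <- match.arg(model_id, OWL_MODELS)
  terms <- model_psi_terms(model_id)
  need <- setdiff(terms, "(Intercept)")
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols))
    stop("covariates table lacks column(s): ",
         paste(missing_cols, collapse = ", "))

  df <- merge(histories, covariates, by = c("unit", "season"),
              suffixes = c("", ".cov"))
  if (!is.null(invader))
    df <- merge(df, invader[, c("unit", "season", "invader")],
                by = c("unit", "season"), all.x = TRUE)
  else df$invader <- 0
  df$invader[is.na(df$invader)] <- 0
  df <- df[order(df$season, df$unit), ]

  T_ <- N_PERIODS
  y <- as.matrix(df[, paste0("y", seq_len(T_))])
  eff <- as.matrix(df[, paste0("e", seq_len(T_))])
  n <- nrow(y)

  X_psi <- cbind("(Intercept)" = rep(1, n),
                 as.matrix(df[, need, drop = FALSE]))
  colnames(X_psi) <- terms

  seasons <- sort(unique(df$season))
  units <- sort(unique(df$unit))
  year_index <- match(df$season, seasons)
  site_index <- match(df$unit, units)

  date_raw <- period_ordinal_dates(T_)
  obs <- !is.na(y)
  date_mat <- matrix(date_raw, n, T_, byrow = TRUE)
  date_std <- zscore(date_mat[obs])
  rug_std <- zscore(df$ruggedness)
  eff_std <- zscore(eff[obs])

  p_terms <- c("(Intercept)", "date",
               if (length(seasons) > 1) paste0("year", seasons[-1]),
               "ruggedness", "effort", "invader")
  X_p <- array(0, c(n, T_, length(p_terms)),
               dimnames = list(NULL, NULL, p_terms))
  X_p[, , "(Intercept)"] <- 1
  dmat <- matrix(0, n, T_); dmat[obs] <- date_std
  X_p[, , "date"] <- dmat
  if (length(seasons) > 1)
    for (s in seasons[-1])
      X_p[, , paste0("year", s)] <- as.numeric(df$season == s)
  X_p[, , "ruggedness"] <- matrix(as.numeric(rug_std), n, T_)
  emat <- matrix(0, n, T_); emat[obs] <- eff_std
  X_p[, , "effort"] <- emat
  X_p[, , "invader"] <- matrix(df$invader, n, T_)
  # zero out unused entries so they carry no information
  for (k in seq_along(p_terms)) { Xk <- X_p[, , k]; Xk[!obs] <- 0; X_p[, , k] <- Xk }

  new_owl_design(y, X_psi, X_p, year_index, site_index, seasons,
                 units, terms, p_terms, model_id,
                 scale_info = list(
                   date = attributes(date_std)[c("center", "scale")],
                   ruggedness = attributes(rug_std)[c("center", "scale")],
                   effort = attributes(eff_std)[c("center", "scale")]))
}
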