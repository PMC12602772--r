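## MacKenzie-Bailey goodness-of-fit via posterior predictive checks.

#' Pearson chi-square statistic over encounter-history frequencies
#'
#' Rows are cohorted by their missingness pattern (histories are only
#' comparable on the periods actually surveyed); cohorts with fewer than
#' 2 rows are merged into the cohort with the nearest pattern (Hamming
#' distance) so expected counts stay away from zero. Within a cohort, the
#' expected count of each distinct observed history is the sum over rows of
#' its marginal probability under the model, and all never-observed
#' histories contribute their pooled expectation (observed count 0).
#'
#' @param y Detection matrix (0/1/`NA`).
#' @param psi Per-row occupancy probabilities.
#' @param p Per-row-period detection probability matrix.
#' @return The chi-square statistic.
#' @export
mb_chisq <- function(y, psi, p) {
  n <- nrow(y)
  pat <- apply(1L * !is.na(y), 1, paste, collapse = "")
  cohorts <- split(seq_len(n), pat)
  # merge small cohorts into the nearest pattern
  if (length(cohorts) > 1) {
    repeat {
      sizes <- lengths(cohorts)
      small <- which(sizes < 2)
      if (!length(small) || length(cohorts) == 1) break
      i <- small[1]
      pm <- do.call(rbind, strsplit(names(cohorts), ""))
      dist <- rowSums(pm != matrix(pm[i, ], nrow(pm), ncol(pm), byrow = TRUE))
      dist[i] <- Inf
      j <- which.min(dist)
      cohorts[[j]] <- c(cohorts[[j]], cohorts[[i]])
      cohorts <- cohorts[-i]
    }
  }

  stat <- 0
  for (rows in cohorts) {
    # merged cohorts may mix patterns: compare on the jointly observed periods
    obs_cols <- which(colSums(is.na(y[rows, , drop = FALSE])) == 0)
    if (!length(obs_cols)) next
    yh <- y[rows, obs_cols, drop = FALSE]
    hist_key <- apply(yh, 1, paste, collapse = "")
    O <- table(hist_key)
    E_tot <- 0
    for (h in names(O)) {
      hv <- as.integer(strsplit(h, "")[[1]])
      ph <- p[rows, obs_cols, drop = FALSE]
      if (any(hv == 1)) {
        lp <- colSums(t(log(ph)) * hv + t(log(1 - ph)) * (1 - hv))
        prob <- psi[rows] * exp(lp)
      } else {
        prob <- psi[rows] * apply(1 - ph, 1, prod) + 1 - psi[rows]
      }
      E <- sum(prob)
      E_tot <- E_tot + E
      stat <- stat + (O[[h]] - E)^2 / max(E, 1e-12)
    }
    # pooled contribution of all unobserved histories: O = 0, E = N - sum(E)
    stat <- stat + max(length(rows) - E_tot, 0)
  }
  unname(stat)
}

#' MacKenzie-Bailey posterior predictive goodness-of-fit test
#'
#' For a thinned subset of posterior draws, computes the encounter-history
#' chi-square statistic on the observed data and on a replicate dataset
#' simulated from that draw's parameters (same missingness pattern; latent
#' occupancy redrawn), and reports the posterior predictive p-value: the
#' fraction of replicates whose statistic is at least as large as the
#' observed one. Values near 0 indicate lack of fit; under the generating
#' model the p-value is approximately uniform.
#'
#' @param draws An `owl_draws`.
#' @param n_rep Number of posterior draws / replicates to use (>= 100 for a
#'   stable p-value; default 100).
#' @param seed Integer RNG seed for the replicates.
#' @return List with `p_value`, `chisq_obs` (vector over draws) and
#'   `chisq_rep`.
#' @export
mb_gof <- function(draws, n_rep = 100, seed = 1) {
  stopifnot(inherits(draws, "owl_draws"), n_rep >= 1)
  design <- draws$design
  m <- as.matrix(draws)
  if (nrow(m) < n_rep)
    stop("not enough posterior draws for n_rep = ", n_rep)
  idx <- round(seq(1, nrow(m), length.out = n_rep))
  y <- design$y
  n <- nrow(y); T_ <- ncol(y)
  obs <- !is.na(y)
  Kp <- dim(design$X_p)[3]
  set.seed(derive_seed(seed, 77))

  beta_cols <- paste0("beta_", design$psi_terms)
  alpha_cols <- paste0("alpha_", design$p_terms)
  uy_cols <- paste0("u_year[", design$seasons, "]")
  us_cols <- paste0("u_site[", design$units, "]")

  chisq_obs <- numeric(n_rep); chisq_rep <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    th <- m[idx[r], ]
    eta_psi <- drop(design$X_psi %*% th[beta_cols]) +
      th[uy_cols][design$year_index] + th[us_cols][design$site_index]
    psi <- invlogit(eta_psi)
    eta_p <- matrix(0, n, T_)
    for (k in seq_len(Kp))
      eta_p <- eta_p + design$X_p[, , k] * th[alpha_cols][k]
    p <- invlogit(eta_p)

    chisq_obs[r] <- mb_chisq(y, psi, p)
    z_rep <- stats::rbinom(n, 1, psi)
    y_rep <- matrix(NA_integer_, n, T_)
    y_rep[obs] <- stats::rbinom(sum(obs), 1, (z_rep * p)[obs])
    chisq_rep[r] <- mb_chisq(y_rep, psi, p)
  }
  list(p_value = mean(chisq_rep >= chisq_obs), chisq_obs = chisq_obs,
       chisq_rep = chisq_rep)
}
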