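## Bayesian stacked single-season occupancy models: marginalized likelihood,
## adaptive Metropolis-within-Gibbs sampler, convergence diagnostics, and
## occupancy prediction.

#' Marginalized site likelihood of one encounter history
#'
#' The single-season occupancy likelihood with the latent occupancy state
#' summed out: if the history contains any detection, the site must be
#' occupied and the log-likelihood is
#' `log(psi) + sum_t [y log p_t + (1 - y) log(1 - p_t)]`; with no
#' detections it is `log(psi * prod_t(1 - p_t) + 1 - psi)`. Missing periods
#' contribute nothing (closure is assumed within the season), so an
#' all-missing history has probability 1.
#'
#' @param psi Occupancy probability (scalar in `[0, 1]`).
#' @param p Per-period detection probabilities (vector; entries for missing
#'   periods are ignored).
#' @param y Detection history: 0/1/`NA` vector of the same length as `p`.
#' @return Log-probability of the history.
#' @examples
#' exp(site_log_likelihood(0.5, c(0.5, 0.5), c(1, 0))) # 0.125
#' exp(site_log_likelihood(0.5, c(0.5, 0.5), c(0, 0))) # 0.625
#' @export
site_log_likelihood <- function(psi, p, y) {
  stopifnot(length(p) == length(y), psi >= 0, psi <= 1)
  obs <- !is.na(y)
  if (!any(obs)) return(0)
  yo <- y[obs]; po <- p[obs]
  if (!all(is.finite(po))) stop("non-finite detection probability")
  if (any(yo == 1)) {
    log(psi) + sum(yo * log(po) + (1 - yo) * log(1 - po))
  } else {
    log(psi * prod(1 - po) + 1 - psi)
  }
}

## ---- vectorized likelihood internals ------------------------------------

#' Detection-side caches from the detection linear predictor
#' @noRd
det_cache <- function(eta_p, y) {
  obs <- !is.na(y)
  logp <- stats::plogis(eta_p, log.p = TRUE)
  log1mp <- stats::plogis(-eta_p, log.p = TRUE)
  yy <- y; yy[!obs] <- 0
  detD <- rowSums((yy * logp + (1 - yy) * log1mp) * obs)
  logQ <- rowSums(log1mp * obs)
  list(detD = detD, logQ = logQ)
}

#' Per-row marginal log-likelihood from caches
#' @noRd
row_loglik <- function(eta_psi, cache, det_any) {
  psi <- stats::plogis(eta_psi)
  ll <- numeric(length(eta_psi))
  ll[det_any] <- log(psi[det_any]) + cache$detD[det_any]
  nd <- !det_any
  ll[nd] <- log(psi[nd] * exp(cache$logQ[nd]) + 1 - psi[nd])
  ll
}

#' Default weakly informative priors
#'
#' Normal(0, 2.5^2) on occupancy and detection coefficients (covariates are
#' standardized or bounded) and half-Normal(0, 1) on the random-effect SDs.
#' @return Named list `beta_sd`, `alpha_sd`, `sigma_scale`.
#' @export
owl_priors <- function() list(beta_sd = 2.5, alpha_sd = 2.5, sigma_scale = 1)

#' Sample the posterior of a stacked occupancy model
#'
#' Adaptive Metropolis-within-Gibbs over the marginalized occupancy
#' likelihood: single-coordinate random-walk updates for the occupancy and
#' detection coefficients, jointly vectorized elementwise updates for the
#' year and site random effects (valid because the likelihood factorizes
#' over the rows each effect touches), and random-walk updates of the
#' log random-effect SDs against their half-Normal priors. Proposal scales
#' adapt in batches toward a 44% acceptance rate during burn-in only, so
#' the retained chain is a valid Markov chain.
#'
#' @param design An `owl_design`.
#' @param priors See [owl_priors()].
#' @param chains Number of chains (default 4).
#' @param iters Iterations per chain (default 2600).
#' @param burn Burn-in iterations discarded (default half).
#' @param seed Integer master seed; chain seeds are derived from it.
#' @param random_effects Include the year and site random effects
#'   (default `TRUE`; `FALSE` fixes them at zero, giving a plain
#'   fixed-effects occupancy model).
#' @return An object of class `owl_draws`: list with `samples` (array
#'   kept-iterations x chains x parameters, with parameter dimnames),
#'   `design`, and `settings`. Random-effect SDs are stored on the SD
#'   scale.
#' @export
sample_posterior <- function(design, priors = owl_priors(), chains = 4,
                             iters = 2600, burn = floor(iters / 2),
                             seed = 1, random_effects = TRUE) {
  stopifnot(inherits(design, "owl_design"), chains >= 1, iters > burn)
  y <- design$y
  n <- nrow(y); T_ <- ncol(y)
  obs <- !is.na(y)
  det_any <- rowSums(y == 1, na.rm = TRUE) > 0
  K <- ncol(design$X_psi)
  Kp <- dim(design$X_p)[3]
  Xp <- lapply(seq_len(Kp), function(k) design$X_p[, , k])
  constant_cols <- apply(design$X_psi, 2, function(v) stats::sd(v) == 0)
  if (any(constant_cols[-1]))
    warning("constant occupancy design column(s): ",
            paste(colnames(design$X_psi)[-1][constant_cols[-1]],
                  collapse = ", "))
  J <- length(design$seasons); S <- length(design$units)
  yi <- design$year_index; si <- design$site_index

  par_names <- c(paste0("beta_", design$psi_terms),
                 paste0("alpha_", design$p_terms),
                 paste0("u_year[", design$seasons, "]"),
                 paste0("u_site[", design$units, "]"),
                 "sigma_year", "sigma_site")
  kept <- iters - burn
  samples <- array(NA_real_, c(kept, chains, length(par_names)),
                   dimnames = list(NULL, NULL, par_names))

  eta_p_of <- function(alpha) {
    e <- matrix(0, n, T_)
    for (k in seq_len(Kp)) e <- e + Xp[[k]] * alpha[k]
    e
  }

  for (ch in seq_len(chains)) {
    set.seed(derive_seed(seed, 1000 + ch))
    beta <- stats::rnorm(K, 0, 0.1)
    alpha <- stats::rnorm(Kp, 0, 0.1)
    uy <- rep(0, J); us <- rep(0, S)
    lsy <- log(0.5); lss <- log(0.5)

    eta_psi <- drop(design$X_psi %*% beta) + uy[yi] + us[si]
    eta_p <- eta_p_of(alpha)
    cache <- det_cache(eta_p, y)
    ll <- row_loglik(eta_psi, cache, det_any)

    sc <- list(beta = rep(0.3, K), alpha = rep(0.3, Kp), uy = 0.5, us = 0.8,
               sig = 0.5)
    acc <- list(beta = rep(0, K), alpha = rep(0, Kp), uy = 0, us = 0,
                sig = c(0, 0))
    batch <- 50L; n_batch <- 0L

    for (it in seq_len(iters)) {
      # occupancy coefficients, coordinate-wise
      for (k in seq_len(K)) {
        prop <- stats::rnorm(1, 0, sc$beta[k])
        eta2 <- eta_psi + design$X_psi[, k] * prop
        ll2 <- row_loglik(eta2, cache, det_any)
        lr <- sum(ll2 - ll) +
          stats::dnorm(beta[k] + prop, 0, priors$beta_sd, log = TRUE) -
          stats::dnorm(beta[k], 0, priors$beta_sd, log = TRUE)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          beta[k] <- beta[k] + prop; eta_psi <- eta2; ll <- ll2
          acc$beta[k] <- acc$beta[k] + 1
        }
      }
      # detection coefficients, coordinate-wise
      for (k in seq_len(Kp)) {
        prop <- stats::rnorm(1, 0, sc$alpha[k])
        eta_p2 <- eta_p + Xp[[k]] * prop
        cache2 <- det_cache(eta_p2, y)
        ll2 <- row_loglik(eta_psi, cache2, det_any)
        lr <- sum(ll2 - ll) +
          stats::dnorm(alpha[k] + prop, 0, priors$alpha_sd, log = TRUE) -
          stats::dnorm(alpha[k], 0, priors$alpha_sd, log = TRUE)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          alpha[k] <- alpha[k] + prop; eta_p <- eta_p2; cache <- cache2
          ll <- ll2; acc$alpha[k] <- acc$alpha[k] + 1
        }
      }
      if (random_effects) {
      # year effects: elementwise (years partition the rows)
      sy <- exp(lsy)
      prop <- stats::rnorm(J, 0, sc$uy)
      eta2 <- eta_psi + prop[yi]
      ll2 <- row_loglik(eta2, cache, det_any)
      dll <- rowsum(ll2 - ll, yi, reorder = TRUE)[, 1]
      lr <- dll + stats::dnorm(uy + prop, 0, sy, log = TRUE) -
        stats::dnorm(uy, 0, sy, log = TRUE)
      ok <- is.finite(lr) & log(stats::runif(J)) < lr
      if (any(ok)) {
        uy[ok] <- uy[ok] + prop[ok]
        eta_psi <- eta_psi + (prop * ok)[yi]
        ll <- row_loglik(eta_psi, cache, det_any)
      }
      acc$uy <- acc$uy + mean(ok)
      # site effects: elementwise (sites partition the rows)
      ss <- exp(lss)
      prop <- stats::rnorm(S, 0, sc$us)
      eta2 <- eta_psi + prop[si]
      ll2 <- row_loglik(eta2, cache, det_any)
      dll <- rowsum(ll2 - ll, si, reorder = TRUE)[, 1]
      lr <- dll + stats::dnorm(us + prop, 0, ss, log = TRUE) -
        stats::dnorm(us, 0, ss, log = TRUE)
      ok <- is.finite(lr) & log(stats::runif(S)) < lr
      if (any(ok)) {
        us[ok] <- us[ok] + prop[ok]
        eta_psi <- eta_psi + (prop * ok)[si]
        ll <- row_loglik(eta_psi, cache, det_any)
      }
      acc$us <- acc$us + mean(ok)
      # random-effect SDs on the log scale (prior + Jacobian only)
      lp_sig <- function(ls, u, scale) {
        s <- exp(ls)
        sum(stats::dnorm(u, 0, s, log = TRUE)) - 0.5 * (s / scale)^2 + ls
      }
      for (which_s in 1:2) {
        ls <- if (which_s == 1) lsy else lss
        u <- if (which_s == 1) uy else us
        prop <- stats::rnorm(1, 0, sc$sig)
        lr <- lp_sig(ls + prop, u, priors$sigma_scale) -
          lp_sig(ls, u, priors$sigma_scale)
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          if (which_s == 1) lsy <- ls + prop else lss <- ls + prop
          acc$sig[which_s] <- acc$sig[which_s] + 1
        }
      }
      }

      # batch adaptation during burn-in only
      if (it %% batch == 0 && it <= burn) {
        n_batch <- n_batch + 1L
        delta <- min(0.1, 1 / sqrt(n_batch))
        tune <- function(s, a) s * exp(delta * sign(a / batch - 0.44))
        sc$beta <- tune(sc$beta, acc$beta)
        sc$alpha <- tune(sc$alpha, acc$alpha)
        sc$uy <- tune(sc$uy, acc$uy)
        sc$us <- tune(sc$us, acc$us)
        sc$sig <- tune(sc$sig, mean(acc$sig))
        acc <- list(beta = rep(0, K), alpha = rep(0, Kp), uy = 0, us = 0,
                    sig = c(0, 0))
      }
      if (it > burn)
        samples[it - burn, ch, ] <- c(beta, alpha, uy, us,
                                      if (random_effects) c(exp(lsy), exp(lss))
                                      else c(0, 0))
    }
  }

  structure(list(samples = samples, design = design,
                 settings = list(chains = chains, iters = iters, burn = burn,
                                 seed = seed, priors = priors)),
            class = "owl_draws")
}

#' Flatten posterior draws to a matrix (draws x parameters)
#' @param x An `owl_draws`.
#' @param ... Unused.
#' @export
as.matrix.owl_draws <- function(x, ...) {
  d <- dim(x$samples)
  m <- matrix(x$samples, d[1] * d[2], d[3])
  colnames(m) <- dimnames(x$samples)[[3]]
  m
}

#' @export
print.owl_draws <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<owl_draws> model %s: %d chains x %d kept iterations, %d parameters\n",
              x$design$model_id, d[2], d[1], d[3]))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain variance ratio,
#' `sqrt(((n-1)/n * W + B/n) / W)`, per parameter; values at or below 1.1
#' are taken as converged.
#'
#' @param draws An `owl_draws` (needs >= 2 chains) or a matrix with one
#'   column per chain for a single parameter.
#' @return Named vector of R-hat values (`NA` for degenerate, zero-variance
#'   parameters).
#' @export
gelman_rubin <- function(draws) {
  if (inherits(draws, "owl_draws")) {
    a <- draws$samples
    if (dim(a)[2] < 2) stop("Gelman-Rubin requires at least 2 chains")
    return(vapply(seq_len(dim(a)[3]),
                  function(k) gelman_rubin(a[, , k]),
                  numeric(1)) |> stats::setNames(dimnames(a)[[3]]))
  }
  m <- as.matrix(draws)
  n <- nrow(m)
  if (ncol(m) < 2) stop("Gelman-Rubin requires at least 2 chains")
  W <- mean(apply(m, 2, stats::var))
  B_over_n <- stats::var(colMeans(m))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Posterior summary table
#'
#' @param object An `owl_draws`.
#' @param level Credible-interval level (default 0.85, equal-tailed).
#' @param ... Unused.
#' @return Data frame: parameter, mean, sd, lower, upper, and `rhat` when
#'   at least 2 chains are present.
#' @export
summary.owl_draws <- function(object, level = 0.85, ...) {
  m <- as.matrix(object)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- data.frame(parameter = colnames(m), mean = colMeans(m),
                    sd = apply(m, 2, stats::sd),
                    lower = apply(m, 2, stats::quantile, qs[1]),
                    upper = apply(m, 2, stats::quantile, qs[2]),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (dim(object$samples)[2] >= 2) out$rhat <- unname(gelman_rubin(object))
  out
}

#' Posterior occupancy prediction at a covariate profile
#'
#' Computes `invlogit` of the occupancy linear predictor over the posterior
#' draws at a supplied covariate profile and summarizes with the posterior
#' mean and an equal-tailed credible interval. Random effects are either
#' marginalized by drawing fresh year and site effects from their posterior
#' SDs at each draw (`re = "marginal"`, the default: predictions describe a
#' new site in a new year) or fixed at zero (`re = "zero"`).
#'
#' @param draws An `owl_draws`.
#' @param profile Named numeric vector/list covering every occupancy term
#'   except the intercept (e.g. `c(burn = 1, allpostburn = 0.8)`).
#' @param re `"marginal"` or `"zero"`.
#' @param level Credible level (default 0.85).
#' @param seed Seed for the marginalization draws.
#' @return List with `mean`, `lower`, `upper`, and the per-draw occupancy
#'   probabilities in `draws`.
#' @export
predict_occupancy <- function(draws, profile, re = c("marginal", "zero"),
                              level = 0.85, seed = 1) {
  re <- match.arg(re)
  terms <- draws$design$psi_terms
  need <- setdiff(terms, "(Intercept)")
  profile <- unlist(profile)
  missing_terms <- setdiff(need, names(profile))
  if (length(missing_terms))
    stop("profile lacks occupancy term(s): ",
         paste(missing_terms, collapse = ", "))
  x <- c(1, profile[need])
  m <- as.matrix(draws)
  eta <- drop(m[, paste0("beta_", terms), drop = FALSE] %*% x)
  if (re == "marginal") {
    set.seed(seed)
    eta <- eta + stats::rnorm(length(eta), 0, m[, "sigma_year"]) +
      stats::rnorm(length(eta), 0, m[, "sigma_site"])
  }
  psi <- invlogit(eta)
  qs <- stats::quantile(psi, c((1 - level) / 2, 1 - (1 - level) / 2))
  list(mean = mean(psi), lower = unname(qs[1]), upper = unname(qs[2]),
       draws = psi)
}
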