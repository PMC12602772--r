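# Shared fixtures, built in code at test time.

# A hand-built two-hexagon survey with known geometry and continuous
# 5-week deployments, for encounter-history tests.
make_mini_survey <- function(seasons = c(2021, 2022)) {
  hexagons <- data.frame(hex_id = c("H001", "H002"),
                         x = c(2000, 6000), y = c(2000, 2000),
                         stringsAsFactors = FALSE)
  arus <- data.frame(aru_id = c("H001A", "H001B", "H002A", "H002B"),
                     hex_id = rep(hexagons$hex_id, each = 2),
                     x = c(1700, 2300, 5700, 6300),
                     y = rep(2000, 4), stringsAsFactors = FALSE)
  deployments <- do.call(rbind, lapply(seasons, function(yr) {
    st <- as.POSIXct(sprintf("%d-05-07 00:00:00", yr), tz = "UTC")
    data.frame(aru_id = arus$aru_id, season = yr, start = st,
               end = st + 35 * 86400, stringsAsFactors = FALSE)
  }))
  structure(list(hexagons = hexagons, arus = arus, seasons = seasons,
                 deployments = deployments, hex_spacing = 2149),
            class = "owl_survey")
}

empty_detections <- function() {
  data.frame(aru_id = character(0),
             timestamp = as.POSIXct(character(0), tz = "UTC"),
             species = character(0), stringsAsFactors = FALSE)
}

# Posterior-draw stand-in with prescribed coefficient draws, for testing
# prediction and contrast arithmetic in isolation from the sampler.
make_fake_draws <- function(beta_draws, psi_terms, n_chains = 2,
                            sigma_year = 0, sigma_site = 0) {
  n <- nrow(beta_draws)
  p_terms <- "(Intercept)"
  par_names <- c(paste0("beta_", psi_terms), paste0("alpha_", p_terms),
                 "u_year[2021]", "u_site[S1]", "sigma_year", "sigma_site")
  kept <- n %/% n_chains
  samples <- array(0, c(kept, n_chains, length(par_names)),
                   dimnames = list(NULL, NULL, par_names))
  for (k in seq_along(psi_terms))
    samples[, , k] <- matrix(beta_draws[seq_len(kept * n_chains), k],
                             kept, n_chains)
  samples[, , "sigma_year"] <- sigma_year
  samples[, , "sigma_site"] <- sigma_site
  design <- list(psi_terms = psi_terms, p_terms = p_terms,
                 seasons = 2021, units = "S1", model_id = "fire_tc")
  structure(list(samples = samples, design = design,
                 settings = list(chains = n_chains)),
            class = "owl_draws")
}

# Brute-force likelihood oracle: explicit sum over the latent state.
oracle_history_prob <- function(psi, p, y) {
  obs <- !is.na(y)
  if (!any(obs)) return(1)
  yo <- y[obs]; po <- p[obs]
  p_occ <- prod(po^yo * (1 - po)^(1 - yo))
  p_unocc <- if (any(yo == 1)) 0 else 1
  psi * p_occ + (1 - psi) * p_unocc
}

# Brute-force terrain ruggedness oracle (double loop).
oracle_ruggedness <- function(E, cell_size, point, radius = 390) {
  vals <- c()
  for (i in 2:(nrow(E) - 1)) for (j in 2:(ncol(E) - 1)) {
    cx <- (j - 0.5) * cell_size; cy <- (i - 0.5) * cell_size
    if ((cx - point[1])^2 + (cy - point[2])^2 > radius^2) next
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- c(nb, abs(E[i + di, j + dj] - E[i, j]))
    }
    vals <- c(vals, mean(nb))
  }
  mean(vals)
}
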