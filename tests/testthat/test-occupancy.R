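# Helpers building small designs directly, bypassing the survey machinery.
make_io_design <- function(n, T_, psi, p, seed) {
  set.seed(seed)
  z <- rbinom(n, 1, psi)
  y <- matrix(rbinom(n * T_, 1, rep(z, T_) * p), n, T_)
  X_psi <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X_p <- array(1, c(n, T_, 1), dimnames = list(NULL, NULL, "(Intercept)"))
  owlbaci:::new_owl_design(y, X_psi, X_p, rep(1L, n), seq_len(n), 2021,
                           sprintf("S%04d", 1:n), "(Intercept)",
                           "(Intercept)", "fire_tc")
}

make_cov_table <- function(survey) {
  units <- survey$arus$aru_id
  do.call(rbind, lapply(survey$seasons, function(yr) {
    codes <- t(vapply(seq_along(units), function(i)
      time_since_codings(yr, fire_year = ifelse(i %% 2 == 0, 2021, NA),
                         removal_year = ifelse(i %% 2 == 1, 2021, NA),
                         fraction = ifelse(i %% 2 == 0, 0.7, 0)),
      numeric(13)))
    data.frame(unit = units, season = yr, ruggedness = seq_along(units),
               site_type = as.integer(seq_along(units) %% 2 == 1),
               codes, stringsAsFactors = FALSE)
  }))
}

test_that("design matrices carry exactly the model's predictor columns", {
  sv <- make_mini_survey(seasons = c(2021, 2022))
  hist <- build_history(empty_detections(), sv$deployments, sv, level = "aru")
  cov <- make_cov_table(sv)

  d1 <- build_design("fire_tc", hist, cov)
  expect_equal(colnames(d1$X_psi), c("(Intercept)", "burn", "allpostburn"))
  d2 <- build_design("bo_td", hist, cov)
  expect_equal(colnames(d2$X_psi),
               c("(Intercept)", "site_type", "lethal1", "lethal2",
                 "lethal3plus"))
  d3 <- build_design("int_tc", hist, cov)
  expect_equal(colnames(d3$X_psi),
               c("(Intercept)", "site_type", "burn", "apl_burnyrs"))
  # detection design has the five predictors (year as dummies)
  expect_setequal(d1$p_terms, c("(Intercept)", "date", "year2022",
                                "ruggedness", "effort", "invader"))
  # detection covariates are zeroed where y is missing
  miss <- is.na(d1$y)
  expect_true(all(d1$X_p[, , "effort"][miss] == 0))

  cov_bad <- cov[, setdiff(names(cov), "allpostburn")]
  expect_error(build_design("fire_tc", hist, cov_bad), "allpostburn")
})

test_that("site likelihood matches worked examples and handles edge cases", {
  expect_equal(exp(site_log_likelihood(0.5, c(0.5, 0.5), c(1, 0))), 0.125)
  expect_equal(exp(site_log_likelihood(0.5, c(0.5, 0.5), c(0, 0))), 0.625)
  expect_equal(site_log_likelihood(0.3, c(0.5, 0.5), c(NA, NA)), 0)
  expect_error(site_log_likelihood(0.5, c(Inf, 0.5), c(1, 0)), "non-finite")
})

test_that("site likelihood equals latent-state enumeration on all histories", {
  set.seed(71)
  for (T_ in 2:4) {
    pats <- expand.grid(rep(list(c(0L, 1L, NA)), T_))
    for (i in seq_len(nrow(pats))) {
      y <- as.integer(pats[i, ])
      psi <- runif(1, 0.05, 0.95)
      p <- runif(T_, 0.05, 0.95)
      expect_equal(site_log_likelihood(psi, p, y),
                   log(oracle_history_prob(psi, p, y)))
    }
  }
})

test_that("likelihood is invariant to row order and probabilities are valid", {
  sim <- simulate_occupancy_data("fire_tc", n_sites = 40, n_seasons = 1,
                                 seed = 72)
  d <- sim$design
  n <- nrow(d$y)
  psi <- plogis(drop(d$X_psi %*% c(-1, 0.5, -3)))
  ll <- vapply(seq_len(n), function(i)
    site_log_likelihood(psi[i], rep(0.4, ncol(d$y)), d$y[i, ]), numeric(1))
  expect_true(all(ll <= 0))
  ord <- sample(n)
  expect_equal(sum(ll), sum(ll[ord]))
})

test_that("the sampler is deterministic under a fixed seed", {
  d <- make_io_design(40, 4, 0.6, 0.5, seed = 73)
  a <- sample_posterior(d, chains = 2, iters = 120, burn = 60, seed = 9)
  b <- sample_posterior(d, chains = 2, iters = 120, burn = 60, seed = 9)
  expect_identical(a$samples, b$samples)
})

test_that("intercept-only occupancy and detection are recovered", {
  d <- make_io_design(500, 8, psi = 0.6, p = 0.7, seed = 61)
  dr <- sample_posterior(d, chains = 2, iters = 800, burn = 400, seed = 62,
                         random_effects = FALSE)
  m <- as.matrix(dr)
  expect_lt(abs(mean(plogis(m[, "beta_(Intercept)"])) - 0.6), 0.05)
  expect_lt(abs(mean(plogis(m[, "alpha_(Intercept)"])) - 0.7), 0.05)
})

test_that("with near-complete detection the posterior matches the conjugate oracle", {
  # at p ~ 1 the occupancy posterior reduces to Beta(1 + k, 1 + n - k)
  d <- make_io_design(300, 6, psi = 0.6, p = 0.985, seed = 63)
  dr <- sample_posterior(d, chains = 2, iters = 1000, burn = 500, seed = 64,
                         random_effects = FALSE)
  psi_draws <- plogis(as.matrix(dr)[, "beta_(Intercept)"])
  k <- sum(rowSums(d$y) > 0); n <- nrow(d$y)
  beta_mean <- (k + 1) / (n + 2)
  beta_sd <- sqrt((k + 1) * (n + 1 - k) / ((n + 2)^2 * (n + 3)))
  expect_lt(abs(mean(psi_draws) - beta_mean), 3 * beta_sd / sqrt(10))
  expect_lt(abs(sd(psi_draws) / beta_sd - 1), 0.25)
})

test_that("R-hat follows the textbook formula and flags divergent chains", {
  set.seed(74)
  # oracle: direct evaluation of the formula on a fixed two-chain array
  x <- matrix(rnorm(200), 100, 2)
  W <- mean(apply(x, 2, var))
  B_n <- var(colMeans(x))
  expect_equal(gelman_rubin(x), sqrt((99 / 100 * W + B_n) / W))

  same <- matrix(rnorm(2000), 1000, 2)
  expect_lt(gelman_rubin(same), 1.05)
  apart <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(gelman_rubin(apart), 5)
  expect_error(gelman_rubin(matrix(rnorm(100), 100, 1)), "2 chains")
})

test_that("prediction reflects the coefficient draws and random effects", {
  terms <- c("(Intercept)", "burn", "allpostburn")
  zero <- make_fake_draws(matrix(0, 100, 3), terms)
  pr <- predict_occupancy(zero, c(burn = 1, allpostburn = 0.5), re = "zero")
  expect_equal(pr$mean, 0.5)
  expect_equal(pr$upper - pr$lower, 0)

  expect_error(predict_occupancy(zero, c(burn = 1)), "allpostburn")

  set.seed(75)
  pos <- make_fake_draws(cbind(rnorm(100, 0, 0.1), runif(100, 0.5, 1),
                               runif(100, 1, 2)), terms)
  lo <- predict_occupancy(pos, c(burn = 0, allpostburn = 0.2), re = "zero")
  hi <- predict_occupancy(pos, c(burn = 0, allpostburn = 0.8), re = "zero")
  expect_gt(hi$mean, lo$mean)
  expect_true(all(predict_occupancy(pos, c(burn = 1, allpostburn = 1),
                                    re = "zero")$draws >= 0))

  # marginalizing widens the interval when the SDs are positive
  wide <- make_fake_draws(matrix(0, 100, 3), terms, sigma_year = 1,
                          sigma_site = 1)
  pm <- predict_occupancy(wide, c(burn = 0, allpostburn = 0), re = "marginal")
  expect_gt(pm$upper - pm$lower, 0.2)
})

test_that("constant occupancy columns trigger a warning", {
  sv <- make_mini_survey(seasons = c(2021, 2022))
  hist <- build_history(empty_detections(), sv$deployments, sv, level = "aru")
  cov <- make_cov_table(sv)
  cov$burn <- 0; cov$allpostburn <- 0 # nothing burned
  d <- build_design("fire_tc", hist, cov)
  expect_warning(sample_posterior(d, chains = 1, iters = 60, burn = 30,
                                  seed = 1),
                 "constant")
})
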