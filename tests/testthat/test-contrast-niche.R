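test_that("posterior overlap matches analytic values and is well behaved", {
  set.seed(91)
  a <- rnorm(5000); b <- rnorm(5000, 2)
  ov <- posterior_overlap(a, b)
  expect_lt(abs(ov$overlap - 2 * pnorm(-1)), 0.02)
  expect_false(ov$meaningful)

  same <- posterior_overlap(rnorm(5000), rnorm(5000))
  expect_gte(same$overlap, 0.95)

  far <- posterior_overlap(rnorm(2000), rnorm(2000, 50))
  expect_lt(far$overlap, 0.01)
  expect_true(far$meaningful)

  # symmetry and common-shift invariance
  expect_equal(posterior_overlap(a, b)$overlap,
               posterior_overlap(b, a)$overlap)
  expect_equal(posterior_overlap(a + 10, b + 10)$overlap,
               posterior_overlap(a, b)$overlap, tolerance = 1e-3)

  expect_error(posterior_overlap(rep(1, 100), rnorm(100)), "degenerate")
})

test_that("removal contrasts compare pre- and post-removal linear predictors", {
  set.seed(92)
  terms <- c("(Intercept)", "site_type", "allpostlethal")
  dr <- make_fake_draws(cbind(rnorm(1000, -2, 0.2), rnorm(1000, -0.9, 0.2),
                              rnorm(1000, 0.9, 0.2)), terms)
  ct <- removal_contrast(dr, "allpostlethal")
  # effect of +0.9 with sd ~0.28: overlap should be small but nonzero
  expect_lt(ct$overlap, 0.3)
  expect_gt(ct$overlap, 0)
  expect_equal(ct$scale, "logit")
  expect_equal(mean(ct$eta_post - ct$eta_pre),
               mean(as.matrix(dr)[, "beta_allpostlethal"]))
  expect_error(removal_contrast(dr, "lethal1"), "lethal1")
})

test_that("occurrence model recovers generating coefficients", {
  set.seed(93)
  n <- 1000
  X <- data.frame(elevation = rnorm(n), ruggedness = rnorm(n),
                  seral_frac = runif(n))
  eta <- -1 + 4.2 * (X$seral_frac - mean(X$seral_frac)) / sd(X$seral_frac)
  occ <- rbinom(n, 1, plogis(eta))
  fit <- fit_occurrence_logistic(occ, X)
  expect_false(fit$flagged)
  # seral effect recovered within its interval; null effects near zero
  expect_gt(fit$upper[["seral_frac"]], 4.2 - 1)
  expect_lt(abs(fit$coef[["elevation"]]), 3.5 * fit$se[["elevation"]])
  expect_lt(abs(fit$coef[["ruggedness"]]), 3.5 * fit$se[["ruggedness"]])

  expect_error(fit_occurrence_logistic(rep(0, 50),
                                       data.frame(x = rnorm(50))),
               "both 0s and 1s")
})

test_that("separated occurrence data falls back to a flagged penalized fit", {
  x <- c(seq(-3, -1, length.out = 30), seq(1, 3, length.out = 30))
  occ <- rep(c(0L, 1L), each = 30)
  fit <- fit_occurrence_logistic(occ, data.frame(x = x))
  expect_true(fit$flagged)
  expect_true(all(is.finite(fit$coef)))
})

test_that("average marginal effects match the finite-difference oracle", {
  set.seed(94)
  n <- 400
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  occ <- rbinom(n, 1, plogis(0.3 + 0.8 * X$a - 0.5 * X$b))
  fit <- fit_occurrence_logistic(occ, X, standardize = FALSE)
  for (v in c("a", "b")) {
    ame <- average_marginal_effect(fit, v)
    # numeric derivative: nudge the covariate itself by +/- h in every row
    h <- 1e-5
    Xm <- cbind(1, as.matrix(fit$data[, c("a", "b")]))
    bv <- fit$coef
    eta <- drop(Xm %*% bv)
    fd <- (mean(plogis(eta + h * bv[[v]])) -
             mean(plogis(eta - h * bv[[v]]))) / (2 * h)
    expect_equal(ame, fd, tolerance = 1e-6)
  }
  # zero coefficient: zero AME
  fit0 <- fit
  fit0$coef[["a"]] <- 0
  expect_equal(average_marginal_effect(fit0, "a"), 0)
  expect_error(average_marginal_effect(fit, "zzz"), "unknown covariate")
})

test_that("a single observation at linear predictor zero gives AME 0.25", {
  fit <- structure(list(coef = c("(Intercept)" = 0, x = 1), fitted = 0.5,
                        data = data.frame(occ = 1, x = 0)),
                   class = "owl_occurrence")
  expect_equal(average_marginal_effect(fit, "x"), 0.25)
})

test_that("standard ellipses have the chi-square area and 85% coverage", {
  # four points with exactly unit sample covariance
  P <- sqrt(3 / 2) * rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  e <- standard_ellipse(P, 0.85)
  expect_equal(e$cov, diag(2), ignore_attr = TRUE)
  expect_equal(e$area, pi * qchisq(0.85, 2))
  expect_equal(e$area, pi * (-2 * log(0.15)))

  # doubling one axis doubles the area
  P2 <- P %*% diag(c(2, 1))
  expect_equal(standard_ellipse(P2, 0.85)$area, 2 * e$area)

  # area strictly increasing in the level
  lv <- c(0.5, 0.7, 0.85, 0.95)
  areas <- vapply(lv, function(l) standard_ellipse(P, l)$area, numeric(1))
  expect_true(all(diff(areas) > 0))

  expect_error(standard_ellipse(cbind(1:10, 2 * (1:10))), "collinear")
  expect_error(standard_ellipse(P[1:2, ]), "3 points")

  set.seed(95)
  G <- matrix(rnorm(40000), ncol = 2) %*% chol(matrix(c(2, 0.8, 0.8, 1), 2))
  eg <- standard_ellipse(G, 0.85)
  d <- sweep(G, 2, eg$center)
  inside <- rowSums((d %*% solve(eg$cov)) * d) <= qchisq(0.85, 2)
  expect_lt(abs(mean(inside) - 0.85), 0.02)
})

test_that("ellipse overlap reproduces the circular lens area", {
  unit_circle <- function(cx) {
    cc <- qchisq(0.85, 2)
    structure(list(center = c(cx, 0), cov = diag(2) / cc, level = 0.85,
                   area = pi), class = "owl_ellipse")
  }
  a <- unit_circle(0); b <- unit_circle(1)
  lens <- 2 * acos(1 / 2) - (1 / 2) * sqrt(3)
  got512 <- ellipse_overlap(a, b, 512)
  expect_lt(abs(got512$intersection_area - lens) / lens, 0.001)
  got256 <- ellipse_overlap(a, b, 256)
  expect_lt(abs(got256$intersection_area - lens) / lens, 0.001)
  # polygonal approximation converges with the vertex count
  err <- vapply(c(64, 128, 256, 512), function(nv)
    abs(ellipse_overlap(a, b, nv)$intersection_area - lens), numeric(1))
  expect_true(all(diff(err) < 0))

  expect_equal(ellipse_overlap(a, a)$overlap_fraction, 1, tolerance = 1e-3)
  expect_equal(ellipse_overlap(a, unit_circle(10))$overlap_fraction, 0)
  expect_lte(got512$overlap_fraction, 1)
  expect_gte(got512$overlap_fraction, 0)
})
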