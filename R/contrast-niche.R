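## Posterior-overlap contrasts and habitat niche segregation: kernel-density
## overlap of posterior samples, invader occurrence models, average marginal
## effects, standard ellipses, and ellipse overlap by polygon clipping.

#' Overlap between two posterior distributions
#'
#' Estimates the overlapping index `integral of min(f_a, f_b)` from two
#' draw vectors using Gaussian kernel densities evaluated on a shared grid
#' spanning both samples plus three bandwidths on each side. Differences
#' are conventionally called biologically meaningful when the overlap falls
#' below `threshold` (default 15%).
#'
#' @param draws_a,draws_b Numeric vectors of posterior draws (typically on
#'   the logit scale).
#' @param n_grid Number of shared grid points (default 512).
#' @param threshold Meaningful-difference threshold on the overlap
#'   (default 0.15).
#' @return An object of class `owl_overlap`: list with `overlap` in
#'   `[0, 1]`, `meaningful` (`TRUE` iff `overlap < threshold`), and
#'   `threshold`.
#' @export
posterior_overlap <- function(draws_a, draws_b, n_grid = 512,
                              threshold = 0.15) {
  if (stats::sd(draws_a) == 0 || stats::sd(draws_b) == 0)
    stop("degenerate (zero-variance) draws")
  bw_a <- tryCatch(stats::bw.SJ(draws_a), error = function(e) stats::bw.nrd0(draws_a))
  bw_b <- tryCatch(stats::bw.SJ(draws_b), error = function(e) stats::bw.nrd0(draws_b))
  lo <- min(draws_a, draws_b) - 3 * max(bw_a, bw_b)
  hi <- max(draws_a, draws_b) + 3 * max(bw_a, bw_b)
  fa <- stats::density(draws_a, bw = bw_a, from = lo, to = hi, n = n_grid)
  fb <- stats::density(draws_b, bw = bw_b, from = lo, to = hi, n = n_grid)
  ov <- min(1, trapz(fa$x, pmin(fa$y, fb$y)))
  structure(list(overlap = ov, meaningful = ov < threshold,
                 threshold = threshold, scale = "as supplied"),
            class = "owl_overlap")
}

#' @export
print.owl_overlap <- function(x, ...) {
  cat(sprintf("<owl_overlap> %.1f%% overlap (%smeaningful difference at <%.0f%%)\n",
              100 * x$overlap, if (x$meaningful) "" else "not a ",
              100 * x$threshold))
  invisible(x)
}

#' Pre- vs post-removal posterior contrast at removal sites
#'
#' Compares the occupancy linear predictor at removal sites before removals
#' (intercept + site-type effect) with the same sites after removals
#' (adding the chosen post-removal effect), on the logit scale, and reports
#' the posterior overlap. Applicable to the removal models (`bo_tc`,
#' `bo_td`) and their post-removal terms.
#'
#' @param draws An `owl_draws` from a removal model.
#' @param effect Post-removal term: `"allpostlethal"` (bo_tc) or one of
#'   `"lethal1"`, `"lethal2"`, `"lethal3plus"` (bo_td).
#' @param threshold Meaningful-difference threshold (default 0.15).
#' @return An `owl_overlap` with the pre/post draw vectors attached as
#'   `eta_pre` / `eta_post`.
#' @export
removal_contrast <- function(draws, effect = "allpostlethal",
                             threshold = 0.15) {
  m <- as.matrix(draws)
  need <- paste0("beta_", c("(Intercept)", "site_type", effect))
  missing_cols <- setdiff(need, colnames(m))
  if (length(missing_cols))
    stop("draws lack parameter(s): ", paste(missing_cols, collapse = ", "),
         " (is this a removal model?)")
  eta_pre <- m[, need[1]] + m[, need[2]]
  eta_post <- eta_pre + m[, need[3]]
  out <- posterior_overlap(eta_pre, eta_post, threshold = threshold)
  out$scale <- "logit"
  out$eta_pre <- eta_pre
  out$eta_post <- eta_post
  out
}

#' Logistic occurrence model for the invader
#'
#' Fits a maximum-likelihood logistic regression of hexagon-level
#' occurrence on standardized elevation, terrain ruggedness, and seral
#' forest fraction — appropriate for a species surveyed without repeat
#' visits whose seasonal detection probability is high. Complete
#' separation triggers a lightly ridge-penalized fit, flagged in the
#' result.
#'
#' @param occurrence Binary 0/1 vector (one value per hexagon).
#' @param covariates Data frame of predictors (default expectation:
#'   `elevation`, `ruggedness`, `seral_frac`).
#' @param standardize Z-standardize the predictors (default `TRUE`).
#' @param level Interval level (default 0.85).
#' @return An object of class `owl_occurrence`: list with `coef`, `se`,
#'   `lower`, `upper`, `fitted`, `data` (model frame used), `flagged`.
#' @export
fit_occurrence_logistic <- function(occurrence, covariates,
                                    standardize = TRUE, level = 0.85) {
  occurrence <- as.integer(occurrence)
  if (length(unique(occurrence)) < 2)
    stop("occurrence must contain both 0s and 1s")
  X <- as.data.frame(covariates)
  if (standardize)
    X[] <- lapply(X, function(v) as.numeric(zscore(v)))
  df <- cbind(data.frame(occ = occurrence), X)
  fit <- suppressWarnings(stats::glm(occ ~ ., data = df,
                                     family = stats::binomial()))
  b <- stats::coef(fit)
  flagged <- !fit$converged || any(!is.finite(b)) || any(abs(b) > 15)
  if (flagged) {
    Xm <- cbind(1, as.matrix(X))
    b <- ridge_logistic(Xm, occurrence, lambda = 0.01)
    names(b) <- c("(Intercept)", names(X))
    eta <- drop(Xm %*% b)
    w <- invlogit(eta) * (1 - invlogit(eta))
    se <- sqrt(diag(solve(crossprod(Xm * w, Xm) + diag(0.01, ncol(Xm)))))
  } else {
    se <- summary(fit)$coefficients[, "Std. Error"]
    eta <- stats::predict(fit)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(coef = b, se = se, lower = b - z * se, upper = b + z * se,
                 fitted = invlogit(eta), data = df, level = level,
                 flagged = flagged),
            class = "owl_occurrence")
}

#' Average marginal effect of a covariate in a logistic model
#'
#' The mean, over the observed covariate rows, of the derivative of the
#' occurrence probability with respect to the covariate:
#' `mean(beta_j * p * (1 - p))`.
#'
#' @param fit An `owl_occurrence`.
#' @param covariate Name of the covariate.
#' @return The average marginal effect (probability units per unit of the
#'   covariate as entered in the model).
#' @export
average_marginal_effect <- function(fit, covariate) {
  stopifnot(inherits(fit, "owl_occurrence"))
  if (!covariate %in% names(fit$coef))
    stop("unknown covariate: ", covariate)
  mean(fit$coef[[covariate]] * fit$fitted * (1 - fit$fitted))
}

#' Standard ellipse of bivariate habitat-use points
#'
#' The Gaussian quantile ellipse: centered at the sample mean with shape
#' given by the sample covariance scaled by the chi-square(2) quantile of
#' the requested level, so the ellipse encloses the stated fraction of a
#' bivariate normal population. Its area, `pi * chisq_2(level) *
#' sqrt(det(Sigma))`, measures niche breadth on the two covariate axes.
#'
#' @param points 2-column matrix or data.frame of (standardized) covariate
#'   values at detection sites; at least 3 non-collinear points.
#' @param level Enclosed probability level (default 0.85).
#' @param label Optional species label.
#' @return An object of class `owl_ellipse`: list with `center`, `cov`,
#'   `level`, `area`, `label`.
#' @export
standard_ellipse <- function(points, level = 0.85, label = NULL) {
  P <- as.matrix(points)
  stopifnot(ncol(P) == 2)
  if (nrow(P) < 3) stop("at least 3 points are required")
  S <- stats::cov(P)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev)) stop("points are (nearly) collinear")
  cc <- stats::qchisq(level, df = 2)
  structure(list(center = colMeans(P), cov = S, level = level,
                 area = pi * cc * sqrt(det(S)), label = label),
            class = "owl_ellipse")
}

#' @export
print.owl_ellipse <- function(x, ...) {
  cat(sprintf("<owl_ellipse>%s level %.2f, area %.3f, center (%.2f, %.2f)\n",
              if (!is.null(x$label)) paste0(" ", x$label), x$level, x$area,
              x$center[1], x$center[2]))
  invisible(x)
}

#' Boundary polygon of a standard ellipse
#' @noRd
ellipse_polygon <- function(e, n_vertices = 512) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  L <- t(chol(e$cov))
  r <- sqrt(stats::qchisq(e$level, 2))
  t(e$center + r * L %*% rbind(cos(th), sin(th)))
}

#' Shoelace polygon area (absolute)
#' @noRd
polygon_area <- function(P) {
  n <- nrow(P)
  if (is.null(n) || n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(P[, 1] * P[i2, 2] - P[i2, 1] * P[, 2])) / 2
}

#' Sutherland-Hodgman clipping of convex polygon P by convex polygon Q
#' @noRd
convex_clip <- function(P, Q) {
  # ensure counter-clockwise orientation of the clip polygon
  n <- nrow(Q); i2 <- c(2:n, 1)
  if (sum(Q[, 1] * Q[i2, 2] - Q[i2, 1] * Q[, 2]) < 0) Q <- Q[n:1, ]
  out <- P
  nq <- nrow(Q)
  for (e in seq_len(nq)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    A <- Q[e, ]; B <- Q[if (e == nq) 1 else e + 1, ]
    # inside = left of directed edge A->B
    side <- function(p) (B[1] - A[1]) * (p[2] - A[2]) - (B[2] - A[2]) * (p[1] - A[1])
    inp <- apply(out, 1, side) >= 0
    m <- nrow(out)
    res <- list()
    for (i in seq_len(m)) {
      j <- if (i == m) 1 else i + 1
      p1 <- out[i, ]; p2 <- out[j, ]
      if (inp[i]) res[[length(res) + 1]] <- p1
      if (inp[i] != inp[j]) {
        s1 <- side(p1); s2 <- side(p2)
        t <- s1 / (s1 - s2)
        res[[length(res) + 1]] <- p1 + t * (p2 - p1)
      }
    }
    out <- if (length(res) >= 3) do.call(rbind, res) else NULL
  }
  out
}

#' Intersection area and overlap fraction of two standard ellipses
#'
#' Each ellipse boundary is approximated by a polygon (default 512
#' vertices) and the intersection is computed by convex polygon clipping;
#' the overlap fraction normalizes the intersection area by the smaller
#' ellipse's area.
#'
#' @param a,b `owl_ellipse` objects in the same covariate space.
#' @param n_vertices Boundary vertices per ellipse (default 512).
#' @return List with `intersection_area` and `overlap_fraction` in
#'   `[0, 1]`.
#' @export
ellipse_overlap <- function(a, b, n_vertices = 512) {
  stopifnot(inherits(a, "owl_ellipse"), inherits(b, "owl_ellipse"))
  Pa <- ellipse_polygon(a, n_vertices)
  Pb <- ellipse_polygon(b, n_vertices)
  inter <- convex_clip(Pa, Pb)
  area <- if (is.null(inter)) 0 else polygon_area(inter)
  list(intersection_area = area,
       overlap_fraction = min(1, area / min(a$area, b$area)))
}

#' Plot standard ellipses with their defining points
#'
#' @param x An `owl_ellipse`.
#' @param points Optional point matrix to overlay.
#' @param add Add to an existing plot.
#' @param ... Passed to [graphics::lines()].
#' @export
plot.owl_ellipse <- function(x, points = NULL, add = FALSE, ...) {
  P <- ellipse_polygon(x, 256)
  P <- rbind(P, P[1, ])
  if (!add)
    graphics::plot(P, type = "n", xlab = "axis 1 (standardized)",
                   ylab = "axis 2 (standardized)", asp = 1)
  graphics::lines(P, ...)
  if (!is.null(points)) graphics::points(points, pch = 16, cex = 0.5)
  invisible(x)
}
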