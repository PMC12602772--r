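#' @keywords internal
"_PACKAGE"

## Small shared helpers. Nothing here is exported.

invlogit <- function(x) stats::plogis(x)

logit <- function(p) stats::qlogis(p)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoid-rule integral on an ordered grid
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Z-standardize, recording center/scale as attributes.
#' A constant column maps to all zeros (scale recorded as 1).
#' @noRd
zscore <- function(x, center = NULL, scale = NULL) {
  center <- center %||% mean(x, na.rm = TRUE)
  scale <- scale %||% stats::sd(x, na.rm = TRUE)
  if (!is.finite(scale) || scale == 0) scale <- 1
  out <- (x - center) / scale
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Derive a stage- or chain-specific RNG seed from a master seed.
#'
#' Simple multiplicative splitting kept below 2^31 so the result is always a
#' valid R integer seed; documented so runs are reproducible stage by stage.
#' @noRd
derive_seed <- function(master, offset) {
  as.integer((abs(as.numeric(master)) %% 100000) * 20011 + offset * 7919) %% 2147483399L + 1L
}

#' Separable Gaussian smoothing of a matrix with edge renormalization.
#' @noRd
gauss_smooth <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  k <- max(1L, ceiling(3 * sigma_cells))
  w <- stats::dnorm(-k:k, sd = sigma_cells)
  smooth1 <- function(mat) {
    # filter along columns; renormalize by the filtered weights of a ones-matrix
    num <- stats::filter(mat, w, sides = 2)
    den <- stats::filter(matrix(1, nrow(mat), ncol(mat)), w, sides = 2)
    num[is.na(num)] <- 0
    den[is.na(den) | den == 0] <- 1
    matrix(num / den, nrow(mat), ncol(mat))
  }
  t(smooth1(t(smooth1(m))))
}

#' Hours (possibly fractional) of overlap between two time intervals
#' @noRd
interval_overlap_hours <- function(a_start, a_end, b_start, b_end) {
  lo <- pmax(as.numeric(a_start), as.numeric(b_start))
  hi <- pmin(as.numeric(a_end), as.numeric(b_end))
  pmax(0, hi - lo) / 3600
}
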