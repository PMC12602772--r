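## Synthetic acoustic survey design: hexagonal grid, ARU placement, deployments.

HEX_AREA_M2 <- 400 * 1e4 # 400-ha survey hexagons, matching the study grid

#' Center-to-center spacing of a hexagonal grid with 400-ha cells
#' @noRd
hex_spacing <- function(area_m2 = HEX_AREA_M2) sqrt(2 * area_m2 / sqrt(3))

#' Simulate the acoustic survey design
#'
#' Places `n_hex` non-contiguous 400-ha hexagonal survey cells on the
#' landscape (candidate cells sharing an edge with an already selected cell
#' are rejected, so sampled cells never touch), puts two autonomous recording
#' units (ARUs) at least 500 m apart inside each, and schedules per-season
#' recording deployments.
#'
#' Two deployment plans are supported, mirroring the two survey protocols:
#' `"continuous"` is a single 5-week (35-day) deployment starting May 7;
#' `"pulse"` is three 1-week deployments separated by gaps of at least 14
#' days (starts May 7, May 28, June 18).
#'
#' @param landscape An `owl_landscape`.
#' @param n_hex Number of hexagonal cells to sample (default 60).
#' @param seasons Integer vector of survey years
#'   (default `c(2018, 2021, 2022, 2023)`).
#' @param deployment_plan Named character vector mapping season to
#'   `"pulse"` or `"continuous"`; unnamed scalar recycles to all seasons.
#'   Default: `"pulse"` for the first season, `"continuous"` afterwards.
#' @param seed Integer RNG seed.
#'
#' @return An object of class `owl_survey`: list with `hexagons`
#'   (data.frame: hex_id, x, y), `arus` (data.frame: aru_id, hex_id, x, y),
#'   `seasons`, and `deployments` (data.frame: aru_id, season, start, end —
#'   POSIXct UTC, non-overlapping within an ARU-season).
#' @export
simulate_survey <- function(landscape, n_hex = 60,
                            seasons = c(2018, 2021, 2022, 2023),
                            deployment_plan = NULL, seed = 1) {
  stopifnot(inherits(landscape, "owl_landscape"), n_hex >= 1)
  set.seed(seed)
  d <- hex_spacing()
  ext <- landscape$extent
  # hexagonal lattice of candidate centers; the margin leaves room for the
  # cell itself plus ARU-centered covariate buffers near the border
  margin <- d / sqrt(3) + 500
  rows <- floor((ext[2] - 2 * margin) / (d * sqrt(3) / 2)) + 1
  cand <- do.call(rbind, lapply(seq_len(rows) - 1L, function(j) {
    y <- margin + j * d * sqrt(3) / 2
    x0 <- margin + (j %% 2) * d / 2
    x <- seq(x0, ext[1] - margin, by = d)
    if (!length(x)) return(NULL)
    cbind(x = x, y = y)
  }))
  if (is.null(cand) || !nrow(cand)) stop("landscape too small for the hexagon grid")

  ord <- sample(nrow(cand))
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= n_hex) break
    if (!length(sel) ||
        min(sqrt((cand[sel, 1] - cand[i, 1])^2 +
                 (cand[sel, 2] - cand[i, 2])^2)) > 1.05 * d)
      sel <- c(sel, i)
  }
  if (length(sel) < n_hex)
    stop(sprintf("cannot place %d non-contiguous hexagons (max %d on this landscape)",
                 n_hex, length(sel)))
  hexagons <- data.frame(hex_id = sprintf("H%03d", seq_len(n_hex)),
                         x = cand[sel, 1], y = cand[sel, 2],
                         stringsAsFactors = FALSE)

  inradius <- d / 2
  arus <- do.call(rbind, lapply(seq_len(n_hex), function(h) {
    repeat {
      th <- stats::runif(2, 0, 2 * pi)
      r <- sqrt(stats::runif(2)) * 0.85 * inradius
      px <- hexagons$x[h] + r * cos(th)
      py <- hexagons$y[h] + r * sin(th)
      if (sqrt(diff(px)^2 + diff(py)^2) >= 500) break
    }
    data.frame(aru_id = paste0(hexagons$hex_id[h], c("A", "B")),
               hex_id = hexagons$hex_id[h], x = px, y = py,
               stringsAsFactors = FALSE)
  }))

  if (is.null(deployment_plan)) {
    deployment_plan <- stats::setNames(
      c("pulse", rep("continuous", length(seasons) - 1)), seasons)
  } else if (is.null(names(deployment_plan))) {
    deployment_plan <- stats::setNames(rep(deployment_plan, length(seasons)),
                                       seasons)
  }
  bad <- setdiff(deployment_plan, c("pulse", "continuous"))
  if (length(bad)) stop("unknown deployment plan: ", paste(bad, collapse = ", "))

  deployments <- do.call(rbind, lapply(seasons, function(yr) {
    plan <- deployment_plan[[as.character(yr)]]
    starts <- if (plan == "continuous") "05-07" else c("05-07", "05-28", "06-18")
    len_days <- if (plan == "continuous") 35 else 7
    do.call(rbind, lapply(starts, function(s) {
      st <- as.POSIXct(paste0(yr, "-", s, " 00:00:00"), tz = "UTC")
      data.frame(aru_id = arus$aru_id, season = yr, start = st,
                 end = st + len_days * 86400, stringsAsFactors = FALSE)
    }))
  }))
  rownames(deployments) <- NULL

  structure(list(hexagons = hexagons, arus = arus, seasons = seasons,
                 deployments = deployments, hex_spacing = d),
            class = "owl_survey")
}

#' @export
print.owl_survey <- function(x, ...) {
  cat(sprintf("<owl_survey> %d hexagons (400 ha), %d ARUs, seasons %s\n",
              nrow(x$hexagons), nrow(x$arus),
              paste(x$seasons, collapse = ", ")))
  invisible(x)
}
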