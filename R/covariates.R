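## Site-year covariate engine: home-range buffers, severe-fire fraction,
## removal overlap, time-since codings, terrain ruggedness, seral fraction.

#' Radius of a circular buffer of a given area
#'
#' Species home ranges are represented as circles; the buffer radius solves
#' `area = pi * r^2`. Areas are in hectares, the radius in meters.
#'
#' @param area_ha Buffer area in hectares (> 0).
#' @return Radius in meters.
#' @examples
#' buffer_radius(50)   # flammulated owl home range, ~398.9 m
#' buffer_radius(2004) # barred owl home range, ~2525.7 m
#' @export
buffer_radius <- function(area_ha) {
  if (any(area_ha <= 0)) stop("buffer area must be positive")
  sqrt(area_ha * 1e4 / pi)
}

#' Default home-range buffer areas (ha) per species
#'
#' Flammulated and pygmy owl buffers are centered on individual ARUs; the
#' great horned owl buffer on the hexagon center; the invader (barred owl)
#' buffer on each removal location.
#' @return Named numeric vector of areas in hectares.
#' @export
species_buffer_areas <- function() {
  c(flammulated = 50, pygmy = 300, great_horned = 700, invader = 2004)
}

#' Mean absolute elevation difference of each cell to its 8 neighbors
#' @noRd
neighbor_mad <- function(E) {
  ny <- nrow(E); nx <- ncol(E)
  M <- matrix(NA_real_, ny, nx)
  acc <- matrix(0, ny - 2, nx - 2)
  core <- E[2:(ny - 1), 2:(nx - 1)]
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    acc <- acc + abs(E[2:(ny - 1) + dy, 2:(nx - 1) + dx] - core)
  }
  M[2:(ny - 1), 2:(nx - 1)] <- acc / 8
  M
}

#' Terrain ruggedness around a point
#'
#' For every grid cell whose center lies within `radius` of `point`, computes
#' the mean absolute difference between the cell's elevation and its eight
#' surrounding cells, then averages those per-cell values over the buffer.
#' Units are meters. No edge extrapolation is performed: if the buffer
#' touches the grid border (where cells lack a full 8-neighborhood) an error
#' is raised.
#'
#' @param landscape An `owl_landscape` (or a bare elevation matrix, in which
#'   case `cell_size` must be supplied).
#' @param point Length-2 xy coordinates in meters.
#' @param radius Neighborhood radius in meters (default 390).
#' @param cell_size Cell size when `landscape` is a bare matrix.
#' @return Ruggedness in meters (0 on constant terrain).
#' @export
terrain_ruggedness <- function(landscape, point, radius = 390,
                               cell_size = NULL) {
  if (inherits(landscape, "owl_landscape")) {
    E <- landscape$elevation
  } else {
    E <- landscape
    landscape <- structure(list(elevation = E, cell_size = cell_size,
                                origin = c(0, 0)), class = "owl_landscape")
  }
  cells <- cells_in_circle(landscape, point, radius)
  if (!nrow(cells)) stop("ruggedness buffer contains no grid cells")
  if (any(cells[, "row"] <= 1 | cells[, "row"] >= nrow(E) |
          cells[, "col"] <= 1 | cells[, "col"] >= ncol(E)))
    stop("ruggedness buffer exceeds the elevation grid (no edge extrapolation)")
  M <- neighbor_mad(E)
  mean(M[cells])
}

#' Severe-burn indicator and high-severity fraction within a buffer
#'
#' Cells count by cell-center inclusion in the circular buffer. Survey
#' seasons at or before the fire's calendar year are prefire and return
#' `c(burn = 0, frac = 0)`.
#'
#' @param landscape An `owl_landscape`.
#' @param fire One element of `landscape$fires` (or its index).
#' @param centre Buffer center xy in meters.
#' @param radius Buffer radius in meters.
#' @param season Survey calendar year.
#' @return Named numeric vector `c(burn =, frac =)`; `burn` is 1 iff
#'   `frac > 0`.
#' @export
severe_fraction <- function(landscape, fire, centre, radius, season) {
  if (is.numeric(fire) && length(fire) == 1) fire <- landscape$fires[[fire]]
  if (season <= fire$year) return(c(burn = 0, frac = 0))
  cells <- cells_in_circle(landscape, centre, radius)
  if (!nrow(cells)) return(c(burn = 0, frac = 0))
  frac <- mean(fire$burn[cells])
  c(burn = as.numeric(frac > 0), frac = frac)
}

#' Fraction of intermediate-to-late seral forest within a buffer
#' @noRd
seral_fraction <- function(landscape, centre, radius) {
  cells <- cells_in_circle(landscape, centre, radius)
  if (!nrow(cells)) return(0)
  mean(landscape$seral[cells])
}

#' Home-range overlap between a site and barred owl removal locations
#'
#' A site is a removal site (`site_type = 1`) iff its species home-range
#' circle intersects any removal home-range circle; circles intersect iff
#' the center distance is strictly less than the sum of radii (tangency
#' counts as non-overlap).
#'
#' @param site_xy Length-2 site buffer center.
#' @param site_r Site buffer radius in meters.
#' @param removals Data frame with columns `x`, `y`, `year`.
#' @param removal_r Removal buffer radius in meters
#'   (default `buffer_radius(2004)`).
#' @return List with `site_type` (0/1) and `removal_year` (earliest year of
#'   an overlapping removal; `NA` if none overlap).
#' @export
removal_overlap <- function(site_xy, site_r, removals,
                            removal_r = buffer_radius(2004)) {
  if (is.null(removals) || !nrow(removals))
    return(list(site_type = 0L, removal_year = NA_integer_))
  d <- sqrt((removals$x - site_xy[1])^2 + (removals$y - site_xy[2])^2)
  hit <- d < site_r + removal_r
  list(site_type = as.integer(any(hit)),
       removal_year = if (any(hit)) min(removals$year[hit]) else NA_integer_)
}

#' Time-since-disturbance covariate codings for one site-year row
#'
#' Produces every BACI occupancy predictor for a stacked site-year row from
#' the survey season, the (optional) fire year and high-severity fraction,
#' and the (optional) removal year:
#'
#' * `burn` — 1 iff the site is postfire with `fraction > 0`;
#' * `allpostburn` — the high-severity fraction, any year postfire;
#' * `burn1`..`burn3` — the fraction in exactly the 1st/2nd/3rd postfire
#'   year (fraction-valued, zero otherwise);
#' * `allpostlethal` — 1 iff the season is after the removal year;
#' * `lethal1`, `lethal2`, `lethal3plus` — indicators for exactly 1, 2, and
#'   3-or-more years post-removal;
#' * `apl_burnyrs` — binary interaction: removal preceded the fire and the
#'   season is postfire (any year);
#' * `apl_burn1`..`apl_burn3` — binary interactions at fixed years postfire.
#'
#' Prefire and pre-removal rows carry zeros so the stacked design is
#' estimable. A removal after the last season simply yields all-zero
#' post fields.
#'
#' @param season Survey calendar year (integer).
#' @param fire_year Calendar year of the fire (`NA` for unburned sites).
#' @param removal_year Calendar year of the removal (`NA` for non-removal
#'   sites).
#' @param fraction High-severity fraction of the home-range buffer in
#'   `[0, 1]` (postfire value; gating by season happens here).
#' @return Named numeric vector of the 12 covariates listed above.
#' @export
time_since_codings <- function(season, fire_year = NA, removal_year = NA,
                               fraction = 0) {
  stopifnot(fraction >= 0, fraction <= 1)
  postfire <- !is.na(fire_year) && season > fire_year && fraction > 0
  dy_fire <- if (postfire) season - fire_year else NA
  burnK <- function(k) if (postfire && dy_fire == k) fraction else 0
  apl <- !is.na(removal_year) && season > removal_year
  dy_rem <- if (apl) season - removal_year else NA
  inter <- apl && postfire && removal_year < fire_year
  c(burn = as.numeric(postfire),
    allpostburn = if (postfire) fraction else 0,
    burn1 = burnK(1), burn2 = burnK(2), burn3 = burnK(3),
    allpostlethal = as.numeric(apl),
    lethal1 = as.numeric(apl && dy_rem == 1),
    lethal2 = as.numeric(apl && dy_rem == 2),
    lethal3plus = as.numeric(apl && dy_rem >= 3),
    apl_burnyrs = as.numeric(inter),
    apl_burn1 = as.numeric(inter && dy_fire == 1),
    apl_burn2 = as.numeric(inter && dy_fire == 2),
    apl_burn3 = as.numeric(inter && dy_fire == 3))
}

#' Build the site-year covariate table for one species
#'
#' Computes, for every sampling unit (ARU or hexagon, depending on the
#' species' home-range size) and every season: elevation, terrain
#' ruggedness, seral forest fraction, removal-site status, the fire
#' affecting the unit's buffer (the one with the largest high-severity
#' fraction, when footprints could touch several), and all time-since
#' covariate codings.
#'
#' @param survey An `owl_survey`.
#' @param landscape An `owl_landscape`.
#' @param removals Data frame of removal locations (`x`, `y`, `year`) or
#'   `NULL`.
#' @param buffer_ha Home-range buffer area in hectares.
#' @param level `"aru"` (buffer on each ARU) or `"hexagon"` (buffer on the
#'   hexagon center; units are hexagons).
#' @return Data frame keyed by (`unit`, `season`) with geometry, habitat and
#'   BACI covariates; standardization attributes are added downstream.
#' @export
build_site_covariates <- function(survey, landscape, removals = NULL,
                                  buffer_ha = 50,
                                  level = c("aru", "hexagon")) {
  level <- match.arg(level)
  r <- buffer_radius(buffer_ha)
  units <- if (level == "aru") {
    data.frame(unit = survey$arus$aru_id, hexagon = survey$arus$hex_id,
               x = survey$arus$x, y = survey$arus$y, stringsAsFactors = FALSE)
  } else {
    data.frame(unit = survey$hexagons$hex_id, hexagon = survey$hexagons$hex_id,
               x = survey$hexagons$x, y = survey$hexagons$y,
               stringsAsFactors = FALSE)
  }

  g <- grid_centers(landscape)
  static <- lapply(seq_len(nrow(units)), function(i) {
    p <- c(units$x[i], units$y[i])
    ov <- removal_overlap(p, r, removals)
    # fire relevant to this unit: largest ungated fraction among footprints
    fr_all <- vapply(landscape$fires, function(f) {
      cells <- cells_in_circle(landscape, p, r)
      if (!nrow(cells)) 0 else mean(f$burn[cells])
    }, numeric(1))
    fi <- if (length(fr_all) && max(fr_all) > 0) which.max(fr_all) else NA
    row <- which.min(abs(g$y - p[2])); col <- which.min(abs(g$x - p[1]))
    list(elevation = landscape$elevation[row, col],
         ruggedness = terrain_ruggedness(landscape, p),
         seral_frac = seral_fraction(landscape, p, r),
         site_type = ov$site_type, removal_year = ov$removal_year,
         fire_year = if (is.na(fi)) NA else landscape$fires[[fi]]$year,
         burn_frac_total = if (is.na(fi)) 0 else fr_all[fi])
  })

  rows <- do.call(rbind, lapply(survey$seasons, function(yr) {
    do.call(rbind, lapply(seq_len(nrow(units)), function(i) {
      s <- static[[i]]
      codes <- time_since_codings(yr, s$fire_year, s$removal_year,
                                  s$burn_frac_total)
      data.frame(unit = units$unit[i], hexagon = units$hexagon[i],
                 season = yr, x = units$x[i], y = units$y[i],
                 elevation = s$elevation, ruggedness = s$ruggedness,
                 seral_frac = s$seral_frac, site_type = s$site_type,
                 removal_year = s$removal_year, fire_year = s$fire_year,
                 t(codes), stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  attr(rows, "level") <- level
  attr(rows, "buffer_ha") <- buffer_ha
  rows
}

#' Pairwise Pearson correlations among occupancy predictors
#'
#' Computes the correlation matrix of the supplied predictor columns and
#' warns when any absolute pairwise correlation reaches 0.6, the screening
#' rule used before fitting the occupancy models.
#'
#' @param covariates Data frame of site-year covariates.
#' @param columns Character vector of predictor columns to screen.
#' @param threshold Warning threshold on `|r|` (default 0.6).
#' @return The correlation matrix (invisibly usable); constant columns give
#'   `NA` entries and are not flagged.
#' @export
check_collinearity <- function(covariates, columns, threshold = 0.6) {
  X <- as.matrix(covariates[, columns, drop = FALSE])
  cm <- suppressWarnings(stats::cor(X))
  off <- abs(cm[upper.tri(cm)])
  if (any(off >= threshold, na.rm = TRUE)) {
    pairs <- which(abs(cm) >= threshold & upper.tri(cm), arr.ind = TRUE)
    msg <- paste(sprintf("%s~%s (r=%.2f)", rownames(cm)[pairs[, 1]],
                         colnames(cm)[pairs[, 2]], cm[pairs]), collapse = ", ")
    warning("highly correlated predictors (|r| >= ", threshold, "): ", msg)
  }
  cm
}
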