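#' Simulate a synthetic study landscape
#'
#' Generates the raster-like layers the covariate engine consumes: a smoothed
#' Gaussian random-field elevation grid, one binary severe-burn layer per fire
#' event, and a binary intermediate-to-late seral forest layer. All layers
#' share shape and registration on a planar grid in meters (no geodesy).
#'
#' Severe-burn cells are assigned inside each circular fire footprint so the
#' realized high-severity fraction matches the requested fraction exactly up
#' to integer rounding of the cell count. The seral layer is obtained by
#' thresholding a second, independently smoothed field at the quantile giving
#' the requested landscape-wide seral fraction, which produces spatially
#' clumped stands rather than salt-and-pepper noise.
#'
#' @param extent Numeric length-2, landscape size in meters `c(xmax, ymax)`
#'   with origin at `c(0, 0)`.
#' @param cell_size Grid cell edge length in meters (default 30).
#' @param fire_specs List of fires; each element a list with `year` (calendar
#'   year of the burn), `centre` (length-2 xy in meters), `radius` (footprint
#'   radius, meters) and `severity_frac` (requested high-severity proportion
#'   within the footprint, in `[0, 1]`).
#' @param seral_frac Landscape-wide fraction of intermediate-to-late seral
#'   forest cells (default 0.45).
#' @param elev_range Length-2 numeric, approximate min/max elevation in meters.
#' @param smooth Gaussian smoothing scale of the elevation field in meters.
#' @param seed Integer RNG seed; fixed seed gives bit-identical layers.
#'
#' @return An object of class `owl_landscape`: a list with `elevation`
#'   (matrix, rows indexing y from the origin upward, columns indexing x),
#'   `seral` (binary matrix), `fires` (each with `year`, `centre`, `radius`,
#'   `severity_frac`, and binary `burn` matrix), `cell_size`, `extent`,
#'   and `origin`.
#' @export
simulate_landscape <- function(extent, cell_size = 30, fire_specs = list(),
                               seral_frac = 0.45,
                               elev_range = c(700, 2250), smooth = 300,
                               seed = 1) {
  stopifnot(length(extent) == 2, all(extent > 0), cell_size > 0)
  for (fs in fire_specs) {
    stopifnot(!is.null(fs$year), !is.null(fs$centre), !is.null(fs$radius),
              !is.null(fs$severity_frac))
    if (fs$severity_frac < 0 || fs$severity_frac > 1)
      stop("fire severity_frac must be in [0, 1]")
    if (any(fs$centre - fs$radius < 0) || fs$centre[1] + fs$radius > extent[1] ||
        fs$centre[2] + fs$radius > extent[2])
      stop("fire footprint falls outside the landscape extent")
  }
  set.seed(seed)
  nx <- max(2L, floor(extent[1] / cell_size))
  ny <- max(2L, floor(extent[2] / cell_size))
  # rows = y, cols = x; cell centers
  xc <- (seq_len(nx) - 0.5) * cell_size
  yc <- (seq_len(ny) - 0.5) * cell_size

  field <- gauss_smooth(matrix(stats::rnorm(ny * nx), ny, nx),
                        smooth / cell_size)
  f <- (field - mean(field)) / max(stats::sd(field), 1e-12)
  elevation <- elev_range[1] + (f - min(f)) / max(max(f) - min(f), 1e-12) *
    diff(elev_range)

  sfield <- gauss_smooth(matrix(stats::rnorm(ny * nx), ny, nx),
                         smooth / cell_size)
  seral <- matrix(0L, ny, nx)
  if (seral_frac > 0)
    seral[sfield >= stats::quantile(sfield, 1 - seral_frac)] <- 1L

  cy <- matrix(yc, ny, nx)
  cx <- matrix(xc, ny, nx, byrow = TRUE)
  fires <- lapply(fire_specs, function(fs) {
    inside <- which((cx - fs$centre[1])^2 + (cy - fs$centre[2])^2 <= fs$radius^2)
    burn <- matrix(0L, ny, nx)
    n_sev <- round(fs$severity_frac * length(inside))
    if (n_sev > 0)
      burn[sample(inside, n_sev)] <- 1L
    list(year = fs$year, centre = fs$centre, radius = fs$radius,
         severity_frac = fs$severity_frac, burn = burn)
  })

  structure(list(elevation = elevation, seral = seral, fires = fires,
                 cell_size = cell_size, extent = extent, origin = c(0, 0)),
            class = "owl_landscape")
}

#' Cell-center coordinates of a landscape grid
#' @noRd
grid_centers <- function(landscape) {
  cs <- landscape$cell_size
  list(x = (seq_len(ncol(landscape$elevation)) - 0.5) * cs + landscape$origin[1],
       y = (seq_len(nrow(landscape$elevation)) - 0.5) * cs + landscape$origin[2])
}

#' Matrix indices of cells whose center lies within `radius` of `centre`
#' @noRd
cells_in_circle <- function(landscape, centre, radius) {
  g <- grid_centers(landscape)
  ix <- which(abs(g$x - centre[1]) <= radius)
  iy <- which(abs(g$y - centre[2]) <= radius)
  if (!length(ix) || !length(iy)) return(matrix(integer(0), 0, 2))
  sub <- expand.grid(row = iy, col = ix)
  d2 <- (g$x[sub$col] - centre[1])^2 + (g$y[sub$row] - centre[2])^2
  as.matrix(sub[d2 <= radius^2, , drop = FALSE])
}

#' @export
print.owl_landscape <- function(x, ...) {
  cat(sprintf("<owl_landscape> %d x %d cells of %g m (%.1f x %.1f km), %d fire(s)\n",
              nrow(x$elevation), ncol(x$elevation), x$cell_size,
              x$extent[1] / 1000, x$extent[2] / 1000, length(x$fires)))
  invisible(x)
}
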