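## Weekly encounter histories from detection events and deployment records.

N_PERIODS <- 11L # week-long secondary sampling periods, May 7 - July 23

#' Start of the survey season (May 7, 00:00 UTC) for a calendar year
#' @noRd
season_start <- function(season) {
  as.POSIXct(sprintf("%d-05-07 00:00:00", season), tz = "UTC")
}

#' Map a timestamp to its weekly secondary sampling period
#'
#' The survey season is divided into 11 consecutive 1-week secondary
#' sampling periods. Bins are half-open 7-day intervals anchored at
#' May 7 00:00, so the season ends (exclusively) on July 23 00:00; a
#' timestamp outside the season maps to `NA`.
#'
#' @param timestamp POSIXct (UTC) vector.
#' @param season Calendar year of the season.
#' @return Integer period index in `1..11`, or `NA` outside the season.
#' @examples
#' assign_period(as.POSIXct("2022-05-07 00:30", tz = "UTC"), 2022) # 1
#' assign_period(as.POSIXct("2022-05-14 00:00", tz = "UTC"), 2022) # 2
#' @export
assign_period <- function(timestamp, season) {
  k <- floor(as.numeric(difftime(timestamp, season_start(season),
                                 units = "days")) / 7) + 1
  k[k < 1 | k > N_PERIODS] <- NA
  as.integer(k)
}

#' Nocturnal filter: survey hours run from 20:00 to 08:00
#' @noRd
is_nocturnal <- function(timestamp) {
  h <- as.integer(format(timestamp, "%H", tz = "UTC"))
  h >= 20 | h < 8
}

#' Build weekly encounter histories with effort covariates
#'
#' Converts a table of detection events and a table of deployment intervals
#' into one row per sampling-unit-season with weekly detection columns
#' `y1..y11` (0/1/`NA`) and effort columns `e1..e11` (hours the unit
#' recorded in that period). A period with zero recording effort is missing
#' (`NA`): the unit was not surveyed. A partly-covered period keeps its data,
#' with the recorded hours available as a detection covariate. Only
#' nocturnal events (20:00-08:00) count as detections.
#'
#' At `level = "hexagon"` the two ARUs of a hexagon are pooled: detections
#' are unioned and effort hours summed (bounded by 336 h/week), for species
#' whose home range spans the whole hexagon.
#'
#' @param detections Data frame with columns `aru_id`, `timestamp`
#'   (POSIXct UTC), and optionally `species` (filtered by `species` if
#'   given). May have zero rows.
#' @param deployments Data frame with `aru_id`, `season`, `start`, `end`.
#' @param survey An `owl_survey` (supplies the ARU-to-hexagon map and
#'   seasons).
#' @param level `"aru"` or `"hexagon"`.
#' @param species Optional species label to filter `detections`.
#' @return An object of class `owl_history`: data.frame with `unit`,
#'   `hexagon`, `season`, `y1..y11`, `e1..e11`.
#' @export
build_history <- function(detections, deployments, survey,
                          level = c("aru", "hexagon"), species = NULL) {
  level <- match.arg(level)
  if (!is.null(species) && nrow(detections))
    detections <- detections[detections$species == species, , drop = FALSE]
  if (nrow(detections)) {
    unknown <- setdiff(detections$aru_id, survey$arus$aru_id)
    if (length(unknown))
      stop("detection event(s) for unknown ARU: ",
           paste(utils::head(unknown, 3), collapse = ", "))
  }

  aru_hex <- stats::setNames(survey$arus$hex_id, survey$arus$aru_id)
  seasons <- survey$seasons

  # per-ARU-season effort hours per period
  effort_row <- function(aru, yr) {
    dep <- deployments[deployments$aru_id == aru & deployments$season == yr, ,
                       drop = FALSE]
    e <- numeric(N_PERIODS)
    if (nrow(dep)) {
      s0 <- season_start(yr)
      for (k in seq_len(N_PERIODS)) {
        ws <- s0 + (k - 1) * 7 * 86400
        e[k] <- sum(interval_overlap_hours(dep$start, dep$end, ws,
                                           ws + 7 * 86400))
      }
    }
    e
  }

  arus <- survey$arus$aru_id
  eff <- array(0, c(length(arus), length(seasons), N_PERIODS),
               dimnames = list(arus, seasons, NULL))
  for (a in seq_along(arus)) for (s in seq_along(seasons))
    eff[a, s, ] <- effort_row(arus[a], seasons[s])

  det <- array(0L, dim(eff), dimnames = dimnames(eff))
  if (nrow(detections)) {
    detections <- detections[is_nocturnal(detections$timestamp), , drop = FALSE]
    for (i in seq_len(nrow(detections))) {
      yr <- as.integer(format(detections$timestamp[i], "%Y", tz = "UTC"))
      si <- match(yr, seasons)
      if (is.na(si)) next
      k <- assign_period(detections$timestamp[i], yr)
      if (is.na(k)) next
      det[detections$aru_id[i], si, k] <- 1L
    }
  }

  if (level == "hexagon") {
    hexes <- survey$hexagons$hex_id
    eff_h <- array(0, c(length(hexes), length(seasons), N_PERIODS),
                   dimnames = list(hexes, seasons, NULL))
    det_h <- array(0L, dim(eff_h), dimnames = dimnames(eff_h))
    for (h in hexes) {
      members <- arus[aru_hex[arus] == h]
      eff_h[h, , ] <- apply(eff[members, , , drop = FALSE], c(2, 3), sum)
      det_h[h, , ] <- apply(det[members, , , drop = FALSE], c(2, 3), max)
    }
    eff <- eff_h; det <- det_h
    units <- hexes; unit_hex <- stats::setNames(hexes, hexes)
  } else {
    units <- arus; unit_hex <- aru_hex
  }

  rows <- do.call(rbind, lapply(seq_along(seasons), function(s) {
    y <- det[, s, , drop = TRUE]
    e <- eff[, s, , drop = TRUE]
    if (is.null(dim(y))) { y <- matrix(y, 1); e <- matrix(e, 1) }
    y[e == 0] <- NA # no effort: period was not surveyed
    out <- data.frame(unit = units, hexagon = unname(unit_hex[units]),
                      season = seasons[s], stringsAsFactors = FALSE)
    colnames(y) <- paste0("y", seq_len(N_PERIODS))
    colnames(e) <- paste0("e", seq_len(N_PERIODS))
    cbind(out, y, e)
  }))
  rownames(rows) <- NULL
  structure(rows, class = c("owl_history", "data.frame"), level = level)
}

#' Invader detection covariate per hexagon-season
#'
#' A hexagonal cell is coded 1 for a season if the invader (barred owl) was
#' detected at least once that year at either of its ARUs, else 0. For
#' ARU-level analyses the flag is propagated to both ARUs of the hexagon.
#'
#' @param invader_history An `owl_history` for the invader (either level).
#' @param survey An `owl_survey`.
#' @param level Level of the table to produce: `"hexagon"` or `"aru"`.
#' @return Data frame `unit`, `hexagon`, `season`, `invader` (0/1).
#' @export
invader_covariate <- function(invader_history, survey,
                              level = c("hexagon", "aru")) {
  level <- match.arg(level)
  ycols <- paste0("y", seq_len(N_PERIODS))
  det <- rowSums(invader_history[, ycols], na.rm = TRUE) > 0
  agg <- stats::aggregate(det,
                          by = list(hexagon = invader_history$hexagon,
                                    season = invader_history$season),
                          FUN = any)
  names(agg)[3] <- "invader"
  agg$invader <- as.integer(agg$invader)
  units <- if (level == "aru") {
    data.frame(unit = survey$arus$aru_id, hexagon = survey$arus$hex_id,
               stringsAsFactors = FALSE)
  } else {
    data.frame(unit = survey$hexagons$hex_id, hexagon = survey$hexagons$hex_id,
               stringsAsFactors = FALSE)
  }
  out <- merge(merge(units, data.frame(season = survey$seasons)), agg,
               by = c("hexagon", "season"), all.x = TRUE)
  out$invader[is.na(out$invader)] <- 0L
  out[order(out$season, out$unit), c("unit", "hexagon", "season", "invader")]
}
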