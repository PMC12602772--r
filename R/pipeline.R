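## End-to-end orchestration: simulate -> calibrate -> build -> fit ->
## contrast -> niche, from a single config, with per-stage derived seeds
## and plain CSV/JSON artifacts so any stage can be inspected or replaced.

#' Default pipeline configuration
#'
#' All operating constants of the analysis live here: the survey scale
#' (60 hexagons of 400 ha over four seasons by default), fire and removal
#' scenarios, species-to-unit mapping (small-bodied species at ARU level
#' with small home-range buffers; the large species at hexagon level),
#' calibration target (<1% weekly false positives over 84 h), MCMC
#' settings (4 chains of 2600 iterations, half burn-in, 85% credible
#' intervals) and the 15% posterior-overlap rule.
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @param ... Named overrides of the defaults (nested lists are replaced
#'   wholesale).
#' @return A list of class `owl_config`.
#' @export
owl_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    landscape = list(extent = c(36000, 30000), cell_size = 50,
                     seral_frac = 0.45),
    fires = list(
      list(year = 2020, centre = c(9000, 9000), radius = 6000,
           severity_frac = 0.49),
      list(year = 2021, centre = c(26000, 20000), radius = 8000,
           severity_frac = 0.56)),
    n_hex = 60,
    seasons = c(2018, 2021, 2022, 2023),
    removal = list(n = 12, year = 2019, placement = "niche"),
    invader = list(beta = c(-1, -0.3, -0.6, 4.2), p_weekly = 0.5,
                   persist = 0.7, extinct_post_removal = 0.92),
    species = list(
      flammulated = list(buffer_ha = 50, level = "aru"),
      pygmy = list(buffer_ha = 300, level = "aru"),
      great_horned = list(buffer_ha = 700, level = "hexagon")),
    gen_model = "int_tc",
    models = OWL_MODELS,
    calibration = list(target = 0.01, n_hours = 84, n_validation = 200),
    mcmc = list(chains = 4, iters = 2600, burn = 1300, ci = 0.85,
                gof = FALSE, gof_rep = 100),
    overlap_threshold = 0.15,
    resume = FALSE)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  bad <- setdiff(cfg$models, OWL_MODELS)
  if (length(bad))
    stop("unknown model id(s) in config: ", paste(bad, collapse = ", "))
  if (!cfg$removal$placement %in% c("niche", "uniform"))
    stop("removal placement must be 'niche' or 'uniform'")
  structure(cfg, class = c("owl_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with (a subset of) the [owl_config()] fields.
#' @return An `owl_config` with defaults filled in.
#' @export
read_config <- function(path) {
  do.call(owl_config, yaml::read_yaml(path))
}

#' Write a grid layer as plain text with a small JSON header
#'
#' @param grid Numeric matrix.
#' @param path Output path (a `.json` header is written alongside).
#' @param cell_size,origin Grid registration recorded in the header.
#' @export
write_grid <- function(grid, path, cell_size, origin = c(0, 0)) {
  jsonlite::write_json(list(shape = dim(grid), cell_size = cell_size,
                            origin = origin),
                       paste0(path, ".json"), auto_unbox = TRUE)
  utils::write.table(grid, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a grid layer written by [write_grid()]
#' @param path Grid file path.
#' @return Matrix with `cell_size` and `origin` attributes.
#' @export
read_grid <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  stopifnot(all(dim(m) == hdr$shape))
  attr(m, "cell_size") <- hdr$cell_size
  attr(m, "origin") <- hdr$origin
  m
}

#' Simulate the invader's hexagon occupancy, removals, and detections
#' @noRd
simulate_invader <- function(survey, landscape, cfg, seed) {
  set.seed(seed)
  hex_cov <- build_site_covariates(survey, landscape, removals = NULL,
                                   buffer_ha = species_buffer_areas()[["invader"]],
                                   level = "hexagon")
  h1 <- hex_cov[hex_cov$season == survey$seasons[1], ]
  X <- cbind(1, as.numeric(zscore(h1$elevation)),
             as.numeric(zscore(h1$ruggedness)), h1$seral_frac)
  psi <- invlogit(drop(X %*% cfg$invader$beta))
  occ1 <- stats::rbinom(nrow(h1), 1, psi)
  occ_hex <- h1$unit[occ1 == 1]

  n_rem <- min(cfg$removal$n, length(occ_hex))
  rem_hex <- if (cfg$removal$placement == "niche") {
    # removals where the invader actually is: high-seral, flatter cells
    if (n_rem > 0) sample(occ_hex, n_rem) else character(0)
  } else {
    sample(h1$unit, min(cfg$removal$n, nrow(h1)))
  }
  removals <- if (length(rem_hex)) {
    idx <- match(rem_hex, survey$hexagons$hex_id)
    data.frame(x = survey$hexagons$x[idx], y = survey$hexagons$y[idx],
               year = cfg$removal$year, stringsAsFactors = FALSE)
  } else data.frame(x = numeric(0), y = numeric(0), year = integer(0))

  # occupancy over seasons: persistence, with near-certain extinction at
  # removal sites after removals
  occ <- list(); occ[[1]] <- occ_hex
  for (s in seq_along(survey$seasons)[-1]) {
    yr <- survey$seasons[s]
    prev <- occ[[s - 1]]
    keep <- vapply(prev, function(h) {
      p_keep <- if (h %in% rem_hex && yr > cfg$removal$year)
        1 - cfg$invader$extinct_post_removal else cfg$invader$persist
      stats::runif(1) < p_keep
    }, logical(1))
    occ[[s]] <- prev[keep]
  }

  events <- list()
  dep <- survey$deployments
  for (s in seq_along(survey$seasons)) {
    yr <- survey$seasons[s]
    for (h in occ[[s]]) {
      arus <- survey$arus$aru_id[survey$arus$hex_id == h]
      for (a in arus) {
        di <- dep[dep$aru_id == a & dep$season == yr, , drop = FALSE]
        for (j in seq_len(nrow(di))) {
          n_weeks <- max(1, round(as.numeric(difftime(di$end[j], di$start[j],
                                                      units = "days")) / 7))
          for (w in seq_len(n_weeks)) {
            if (stats::runif(1) > cfg$invader$p_weekly) next
            ts <- di$start[j] + (w - 1) * 7 * 86400 +
              stats::runif(1, 0, 6.9 * 86400)
            hh <- as.integer(format(ts, "%H", tz = "UTC"))
            if (!(hh >= 20 || hh < 8)) # shift into the nocturnal window
              ts <- ts + (22 - hh) * 3600
            events[[length(events) + 1]] <- data.frame(
              aru_id = a, timestamp = ts, species = "invader",
              score = round(stats::rbeta(1, 12, 2), 4),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(aru_id = character(0),
               timestamp = as.POSIXct(character(0), tz = "UTC"),
               species = character(0), score = numeric(0))
  list(events = events, removals = removals, occupancy = occ,
       psi = psi, hex_cov = hex_cov)
}

#' Run the full BACI pipeline from a config
#'
#' Executes, in order: synthetic-data simulation (landscape, survey,
#' invader, removals, species detections, score streams), score-threshold
#' calibration, encounter-history and covariate construction, occupancy
#' model fitting for every species and model in the config, pre/post
#' removal posterior contrasts, and the niche segregation analysis. Every
#' stage writes plain CSV/JSON artifacts into `out_dir` and draws its seed
#' deterministically from the master seed, so reruns reproduce byte-equal
#' summaries and individual stages can be resumed (`resume = TRUE` skips
#' stages whose outputs exist).
#'
#' @param config An [owl_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the key in-memory objects (`survey`,
#'   `landscape`, `fits`, `contrasts`, `niche`, paths).
#' @export
run_pipeline <- function(config = owl_config(), out_dir = tempfile("owlrun")) {
  stopifnot(inherits(config, "owl_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf("[owlbaci] %s", sprintf(...)))
  pth <- function(...) file.path(out_dir, ...)
  stage_done <- function(f) config$resume && file.exists(pth(f))

  ## stage 1: simulate ----------------------------------------------------
  log_msg("stage simulate (seed %d)", derive_seed(config$seed, 1))
  landscape <- simulate_landscape(config$landscape$extent,
                                  config$landscape$cell_size,
                                  fire_specs = config$fires,
                                  seral_frac = config$landscape$seral_frac,
                                  seed = derive_seed(config$seed, 1))
  survey <- simulate_survey(landscape, n_hex = config$n_hex,
                            seasons = config$seasons,
                            seed = derive_seed(config$seed, 2))
  inv <- simulate_invader(survey, landscape, config,
                          seed = derive_seed(config$seed, 3))

  truth <- default_truth(config$gen_model)
  species_sims <- lapply(seq_along(config$species), function(i) {
    sp <- names(config$species)[i]
    spec <- config$species[[i]]
    cov <- build_site_covariates(survey, landscape, removals = inv$removals,
                                 buffer_ha = spec$buffer_ha,
                                 level = spec$level)
    sim <- simulate_detections(survey, landscape, truth, config$gen_model,
                               covariates = cov, species = sp,
                               level = spec$level, buffer_ha = spec$buffer_ha,
                               seed = derive_seed(config$seed, 10 + i))
    list(species = sp, covariates = cov, sim = sim)
  })
  names(species_sims) <- names(config$species)

  detections <- do.call(rbind, c(lapply(species_sims, function(s)
    s$sim$events), list(inv$events)))
  if (!stage_done("detections.csv")) {
    utils::write.csv(data.frame(
      aru_id = detections$aru_id,
      timestamp = format(detections$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                         tz = "UTC"),
      species = detections$species, score = detections$score),
      pth("detections.csv"), row.names = FALSE)
    utils::write.csv(data.frame(
      aru_id = survey$deployments$aru_id, season = survey$deployments$season,
      start = format(survey$deployments$start, "%Y-%m-%dT%H:%M:%SZ"),
      end = format(survey$deployments$end, "%Y-%m-%dT%H:%M:%SZ")),
      pth("deployments.csv"), row.names = FALSE)
    utils::write.csv(survey$arus[, c("aru_id", "hex_id", "x", "y")],
                     pth("sites.csv"), row.names = FALSE)
    utils::write.csv(inv$removals, pth("removals.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, gen_model = config$gen_model,
           beta = as.list(truth$beta), sigma_year = truth$sigma_year,
           sigma_site = truth$sigma_site, alpha = as.list(truth$alpha)),
      pth("truth.json"), auto_unbox = TRUE, digits = NA)
    write_grid(landscape$elevation, pth("elevation.txt"),
               landscape$cell_size)
    write_grid(landscape$seral, pth("seral.txt"), landscape$cell_size)
  }

  ## stage 2: calibrate ---------------------------------------------------
  log_msg("stage calibrate")
  profile <- species_profile()
  stream <- simulate_scores(profile,
                            n_hours = config$calibration$n_validation,
                            survey = survey,
                            seed = derive_seed(config$seed, 20))
  cal <- calibrate(stream, target = config$calibration$target,
                   n_hours = config$calibration$n_hours)
  jsonlite::write_json(list(table = cal$table, selected = cal$selected,
                            target = cal$target, n_hours = cal$n_hours),
                       pth("calibration.json"), auto_unbox = TRUE,
                       digits = NA)

  ## stage 3: build -------------------------------------------------------
  log_msg("stage build")
  inv_hist <- build_history(inv$events, survey$deployments, survey,
                            level = "aru", species = "invader")
  builds <- lapply(species_sims, function(ss) {
    spec <- config$species[[ss$species]]
    hist <- build_history(detections, survey$deployments, survey,
                          level = spec$level, species = ss$species)
    invc <- invader_covariate(inv_hist, survey, level = spec$level)
    utils::write.csv(hist, pth(sprintf("history_%s.csv", ss$species)),
                     row.names = FALSE)
    utils::write.csv(ss$covariates,
                     pth(sprintf("covariates_%s.csv", ss$species)),
                     row.names = FALSE)
    list(history = hist, invader = invc)
  })

  ## stage 4: fit ---------------------------------------------------------
  fits <- list()
  for (sp in names(config$species)) {
    for (mid in config$models) {
      log_msg("stage fit: %s / %s", sp, mid)
      design <- build_design(mid, builds[[sp]]$history,
                             species_sims[[sp]]$covariates,
                             invader = builds[[sp]]$invader)
      draws <- sample_posterior(design, chains = config$mcmc$chains,
                                iters = config$mcmc$iters,
                                burn = config$mcmc$burn,
                                seed = derive_seed(config$seed, 30))
      smry <- summary(draws, level = config$mcmc$ci)
      gof <- if (isTRUE(config$mcmc$gof))
        mb_gof(draws, n_rep = config$mcmc$gof_rep,
               seed = derive_seed(config$seed, 40))$p_value else NULL
      fits[[paste(sp, mid, sep = ".")]] <- list(draws = draws,
                                                summary = smry, gof = gof)
      out <- list(species = sp, model = mid, summary = smry)
      if (!is.null(gof)) out$gof_p <- gof
      jsonlite::write_json(out, pth(sprintf("summary_%s_%s.json", sp, mid)),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  }

  ## stage 5: contrast ----------------------------------------------------
  contrasts <- list()
  if (any(c("bo_tc", "bo_td") %in% config$models)) {
    log_msg("stage contrast")
    for (sp in names(config$species)) {
      if ("bo_tc" %in% config$models) {
        ct <- removal_contrast(fits[[paste(sp, "bo_tc", sep = ".")]]$draws,
                               "allpostlethal",
                               threshold = config$overlap_threshold)
        contrasts[[paste0(sp, ".allpostlethal")]] <-
          list(species = sp, effect = "allpostlethal",
               overlap = ct$overlap, meaningful = ct$meaningful)
      }
      if ("bo_td" %in% config$models) {
        for (ef in c("lethal1", "lethal2", "lethal3plus")) {
          ct <- removal_contrast(fits[[paste(sp, "bo_td", sep = ".")]]$draws,
                                 ef, threshold = config$overlap_threshold)
          contrasts[[paste0(sp, ".", ef)]] <-
            list(species = sp, effect = ef, overlap = ct$overlap,
                 meaningful = ct$meaningful)
        }
      }
    }
    jsonlite::write_json(unname(contrasts), pth("contrasts.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## stage 6: niche -------------------------------------------------------
  log_msg("stage niche")
  niche <- niche_analysis(species_sims, builds, inv, survey, config)
  jsonlite::write_json(niche, pth("niche.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(survey = survey, landscape = landscape,
                 calibration = cal, fits = fits, contrasts = contrasts,
                 niche = niche, out_dir = out_dir))
}

#' Niche segregation analysis across species
#' @noRd
niche_analysis <- function(species_sims, builds, inv, survey, config) {
  s1 <- survey$seasons[1]
  # invader conditions: first-season occupied hexagons plus removal cells
  hex1 <- inv$hex_cov[inv$hex_cov$season == s1, ]
  ez <- zscore(hex1$elevation); rz <- zscore(hex1$ruggedness)
  inv_units <- unique(c(inv$occupancy[[1]],
                        survey$hexagons$hex_id[match(
                          paste(inv$removals$x, inv$removals$y),
                          paste(survey$hexagons$x, survey$hexagons$y))]))
  inv_units <- inv_units[!is.na(inv_units)]
  occ_flag <- as.integer(hex1$unit %in% inv_units)

  fit <- fit_occurrence_logistic(occ_flag,
                                 hex1[, c("elevation", "ruggedness",
                                          "seral_frac")])
  ames <- vapply(c("elevation", "ruggedness", "seral_frac"),
                 function(v) average_marginal_effect(fit, v), numeric(1))

  axes <- list(c("elevation", "ruggedness"),
               c("elevation", "seral_frac"),
               c("ruggedness", "seral_frac"))
  std <- data.frame(unit = hex1$unit,
                    elevation = as.numeric(ez),
                    ruggedness = as.numeric(rz),
                    seral_frac = hex1$seral_frac)
  pts_of <- function(units) std[std$unit %in% units, -1, drop = FALSE]
  inv_pts <- pts_of(inv_units)

  per_species <- list()
  for (sp in names(species_sims)) {
    hist <- builds[[sp]]$history
    det1 <- hist[hist$season == s1 &
                   rowSums(hist[, paste0("y", 1:N_PERIODS)], na.rm = TRUE) > 0, ]
    units <- unique(det1$hexagon)
    sp_pts <- pts_of(units)
    pairs <- list()
    for (ax in axes) {
      key <- paste(ax, collapse = "~")
      res <- tryCatch({
        ea <- standard_ellipse(sp_pts[, ax], label = sp)
        eb <- standard_ellipse(inv_pts[, ax], label = "invader")
        ov <- ellipse_overlap(ea, eb)
        list(species_area = ea$area, invader_area = eb$area,
             overlap_fraction = ov$overlap_fraction)
      }, error = function(e) list(error = conditionMessage(e)))
      pairs[[key]] <- res
    }
    per_species[[sp]] <- list(n_detection_sites = length(units),
                              pairs = pairs)
  }
  list(invader = list(coef = as.list(fit$coef), lower = as.list(fit$lower),
                      upper = as.list(fit$upper), flagged = fit$flagged,
                      ame = as.list(ames),
                      n_occurrence_units = length(inv_units)),
       species = per_species)
}
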