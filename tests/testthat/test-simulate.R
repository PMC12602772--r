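test_that("empirical occupancy matches the generating probabilities", {
  # logit-psi = 0 everywhere, no random effects: occupancy 0.5
  tr <- default_truth("fire_tc")
  tr$beta[] <- 0
  tr$sigma_year <- tr$sigma_site <- 0
  sim <- simulate_occupancy_data("fire_tc", truth = tr, n_sites = 1000,
                                 n_seasons = 1, seed = 31)
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(mean(sim$truth$z) - 0.5), 3 * se)

  # fire_tc at (-1, 0.5, -3): burned and unburned groups match closed form
  tr2 <- default_truth("fire_tc")
  tr2$sigma_year <- tr2$sigma_site <- 0
  sim2 <- simulate_occupancy_data("fire_tc", truth = tr2, n_sites = 1000,
                                  n_seasons = 2, seed = 32)
  X <- sim2$design$X_psi
  psi_exp <- plogis(drop(X %*% tr2$beta))
  burned <- X[, "burn"] == 1
  for (grp in list(burned, !burned)) {
    n <- sum(grp)
    mc_se <- sqrt(mean(psi_exp[grp] * (1 - psi_exp[grp])) / n)
    expect_lt(abs(mean(sim2$truth$z[grp]) - mean(psi_exp[grp])), 3 * mc_se)
  }
})

test_that("zero detection probability yields no detections despite occupancy", {
  tr <- default_truth("fire_tc")
  tr$alpha["(Intercept)"] <- -30
  tr$alpha[c("date", "ruggedness", "effort", "invader")] <- 0
  sim <- simulate_occupancy_data("fire_tc", truth = tr, n_sites = 200,
                                 n_seasons = 1, seed = 33)
  expect_gt(sum(sim$truth$z), 0)
  expect_equal(sum(sim$design$y, na.rm = TRUE), 0)
})

test_that("unknown model ids are rejected", {
  expect_error(simulate_occupancy_data("volcano_tc"))
  expect_error(model_psi_terms("volcano_tc"))
})

test_that("weekly detection frequency tracks the detection model", {
  tr <- default_truth("fire_tc")
  tr$beta[] <- c(5, 0, 0) # essentially all sites occupied
  tr$sigma_year <- tr$sigma_site <- 0
  tr$alpha[] <- 0          # p = 0.5 each week
  tr$alpha["(Intercept)"] <- 0
  sim <- simulate_occupancy_data("fire_tc", truth = tr, n_sites = 500,
                                 n_seasons = 1, p_missing = 0, seed = 35)
  y <- sim$design$y
  expect_lt(abs(mean(y, na.rm = TRUE) - 0.5), 3 * sqrt(0.25 / length(y)))
})

test_that("event-level simulation respects deployments and the seed", {
  L <- simulate_landscape(c(14000, 14000), cell_size = 100, seed = 41)
  sv <- simulate_survey(L, n_hex = 4, seasons = c(2021, 2022), seed = 42)
  sim <- simulate_detections(sv, L, model_id = "fire_tc", seed = 43)
  sim_b <- simulate_detections(sv, L, model_id = "fire_tc", seed = 43)
  expect_identical(sim$events, sim_b$events)
  expect_identical(sim$truth, sim_b$truth)

  if (nrow(sim$events)) {
    dep <- sv$deployments
    inside <- vapply(seq_len(nrow(sim$events)), function(i) {
      d <- dep[dep$aru_id == sim$events$aru_id[i], ]
      any(sim$events$timestamp[i] >= d$start &
            sim$events$timestamp[i] <= d$end)
    }, logical(1))
    expect_true(all(inside))
    # events re-binned through the encounter builder match the latent weeks
    h <- build_history(sim$events, sv$deployments, sv, level = "aru")
    y <- as.matrix(h[order(h$season, h$unit), paste0("y", 1:11)])
    expect_true(all((y == 1) <= (sim$weekly == 1), na.rm = TRUE))
  }
})

test_that("score streams respect their generative profile", {
  expect_error(species_profile(true_rate = -1), "non-negative")
  # no true calls: every validated hour is a false-positive hour
  pr0 <- species_profile(true_rate = 0, fp_rate = 8, fp_min = 0.1,
                         fp_max = 0.35)
  st0 <- simulate_scores(pr0, n_hours = 50, seed = 51)
  expect_true(all(st0$hours$label == 0))
  # FP scores bounded above by fp_max: nothing above a higher threshold
  expect_true(all(vapply(st0$scores, max, numeric(1)) <= 0.35))
  expect_equal(sum(vapply(st0$scores, function(s) sum(s >= 0.5),
                          numeric(1))), 0)
  # labels flag hours with at least one planted true call
  pr1 <- species_profile(true_rate = 5, fp_rate = 0.5)
  st1 <- simulate_scores(pr1, n_hours = 50, seed = 52)
  expect_gt(mean(st1$hours$label), 0.9)
  # determinism
  st1b <- simulate_scores(pr1, n_hours = 50, seed = 52)
  expect_identical(st1$hours, st1b$hours)
  expect_identical(st1$scores, st1b$scores)
})
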