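test_that("fire footprints realize the requested high-severity fraction", {
  L <- simulate_landscape(c(12000, 12000), cell_size = 50,
                          fire_specs = list(list(year = 2021,
                                                 centre = c(6000, 6000),
                                                 radius = 3000,
                                                 severity_frac = 0.56)),
                          seed = 4)
  burn <- L$fires[[1]]$burn
  inside <- owlbaci:::cells_in_circle(L, c(6000, 6000), 3000)
  expect_lt(abs(mean(burn[inside]) - 0.56), 0.05)
  # no severe cells outside the footprint
  outside <- burn
  outside[inside] <- 0L
  expect_identical(sum(outside), 0L)

  L0 <- simulate_landscape(c(6000, 6000), cell_size = 50,
                           fire_specs = list(list(year = 2021,
                                                  centre = c(3000, 3000),
                                                  radius = 2000,
                                                  severity_frac = 0)),
                           seed = 4)
  expect_identical(sum(L0$fires[[1]]$burn), 0L)
})

test_that("landscape generation is deterministic and validates footprints", {
  fs <- list(list(year = 2021, centre = c(3000, 3000), radius = 1000,
                  severity_frac = 0.5))
  a <- simulate_landscape(c(6000, 6000), cell_size = 100, fire_specs = fs,
                          seed = 7)
  b <- simulate_landscape(c(6000, 6000), cell_size = 100, fire_specs = fs,
                          seed = 7)
  expect_identical(a$elevation, b$elevation)
  expect_identical(a$fires[[1]]$burn, b$fires[[1]]$burn)
  expect_identical(a$seral, b$seral)

  expect_error(
    simulate_landscape(c(6000, 6000), fire_specs = list(
      list(year = 2021, centre = c(5800, 3000), radius = 1000,
           severity_frac = 0.5))),
    "outside")
})

test_that("survey places non-contiguous hexagons with two spaced ARUs each", {
  L <- simulate_landscape(c(20000, 20000), cell_size = 100, seed = 1)
  sv <- simulate_survey(L, n_hex = 8, seed = 2)
  expect_equal(nrow(sv$hexagons), 8)
  expect_equal(nrow(sv$arus), 16)
  expect_true(all(table(sv$arus$hex_id) == 2))
  # sampled cells share no edges: center spacing exceeds one lattice step
  d <- as.matrix(dist(sv$hexagons[, c("x", "y")]))
  expect_gt(min(d[upper.tri(d)]), sv$hex_spacing * 1.05)
  # ARU spacing within hexagons
  for (h in sv$hexagons$hex_id) {
    a <- sv$arus[sv$arus$hex_id == h, ]
    expect_gte(sqrt(diff(a$x)^2 + diff(a$y)^2), 500)
  }
})

test_that("a single hexagon still gets two ARUs at least 500 m apart", {
  L <- simulate_landscape(c(8000, 8000), cell_size = 100, seed = 1)
  sv <- simulate_survey(L, n_hex = 1, seed = 5)
  a <- sv$arus
  expect_equal(nrow(a), 2)
  expect_gte(sqrt(diff(a$x)^2 + diff(a$y)^2), 500)
})

test_that("deployment plans produce the right intervals", {
  L <- simulate_landscape(c(14000, 14000), cell_size = 100, seed = 1)
  sv <- simulate_survey(L, n_hex = 2, seasons = c(2018, 2021),
                        deployment_plan = c("2018" = "pulse",
                                            "2021" = "continuous"),
                        seed = 2)
  cont <- sv$deployments[sv$deployments$season == 2021 &
                           sv$deployments$aru_id == sv$arus$aru_id[1], ]
  expect_equal(nrow(cont), 1)
  expect_equal(as.numeric(difftime(cont$end, cont$start, units = "days")), 35)

  pulse <- sv$deployments[sv$deployments$season == 2018 &
                            sv$deployments$aru_id == sv$arus$aru_id[1], ]
  pulse <- pulse[order(pulse$start), ]
  expect_equal(nrow(pulse), 3)
  expect_true(all(as.numeric(difftime(pulse$end, pulse$start,
                                      units = "days")) == 7))
  gaps <- as.numeric(difftime(pulse$start[-1], pulse$end[-3], units = "days"))
  expect_true(all(gaps >= 14))
})

test_that("asking for more hexagons than fit is an error", {
  L <- simulate_landscape(c(8000, 8000), cell_size = 100, seed = 1)
  expect_error(simulate_survey(L, n_hex = 500, seed = 1), "non-contiguous")
})
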