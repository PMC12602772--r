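test_that("buffer radius solves area = pi r^2", {
  expect_equal(buffer_radius(50), sqrt(50e4 / pi))
  expect_equal(buffer_radius(50), 398.94, tolerance = 1e-4)
  expect_equal(buffer_radius(2004), 2525.65, tolerance = 1e-4)
  # round trip: a circle of radius 100 m has area pi * 100^2
  expect_equal(buffer_radius(pi * 100^2 / 1e4), 100)
  expect_error(buffer_radius(0), "positive")
})

test_that("ruggedness is zero on flat terrain and exact on a planar slope", {
  flat <- matrix(1500, 100, 100)
  expect_equal(terrain_ruggedness(flat, c(500, 500), cell_size = 10), 0)

  # plane rising s per cell along x: 6 of 8 neighbors differ by s, 2 by 0
  s <- 3.7
  plane <- matrix(rep(s * (1:100), each = 100), 100, 100)
  expect_equal(terrain_ruggedness(plane, c(500, 500), cell_size = 10),
               6 * s / 8)
})

test_that("ruggedness equals the brute-force oracle on a random grid", {
  set.seed(42)
  E <- matrix(rnorm(90 * 90, 1500, 40), 90, 90)
  got <- terrain_ruggedness(E, c(450, 450), radius = 150, cell_size = 10)
  expect_equal(got, oracle_ruggedness(E, 10, c(450, 450), radius = 150))
})

test_that("ruggedness refuses buffers reaching the grid border", {
  E <- matrix(rnorm(40 * 40), 40, 40)
  expect_error(terrain_ruggedness(E, c(30, 200), radius = 390,
                                  cell_size = 10),
               "exceeds")
})

test_that("severe fraction gates on season and counts cell centers", {
  L <- simulate_landscape(c(10000, 10000), cell_size = 50,
                          fire_specs = list(list(year = 2020,
                                                 centre = c(5000, 5000),
                                                 radius = 3000,
                                                 severity_frac = 1)),
                          seed = 3)
  # buffer fully inside an all-severe footprint
  expect_equal(severe_fraction(L, 1, c(5000, 5000), 500, season = 2021),
               c(burn = 1, frac = 1))
  # prefire season
  expect_equal(severe_fraction(L, 1, c(5000, 5000), 500, season = 2020),
               c(burn = 0, frac = 0))
  # partial severity agrees with an explicit cell-counting oracle
  L2 <- simulate_landscape(c(10000, 10000), cell_size = 50,
                           fire_specs = list(list(year = 2020,
                                                  centre = c(5000, 5000),
                                                  radius = 3000,
                                                  severity_frac = 0.4)),
                           seed = 3)
  got <- severe_fraction(L2, 1, c(4600, 5100), 400, season = 2022)
  burn <- L2$fires[[1]]$burn
  hits <- tot <- 0
  for (i in seq_len(nrow(burn))) for (j in seq_len(ncol(burn))) {
    cx <- (j - 0.5) * 50; cy <- (i - 0.5) * 50
    if ((cx - 4600)^2 + (cy - 5100)^2 <= 400^2) {
      tot <- tot + 1; hits <- hits + burn[i, j]
    }
  }
  expect_equal(unname(got["frac"]), hits / tot)
})

test_that("time-since codings follow the BACI definitions", {
  x <- time_since_codings(2022, fire_year = 2021, fraction = 0.6)
  expect_equal(unname(x[c("burn", "allpostburn", "burn1", "burn2", "burn3")]),
               c(1, 0.6, 0.6, 0, 0))

  x <- time_since_codings(2023, removal_year = 2019)
  expect_equal(unname(x[c("allpostlethal", "lethal1", "lethal2",
                          "lethal3plus")]),
               c(1, 0, 0, 1))

  # removal preceding fire: binary interaction at the stated year offset
  x <- time_since_codings(2024, fire_year = 2021, removal_year = 2019,
                          fraction = 0.35)
  expect_equal(unname(x[c("apl_burnyrs", "apl_burn1", "apl_burn2",
                          "apl_burn3")]),
               c(1, 0, 0, 1))

  # removal after the last season: all post fields zero, not an error
  x <- time_since_codings(2022, removal_year = 2025)
  expect_true(all(x == 0))

  # bookkeeping: at most one of burn1..burn3 nonzero, each <= allpostburn
  for (yr in 2021:2026) {
    x <- time_since_codings(yr, fire_year = 2021, fraction = 0.8)
    bk <- x[c("burn1", "burn2", "burn3")]
    expect_lte(sum(bk > 0), 1)
    expect_lte(sum(bk), x[["allpostburn"]])
  }
})

test_that("removal overlap uses strict circle intersection", {
  r_flam <- buffer_radius(50)
  rem <- data.frame(x = 3000, y = 0, year = 2019)
  # 398.9 + 2525.7 = 2924.6 < 3000: no overlap
  expect_equal(removal_overlap(c(0, 0), r_flam, rem)$site_type, 0L)
  # concentric circles overlap
  expect_equal(removal_overlap(c(3000, 0), r_flam, rem)$site_type, 1L)
  # exact tangency counts as non-overlap
  rem2 <- data.frame(x = r_flam + 100, y = 0, year = 2019)
  expect_equal(removal_overlap(c(0, 0), r_flam, rem2,
                               removal_r = 100)$site_type, 0L)
  # earliest overlapping removal year is reported
  rem3 <- data.frame(x = c(0, 10), y = c(0, 0), year = c(2020, 2018))
  expect_equal(removal_overlap(c(0, 0), r_flam, rem3)$removal_year, 2018)
})

test_that("collinearity screening warns at |r| >= 0.6", {
  set.seed(1)
  df <- data.frame(a = rnorm(100))
  df$b <- df$a + rnorm(100, sd = 0.1)  # r ~ 0.99
  df$c <- rnorm(100)
  expect_warning(check_collinearity(df, c("a", "b", "c")), "correlated")
  expect_silent(cm <- check_collinearity(df, c("a", "c")))
  expect_equal(dim(cm), c(2, 2))
})
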