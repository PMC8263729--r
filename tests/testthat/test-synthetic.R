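test_that("generate_landscape respects degenerate and mixed class proportions", {
  cfg <- landscape_config(grid_height = 40, grid_width = 40,
                          class_mix = c(forestland = 1), seed = 1)
  g <- generate_landscape(cfg)
  expect_true(all(g$values == 2L))

  mix <- c(cropland = 0.4, forestland = 0.4, water = 0.1, city_town = 0.1)
  cfg <- landscape_config(grid_height = 256, grid_width = 256,
                          class_mix = mix, seed = 7)
  g <- generate_landscape(cfg)
  prop <- table(factor(g$values, levels = habitat_classes()$code)) /
    length(g$values)
  expect_lt(abs(prop[["1"]] - 0.4), 0.03)
  expect_lt(abs(prop[["2"]] - 0.4), 0.03)
  expect_lt(abs(prop[["9"]] - 0.1), 0.03)
  expect_lt(abs(prop[["12"]] - 0.1), 0.03)
})

test_that("generate_landscape is deterministic and rejects unknown classes", {
  cfg <- landscape_config(grid_height = 48, grid_width = 48, seed = 11)
  expect_identical(generate_landscape(cfg)$values,
                   generate_landscape(cfg)$values)
  expect_error(landscape_config(class_mix = c(lava_field = 1)),
               "unknown land-use classes")
  expect_error(landscape_config(class_mix = c(forestland = 0.6)),
               "sum to 1")
})

test_that("urban cells start as the requested number of connected clusters", {
  cfg <- landscape_config(grid_height = 128, grid_width = 128,
                          n_urban_seeds = 4, seed = 5)
  g <- generate_landscape(cfg)
  urb <- matrix(g$values %in% construction_codes(), 128, 128)
  expect_equal(n_components(urb), 4)
  expect_true(all(g$values %in% habitat_classes()$code))
})

test_that("grow_urban converts the exact cell count and only adds construction", {
  cfg <- landscape_config(grid_height = 100, grid_width = 100,
                          class_mix = c(cropland = 0.45, forestland = 0.45,
                                        city_town = 0.10),
                          n_urban_seeds = 2, seed = 3)
  g <- generate_landscape(cfg)
  constr <- construction_codes()
  n_urb <- sum(g$values %in% constr)
  expect_equal(n_urb, 1000)

  expect_identical(grow_urban(g, 0, seed = 1)$values, g$values)
  g_all <- grow_urban(g, 1, seed = 1)
  expect_true(all(g_all$values %in% constr))

  g2 <- grow_urban(g, 0.1, seed = 2)
  was_urb <- g$values %in% constr
  now_urb <- g2$values %in% constr
  expect_equal(sum(now_urb) - sum(was_urb), round(0.1 * (10000 - n_urb)))
  expect_true(all(now_urb[was_urb]))          # strict superset
  expect_identical(dim(g2$values), dim(g$values))
  expect_error(grow_urban(g, 1.2), "growth_rate")
})

test_that("urban growth is biased toward dense urban neighbourhoods", {
  cfg <- landscape_config(grid_height = 64, grid_width = 64,
                          n_urban_seeds = 2, seed = 8)
  g <- generate_landscape(cfg)
  constr <- construction_codes()
  is_urb <- matrix(g$values %in% constr, 64, 64)
  # neighbourhood urban fraction of each converted vs unconverted cell
  f <- matrix(0, 64, 64)
  for (dr in -1:1) for (dc in -1:1) {
    sh <- matrix(0, 64, 64)
    rs <- max(1, 1 + dr):min(64, 64 + dr); cs <- max(1, 1 + dc):min(64, 64 + dc)
    sh[rs, cs] <- is_urb[rs - dr, cs - dc]
    f <- f + sh
  }
  conv_f <- un_f <- numeric(0)
  for (s in 1:10) {
    g2 <- grow_urban(g, 0.05, compactness = 4, seed = s)
    newly <- (g2$values %in% constr) & !is_urb
    stayed <- !(g2$values %in% constr)
    conv_f <- c(conv_f, mean(f[newly]))
    un_f <- c(un_f, mean(f[stayed]))
  }
  expect_gt(mean(conv_f), mean(un_f))
})

test_that("covariates hit their closed-form extremes and track built-up density", {
  cc0 <- covariate_config(noise_sd = 0)
  g_urb <- uniform_grid(12, 16, 16)
  cov <- generate_covariates(g_urb, cc0)
  expect_equal(max(abs(cov$ntl - cc0$ntl_urban_mean)), 0)
  expect_equal(max(abs(cov$pop - cc0$pop_urban_mean)), 0)

  g_nat <- uniform_grid(2, 16, 16)
  cov <- generate_covariates(g_nat, cc0)
  expect_equal(max(abs(cov$ntl - cc0$ntl_background_mean)), 0)
  expect_equal(max(abs(cov$pop - cc0$pop_background_mean)), 0)

  half <- matrix(2L, 128, 128); half[, 1:64] <- 12L
  g <- land_grid(half)
  cov <- generate_covariates(g, covariate_config(seed = 2))
  expect_gt(cor(as.vector(cov$builtup), as.vector(cov$ntl)), 0.5)
  expect_gt(cor(as.vector(cov$builtup), as.vector(cov$pop)), 0.5)
  expect_true(all(cov$ntl >= 0) && all(cov$pop >= 0))
  expect_error(covariate_config(ntl_urban_mean = 1, ntl_background_mean = 5),
               "urban means")
})

test_that("basin tessellation is complete, connected, merged and deterministic", {
  expect_identical(unique(as.vector(generate_basins(c(20, 20), 1, 0, 30, 1))),
                   1L)
  b1 <- generate_basins(c(60, 60), 25, min_area_km2 = 0.02,
                        cell_size = 30, seed = 4)
  b2 <- generate_basins(c(60, 60), 25, min_area_km2 = 0.02,
                        cell_size = 30, seed = 4)
  expect_identical(b1, b2)
  expect_false(anyNA(b1))
  labs <- sort(unique(as.vector(b1)))
  expect_identical(labs, seq_along(labs))
  for (l in labs) expect_equal(n_components(b1 == l), 1)
  expect_error(generate_basins(c(3, 3), 100, 0, 30, 1), "exceeds cell count")
})

test_that("minimum-area merge leaves no basin below the threshold", {
  # 150 x 150 at 500 m = 5625 km^2; request many basins, merge at 5 km^2
  b <- generate_basins(c(150, 150), 374, min_area_km2 = 5,
                       cell_size = 500, seed = 2)
  areas <- table(b) * (0.5)^2
  expect_true(all(areas >= 5))
  for (l in sort(unique(as.vector(b))))
    expect_equal(n_components(b == l), 1)
})

test_that("resample_grid block-averages and subsamples correctly", {
  m <- matrix(1:16, 4, 4)
  avg <- resample_grid(m, 2, "mean")
  expect_equal(avg, matrix(c(3.5, 5.5, 11.5, 13.5), 2, 2))
  nea <- resample_grid(m, 2, "nearest")
  expect_equal(nea, matrix(c(m[1, 1], m[3, 1], m[1, 3], m[3, 3]), 2, 2))
  up <- resample_grid(m, 2, coarsen = FALSE)
  expect_equal(dim(up), c(8, 8))
  expect_equal(up[1:2, 1:2], matrix(m[1, 1], 2, 2))
})

test_that("ascii grid round-trips values, geometry and nodata", {
  m <- matrix(rnorm(30), 5, 6)
  m[2, 3] <- NA
  f <- tempfile(fileext = ".asc")
  write_asc(round(m, 6), f, cell_size = 30)
  r <- read_asc(f)
  expect_equal(r$values, round(m, 6))
  expect_equal(r$cell_size, 30)
})
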