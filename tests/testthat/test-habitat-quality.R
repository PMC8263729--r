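test_that("decay_factor matches its closed forms and truncates at d_rmax", {
  expect_equal(decay_factor(0, 9, "exponential"), 1.0)
  expect_equal(decay_factor(5, 5, "linear"), 0.0)
  expect_equal(decay_factor(9, 9, "exponential"), exp(-2.99))
  expect_equal(decay_factor(9, 9, "exponential"), 0.0502875, tolerance = 1e-5)
  expect_equal(decay_factor(c(5.0001, 12), 5, "linear"), c(0, 0))
  expect_equal(decay_factor(c(9.0001, 20), 9, "exponential"), c(0, 0))
  d <- seq(0, 10, by = 0.1)
  expect_true(all(diff(decay_factor(d, 6, "linear")) <= 0))
  expect_true(all(diff(decay_factor(d, 6, "exponential")) <= 0))
  expect_true(all(decay_factor(d, 6, "exponential") >= 0 &
                  decay_factor(d, 6, "exponential") <= 1))
  expect_error(decay_factor(-1, 5, "linear"), "negative distance")
})

test_that("threat_presence is the exact indicator of source codes", {
  g <- uniform_grid(1, 6, 6)          # all cropland
  expect_true(all(threat_presence(g, 1L) == 1))
  expect_true(all(threat_presence(g, 12L) == 0))
  chk <- matrix(rep_len(c(1L, 2L), 36), 6, 6)  # checkerboard-ish crop/forest
  g <- land_grid(chk)
  expect_equal(sum(threat_presence(g, 1L)), 18)
  expect_warning(threat_presence(g, 99L), "not in class dictionary")
})

test_that("threat density is kernel-normalized with in-bounds edge handling", {
  ones <- matrix(1, 12, 12)
  d_all <- threat_density(ones, 0.2, "linear", 30)
  expect_equal(max(abs(d_all - 1)), 0, tolerance = 1e-12)  # edges included
  d_none <- threat_density(ones * 0, 0.2, "linear", 30)
  expect_equal(max(abs(d_none)), 0, tolerance = 1e-12)
})

test_that("threat density of a point source matches the brute-force pairwise oracle", {
  for (decay in c("linear", "exponential")) {
    pres <- matrix(0, 21, 21); pres[11, 11] <- 1
    d_rmax <- 0.3; cs <- 30
    got <- threat_density(pres, d_rmax, decay, cs)
    want <- oracle_density(pres, d_rmax, decay, cs)
    expect_lt(max(abs(got - want)), 1e-12)
    # spec'd point value: at distance d_rmax/2 the numerator is decay(d_rmax/2)
    at <- c(11, 11 + round(d_rmax / 2 * 1000 / cs))
    K <- sum(oracle_decay(oracle_pairwise_km(21, 21, cs)[
      (at[2] - 1) * 21 + at[1], ], d_rmax, decay))
    expect_equal(got[at[1], at[2]],
                 decay_factor(d_rmax / 2, d_rmax, decay) / K,
                 tolerance = 1e-12)
  }
})

test_that("degradation matches direct evaluation in engineered cases", {
  sens1 <- data.frame(code = 1L, habitat_type = "cropland", H = 0.4,
                      cropland = 0.8, city_town = 0.5)
  th1 <- data.frame(threat = "cropland", d_rmax_km = 1, weight = 2,
                    decay = "linear", stringsAsFactors = FALSE)
  th1$source_codes <- list(1L)
  g <- uniform_grid(1, 10, 10)

  # single threat, density 1 everywhere, S = 0.8 -> D = 0.8
  D <- compute_degradation(g, th1, sens1)
  expect_equal(max(abs(D$values - 0.8)), 0, tolerance = 1e-12)

  # weight scale-freeness: multiplying all weights leaves D unchanged
  th_scaled <- th1; th_scaled$weight <- th1$weight * 37
  expect_equal(compute_degradation(g, th_scaled, sens1)$values, D$values,
               tolerance = 1e-14)

  # two equal-weight threats with densities 1 and 0 -> D = 0.5 * S_1
  th2 <- data.frame(threat = c("cropland", "city_town"),
                    d_rmax_km = c(1, 1), weight = c(1, 1),
                    decay = c("linear", "linear"), stringsAsFactors = FALSE)
  th2$source_codes <- list(1L, 12L)
  D2 <- compute_degradation(g, th2, sens1)
  expect_equal(max(abs(D2$values - 0.5 * 0.8)), 0, tolerance = 1e-12)

  # no threat cells anywhere -> D = 0
  g_forest <- uniform_grid(2, 10, 10)
  sens_f <- data.frame(code = 2L, habitat_type = "forestland", H = 1,
                       cropland = 0.7, city_town = 0.9)
  expect_equal(max(abs(compute_degradation(g_forest, th2, sens_f)$values)), 0)
  th0 <- th1; th0$weight <- 0
  expect_error(compute_degradation(g, th0, sens1), "weights")
})

test_that("degradation equals the pairwise brute-force oracle on random landscapes", {
  pair_km <- oracle_pairwise_km(24, 24, 30)
  for (i in 1:5) {
    g <- generate_landscape(landscape_config(grid_height = 24,
                                             grid_width = 24, seed = 50 + i))
    got <- compute_degradation(g)$values
    want <- oracle_degradation(g, pair_km = pair_km)
    expect_lt(max(abs(got - want)), 1e-10)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("quality follows the half-saturation closed forms", {
  g <- uniform_grid(2, 4, 4)  # forestland, H = 1.0
  Q0 <- compute_quality(make_degradation(matrix(0, 4, 4)), g)
  expect_equal(max(abs(Q0$values - 1.0)), 0, tolerance = 1e-15)

  Qk <- compute_quality(make_degradation(matrix(0.5, 4, 4)), g, k = 0.5)
  expect_equal(max(abs(Qk$values - 0.5)), 0, tolerance = 1e-15)

  Q1 <- compute_quality(make_degradation(matrix(1, 4, 4)), g, k = 0.5)
  expect_equal(max(abs(Q1$values - 0.2)), 0, tolerance = 1e-12)

  g_water <- uniform_grid(9, 4, 4)  # H = 0.8
  Qw <- compute_quality(make_degradation(matrix(0.8, 4, 4)), g_water, k = 0.8)
  expect_equal(max(abs(Qw$values - 0.4)), 0, tolerance = 1e-12)
  expect_error(compute_quality(make_degradation(matrix(0, 4, 4)), g, k = 0))
})

test_that("quality limits in k agree with theory", {
  g <- uniform_grid(2, 4, 4)
  D <- make_degradation(matrix(0.7, 4, 4))
  expect_equal(compute_quality(D, g, k = 1e8)$values[1, 1], 1, tolerance = 1e-12)
  expect_lt(compute_quality(D, g, k = 1e-8)$values[1, 1], 1e-10)
})

test_that("grading uses half-open five-level thresholds and partitions area", {
  expect_equal(grade_quality(c(0.1, 0.5, 0.85)), c(1L, 3L, 5L))
  expect_equal(grade_quality(0.2), 2L)
  expect_equal(grade_quality(1.0), 5L)
  expect_equal(grade_quality(0.0), 1L)
  expect_error(grade_quality(1.2), "outside")
  q <- matrix(runif(400), 20, 20)
  g <- grade_quality(q)
  expect_true(all(g %in% 1:5))
  expect_equal(sum(table(g)), 400)  # every cell exactly one grade
})

test_that("adding threat cells never lowers D nor raises Q at unchanged cells", {
  set.seed(77)
  threats <- threat_table(); sens <- sensitivity_table()
  nonthreat <- c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L)
  for (i in 1:20) {
    g <- generate_landscape(landscape_config(grid_height = 16, grid_width = 16,
                                             seed = 300 + i))
    cand <- which(matrix(g$values %in% nonthreat, 16, 16))
    if (length(cand) == 0) next
    cell <- sample(cand, 1)
    v2 <- g$values
    v2[cell] <- sample(c(1L, 10L, 11L, 12L, 13L, 14L), 1)
    g2 <- land_grid(v2, cell_size = g$cell_size)
    D1 <- compute_degradation(g, threats, sens)
    D2 <- compute_degradation(g2, threats, sens)
    Q1 <- compute_quality(D1, g, sens)
    Q2 <- compute_quality(D2, g2, sens)
    keep <- seq_along(v2) != cell
    expect_true(all(D2$values[keep] >= D1$values[keep] - 1e-12))
    expect_true(all(Q2$values[keep] <= Q1$values[keep] + 1e-12))
  }
})
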