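make_colony_cells <- function(n, R, seed, intensity_fun) {
  set.seed(seed)
  r <- R * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  x <- r * cos(th); y <- r * sin(th)
  data.frame(well = "W01", x = x + 5000, y = y + 5000,
             ch = intensity_fun(x, y))
}

test_that("a single interior negative patch yields one focus at its centre", {
  # high marker everywhere except a disc of radius 300 um at (400, -200)
  f <- function(x, y) ifelse(sqrt((x - 400)^2 + (y + 200)^2) < 300, 10, 1000)
  cells <- make_colony_cells(4000, 1500, 1, f)
  cs <- assign_colonies(cells, eps = 120, min_samples = 5)
  foci <- detect_foci(cs, "ch", polarity = "negative", min_area = 70000,
                      grid_h = 50)
  pts <- foci[[1]]$points
  expect_equal(nrow(pts), 1L)
  expect_lt(abs(pts$x[1] - 400), 100)
  expect_lt(abs(pts$y[1] + 200), 100)
})

test_that("colonies without sub-threshold cells give an empty pattern, not an error", {
  f <- function(x, y) ifelse(x > 1e9, 1, 1000 + x / 100)  # nothing below Otsu
  cells <- make_colony_cells(2000, 1000, 2, function(x, y) 500 + abs(x) / 10)
  cs <- assign_colonies(cells, eps = 120, min_samples = 5)
  foci <- detect_foci(cs, "ch", min_area = 1e9, grid_h = 50)
  expect_equal(nrow(foci[[1]]$points), 0L)
})

test_that("components touching the peripheral band are not foci", {
  # negative wedge hugging the colony edge
  f <- function(x, y) ifelse(sqrt(x^2 + y^2) > 1300 & x > 0 & abs(y) < 400,
                             10, 1000)
  cells <- make_colony_cells(5000, 1500, 3, f)
  cs <- assign_colonies(cells, eps = 120, min_samples = 5)
  foci <- detect_foci(cs, "ch", min_area = 50000, grid_h = 50)
  expect_equal(nrow(foci[[1]]$points), 0L)
})

test_that("NN distances and entropy behave on degenerate patterns", {
  two <- structure(list(points = data.frame(x = c(0, 120), y = c(0, 0)),
                        radius = 500, source = "observed"),
                   class = "point_pattern")
  nn <- nn_distances(two)
  expect_equal(nn$distances, c(120, 120))
  one <- structure(list(points = data.frame(x = 0, y = 0), radius = 500,
                        source = "observed"), class = "point_pattern")
  expect_error(nn_distances(one), "statistic error")
})

test_that("JSD matches direct evaluation, including the frozen hand example", {
  h <- function(p) structure(list(breaks = 0:4, p = p, counts = p * 100),
                             class = "nn_stats")
  expect_equal(compare_distributions(h(c(.25, .25, .25, .25)),
                                     h(c(.25, .25, .25, .25))), 0)
  expect_equal(compare_distributions(h(c(1, 0, 0, 0)), h(c(0, 0, 0, 1))), 1)
  P <- c(1/2, 1/2, 0, 0); Q <- c(1/4, 1/4, 1/4, 1/4)
  expect_equal(oracle_jsd(P, Q), 0.311278, tolerance = 1e-6)
  expect_equal(compare_distributions(h(P), h(Q)), oracle_jsd(P, Q))
  set.seed(5)
  for (i in 1:10) {
    p <- runif(6); p <- p / sum(p)
    q <- runif(6); q <- q / sum(q)
    expect_equal(compare_distributions(
      structure(list(breaks = 0:6, p = p), class = "nn_stats"),
      structure(list(breaks = 0:6, p = q), class = "nn_stats")),
      oracle_jsd(p, q))
  }
})

test_that("mismatched histogram bins are rejected", {
  a <- structure(list(breaks = 0:4, p = rep(.25, 4)), class = "nn_stats")
  b <- structure(list(breaks = seq(0, 8, 2), p = rep(.25, 4)), class = "nn_stats")
  expect_error(compare_distributions(a, b), "mismatched bins")
})

test_that("the Monte-Carlo test is deterministic and detects periodic alternatives", {
  obs <- generate_point_pattern(pattern_spec("jittered-hex", n_points = 30,
                                             radius = 1500, jitter = 26,
                                             seed = 41))
  t1 <- mc_test(obs, n_null = 199, seed = 7)
  t2 <- mc_test(obs, n_null = 199, seed = 7)
  expect_identical(t1$p_value, t2$p_value)
  expect_lte(t1$p_value, 0.05)

  # a jittered lattice deviates from the exact periodic reference
  lattice <- generate_point_pattern(pattern_spec("jittered-hex", d = 300,
                                                 jitter = 0, radius = 1500,
                                                 seed = 1))
  jit <- generate_point_pattern(pattern_spec("jittered-hex", d = 300,
                                             jitter = 15, radius = 1500,
                                             seed = 2))
  jsd <- compare_distributions(nn_distances(jit), nn_distances(lattice))
  expect_gt(jsd, 0)
})

test_that("NN statistics are scale covariant", {
  obs <- generate_point_pattern(pattern_spec("uniform-random", n_points = 40,
                                             radius = 800, seed = 9))
  s <- 3.5
  scaled <- structure(list(points = obs$points * s, radius = obs$radius * s,
                           source = obs$source), class = "point_pattern")
  nn1 <- nn_distances(obs)
  nn2 <- nn_distances(scaled)
  expect_equal(nn2$distances, s * nn1$distances)
  expect_equal(nn2$p, nn1$p)             # bins scale with the domain radius
  expect_equal(nn2$entropy, nn1$entropy)
  p1 <- mc_test(obs, n_null = 99, seed = 3)$p_value
  p2 <- mc_test(scaled, n_null = 99, seed = 3)$p_value
  expect_identical(p1, p2)
})
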