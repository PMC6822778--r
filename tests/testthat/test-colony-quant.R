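disc_cells <- function(n, cx, cy, R, seed) {
  set.seed(seed)
  r <- R * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}

test_that("well-separated dense discs cluster into colonies with noise flagged", {
  a <- disc_cells(100, 0, 0, 150, 1)
  b <- disc_cells(100, 1000, 0, 150, 2)
  iso <- data.frame(x = c(500, 520, 480, 500, 450),
                    y = c(2000, 2200, 2400, 2600, 2800))
  cells <- cbind(well = "W01", rbind(a, b, iso), ch = 1)
  cs <- assign_colonies(cells, eps = 60, min_samples = 5)
  expect_equal(nrow(cs$colonies), 2L)
  expect_equal(sum(cs$cells$colony == 0L), 5L)
})

test_that("a regular grid with spacing below eps forms a single colony", {
  g <- expand.grid(x = seq(0, 300, 20), y = seq(0, 300, 20))
  cells <- cbind(well = "W01", g, ch = 1)
  cs <- assign_colonies(cells, eps = 25, min_samples = 4)
  expect_equal(nrow(cs$colonies), 1L)
  expect_true(all(cs$cells$colony == 1L))
})

test_that("synthetic plates are recovered with >= 99% label agreement", {
  plate <- default_plate()
  cs <- default_colonies()
  truth <- plate$truth
  # map each detected colony to the dominant true id
  lab <- cs$cells$colony
  agree <- 0L
  for (k in unique(lab[lab > 0])) {
    tt <- truth$colony[lab == k]
    agree <- agree + max(table(tt))
  }
  agree <- agree + sum(lab == 0L & truth$colony == 0L)
  expect_gte(agree / nrow(truth), 0.99)
  expect_equal(nrow(cs$colonies), 12L)
})

test_that("DBSCAN labels match the brute-force construction exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(50:200, 1)
    x <- runif(n, 0, 500); y <- runif(n, 0, 500)
    eps <- runif(1, 30, 80); ms <- sample(3:8, 1)
    got <- dbscan2d_labels(x, y, eps, ms)
    want <- oracle_dbscan(x, y, eps, ms)
    expect_identical(got, want)
  }
})

test_that("colony filtering flags merged colonies and passes nominal ones", {
  plate <- default_plate()
  cs <- filter_colonies(default_colonies(), nominal_diameter = 500)
  expect_true(all(cs$colonies$kept))

  # merged double colony: two overlapping discs -> ~2x count, oversized radius
  a <- disc_cells(400, 0, 0, 250, 3)
  b <- disc_cells(400, 350, 0, 250, 4)
  norm1 <- disc_cells(400, 2000, 0, 250, 5)
  norm2 <- disc_cells(400, 2000, 2000, 250, 6)
  norm3 <- disc_cells(400, 0, 2000, 250, 7)
  cells <- cbind(well = "W01", rbind(a, b, norm1, norm2, norm3), ch = 1)
  cs2 <- assign_colonies(cells, eps = 60, min_samples = 5)
  cs2 <- filter_colonies(cs2, nominal_diameter = 500)
  col <- cs2$colonies
  merged <- which.max(col$n_cells)
  expect_false(col$kept[merged])
  expect_true(all(col$kept[-merged]))
})

test_that("filtering an empty colony set is a no-op", {
  empty <- structure(list(cells = data.frame(), colonies = NULL),
                     class = "colony_set")
  expect_silent(out <- filter_colonies(empty, 500))
  expect_null(out$colonies)
})

test_that("radial profiles reproduce closed-form statistics on constant colonies", {
  one <- cbind(well = "W01", disc_cells(300, 0, 0, 200, 8), ch = 5)
  cs <- assign_colonies(one, eps = 60, min_samples = 5)
  pr <- radial_profile(cs, "ch", n_bins = 6)
  expect_equal(pr$mean, rep(5, 6))
  expect_equal(pr$sd, rep(0, 6))
  expect_equal(pr$n_colonies, rep(1L, 6))

  two <- rbind(cbind(disc_cells(300, 0, 0, 200, 9), ch = 2),
               cbind(disc_cells(300, 1500, 0, 200, 10), ch = 8))
  cs2 <- assign_colonies(cbind(well = "W01", two), eps = 60, min_samples = 5)
  pr2 <- radial_profile(cs2, "ch", n_bins = 5)
  expect_equal(pr2$mean, rep(5, 5))                   # (2 + 8) / 2
  expect_equal(pr2$sd, rep(abs(2 - 8) / sqrt(2), 5))  # two-point SD
  # t-based CI with n = 2 colonies
  expect_equal(pr2$ci95, rep(qt(0.975, 1) * pr2$sd[1] / sqrt(2), 5))
})

test_that("noise-free plates recover the generating profile within 3% per bin", {
  ch <- channel_spec("peripheral-ring", gain = 1000, sigma = 0, background = 0)
  plate <- generate_plate(plate_spec(n_wells = 1, colonies_per_well = 9,
                                     colony_diameter = 500, cell_density = 3000,
                                     off_colony_rate = 0,
                                     channels = list(m = ch), seed = 21))
  cs <- filter_colonies(assign_colonies(plate$cells), 500)
  pr <- radial_profile(cs, "m", n_bins = 8)
  prof_fun <- channel_profile("peripheral-ring")
  # area-weighted mean of the generating profile over each annular bin
  edges <- seq(0, 1, length.out = 9)
  expected <- vapply(seq_len(8), function(k) {
    rr <- seq(edges[k], edges[k + 1], length.out = 2001)
    1000 * sum(prof_fun(rr) * rr) / sum(rr)
  }, numeric(1))
  expect_true(all(abs(pr$mean - expected) / expected < 0.03))
})

test_that("duplicating all cells of one colony leaves the grand mean unchanged", {
  plate <- default_plate()
  cs <- default_colonies()
  pr1 <- radial_profile(cs, "ch1", n_bins = 6)
  dup <- cs$cells[cs$cells$colony == 1L, ]
  cs2 <- cs
  cs2$cells <- rbind(cs$cells, dup)
  cs2$colonies$n_cells[1] <- cs2$colonies$n_cells[1] * 2L
  pr2 <- radial_profile(cs2, "ch1", n_bins = 6)
  expect_equal(pr1$mean, pr2$mean)
})

test_that("rigid motions leave profiles and percent-positive unchanged", {
  plate <- default_plate()
  cells <- plate$cells
  th <- 0.7
  rot <- data.frame(well = cells$well,
                    x = cos(th) * cells$x - sin(th) * cells$y + 5000,
                    y = sin(th) * cells$x + cos(th) * cells$y - 2000,
                    ch1 = cells$ch1)
  cs_a <- assign_colonies(cells, eps = 40, min_samples = 8)
  cs_b <- assign_colonies(rot, eps = 40, min_samples = 8)
  pr_a <- radial_profile(cs_a, "ch1", n_bins = 6)
  pr_b <- radial_profile(cs_b, "ch1", n_bins = 6)
  expect_equal(pr_a$mean, pr_b$mean, tolerance = 1e-9)
  pp_a <- percent_positive(cs_a, "ch1")
  pp_b <- percent_positive(cs_b, "ch1")
  expect_equal(pp_a$pct_positive, pp_b$pct_positive, tolerance = 1e-9)
})

test_that("hexagonal maps: uniform fields, single cells, and radial consistency", {
  one <- cbind(well = "W01", disc_cells(400, 0, 0, 200, 11), ch = 3)
  cs <- assign_colonies(one, eps = 60, min_samples = 5)
  hm <- hex_map(cs, "ch", hex_width = 60)
  expect_true(all(hm$mean == 3))
  expect_true(all(hm$norm == 0))   # degenerate min-max rule

  # a radially symmetric profile re-binned by hexagon-centre radius agrees
  # with the annular profile
  ch <- channel_spec("ramp", gain = 100, sigma = 0, background = 0)
  plate <- generate_plate(plate_spec(n_wells = 1, colonies_per_well = 9,
                                     colony_diameter = 500, cell_density = 4000,
                                     off_colony_rate = 0,
                                     channels = list(m = ch), seed = 22))
  cs2 <- assign_colonies(plate$cells)
  hm2 <- hex_map(cs2, "m", hex_width = 40)
  R <- mean(cs2$colonies$radius)
  rho <- sqrt(hm2$cx^2 + hm2$cy^2) / R
  sel <- rho > 0.2 & rho < 0.9
  expected <- 100 * rho[sel]
  expect_lt(stats::median(abs(hm2$mean[sel] - expected) / expected), 0.05)
})

test_that("a single cell occupies a single hexagon holding its intensity", {
  cells <- data.frame(well = "W01", x = c(0, 1000), y = c(0, 0), ch = c(7, 7))
  # build a degenerate colony set by hand (one colony per cell is unusable;
  # use one colony of two far cells and a huge hexagon width instead)
  cs <- structure(list(
    cells = data.frame(well = "W01", x = 0, y = 0, ch = 7, colony = 1L,
                       rel_x = 0, rel_y = 0),
    colonies = data.frame(well = "W01", colony = 1L, cx = 0, cy = 0,
                          n_cells = 1L, radius = 1, kept = TRUE)),
    class = "colony_set")
  hm <- hex_map(cs, "ch", hex_width = 50)
  expect_equal(nrow(hm), 1L)
  expect_equal(hm$mean, 7)
})

test_that("percent-positive recovers planted fractions and Otsu splits the modes", {
  ch <- channel_spec(positive_fraction = 0.40, gain = 1000, sigma = 0.2,
                     background = 10)
  for (seed in c(31, 32, 33)) {
    plate <- generate_plate(plate_spec(n_wells = 1, colonies_per_well = 6,
                                       colony_diameter = 400,
                                       cell_density = 3000,
                                       off_colony_rate = 0,
                                       channels = list(m = ch), seed = seed))
    cs <- assign_colonies(plate$cells)
    pp <- percent_positive(cs, "m", threshold_method = "otsu")
    expect_true(all(abs(pp$pct_positive - 40) <= 2 * 100 / sqrt(300)))
    expect_true(all(abs(pp$pct_positive - 40) <= 6))
  }
})

test_that("all-below-threshold channels give 0% positive and Otsu matches brute force", {
  cells <- cbind(well = "W01", disc_cells(200, 0, 0, 150, 12), ch = 5)
  cs <- assign_colonies(cells, eps = 60, min_samples = 5)
  pp <- percent_positive(cs, "ch", threshold_method = "fixed", fixed_value = 100)
  expect_true(all(pp$pct_positive == 0))

  set.seed(13)
  bim <- c(rnorm(150, 10, 0.5), rnorm(150, 100, 5))
  expect_equal(otsu_threshold(bim), oracle_otsu(bim))
  expect_gt(otsu_threshold(bim), 15)
  expect_lt(otsu_threshold(bim), 90)
  set.seed(14)
  for (i in 1:5) {
    x <- runif(sample(20:80, 1))
    expect_equal(otsu_threshold(x), oracle_otsu(x))
  }
})

test_that("degenerate channels fall back to the fixed method with a warning", {
  cells <- cbind(well = "W01", disc_cells(200, 0, 0, 150, 15), ch = 4)
  cs <- assign_colonies(cells, eps = 60, min_samples = 5)
  expect_warning(pp <- percent_positive(cs, "ch", threshold_method = "otsu"),
                 "degenerate")
  expect_true(all(pp$pct_positive == 0))
})

test_that("configuration and input errors are raised", {
  cells <- cbind(well = "W01", disc_cells(50, 0, 0, 100, 16), ch = 1)
  expect_error(assign_colonies(cells, eps = -1), "eps")
  expect_error(assign_colonies(cells, min_samples = 1), "min_samples")
  cs <- assign_colonies(cells, eps = 60, min_samples = 5)
  expect_error(radial_profile(cs, "missing_channel"), "not present")
  expect_error(hex_map(cs, "ch", hex_width = 0), "hex_width")
})
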