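test_that("with all dynamics off, uniform fields stay constant", {
  dom <- dom_500()
  p <- rd_params("SB", rho_b = 0, rho_n = 0, k_ex = 0, mu_b = 0, mu_n = 0)
  sim <- simulate_rd(p, dom, T = 5, save_every = 1,
                     init = list(b = 1, n = 1))
  for (f in sim$fields) {
    expect_equal(f$b, rep(1, dom$n_nodes))
    expect_equal(f$n, rep(1, dom$n_nodes))
  }
})

test_that("no-flux diffusion conserves total mass to 1e-6 relative", {
  dom <- dom_500()
  p <- rd_params("SB", rho_b = 0, rho_n = 0, k_ex = 0, mu_b = 0, mu_n = 0)
  set.seed(42)
  b0 <- runif(dom$n_nodes, 0.5, 1.5)
  sim <- simulate_rd(p, dom, T = 10, save_every = 10, init = list(b = b0))
  m0 <- sum(dom$weights * b0)
  m1 <- sum(dom$weights * sim$fields[[2]]$b)
  expect_lt(abs(m1 - m0) / m0, 1e-6)
  # same check on the 2-D grid
  dom2 <- build_domain("grid-2D", 250, 400, 10)
  set.seed(43)
  b0 <- matrix(runif(dom2$n_nodes, 0.5, 1.5), nrow(dom2$mask))
  sim2 <- simulate_rd(p, dom2, T = 5, save_every = 5, init = list(b = b0))
  expect_lt(abs(sum(dom2$weights * sim2$fields[[2]]$b) -
                  sum(dom2$weights * b0)) / sum(dom2$weights * b0), 1e-6)
})

test_that("concentrations stay non-negative for all shipped presets", {
  dom <- dom_500()
  for (preset in c("SB", "nodal", "turing")) {
    sim <- simulate_rd(rd_params(preset), dom, T = 12, save_every = 3)
    for (f in sim$fields) {
      expect_gte(min(f$b), -1e-9)
      expect_gte(min(f$n), -1e-9)
    }
  }
})

test_that("the SB run organises a monotone edge-high gradient whose readout never exceeds b", {
  sim <- sb_sim_24h()
  prof <- readout_radial(sim, n_bins = 10)
  expect_true(all(diff(prof$mean) > 0))          # increases centre -> edge
  f <- sim$fields[[length(sim$fields)]]
  expect_true(all(f$readout <= f$b + 1e-12))
})

test_that("inhibitor knockout raises the centre-to-edge readout ratio", {
  dom <- dom_500()
  wt <- readout_radial(sb_sim_24h(), n_bins = 10)$mean
  ko <- simulate_rd(rd_params("SB", rho_n = 0), dom, T = 24, save_every = 24)
  kop <- readout_radial(ko, n_bins = 10)$mean
  expect_gt(kop[1] / kop[10], wt[1] / wt[10])
})

test_that("halving the grid spacing changes the 24 h profile by < 2% per bin", {
  simc <- simulate_rd(rd_params("SB"), dom_500(2.5), T = 24, save_every = 24)
  p1 <- readout_radial(sb_sim_24h(), n_bins = 10)$mean
  p2 <- readout_radial(simc, n_bins = 10)$mean
  expect_true(all(abs(p1 - p2) / p2 < 0.02))
})

test_that("radial readout averaging matches closed-form annulus means", {
  dom <- dom_500(2.5)
  cfield <- structure(list(readout = rep(3.5, dom$n_nodes)), class = "rd_field")
  pr <- readout_radial(cfield, dom, n_bins = 7)
  expect_equal(pr$mean, rep(3.5, 7))

  # readout(r) = r: the area-weighted mean radius of the annulus [r1, r2]
  # is (2/3) (r2^3 - r1^3) / (r2^2 - r1^2)
  rfield <- structure(list(readout = dom$r), class = "rd_field")
  pr <- readout_radial(rfield, dom, n_bins = 10)
  edges <- seq(0, 250, length.out = 11)
  expected <- (2 / 3) * diff(edges^3) / diff(edges^2)
  expect_equal(pr$mean, expected, tolerance = 0.01)
})

test_that("2-D axisymmetric runs agree with their radial-1D twin within 2%", {
  p <- rd_params("SB")
  sim1 <- simulate_rd(p, dom_500(5), T = 12, save_every = 12, dt = 0.01)
  dom2 <- build_domain("grid-2D", 250, 500, 5)
  sim2 <- simulate_rd(p, dom2, T = 12, save_every = 12, dt = 0.01)
  pr1 <- readout_radial(sim1, n_bins = 8)$mean
  pr2 <- readout_radial(sim2, n_bins = 8)$mean
  expect_true(all(abs(pr1 - pr2) / pr1 < 0.02))
})

test_that("linear stability reports no band at equal diffusivities and errors without autocatalysis", {
  expect_warning(p_eq <- rd_params("turing", D_n = 600), "Turing regime")
  st <- suppressWarnings(linear_stability(p_eq))
  expect_true(is.na(st$lambda_max))
  expect_error(linear_stability(rd_params("turing", rho_b = 0)),
               "no positive steady state")
})

test_that("the default turing preset has a finite fastest-growing wavelength", {
  st <- linear_stability(rd_params("turing"))
  expect_false(is.na(st$lambda_max))
  expect_gt(st$growth_max, 0)
  expect_gt(st$lambda_max, 100)
  expect_lt(st$lambda_max, 2000)
})

test_that("a null Nodal profile reproduces the nodal-off run bit for bit", {
  dom <- dom_500()
  p_on <- rd_params("nodal")
  p_off <- rd_params("nodal", nodal_on = FALSE)
  s_on <- simulate_rd(p_on, dom, nodal_ring(A = 0), T = 6, save_every = 6, seed = 5)
  s_off <- simulate_rd(p_off, dom, nodal_ring(A = 1), T = 6, save_every = 6, seed = 5)
  expect_identical(s_on$fields[[2]]$b, s_off$fields[[2]]$b)
  expect_identical(s_on$fields[[2]]$readout, s_off$fields[[2]]$readout)
})

test_that("the Nodal ring peaks where specified and ramps with the stated closed form", {
  dom <- dom_500()
  S <- nodal_field(nodal_ring(A = 1, r_peak_frac = 0.8, w = 30), dom)
  expect_equal(dom$r[which.max(S)], 0.8 * 250)
  expect_true(all(S[dom$r > 250] == 0))
  Sr <- nodal_field(nodal_ring(A = 2, r_peak_frac = 0.8, w = 30, tau_ramp = 6),
                    dom, t = 6)
  expect_equal(max(Sr), (1 - exp(-1)) * 2, tolerance = 1e-9)
})

test_that("tabulated Nodal profiles must cover the colony and interpolate linearly", {
  dom <- dom_500()
  tab <- data.frame(r = c(0, 125, 250), S = c(0, 1, 0))
  S <- nodal_field(nodal_ring(A = 1, table = tab), dom)
  expect_equal(S[dom$r == 125], 1)
  expect_equal(S[dom$r == 60], 60 / 125)
  bad <- data.frame(r = c(0, 100), S = c(0, 1))
  expect_error(nodal_field(nodal_ring(table = bad), dom), "cover")
})

test_that("runaway reactions raise an integration error naming the step", {
  dom <- dom_500()
  p <- rd_params("SB", rho_b = 1e7, rho_n = 0, n0 = 1e-6, kappa = 0,
                 mu_b = 0, k_ex = 1)
  expect_error(simulate_rd(p, dom, T = 5, save_every = 5),
               "integration error.*step")
})

test_that("simulations are deterministic given the seed", {
  dom <- dom_500()
  a <- simulate_rd(rd_params("turing"), dom, T = 3, save_every = 3, seed = 7)
  b <- simulate_rd(rd_params("turing"), dom, T = 3, save_every = 3, seed = 7)
  c <- simulate_rd(rd_params("turing"), dom, T = 3, save_every = 3, seed = 8)
  expect_identical(a$fields[[2]]$b, b$fields[[2]]$b)
  expect_false(identical(a$fields[[2]]$b, c$fields[[2]]$b))
})
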