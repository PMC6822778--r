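# Shared, lazily computed fixtures. The heavier simulations are memoised so
# the whole suite pays for each once.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# 500 um radial-1D domain used across RD tests
dom_500 <- function(h = 5) build_domain("radial-1D", 250, 500, h)

sb_sim_24h <- function() memo("sb24", {
  simulate_rd(rd_params("SB"), dom_500(), T = 24, save_every = 2, seed = 1)
})

# 3 mm grid-2D Turing run shared by the foci analyses
turing_sim_3mm <- function() memo("turing3mm", {
  dom <- build_domain("grid-2D", 1500, 3000, 25)
  simulate_rd(rd_params("turing"), dom, T = 72, save_every = 8, seed = 1)
})

# 500 um grid-2D run at the turing parameters
turing_sim_500 <- function() memo("turing500", {
  dom <- build_domain("grid-2D", 250, 500, 10)
  simulate_rd(rd_params("turing"), dom, T = 72, save_every = 8, seed = 1)
})

# default synthetic plate (12 colonies, one well)
default_plate <- function() memo("plate12", {
  generate_plate(plate_spec(n_wells = 1, colonies_per_well = 12,
                            colony_diameter = 500, cell_density = 2500,
                            seed = 11))
})

default_colonies <- function() memo("colonies12", {
  assign_colonies(default_plate()$cells)
})
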