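#' Load a simulation run configuration from YAML
#'
#' Reads a YAML file describing one reaction-diffusion run - parameter
#' overrides, domain geometry, Nodal profile and schedule - and returns the
#' assembled objects ready for [simulate_rd()].
#'
#' Recognised top-level keys: `preset` (default `"SB"`), `params` (named
#' overrides of [rd_params()] fields), `domain` (`kind`, `R_colony`,
#' `R_domain`, `h`), `nodal` (`A`, `r_peak_frac`, `w`, `tau_ramp`), and
#' `run` (`T`, `save_every`, `seed`).
#'
#' @param path path to a YAML file.
#' @return A list with elements `params`, `domain`, `nodal` and `run`.
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c("preset: SB",
#'              "domain: {kind: radial-1D, R_colony: 250, h: 5}",
#'              "run: {T: 24, save_every: 6, seed: 1}"), cfg_file)
#' cfg <- read_run_config(cfg_file)
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  preset <- cfg$preset %||% "SB"
  params <- do.call(rd_params, c(list(preset = preset), cfg$params))
  dom_args <- cfg$domain %||% list()
  dom_args$kind <- dom_args$kind %||% "radial-1D"
  dom_args$R_colony <- dom_args$R_colony %||% 250
  dom_args$h <- dom_args$h %||% (dom_args$R_colony / 50)
  domain <- do.call(build_domain, dom_args)
  nodal <- do.call(nodal_ring, cfg$nodal %||% list())
  run <- cfg$run %||% list()
  run$T <- run$T %||% 24
  run$save_every <- run$save_every %||% run$T
  run$seed <- run$seed %||% 1L
  list(params = params, domain = domain, nodal = nodal, run = run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
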