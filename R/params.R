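#' Reaction-diffusion model parameters
#'
#' Assembles and validates the parameter set of the activator-inhibitor model.
#' The activator `b` stands for extracellular BMP4 read out as pSMAD1 activity;
#' the inhibitor `n` is the pooled secreted-antagonist species (Noggin together
#' with the Nodal-pathway antagonists CER1/GDF3/FST treated as one "BMPi" pool).
#'
#' The reaction terms are
#' \deqn{f(b, n) = \rho_b b^2 / ((n_0 + n)(1 + \kappa b^2)),\qquad
#'       g(b) = \rho_n b^q,}
#' the classical saturating activator-inhibitor (Gierer-Meinhardt) form with a
#' basal inhibitor offset `n0` (which also keeps the Noggin-knockout run,
#' `rho_n = 0`, finite). Exogenous ligand enters as well-mixed bath exchange
#' `k_ex * (c_dose - b)` over the whole domain, because the experiments vary a
#' medium concentration, not an initial condition.
#'
#' Three named presets encode the study conditions:
#' \describe{
#'   \item{`"SB"`}{Nodal signalling blocked (SB431542). Strong bath exchange,
#'     first-order inhibitor induction (`q = 1`): a linearly stable regime
#'     whose inhibitor escape across the colony edge organises the gradual
#'     edge-high pSMAD1 gradient.}
#'   \item{`"nodal"`}{the SB kinetics plus an active Nodal-derived inhibition
#'     ring (`nodal_on = TRUE`, `lambda_s = 2`); reshapes the gradient into a
#'     sharp peripheral peak plus a second interior peak.}
#'   \item{`"turing"`}{weak bath exchange and quadratic inhibitor induction
#'     (`q = 2`): Turing-unstable at high dose, used for multi-foci patterns in
#'     large (3 mm) colonies. Models the serum-replacement-free medium in which
#'     periodic foci are observed.}
#' }
#'
#' @param preset `"SB"`, `"nodal"` or `"turing"`; starting values that can be
#'   overridden by the named arguments.
#' @param D_b,D_n activator / inhibitor diffusivity (um^2/h).
#' @param rho_b activator autocatalysis rate (1/h).
#' @param rho_n inhibitor production rate (1/h).
#' @param mu_b,mu_n first-order decay rates (1/h).
#' @param kappa activator saturation constant (1/concentration^2).
#' @param k_ex bath-exchange rate (1/h).
#' @param c_dose bath BMP4 concentration (a.u., numerically equal to ng/ml).
#' @param lambda_s Nodal-inhibition coupling strength (dimensionless).
#' @param nodal_on logical; when `FALSE` the Nodal profile is ignored.
#' @param n0 basal inhibitor offset (a.u.); also the initial inhibitor level.
#' @param q inhibitor-induction exponent (1 or 2).
#' @return A validated list of class `rd_params`.
#' @examples
#' p <- rd_params("SB", c_dose = 25)
#' p$D_n / p$D_b   # inhibitor must outrun activator
#' @export
rd_params <- function(preset = c("SB", "nodal", "turing"),
                      D_b = NULL, D_n = NULL, rho_b = NULL, rho_n = NULL,
                      mu_b = NULL, mu_n = NULL, kappa = NULL, k_ex = NULL,
                      c_dose = NULL, lambda_s = NULL, nodal_on = NULL,
                      n0 = NULL, q = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    SB = list(D_b = 15, D_n = 60000, rho_b = 0.6, rho_n = 1, mu_b = 2,
              mu_n = 2, kappa = 1e-3, k_ex = 0.5, c_dose = 25, lambda_s = 0,
              nodal_on = FALSE, n0 = 3, q = 1),
    nodal = list(D_b = 15, D_n = 60000, rho_b = 0.6, rho_n = 1, mu_b = 2,
                 mu_n = 2, kappa = 1e-3, k_ex = 0.5, c_dose = 25, lambda_s = 2,
                 nodal_on = TRUE, n0 = 3, q = 1),
    turing = list(D_b = 600, D_n = 150000, rho_b = 8, rho_n = 1, mu_b = 1.5,
                  mu_n = 2, kappa = 1e-4, k_ex = 0.01, c_dose = 200,
                  lambda_s = 0, nodal_on = FALSE, n0 = 0.5, q = 2))
  ovr <- list(D_b = D_b, D_n = D_n, rho_b = rho_b, rho_n = rho_n, mu_b = mu_b,
              mu_n = mu_n, kappa = kappa, k_ex = k_ex, c_dose = c_dose,
              lambda_s = lambda_s, nodal_on = nodal_on, n0 = n0, q = q)
  for (nm in names(ovr)) if (!is.null(ovr[[nm]])) base[[nm]] <- ovr[[nm]]
  base$preset <- preset
  validate_rd_params(base)
}

validate_rd_params <- function(p) {
  num <- c("D_b", "D_n", "rho_b", "rho_n", "mu_b", "mu_n", "kappa", "k_ex",
           "c_dose", "lambda_s", "n0")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter ", nm, " must be a single finite number")
    if (v < 0) stop("parameter ", nm, " must be >= 0")
  }
  if (!is.logical(p$nodal_on) || length(p$nodal_on) != 1L)
    stop("nodal_on must be TRUE or FALSE")
  if (!p$q %in% c(1, 2))
    stop("inhibitor-induction exponent q must be 1 or 2")
  if (p$D_b > 0 && p$D_n / p$D_b <= 1)
    warning("D_n/D_b <= 1: outside the classical Turing regime ",
            "(inhibitor must diffuse faster than activator)")
  class(p) <- "rd_params"
  p
}

#' @export
print.rd_params <- function(x, ...) {
  cat(sprintf("<rd_params> preset '%s'%s\n", x$preset,
              if (x$nodal_on) " (Nodal inhibition on)" else ""))
  cat(sprintf("  D_b=%g D_n=%g um^2/h | rho_b=%g rho_n=%g (q=%d) | mu_b=%g mu_n=%g 1/h\n",
              x$D_b, x$D_n, x$rho_b, x$rho_n, as.integer(x$q), x$mu_b, x$mu_n))
  cat(sprintf("  kappa=%g n0=%g | k_ex=%g 1/h, c_dose=%g a.u. | lambda_s=%g\n",
              x$kappa, x$n0, x$k_ex, x$c_dose, x$lambda_s))
  invisible(x)
}

#' Nodal-derived inhibition ring
#'
#' Parametric description of the spatial profile of Nodal-signalling-mediated
#' inhibition of BMP, modelled after the interior SMAD2 ring observed at 24 h:
#' a Gaussian ring of amplitude `A` centred at `r_peak_frac * R_colony` with
#' width `w`, optionally ramped in over time,
#' \deqn{S(r, t) = \mathrm{ramp}(t)\, A \exp(-(r - r_\mathrm{peak})^2 / 2w^2)}
#' with `ramp(t) = 1 - exp(-t / tau_ramp)` (identically 1 when
#' `tau_ramp = 0`, the static default). A tabulated radial profile can be
#' supplied instead and is interpolated linearly.
#'
#' @param A amplitude (a.u.); `A = 0` gives the null profile.
#' @param r_peak_frac ring position as a fraction of the colony radius, in
#'   \[0, 1\].
#' @param w ring width (micrometres), > 0.
#' @param tau_ramp ramp-in time constant (hours); 0 = static.
#' @param table optional `data.frame(r, S)` overriding the parametric form;
#'   must cover `[0, R_colony]`.
#' @return An object of class `nodal_profile`.
#' @examples
#' np <- nodal_ring(A = 1, r_peak_frac = 0.72, w = 30)
#' @export
nodal_ring <- function(A = 1, r_peak_frac = 0.72, w = 30, tau_ramp = 0,
                       table = NULL) {
  if (!is.numeric(A) || A < 0) stop("A must be >= 0")
  if (r_peak_frac < 0 || r_peak_frac > 1)
    stop("r_peak_frac must lie in [0, 1]")
  if (w <= 0) stop("w must be > 0")
  if (tau_ramp < 0) stop("tau_ramp must be >= 0")
  if (!is.null(table)) {
    if (!is.data.frame(table) || !all(c("r", "S") %in% names(table)))
      stop("table must be a data.frame with columns r and S")
    if (any(table$S < 0)) stop("tabulated S values must be >= 0")
    table <- table[order(table$r), ]
  }
  structure(list(A = A, r_peak_frac = r_peak_frac, w = w,
                 tau_ramp = tau_ramp, table = table),
            class = "nodal_profile")
}

#' Evaluate the Nodal inhibition field on a domain
#'
#' @param spec a [nodal_ring()] profile.
#' @param domain an [build_domain()] object.
#' @param t time (hours) at which to evaluate the ramp.
#' @return The inhibition field `S(r, t)` with the shape of the domain grid
#'   (vector for radial-1D, matrix for grid-2D); zero outside the colony.
#' @examples
#' dom <- build_domain("radial-1D", 250, 500, 5)
#' S <- nodal_field(nodal_ring(A = 1), dom, t = 24)
#' @export
nodal_field <- function(spec, domain, t = Inf) {
  stopifnot(inherits(spec, "nodal_profile"), inherits(domain, "rd_domain"))
  r <- domain_radii(domain)
  Rc <- domain$R_colony
  if (is.null(spec$table)) {
    S <- spec$A * exp(-(r - spec$r_peak_frac * Rc)^2 / (2 * spec$w^2))
  } else {
    tab <- spec$table
    if (min(tab$r) > 0 || max(tab$r) < Rc)
      stop("tabulated Nodal profile must cover [0, R_colony] ",
           "(covers [", min(tab$r), ", ", max(tab$r), "], R_colony = ", Rc, ")")
    S <- stats::approx(tab$r, tab$S, xout = pmin(r, Rc), rule = 2)$y
    S[] <- S * spec$A
  }
  S[r > Rc] <- 0
  S * nodal_ramp(spec, t)
}

nodal_ramp <- function(spec, t) {
  if (spec$tau_ramp == 0) 1 else 1 - exp(-t / spec$tau_ramp)
}
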