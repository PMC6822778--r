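# Reaction-diffusion core: operator-split integrator (implicit diffusion,
# explicit reactions) on radial-1D and grid-2D colony domains.

# finite-volume radial laplacian (1/r d/dr (r d/dr)), symmetry at r = 0,
# no-flux at R_domain; conserves sum(w * u) exactly
radial_laplacian <- function(n, h) {
  L <- matrix(0, n + 1L, n + 1L)
  L[1, 1] <- -4 / h^2
  L[1, 2] <- 4 / h^2
  for (i in 1:n) {
    ri <- i * h
    rp <- if (i < n) ri + h / 2 else 0
    rm <- ri - h / 2
    vol <- if (i < n) ri * h^2 else ri * h^2 / 2   # boundary cell is a half cell
    L[i + 1L, i + 1L] <- -(rp + rm) / vol
    if (i < n) L[i + 1L, i + 2L] <- rp / vol
    L[i + 1L, i] <- rm / vol
  }
  L
}

# 1D cartesian laplacian with no-flux ends (used directionally by the 2D ADI)
cartesian_laplacian <- function(n, h) {
  L <- matrix(0, n + 1L, n + 1L)
  # end cells are half cells, so the single interface flux acts on volume h/2
  L[1, 1] <- -2 / h^2; L[1, 2] <- 2 / h^2
  L[n + 1L, n + 1L] <- -2 / h^2; L[n + 1L, n] <- 2 / h^2
  for (i in 2:n) {
    L[i, i] <- -2 / h^2
    L[i, i - 1L] <- 1 / h^2
    L[i, i + 1L] <- 1 / h^2
  }
  L
}

#' Simulate the confined activator-inhibitor system
#'
#' Integrates
#' \deqn{\partial_t b = D_b \nabla^2 b + m(x) f(b,n) - \mu_b b
#'       - \lambda_s S(r,t)\, b + k_\mathrm{ex}(c_\mathrm{dose} - b)}
#' \deqn{\partial_t n = D_n \nabla^2 n + m(x) g(b) - \mu_n n}
#' with `m` the colony mask, `f`, `g` the kinetics described in [rd_params()],
#' and `S` the Nodal inhibition field (zero when `nodal_on` is `FALSE`).
#' The pSMAD1-like readout is `b / (1 + lambda_s * S)`.
#'
#' Time stepping is operator splitting: implicit (backward-Euler) diffusion,
#' factored by direction in 2D, which is unconditionally stable and
#' positivity-preserving at the large inhibitor diffusivities, and explicit
#' reactions whose sub-step adapts so
#' that `dt * max|df/db| < 0.2`. Initial conditions are `b = 0` and
#' `n = n0 * (1 + 1% uniform noise)`; the seed only perturbs this noise, which
#' is required to break symmetry for Turing foci.
#'
#' @param params an [rd_params()] object.
#' @param domain an [build_domain()] object.
#' @param nodal a [nodal_ring()] profile (used only when `params$nodal_on`).
#' @param T total simulated time (hours), > 0.
#' @param save_every interval between saved fields (hours); fields are saved
#'   at `t = 0, save_every, ..., T`.
#' @param seed integer seed for the initial-condition noise.
#' @param dt outer time step (hours); default `min(save_every, 0.05)`.
#' @param init optional list with elements `b` and/or `n` overriding the
#'   default initial conditions (shapes must match the domain grid).
#' @return An object of class `rd_sim`: a list with `times`, `fields` (each an
#'   `rd_field` with elements `t`, `b`, `n`, `readout`), and the inputs.
#' @examples
#' dom <- build_domain("radial-1D", 250, 500, 5)
#' sim <- simulate_rd(rd_params("SB"), dom, T = 4, save_every = 2)
#' sim
#' @export
simulate_rd <- function(params, domain, nodal = nodal_ring(), T, save_every = T,
                        seed = 1L, dt = NULL, init = NULL) {
  stopifnot(inherits(params, "rd_params"), inherits(domain, "rd_domain"),
            inherits(nodal, "nodal_profile"))
  if (!is.numeric(T) || T <= 0) stop("T must be > 0")
  if (save_every <= 0 || save_every > T) stop("save_every must lie in (0, T]")
  if (is.null(dt)) dt <- min(save_every, 0.05)

  p <- params
  two_d <- domain$kind == "grid-2D"
  mask <- domain$mask
  # production acts on the cell-covered support with sub-cell area accuracy
  prod_w <- if (is.null(domain$coverage)) mask else domain$coverage
  S <- if (p$nodal_on) nodal_field(nodal, domain, t = Inf) else
    (if (two_d) matrix(0, nrow(mask), ncol(mask)) else numeric(length(mask)))
  ramped <- p$nodal_on && nodal$tau_ramp > 0

  n_side <- if (two_d) length(domain$x) - 1L else domain$n_nodes - 1L
  L <- if (two_d) cartesian_laplacian(n_side, domain$h)
       else radial_laplacian(n_side, domain$h)
  I <- diag(n_side + 1L)
  # precomputed diffusion operators per species: backward Euler (factored by
  # direction in 2D). Each factor is inverse-positive, so the diffusion step
  # preserves positivity even at the very large inhibitor diffusivities,
  # where trapezoidal schemes ring at the colony-mask discontinuity.
  cn <- function(D) list(Ainv = solve(I - dt * D * L))
  opb <- cn(p$D_b); opn <- cn(p$D_n)
  diffuse <- if (two_d) {
    function(u, op) {
      u1 <- op$Ainv %*% u            # implicit in x
      t(op$Ainv %*% t(u1))           # implicit in y
    }
  } else {
    function(u, op) as.numeric(op$Ainv %*% u)
  }

  set.seed(seed)
  b <- mask * 0
  n <- p$n0 * (1 + 0.01 * (if (two_d)
    matrix(stats::runif(length(mask), -1, 1), nrow(mask))
    else stats::runif(length(mask), -1, 1)))
  if (!is.null(init)) {
    if (!is.null(init$b)) b <- mask * 0 + init$b
    if (!is.null(init$n)) n <- mask * 0 + init$n
  }

  n_steps <- ceiling(T / dt - 1e-9)
  save_idx <- unique(round(seq(0, T, by = save_every) / dt))
  fields <- vector("list", length(save_idx))
  times <- numeric(length(save_idx))
  k_save <- 1L

  store <- function(step) {
    t_now <- step * dt
    Sr <- if (ramped) S * nodal_ramp(nodal, t_now) else S
    ro <- b / (1 + p$lambda_s * Sr)
    f <- list(t = t_now, b = b, n = n, readout = ro)
    class(f) <- "rd_field"
    f
  }
  if (0L %in% save_idx) {
    fields[[k_save]] <- store(0L); times[k_save] <- 0; k_save <- k_save + 1L
  }

  for (step in seq_len(n_steps)) {
    t_now <- (step - 1L) * dt
    Sr <- if (ramped) S * nodal_ramp(nodal, t_now) else S
    # explicit reactions, sub-cycled to honour the slope bound
    slope <- max(2 * p$rho_b * b / (pmax(p$n0 + n, 1e-12) *
                                      (1 + p$kappa * b^2)^2),
                 p$mu_n, p$mu_b + p$k_ex + p$lambda_s * max(Sr))
    m_sub <- max(1L, ceiling(dt * slope / 0.2))
    if (m_sub > 1000L)
      stop("integration error: reaction terms too stiff (blow-up) at step ",
           step, " (t = ", format((step - 1L) * dt), " h)")
    dts <- dt / m_sub
    for (j in seq_len(m_sub)) {
      fb <- p$rho_b * b^2 / (pmax(p$n0 + n, 1e-12) * (1 + p$kappa * b^2))
      gb <- p$rho_n * b^p$q
      b <- b + dts * (prod_w * fb - p$mu_b * b - p$lambda_s * Sr * b +
                        p$k_ex * (p$c_dose - b))
      n <- n + dts * (prod_w * gb - p$mu_n * n)
    }
    b <- diffuse(b, opb)
    n <- diffuse(n, opn)
    if (any(!is.finite(b)) || any(!is.finite(n)))
      stop("integration error: non-finite concentration at step ", step,
           " (t = ", format(step * dt), " h)")
    # tiny round-off negatives are clamped; anything beyond a relative
    # tolerance signals numerical instability
    neg_tol <- 0.05 * max(1, max(b), max(n))
    if (min(b) < -neg_tol || min(n) < -neg_tol)
      stop("integration error: negative concentration beyond tolerance at step ",
           step, " (t = ", format(step * dt), " h)")
    b[b < 0] <- 0
    n[n < 0] <- 0
    if (step %in% save_idx) {
      fields[[k_save]] <- store(step)
      times[k_save] <- step * dt
      k_save <- k_save + 1L
    }
  }
  structure(list(times = times, fields = fields, params = params,
                 domain = domain, nodal = nodal, seed = seed, dt = dt),
            class = "rd_sim")
}

#' @export
print.rd_sim <- function(x, ...) {
  d <- x$domain
  cat(sprintf("<rd_sim> preset '%s', %s colony R = %g um, dose %g a.u.\n",
              x$params$preset, d$kind, d$R_colony, x$params$c_dose))
  cat(sprintf("  %d saved fields over t = %g..%g h (dt = %g h)\n",
              length(x$fields), min(x$times), max(x$times), x$dt))
  last <- x$fields[[length(x$fields)]]
  cat(sprintf("  final readout range: %.3g .. %.3g a.u.\n",
              min(last$readout), max(last$readout)))
  invisible(x)
}

#' @export
plot.rd_sim <- function(x, n_bins = 10, ...) {
  prof <- readout_radial(x, n_bins = n_bins)
  graphics::plot(prof$r_mid, prof$mean, type = "b", xlab = "r / R_colony",
                 ylab = "mean readout (a.u.)",
                 main = sprintf("radial readout at t = %g h", max(x$times)), ...)
  invisible(prof)
}

#' Area-weighted radial readout profile
#'
#' Averages the pSMAD1-like readout over equal-width annuli of the colony,
#' weighting each grid node by its finite-volume area, and reports the profile
#' against normalised radius `r / R_colony`.
#'
#' @param field an `rd_field` (one saved time point) or an `rd_sim`
#'   (its last saved field is used).
#' @param domain the simulation domain; taken from the `rd_sim` if omitted.
#' @param n_bins number of annuli (>= 2).
#' @return `data.frame(bin, r_lo, r_hi, r_mid, mean)` in normalised radius.
#' @examples
#' dom <- build_domain("radial-1D", 250, 500, 5)
#' sim <- simulate_rd(rd_params("SB"), dom, T = 4)
#' readout_radial(sim, n_bins = 8)
#' @export
readout_radial <- function(field, domain = NULL, n_bins = 10) {
  if (inherits(field, "rd_sim")) {
    if (is.null(domain)) domain <- field$domain
    field <- field$fields[[length(field$fields)]]
  }
  stopifnot(inherits(domain, "rd_domain"))
  if (n_bins < 2) stop("n_bins must be >= 2")
  r <- domain_radii(domain)
  # average over fully cell-covered nodes: the straddling rim cell represents
  # a half-outside average and would dilute the outermost annulus
  inside <- if (!is.null(domain$coverage)) domain$coverage >= 1 - 1e-9
            else r <= domain$R_colony
  rho <- pmin(r[inside] / domain$R_colony, 1 - 1e-12)
  v <- field$readout[inside]
  w <- domain$weights[inside]
  bin <- pmin(floor(rho * n_bins), n_bins - 1L) + 1L
  means <- vapply(seq_len(n_bins), function(k) {
    sel <- bin == k
    if (!any(sel)) return(NA_real_)
    sum(v[sel] * w[sel]) / sum(w[sel])
  }, numeric(1))
  edges <- seq(0, 1, length.out = n_bins + 1L)
  data.frame(bin = seq_len(n_bins), r_lo = edges[-(n_bins + 1L)],
             r_hi = edges[-1L],
             r_mid = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
             mean = means)
}

#' Linear stability (Turing) analysis of the homogeneous system
#'
#' Finds the positive homogeneous steady state of the mask-free reaction
#' system (activator balance including bath exchange), linearises, and
#' evaluates the dispersion relation `Re lambda(k)` of perturbations
#' `exp(i k x)`: the leading eigenvalue of `J - k^2 diag(D_b, D_n)` over a
#' wavenumber grid. Reports the fastest-growing wavelength when a band of
#' unstable wavenumbers exists.
#'
#' @param params an [rd_params()] object.
#' @param k_max largest wavenumber examined (rad/um).
#' @param n_k number of wavenumbers in the grid.
#' @return An object of class `rd_dispersion`: `data.frame`-like list with
#'   `k`, `re_lambda`, the steady state `(b_star, n_star)`, `growth_max`
#'   (largest `Re lambda` over `k > 0`) and `lambda_max` (fastest-growing
#'   wavelength in micrometres, `NA` when no Turing band exists).
#' @examples
#' st <- linear_stability(rd_params("turing"))
#' st$lambda_max
#' @export
linear_stability <- function(params, k_max = 0.2, n_k = 2000) {
  stopifnot(inherits(params, "rd_params"))
  p <- params
  if (p$rho_b <= 0)
    stop("analysis error: no positive steady state ",
         "(activator is never produced, rho_b = 0)")
  nst <- function(b) p$rho_n * b^p$q / p$mu_n
  bal <- function(b) {
    p$rho_b * b^2 / ((p$n0 + nst(b)) * (1 + p$kappa * b^2)) -
      p$mu_b * b + p$k_ex * (p$c_dose - b)
  }
  hi <- 1e3
  while (bal(hi) > 0 && hi < 1e12) hi <- hi * 10
  if (bal(hi) > 0) stop("analysis error: no positive steady state found")
  lo <- 1e-12
  if (bal(lo) <= 0)
    stop("analysis error: no positive steady state found")
  b_star <- stats::uniroot(bal, c(lo, hi), tol = 1e-12)$root
  if (!is.finite(b_star) || b_star <= 1e-10 ||
      p$rho_b * b_star^2 < .Machine$double.eps)
    stop("analysis error: no positive steady state found")
  n_star <- nst(b_star)

  sig <- 1 + p$kappa * b_star^2
  ntot <- p$n0 + n_star
  a11 <- 2 * p$rho_b * b_star / (ntot * sig^2) - p$mu_b - p$k_ex
  a12 <- -p$rho_b * b_star^2 / (ntot^2 * sig)
  a21 <- p$q * p$rho_n * b_star^(p$q - 1)
  a22 <- -p$mu_n

  k <- seq(0, k_max, length.out = n_k)
  # leading eigenvalue of the 2x2 [[a11-k^2 Db, a12], [a21, a22-k^2 Dn]]
  t1 <- a11 - k^2 * p$D_b
  t2 <- a22 - k^2 * p$D_n
  tr <- t1 + t2
  det <- t1 * t2 - a12 * a21
  disc <- tr^2 / 4 - det
  re <- ifelse(disc >= 0, tr / 2 + sqrt(pmax(disc, 0)), tr / 2)

  pos <- which(re > 0 & k > 0)
  if (length(pos) == 0L) {
    growth <- max(re[k > 0]); lmax <- NA_real_
  } else {
    i_best <- pos[which.max(re[pos])]
    growth <- re[i_best]
    lmax <- 2 * pi / k[i_best]
  }
  structure(list(k = k, re_lambda = re, b_star = b_star, n_star = n_star,
                 jacobian = matrix(c(a11, a12, a21, a22), 2, byrow = TRUE),
                 growth_max = growth, lambda_max = lmax),
            class = "rd_dispersion")
}

#' @export
print.rd_dispersion <- function(x, ...) {
  cat("<rd_dispersion> steady state b* =", format(x$b_star, digits = 4),
      ", n* =", format(x$n_star, digits = 4), "\n")
  if (is.na(x$lambda_max)) {
    cat("  no Turing band: Re lambda(k) <= 0 for all k > 0 (max ",
        format(x$growth_max, digits = 3), "/h)\n", sep = "")
  } else {
    cat(sprintf("  Turing band present: max growth %.3g 1/h at wavelength %.0f um\n",
                x$growth_max, x$lambda_max))
  }
  invisible(x)
}

#' @export
plot.rd_dispersion <- function(x, ...) {
  graphics::plot(x$k, x$re_lambda, type = "l", xlab = "wavenumber k (rad/um)",
                 ylab = "Re lambda(k) (1/h)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Local maxima of a simulated 2-D field
#'
#' Detects focus positions as strict 8-neighbour local maxima of a 2-D field
#' above an intensity quantile, with close maxima merged and an outer
#' exclusion band (the peripheral ring is a boundary feature, not a focus).
#'
#' @param sim an `rd_sim` on a grid-2D domain (last saved field is used), or a
#'   matrix together with `domain`.
#' @param domain required when `sim` is a bare matrix.
#' @param what field component to use, `"readout"` (default), `"b"` or `"n"`.
#' @param quantile intensity quantile (within the colony) below which maxima
#'   are ignored.
#' @param exclude_outer fraction of the colony radius treated as the
#'   peripheral ring band and excluded.
#' @param min_sep merge radius (micrometres): of any two maxima closer than
#'   this, only the higher is kept. Defaults to 6 grid spacings.
#' @return `data.frame(x, y, value, r)` of focus positions (colony-centred
#'   micrometres).
#' @export
field_maxima <- function(sim, domain = NULL, what = "readout", quantile = 0.6,
                         exclude_outer = 0.05, min_sep = NULL) {
  if (inherits(sim, "rd_sim")) {
    domain <- sim$domain
    M <- sim$fields[[length(sim$fields)]][[what]]
  } else M <- sim
  stopifnot(inherits(domain, "rd_domain"), domain$kind == "grid-2D")
  if (is.null(min_sep)) min_sep <- 6 * domain$h
  rr <- domain$rr
  Rc <- domain$R_colony
  thr <- stats::quantile(M[rr <= Rc], quantile)
  nr <- nrow(M)
  keep_r <- (1 - exclude_outer) * Rc
  cand <- NULL
  for (i in 2:(nr - 1L)) for (j in 2:(nr - 1L)) {
    if (rr[i, j] > keep_r) next
    v <- M[i, j]
    if (v < thr) next
    nb <- M[(i - 1L):(i + 1L), (j - 1L):(j + 1L)]
    if (v >= max(nb) && sum(nb == v) == 1L)
      cand <- rbind(cand, c(i, j, v))
  }
  if (is.null(cand))
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0),
                      r = numeric(0)))
  cand <- cand[order(-cand[, 3]), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (a in seq_len(nrow(cand))) {
    if (!keep[a]) next
    d2 <- (cand[, 1] - cand[a, 1])^2 + (cand[, 2] - cand[a, 2])^2
    close <- d2 * domain$h^2 < min_sep^2
    close[seq_len(a)] <- FALSE
    keep[close & keep] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  x <- domain$x[cand[, 1]]
  y <- domain$x[cand[, 2]]
  data.frame(x = x, y = y, value = cand[, 3], r = sqrt(x^2 + y^2))
}
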