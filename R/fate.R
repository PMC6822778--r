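# Positional-information fate rule: fates from signalling histories.

#' Cumulative signalling exposure per position
#'
#' Fates in the colony arise as a function of both morphogen level and
#' induction time. The default exposure measure is the cumulative readout
#' \deqn{E(x) = \int_0^T \mathrm{readout}(x, t)\, dt}
#' computed by the trapezoidal rule over the saved fields (units a.u. h).
#' The alternative rule `"time-above"` instead accumulates the time (hours)
#' the readout spends at or above a level; both implement the dose-by-time
#' interchangeability, cumulative exposure is the default.
#'
#' @param sim an `rd_sim` with at least two saved time points.
#' @param rule `"integral"` (default) or `"time-above"`.
#' @param level readout level (a.u.) for the `"time-above"` rule.
#' @return An `exposure_map` object: the per-position exposure `E` (vector or
#'   matrix matching the domain grid) with the domain attached.
#' @examples
#' dom <- build_domain("radial-1D", 250, 500, 5)
#' sim <- simulate_rd(rd_params("SB"), dom, T = 4, save_every = 1)
#' E <- exposure_map(sim)
#' @export
exposure_map <- function(sim, rule = c("integral", "time-above"), level = NULL) {
  stopifnot(inherits(sim, "rd_sim"))
  rule <- match.arg(rule)
  if (length(sim$fields) < 2L)
    stop("cannot integrate exposure from a single saved time point; ",
         "save at least two fields")
  ts <- sim$times
  E <- sim$fields[[1]]$readout * 0
  for (i in seq_len(length(ts) - 1L)) {
    dtl <- ts[i + 1L] - ts[i]
    if (rule == "integral") {
      E <- E + dtl * (sim$fields[[i]]$readout + sim$fields[[i + 1L]]$readout) / 2
    } else {
      if (is.null(level)) stop("the time-above rule needs a level")
      above <- (sim$fields[[i]]$readout >= level) +
        (sim$fields[[i + 1L]]$readout >= level)
      E <- E + dtl * above / 2
    }
  }
  structure(list(E = E, domain = sim$domain, rule = rule,
                 T = max(ts), nodal_on = sim$params$nodal_on),
            class = "exposure_map")
}

#' Fate-switch thresholds
#'
#' @param T_low exposure (a.u. h) below which the pluripotency/preneural
#'   marker (SOX2-like) is retained.
#' @param T_switch exposure threshold of the patterned fate: GATA3-like
#'   (non-neural) without Nodal, BRA-like (primitive-streak) with Nodal.
#'   Must satisfy `0 <= T_low <= T_switch`.
#'
#' The defaults place the switch inside the exposure range of the default
#' 24 h SB condition on a 500 um colony, so that the boundary annulus
#' exceeds `T_switch` while the colony centre stays below `T_low` - the
#' observed SOX2-centre / GATA3-rim segregation. They are presumptive
#' thresholds in arbitrary exposure units, not measured quantities.
#' @return A `fate_thresholds` object.
#' @export
fate_thresholds <- function(T_low = 180, T_switch = 190) {
  if (!(T_low >= 0 && T_low <= T_switch))
    stop("thresholds must satisfy 0 <= T_low <= T_switch")
  structure(list(T_low = T_low, T_switch = T_switch),
            class = "fate_thresholds")
}

#' Assign fates from an exposure map
#'
#' Thresholds the per-position exposure: positions with `E < T_low` retain the
#' SOX2-like fate; positions with `E >= T_switch` acquire the patterned fate -
#' GATA3-like (non-neural, preneurulation) when Nodal signalling is off,
#' BRA-like (primitive streak, peri-gastrulation) when it is on; the
#' intermediate band is labelled `"none"` (differentiated, marker-negative).
#' The labels partition the colony and depend only on `(E, nodal_on)`.
#'
#' @param exposure an [exposure_map()] object, or a bare numeric vector/matrix
#'   of exposures (then `domain` may be `NULL` and all positions are used).
#' @param thresholds a [fate_thresholds()] object.
#' @param nodal_on logical switch selecting the high-exposure fate label;
#'   defaults to the simulation's setting when `exposure` is an
#'   `exposure_map`.
#' @param domain optional domain used to restrict labels to the colony mask.
#' @return A `fate_map` object: factor labels (`SOX2`, `GATA3`, `BRA`,
#'   `none`) per colony position plus the exposure values.
#' @examples
#' dom <- build_domain("radial-1D", 250, 500, 5)
#' sim <- simulate_rd(rd_params("SB"), dom, T = 4, save_every = 1)
#' fm <- assign_fates(exposure_map(sim), fate_thresholds(10, 20))
#' table(fm$fate)
#' @export
assign_fates <- function(exposure, thresholds = fate_thresholds(),
                         nodal_on = NULL, domain = NULL) {
  stopifnot(inherits(thresholds, "fate_thresholds"))
  if (inherits(exposure, "exposure_map")) {
    if (is.null(nodal_on)) nodal_on <- exposure$nodal_on
    if (is.null(domain)) domain <- exposure$domain
    E <- exposure$E
  } else E <- exposure
  if (is.null(nodal_on)) nodal_on <- FALSE
  if (any(E < 0)) stop("exposure must be >= 0")
  inside <- if (!is.null(domain)) {
    # fully cell-covered support only, as in readout_radial
    if (!is.null(domain$coverage)) domain$coverage >= 1 - 1e-9
    else domain_radii(domain) <= domain$R_colony
  } else rep(TRUE, length(E))
  Ei <- E[inside]
  high_label <- if (nodal_on) "BRA" else "GATA3"
  fate <- rep("none", length(Ei))
  fate[Ei < thresholds$T_low] <- "SOX2"
  fate[Ei >= thresholds$T_switch] <- high_label
  fate <- factor(fate, levels = c("SOX2", "GATA3", "BRA", "none"))
  r <- if (!is.null(domain)) domain_radii(domain)[inside] else rep(NA_real_, length(Ei))
  structure(list(fate = fate, E = Ei, r = r, nodal_on = nodal_on,
                 thresholds = thresholds, domain = domain),
            class = "fate_map")
}

#' @export
print.fate_map <- function(x, ...) {
  tab <- table(x$fate)
  cat("<fate_map>", if (x$nodal_on) "(Nodal on)" else "(Nodal off)", "\n")
  frac <- prop.table(tab)
  for (nm in names(tab))
    cat(sprintf("  %-6s %6d positions (%.1f%%)\n", nm, tab[[nm]], 100 * frac[[nm]]))
  invisible(x)
}

#' Area fraction of each fate within the colony
#'
#' @param fm a `fate_map`.
#' @return Named numeric vector of area fractions summing to 1.
#' @export
fate_fractions <- function(fm) {
  stopifnot(inherits(fm, "fate_map"))
  w <- if (!is.null(fm$domain)) {
    dom <- fm$domain
    sel <- if (!is.null(dom$coverage)) dom$coverage >= 1 - 1e-9
           else domain_radii(dom) <= dom$R_colony
    dom$weights[sel]
  } else rep(1, length(fm$fate))
  v <- tapply(w, fm$fate, sum, default = 0)
  out <- as.vector(v) / sum(w)
  names(out) <- names(v)
  out
}
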