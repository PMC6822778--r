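# Seeded synthetic-data generators emulating the micropatterned-plate
# measurements: per-cell intensity tables, reference point patterns, and
# qPCR Ct tables with planted cluster structure.

#' Radial intensity profile models for synthetic channels
#'
#' Named parametric mean profiles as functions of normalised radius
#' `rho = r/R` in \[0, 1\]:
#' `flat` (constant 1), `peripheral-ring` (low centre, sigmoidal rise near the
#' edge), `ramp` (linear 0 at centre to 1 at edge), `double-peak` (peripheral
#' peak plus interior peak, the Nodal-reshaped shape), or `inverse-ring`
#' (high centre falling towards the edge, a SOX2-like shape).
#'
#' @param name profile name.
#' @return A function of `rho`.
#' @export
channel_profile <- function(name = c("flat", "peripheral-ring", "ramp",
                                     "double-peak", "inverse-ring")) {
  name <- match.arg(name)
  switch(name,
    "flat" = function(rho) rep(1, length(rho)),
    "peripheral-ring" = function(rho) 0.15 + 0.85 / (1 + exp(-(rho - 0.8) / 0.06)),
    "ramp" = function(rho) rho,
    "double-peak" = function(rho)
      0.1 + 0.9 * exp(-(rho - 0.95)^2 / (2 * 0.07^2)) +
        0.55 * exp(-rho^2 / (2 * 0.22^2)),
    "inverse-ring" = function(rho) 0.15 + 0.85 / (1 + exp((rho - 0.6) / 0.08)))
}

#' Specification of a synthetic channel
#'
#' @param profile a profile name (see [channel_profile()]), a function of
#'   normalised radius, or a `radial_readout` data frame from
#'   [readout_radial()] (interpolated linearly).
#' @param gain multiplicative gain (a.u.).
#' @param sigma lognormal noise sigma (log scale); 0 = noiseless.
#' @param background additive background (a.u.).
#' @param positive_fraction optional fraction in \[0, 1\]; when set, cells are
#'   drawn positive/negative with this probability and the channel becomes
#'   bimodal: positives at `gain`, negatives at `gain/20` (both lognormal),
#'   overriding the radial profile. Used for percent-positive tests.
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(profile = "flat", gain = 1000, sigma = 0.2,
                         background = 50, positive_fraction = NULL) {
  if (is.character(profile)) profile <- channel_profile(profile)
  if (is.data.frame(profile)) {
    stopifnot(all(c("r_mid", "mean") %in% names(profile)))
    tab <- profile
    profile <- function(rho)
      stats::approx(tab$r_mid, tab$mean, xout = rho, rule = 2)$y
  }
  stopifnot(is.function(profile), gain >= 0, sigma >= 0, background >= 0)
  if (!is.null(positive_fraction))
    stopifnot(positive_fraction >= 0, positive_fraction <= 1)
  structure(list(profile = profile, gain = gain, sigma = sigma,
                 background = background,
                 positive_fraction = positive_fraction),
            class = "channel_spec")
}

#' Specification of a synthetic micropatterned plate
#'
#' Describes the plate geometry and per-channel intensity models used by
#' [generate_plate()]. Colony sizes cover the geometries used on
#' micropatterned plates (200-700 um series, 500 um default, 1 mm screens,
#' 3 mm foci colonies).
#'
#' @param n_wells number of wells.
#' @param colonies_per_well colonies per well, laid out on a square grid.
#' @param colony_diameter colony diameter (micrometres).
#' @param colony_pitch centre-to-centre spacing (micrometres);
#'   must exceed the diameter. Default `1.5 * colony_diameter`.
#' @param cell_density target cell density inside colonies (cells/mm^2).
#' @param min_separation hard-core minimum nucleus separation (micrometres).
#' @param off_colony_rate density of scattered off-colony cells (cells/mm^2).
#' @param channels named list of [channel_spec()] objects.
#' @param seed integer seed; generation is fully reproducible per seed.
#' @return A `plate_spec` list.
#' @examples
#' sp <- plate_spec(n_wells = 1, colonies_per_well = 4, seed = 7)
#' @export
plate_spec <- function(n_wells = 1, colonies_per_well = 12,
                       colony_diameter = 500,
                       colony_pitch = 1.5 * colony_diameter,
                       cell_density = 2500, min_separation = 10,
                       off_colony_rate = 20,
                       channels = list(ch1 = channel_spec("peripheral-ring")),
                       seed = 1L) {
  stopifnot(n_wells >= 1, colonies_per_well >= 1, colony_diameter > 0,
            cell_density > 0, min_separation >= 0, off_colony_rate >= 0)
  if (colony_pitch <= colony_diameter)
    stop("colony_pitch must exceed colony_diameter")
  exp_cells <- cell_density * pi * (colony_diameter / 2000)^2
  if (exp_cells < 50)
    stop("cell_density too low: expected cells per colony (",
         round(exp_cells), ") < 50")
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be a named list")
  ok <- vapply(channels, inherits, logical(1), what = "channel_spec")
  if (!all(ok)) stop("all channels must be channel_spec objects")
  structure(list(n_wells = n_wells, colonies_per_well = colonies_per_well,
                 colony_diameter = colony_diameter, colony_pitch = colony_pitch,
                 cell_density = cell_density, min_separation = min_separation,
                 off_colony_rate = off_colony_rate, channels = channels,
                 seed = as.integer(seed)),
            class = "plate_spec")
}

# hard-core sequential sampling of n points in a disc of radius R
hardcore_disc <- function(n, R, min_sep, max_tries = 200L) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  pts <- matrix(NA_real_, n, 2L)
  placed <- 0L
  tries_left <- max_tries * n
  while (placed < n && tries_left > 0L) {
    tries_left <- tries_left - 1L
    rr <- R * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    cand <- c(rr * cos(th), rr * sin(th))
    if (placed > 0L && min_sep > 0) {
      d2 <- (pts[seq_len(placed), 1L] - cand[1L])^2 +
            (pts[seq_len(placed), 2L] - cand[2L])^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    pts[placed, ] <- cand
  }
  if (placed < n)
    stop("generation error: packing failure - could not place ", n,
         " cells with min_separation ", min_sep, " um after ",
         max_tries * n, " tries")
  colnames(pts) <- c("x", "y")
  pts
}

#' Generate a synthetic per-cell plate table
#'
#' Emulates a Cellomics-style single-cell export: colony centres on a grid
#' with the given pitch, nuclei placed by sequential hard-core sampling to the
#' target density, channel intensities
#' `gain * profile(r/R) * LogNormal(0, sigma) + background`, and off-colony
#' noise cells scattered uniformly between colonies. The cell table carries no
#' colony label; the ground truth (true colony id, normalised radial position,
#' true positive state) is returned as a separate sidecar table so the
#' pipeline under test cannot consume it by accident.
#'
#' @param spec a [plate_spec()].
#' @return A list of class `synthetic_plate` with elements `cells`
#'   (`data.frame(well, x, y, <one column per channel>)`) and `truth`
#'   (`data.frame(well, cell, colony, rho, <channel>_positive ...)`).
#' @examples
#' plate <- generate_plate(plate_spec(colonies_per_well = 4, seed = 3))
#' head(plate$cells)
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  set.seed(spec$seed)
  R <- spec$colony_diameter / 2
  n_per_colony <- round(spec$cell_density * pi * (R / 1000)^2)
  grid_n <- ceiling(sqrt(spec$colonies_per_well))
  pitch <- spec$colony_pitch
  margin <- pitch / 2
  well_size <- grid_n * pitch + pitch     # square well, one pitch of border

  cells <- NULL
  truth <- NULL
  for (w in seq_len(spec$n_wells)) {
    well_id <- sprintf("W%02d", w)
    centres <- expand.grid(ix = seq_len(grid_n), iy = seq_len(grid_n))
    centres <- centres[seq_len(spec$colonies_per_well), , drop = FALSE]
    cx <- margin + (centres$ix - 0.5) * pitch
    cy <- margin + (centres$iy - 0.5) * pitch
    wx <- NULL
    for (k in seq_len(spec$colonies_per_well)) {
      pts <- hardcore_disc(n_per_colony, R, spec$min_separation)
      rho <- sqrt(pts[, 1]^2 + pts[, 2]^2) / R
      df <- data.frame(well = well_id, x = cx[k] + pts[, 1],
                       y = cy[k] + pts[, 2])
      tr <- data.frame(well = well_id, colony = k, rho = rho)
      for (ch in names(spec$channels)) {
        cs <- spec$channels[[ch]]
        if (is.null(cs$positive_fraction)) {
          mu <- cs$gain * cs$profile(rho)
          pos <- mu > cs$gain * 0.5
        } else {
          pos <- stats::runif(nrow(df)) < cs$positive_fraction
          mu <- ifelse(pos, cs$gain, cs$gain / 20)
        }
        noise <- if (cs$sigma > 0)
          exp(stats::rnorm(nrow(df), 0, cs$sigma)) else 1
        df[[ch]] <- mu * noise + cs$background
        tr[[paste0(ch, "_positive")]] <- pos
      }
      wx <- rbind(wx, cbind(df, tr[, -1, drop = FALSE]))
    }
    # off-colony scattered cells (uniform over the well, outside all colonies)
    n_off <- stats::rpois(1, spec$off_colony_rate * (well_size / 1000)^2)
    if (n_off > 0) {
      ox <- numeric(0); oy <- numeric(0)
      while (length(ox) < n_off) {
        xx <- stats::runif(n_off, 0, well_size)
        yy <- stats::runif(n_off, 0, well_size)
        d2min <- rep(Inf, n_off)
        for (k in seq_len(spec$colonies_per_well))
          d2min <- pmin(d2min, (xx - cx[k])^2 + (yy - cy[k])^2)
        okk <- d2min > (R + spec$min_separation)^2
        ox <- c(ox, xx[okk]); oy <- c(oy, yy[okk])
      }
      ox <- ox[seq_len(n_off)]; oy <- oy[seq_len(n_off)]
      df <- data.frame(well = well_id, x = ox, y = oy)
      tr <- data.frame(colony = 0L, rho = NA_real_)
      for (ch in names(spec$channels)) {
        cs <- spec$channels[[ch]]
        noise <- if (cs$sigma > 0) exp(stats::rnorm(n_off, 0, cs$sigma)) else 1
        df[[ch]] <- cs$background * noise
        tr[[paste0(ch, "_positive")]] <- FALSE
      }
      wx <- rbind(wx, cbind(df, tr))
    }
    cells <- rbind(cells, wx)
  }
  rownames(cells) <- NULL
  chcols <- names(spec$channels)
  truth <- cells[, c("well", "colony", "rho",
                     paste0(chcols, "_positive")), drop = FALSE]
  truth$cell <- seq_len(nrow(truth))
  cells <- cells[, c("well", "x", "y", chcols)]
  structure(list(cells = cells, truth = truth, spec = spec),
            class = "synthetic_plate")
}

#' @export
print.synthetic_plate <- function(x, ...) {
  cat(sprintf("<synthetic_plate> %d wells, %d cells, channels: %s\n",
              length(unique(x$cells$well)), nrow(x$cells),
              paste(names(x$spec$channels), collapse = ", ")))
  invisible(x)
}

#' Specification of a reference point pattern
#'
#' @param kind `"uniform-random"` (points iid uniform on the disc),
#'   `"jittered-hex"` (hexagonal lattice clipped to the disc plus Gaussian
#'   jitter), or `"rd-maxima"` (local maxima of a simulated 2-D field, see
#'   [generate_point_pattern()]).
#' @param n_points number of points (uniform-random; also the matched count
#'   for jittered-hex when `d` is omitted).
#' @param d lattice spacing (micrometres, jittered-hex).
#' @param jitter jitter standard deviation (micrometres).
#' @param radius domain (colony) radius in micrometres.
#' @param field an `rd_sim` on a grid-2D domain (rd-maxima only).
#' @param seed integer seed.
#' @return A `pattern_spec` list.
#' @export
pattern_spec <- function(kind = c("uniform-random", "jittered-hex", "rd-maxima"),
                         n_points = NULL, d = NULL, jitter = 0, radius = 1500,
                         field = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(radius > 0, jitter >= 0)
  if (kind == "uniform-random" && (is.null(n_points) || n_points < 2))
    stop("uniform-random patterns need n_points >= 2")
  if (kind == "jittered-hex") {
    if (is.null(d) && is.null(n_points))
      stop("jittered-hex needs a lattice spacing d or a target n_points")
    if (!is.null(d) && d > 2 * radius)
      stop("generation error: lattice spacing d exceeds the domain diameter")
  }
  if (kind == "rd-maxima" && is.null(field))
    stop("rd-maxima patterns need a grid-2D rd_sim in `field`")
  structure(list(kind = kind, n_points = n_points, d = d, jitter = jitter,
                 radius = radius, field = field, seed = as.integer(seed)),
            class = "pattern_spec")
}

# hexagonal lattice covering a disc of radius R, spacing d, centred
hex_lattice_disc <- function(d, R) {
  ny <- ceiling(2 * R / (d * sqrt(3) / 2)) + 2L
  nx <- ceiling(2 * R / d) + 2L
  pts <- NULL
  for (iy in seq(-ny, ny)) {
    yy <- iy * d * sqrt(3) / 2
    off <- if (iy %% 2 == 0) 0 else d / 2
    xx <- seq(-nx, nx) * d + off
    pts <- rbind(pts, cbind(xx, rep(yy, length(xx))))
  }
  pts[pts[, 1]^2 + pts[, 2]^2 <= R^2, , drop = FALSE]
}

#' Generate a reference point pattern
#'
#' Produces the comparison patterns used by the periodicity analysis:
#' uniform-random (complete spatial randomness on the disc), jittered
#' hexagonal lattices, and focus patterns extracted from a simulated
#' reaction-diffusion field (strict 8-neighbour maxima above an intensity
#' quantile, peripheral ring band excluded, as in [field_maxima()]).
#'
#' @param spec a [pattern_spec()].
#' @return A `point_pattern` object: `data.frame` of points, the domain
#'   radius, and a source tag.
#' @examples
#' pp <- generate_point_pattern(pattern_spec("uniform-random", n_points = 30,
#'                                           radius = 1500, seed = 2))
#' @export
generate_point_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  set.seed(spec$seed)
  R <- spec$radius
  if (spec$kind == "uniform-random") {
    n <- spec$n_points
    rr <- R * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    pts <- cbind(x = rr * cos(th), y = rr * sin(th))
  } else if (spec$kind == "jittered-hex") {
    d <- spec$d
    if (is.null(d)) {
      # spacing whose hex lattice carries about n_points points on the disc
      d <- sqrt(2 * pi * R^2 / (sqrt(3) * spec$n_points))
    }
    pts <- hex_lattice_disc(d, R)
    if (spec$jitter > 0) {
      for (i in seq_len(nrow(pts))) {
        repeat {
          cand <- pts[i, ] + stats::rnorm(2, 0, spec$jitter)
          if (sum(cand^2) <= R^2) { pts[i, ] <- cand; break }
        }
      }
    }
    if (!is.null(spec$n_points)) {
      if (nrow(pts) < spec$n_points)
        stop("test error: matched-count generation failure (lattice holds ",
             nrow(pts), " points, need ", spec$n_points, ")")
      if (nrow(pts) > spec$n_points)
        pts <- pts[sample.int(nrow(pts), spec$n_points), , drop = FALSE]
    }
    colnames(pts) <- c("x", "y")
  } else {
    mx <- field_maxima(spec$field)
    pts <- cbind(x = mx$x, y = mx$y)
  }
  structure(list(points = data.frame(x = pts[, "x"], y = pts[, "y"]),
                 radius = R, source = spec$kind),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern> %s: %d points on a disc of radius %g um\n",
              x$source, nrow(x$points), x$radius))
  invisible(x)
}

#' Specification of a synthetic qPCR Ct table
#'
#' Plants a cluster structure into an embryoid-body style differentiation
#' time course: each line belongs to a cluster, each (gene, cluster) has a
#' log2 fold-change trajectory over days, and Ct values are generated so the
#' delta-delta-Ct analysis recovers exactly the planted trajectories (plus
#' noise).
#'
#' @param lines character vector of cell-line names.
#' @param genes character vector of gene names (reference gene added
#'   automatically).
#' @param days integer vector of days (must include the baseline day 0).
#' @param replicates biological replicates per sample (>= 2).
#' @param line_cluster integer vector (same length as `lines`) assigning each
#'   line to a planted cluster.
#' @param planted_log2fc array/function giving the planted log2 fold change:
#'   either a function `(gene, cluster, day) -> numeric` or a 3-d array
#'   indexed `[gene, cluster, day-as-character]`.
#' @param noise_sd Ct noise standard deviation (cycles); 0 = noiseless.
#' @param ref_gene reference (housekeeping) gene name.
#' @param ref_ct constant reference-gene Ct (cycles).
#' @param base_dct baseline delta-Ct of every target gene at day 0 (cycles).
#' @param seed integer seed.
#' @return A `qpcr_spec` list.
#' @export
qpcr_spec <- function(lines, genes, days = 0:3, replicates = 3,
                      line_cluster = rep(1L, length(lines)),
                      planted_log2fc = function(gene, cluster, day) 0,
                      noise_sd = 0.25, ref_gene = "GAPDH", ref_ct = 18,
                      base_dct = 6, seed = 1L) {
  stopifnot(length(lines) >= 1, length(genes) >= 1, replicates >= 2,
            noise_sd >= 0, 0 %in% days,
            length(line_cluster) == length(lines))
  if (is.array(planted_log2fc)) {
    arr <- planted_log2fc
    planted_log2fc <- function(gene, cluster, day)
      arr[gene, cluster, as.character(day)]
  }
  stopifnot(is.function(planted_log2fc))
  structure(list(lines = lines, genes = genes, days = days,
                 replicates = replicates, line_cluster = line_cluster,
                 planted_log2fc = planted_log2fc, noise_sd = noise_sd,
                 ref_gene = ref_gene, ref_ct = ref_ct, base_dct = base_dct,
                 seed = as.integer(seed)),
            class = "qpcr_spec")
}

#' Generate a synthetic qPCR Ct table
#'
#' `Ct(gene, line, day, rep) = ref_ct + base_dct - planted_log2fc(gene,
#' cluster(line), day) + Normal(0, noise_sd)`; the reference gene is constant
#' at `ref_ct`. With `noise_sd = 0` the downstream delta-delta-Ct log2 fold
#' change equals the planted trajectory exactly (round-trip oracle).
#'
#' @param spec a [qpcr_spec()].
#' @return `data.frame(line, gene, day, replicate, ct)` including reference
#'   gene rows.
#' @examples
#' sp <- qpcr_spec(lines = c("A", "B", "C"), genes = "T",
#'                 planted_log2fc = function(g, cl, d) 2 * d)
#' ct <- generate_qpcr(sp)
#' @export
generate_qpcr <- function(spec) {
  stopifnot(inherits(spec, "qpcr_spec"))
  set.seed(spec$seed)
  grid <- expand.grid(line = spec$lines, gene = spec$genes, day = spec$days,
                      replicate = seq_len(spec$replicates),
                      stringsAsFactors = FALSE)
  planted <- mapply(function(g, l, d)
    spec$planted_log2fc(g, spec$line_cluster[match(l, spec$lines)], d),
    grid$gene, grid$line, grid$day)
  ct <- spec$ref_ct + spec$base_dct - planted +
    stats::rnorm(nrow(grid), 0, spec$noise_sd)
  ref <- expand.grid(line = spec$lines, gene = spec$ref_gene, day = spec$days,
                     replicate = seq_len(spec$replicates),
                     stringsAsFactors = FALSE)
  ref$ct <- spec$ref_ct
  grid$ct <- ct
  out <- rbind(grid, ref)
  rownames(out) <- NULL
  out[order(out$line, out$gene, out$day, out$replicate), ]
}
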