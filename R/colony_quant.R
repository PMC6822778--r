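# Single-cell colony quantification: density-based colony assignment,
# QC filtering, annular radial profiles with SD / 95% CI, hexagonal-bin
# expression maps, and percent-positive statistics.

# DBSCAN on 2-d points with a bucket-grid neighbour search.
# Core points have >= min_samples neighbours within eps (self included);
# clusters are connected components of core points; a border point joins the
# lowest-numbered reachable cluster; clusters are numbered by their smallest
# core-point index (deterministic).
dbscan2d <- function(x, y, eps, min_samples) {
  n <- length(x)
  cx <- floor(x / eps); cy <- floor(y / eps)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  neigh <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(cx[i] + dx, cy[i] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    neigh[[i]] <- cand[d2 <= eps^2]
  }
  core <- lengths(neigh) >= min_samples
  labels <- integer(n)        # 0 = noise / unassigned
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (qq in neigh[[p]]) {
        if (!core[qq] || labels[qq] != 0L) next
        labels[qq] <- cl
        queue <- c(queue, qq)
      }
    }
  }
  # border points: lowest-numbered cluster among reachable cores
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    nb <- neigh[[i]]
    nb_cl <- labels[nb][core[nb] & labels[nb] > 0L]
    if (length(nb_cl) > 0L) labels[i] <- min(nb_cl)
  }
  list(labels = labels, core = core)
}

#' DBSCAN labels for a 2-d point set
#'
#' Low-level access to the clustering used by [assign_colonies()]: returns the
#' integer cluster label per point (0 = noise) for a single set of
#' coordinates, without any colony bookkeeping. Exposed so the clustering can
#' be validated directly.
#'
#' @param x,y point coordinates (micrometres).
#' @param eps neighbourhood radius.
#' @param min_samples minimum neighbours of a core point (self included).
#' @return Integer vector of labels; clusters are numbered by their smallest
#'   core-point index.
#' @export
dbscan2d_labels <- function(x, y, eps, min_samples) {
  dbscan2d(x, y, eps, min_samples)$labels
}

# median nearest-neighbour spacing of up to `cap` sampled points
median_nn_spacing <- function(x, y, cap = 2000L) {
  n <- length(x)
  idx <- if (n > cap) sort(sample.int(n, cap)) else seq_len(n)
  d <- as.matrix(stats::dist(cbind(x[idx], y[idx])))
  diag(d) <- Inf
  stats::median(apply(d, 1L, min))
}

#' Assign cells to colonies by density-based clustering
#'
#' Classifies the cells of each well into colonies with DBSCAN: points with at
#' least `min_samples` neighbours within `eps` are core points, clusters are
#' connected components of core points, remaining cells within `eps` of a
#' cluster are border members, everything else is flagged noise. Also emits
#' centroid-relative coordinates per assigned cell.
#'
#' The defaults follow the scaling of the data rather than fixed lengths:
#' `eps` defaults to 3 times the median nearest-neighbour spacing of the
#' well's cells, `min_samples` to 10.
#'
#' @param cells `data.frame` with columns `well`, `x`, `y` and one column per
#'   intensity channel (as produced by [generate_plate()]).
#' @param eps neighbourhood radius (micrometres); `NULL` for the adaptive
#'   default.
#' @param min_samples minimum neighbours (self included) of a core point,
#'   >= 2.
#' @return A `colony_set`: `cells` (the input plus `colony` label - 0 is
#'   noise - and `rel_x`, `rel_y`), and `colonies`
#'   (`well, colony, cx, cy, n_cells, radius, kept`) where `radius` is the
#'   95th percentile of member cell distances to the centroid, rescaled by
#'   `1/sqrt(0.95)` so it estimates the full colony radius for uniformly
#'   covering colonies while staying robust to stragglers. All colonies
#'   start `kept = TRUE`; see [filter_colonies()].
#' @examples
#' plate <- generate_plate(plate_spec(colonies_per_well = 4, seed = 3))
#' cs <- assign_colonies(plate$cells)
#' cs$colonies
#' @export
assign_colonies <- function(cells, eps = NULL, min_samples = 10) {
  stopifnot(is.data.frame(cells), all(c("well", "x", "y") %in% names(cells)))
  if (!is.null(eps) && eps <= 0) stop("eps must be > 0")
  if (min_samples < 2) stop("min_samples must be >= 2")
  cells$colony <- 0L
  cells$rel_x <- NA_real_
  cells$rel_y <- NA_real_
  colonies <- NULL
  offset <- 0L
  for (w in unique(cells$well)) {
    sel <- which(cells$well == w)
    if (length(sel) < min_samples)
      stop("well ", w, " has fewer than min_samples cells")
    e <- if (is.null(eps))
      3 * median_nn_spacing(cells$x[sel], cells$y[sel]) else eps
    db <- dbscan2d(cells$x[sel], cells$y[sel], e, min_samples)
    lab <- db$labels
    cells$colony[sel] <- ifelse(lab == 0L, 0L, lab + offset)
    for (k in sort(unique(lab[lab > 0L]))) {
      m <- sel[lab == k]
      cx <- mean(cells$x[m]); cy <- mean(cells$y[m])
      cells$rel_x[m] <- cells$x[m] - cx
      cells$rel_y[m] <- cells$y[m] - cy
      rad <- sqrt(cells$rel_x[m]^2 + cells$rel_y[m]^2)
      # 95th-percentile radius, rescaled to be consistent for uniformly
      # covering colonies (the quantile itself sits at sqrt(0.95) * R)
      colonies <- rbind(colonies, data.frame(
        well = w, colony = k + offset, cx = cx, cy = cy,
        n_cells = length(m),
        radius = stats::quantile(rad, 0.95, names = FALSE) / sqrt(0.95),
        kept = TRUE))
    }
    offset <- offset + max(0L, max(lab))
  }
  structure(list(cells = cells, colonies = colonies,
                 eps = eps, min_samples = min_samples),
            class = "colony_set")
}

#' @export
print.colony_set <- function(x, ...) {
  nc <- if (is.null(x$colonies)) 0L else nrow(x$colonies)
  kept <- if (nc) sum(x$colonies$kept) else 0L
  cat(sprintf("<colony_set> %d cells, %d colonies (%d kept), %d noise cells\n",
              nrow(x$cells), nc, kept, sum(x$cells$colony == 0L)))
  invisible(x)
}

#' Quality-filter colonies
#'
#' Flags (never deletes) colonies whose cell count or radius is inconsistent
#' with a single well-formed colony of the nominal size: count outside
#' `count_bounds` times the expected count (the median count of all candidate
#' colonies, a density estimate robust to merged/fragmented outliers) or
#' radius outside +/- 30% of `nominal_diameter / 2`.
#'
#' @param colony_set a [assign_colonies()] result.
#' @param nominal_diameter expected colony diameter (micrometres).
#' @param count_bounds multiplicative bounds on the expected count.
#' @param radius_tol relative tolerance on the nominal radius.
#' @return The `colony_set` with updated `kept` flags.
#' @export
filter_colonies <- function(colony_set, nominal_diameter,
                            count_bounds = c(0.5, 1.6), radius_tol = 0.3) {
  stopifnot(inherits(colony_set, "colony_set"), nominal_diameter > 0)
  col <- colony_set$colonies
  if (is.null(col) || nrow(col) == 0L) return(colony_set)
  expected <- stats::median(col$n_cells)
  r_nom <- nominal_diameter / 2
  col$kept <- col$n_cells >= count_bounds[1] * expected &
    col$n_cells <= count_bounds[2] * expected &
    col$radius >= (1 - radius_tol) * r_nom &
    col$radius <= (1 + radius_tol) * r_nom
  colony_set$colonies <- col
  colony_set
}

kept_cells <- function(colony_set, channel = NULL) {
  col <- colony_set$colonies
  keep_ids <- col$colony[col$kept]
  cells <- colony_set$cells[colony_set$cells$colony %in% keep_ids, ]
  if (!is.null(channel) && !channel %in% names(cells))
    stop("channel '", channel, "' not present in the cell table")
  cells
}

#' Annular radial expression profile across colonies
#'
#' For each kept colony, cell radii are normalised by that colony's effective
#' radius, cells are grouped into equal-width annular bins of normalised
#' radius, and the mean expression per bin is computed. Colonies are then
#' weighted equally: the reported profile is the grand mean of the per-colony
#' bin means, with the SD across colonies and the t-based 95% confidence
#' interval per bin.
#'
#' @param colony_set a [assign_colonies()] (optionally filtered) result with
#'   at least one kept colony.
#' @param channel name of the intensity column.
#' @param n_bins number of annular bins over `r/R` in \[0, 1\].
#' @return An object of class `radial_profile`: `data.frame(bin, r_mid, mean,
#'   sd, ci95, n_colonies)` plus the per-colony bin means in
#'   `attr(, "per_colony")`. Bins a colony has no cells in contribute nothing
#'   for that colony; with a single colony `sd` and `ci95` are reported as 0.
#' @examples
#' plate <- generate_plate(plate_spec(colonies_per_well = 4, seed = 3))
#' cs <- assign_colonies(plate$cells)
#' radial_profile(cs, "ch1", n_bins = 8)
#' @export
radial_profile <- function(colony_set, channel, n_bins = 10) {
  stopifnot(inherits(colony_set, "colony_set"))
  cells <- kept_cells(colony_set, channel)
  if (nrow(cells) == 0L) stop("no kept colonies")
  col <- colony_set$colonies
  ids <- sort(unique(cells$colony))
  per <- matrix(NA_real_, length(ids), n_bins,
                dimnames = list(ids, NULL))
  for (ii in seq_along(ids)) {
    m <- cells[cells$colony == ids[ii], ]
    R <- col$radius[col$colony == ids[ii]]
    rho <- sqrt(m$rel_x^2 + m$rel_y^2) / R
    bin <- pmin(floor(rho * n_bins), n_bins - 1L) + 1L
    agg <- tapply(m[[channel]], bin, mean)
    per[ii, as.integer(names(agg))] <- agg
  }
  nn <- colSums(!is.na(per))
  grand <- colMeans(per, na.rm = TRUE)
  sdv <- apply(per, 2, stats::sd, na.rm = TRUE)
  sdv[nn <= 1L] <- 0
  ci <- ifelse(nn > 1L, stats::qt(0.975, nn - 1L) * sdv / sqrt(nn), 0)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  out <- data.frame(bin = seq_len(n_bins),
                    r_mid = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                    mean = grand, sd = sdv, ci95 = ci, n_colonies = nn)
  attr(out, "per_colony") <- per
  attr(out, "channel") <- channel
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' @export
plot.radial_profile <- function(x, ...) {
  graphics::plot(x$r_mid, x$mean, type = "b", ylim =
                   range(c(x$mean - x$sd, x$mean + x$sd), finite = TRUE),
                 xlab = "r / R", ylab = attr(x, "channel"), ...)
  graphics::arrows(x$r_mid, x$mean - x$ci95, x$r_mid, x$mean + x$ci95,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

# axial hex-binning of points with hexagon width w (flat-to-flat, pointy-top)
hex_assign <- function(x, y, w) {
  size <- w / sqrt(3)
  q <- (sqrt(3) / 3 * x - 1 / 3 * y) / size
  r <- (2 / 3 * y) / size
  # cube rounding
  xc <- q; zc <- r; yc <- -xc - zc
  rx <- round(xc); ry <- round(yc); rz <- round(zc)
  dx <- abs(rx - xc); dy <- abs(ry - yc); dz <- abs(rz - zc)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  cx <- size * sqrt(3) * (rx + rz / 2)
  cy <- size * 3 / 2 * rz
  list(key = paste(rx, rz), cx = cx, cy = cy)
}

#' Hexagonal-bin expression map
#'
#' Pools centroid-relative cell positions across kept colonies, tiles the
#' plane with hexagons of the given width, and reports the mean expression
#' per occupied hexagon together with a min-max normalised value (0 at the
#' lowest-expressing hexagon, 1 at the highest; defined as 0 everywhere when
#' all hexagons are equal).
#'
#' @param colony_set a [assign_colonies()] result.
#' @param channel intensity column name.
#' @param hex_width hexagon width (micrometres), > 0.
#' @return `data.frame(cx, cy, n_cells, mean, norm)` of class `hex_map`.
#' @examples
#' plate <- generate_plate(plate_spec(colonies_per_well = 4, seed = 3))
#' cs <- assign_colonies(plate$cells)
#' hm <- hex_map(cs, "ch1", hex_width = 50)
#' @export
hex_map <- function(colony_set, channel, hex_width = 50) {
  stopifnot(inherits(colony_set, "colony_set"))
  if (hex_width <= 0) stop("hex_width must be > 0")
  cells <- kept_cells(colony_set, channel)
  if (nrow(cells) == 0L) stop("no kept colonies")
  hx <- hex_assign(cells$rel_x, cells$rel_y, hex_width)
  agg <- tapply(cells[[channel]], hx$key, mean)
  cnt <- tapply(cells[[channel]], hx$key, length)
  cxs <- tapply(hx$cx, hx$key, `[`, 1L)
  cys <- tapply(hx$cy, hx$key, `[`, 1L)
  mu <- as.numeric(agg)
  rng <- range(mu)
  norm <- if (diff(rng) == 0) rep(0, length(mu)) else (mu - rng[1]) / diff(rng)
  out <- data.frame(cx = as.numeric(cxs), cy = as.numeric(cys),
                    n_cells = as.integer(cnt), mean = mu, norm = norm)
  class(out) <- c("hex_map", "data.frame")
  out
}

#' Otsu threshold on a numeric sample
#'
#' Exact maximisation of the between-class variance over all splits of the
#' sorted sample (the continuous-data analogue of Otsu's histogram method).
#'
#' @param x numeric vector (at least two distinct values).
#' @return The threshold: midpoint of the optimal split; values strictly above
#'   it are "positive".
#' @export
otsu_threshold <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n < 2L || xs[1] == xs[n]) stop("otsu_threshold needs >= 2 distinct values")
  csum <- cumsum(xs)
  k <- seq_len(n - 1L)
  w0 <- k / n
  mu0 <- csum[k] / k
  mu1 <- (csum[n] - csum[k]) / (n - k)
  bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
  valid <- xs[k] < xs[k + 1L]     # only splits between distinct values
  bcv[!valid] <- -Inf
  i <- which.max(bcv)
  (xs[i] + xs[i + 1L]) / 2
}

#' Per-colony percent-positive statistics
#'
#' Thresholds the pooled log-intensities of all kept-colony cells and reports
#' the percentage of positive cells per colony. Methods: `"otsu"` (exact Otsu
#' on pooled log intensity), `"gmm"` (two-component Gaussian mixture on log
#' intensity via \pkg{mclust}; positive = upper-component posterior > 0.5),
#' or `"fixed"` (a fixed intensity threshold). A degenerate channel (zero
#' variance) makes the adaptive methods fall back to `"fixed"` with a
#' warning.
#'
#' @param colony_set a [assign_colonies()] result.
#' @param channel intensity column name.
#' @param threshold_method `"otsu"`, `"gmm"` or `"fixed"`.
#' @param fixed_value threshold (raw intensity) for the fixed method and the
#'   degenerate fallback.
#' @return `data.frame(well, colony, n_cells, pct_positive)` with the
#'   threshold used in `attr(, "threshold")` (raw intensity scale).
#' @examples
#' ch <- channel_spec(positive_fraction = 0.4, gain = 1000, sigma = 0.2)
#' plate <- generate_plate(plate_spec(colonies_per_well = 4,
#'                                    channels = list(m = ch), seed = 5))
#' cs <- assign_colonies(plate$cells)
#' percent_positive(cs, "m")
#' @export
percent_positive <- function(colony_set, channel,
                             threshold_method = c("otsu", "gmm", "fixed"),
                             fixed_value = NULL) {
  stopifnot(inherits(colony_set, "colony_set"))
  threshold_method <- match.arg(threshold_method)
  cells <- kept_cells(colony_set, channel)
  if (nrow(cells) == 0L) stop("no kept colonies")
  v <- cells[[channel]]
  if (any(v <= 0)) v <- v + 1e-9
  lx <- log(v)
  degenerate <- stats::var(lx) == 0
  if (degenerate && threshold_method != "fixed") {
    warning("degenerate channel (zero variance): falling back to the fixed ",
            "threshold method")
    threshold_method <- "fixed"
  }
  thr <- switch(threshold_method,
    otsu = exp(otsu_threshold(lx)),
    gmm = {
      if (!requireNamespace("mclust", quietly = TRUE))
        stop("the gmm method needs the mclust package")
      fit <- mclust::Mclust(lx, G = 2, modelNames = "V", verbose = FALSE)
      comp_hi <- which.max(fit$parameters$mean)
      pos <- fit$z[, comp_hi] > 0.5
      # the implied boundary: midpoint between the classified groups
      if (!any(pos)) exp(max(lx)) else if (all(pos)) exp(min(lx)) - 1e-9
      else exp((max(lx[!pos]) + min(lx[pos])) / 2)
    },
    fixed = {
      if (is.null(fixed_value)) fixed_value <- max(v)
      fixed_value
    })
  positive <- cells[[channel]] > thr
  out <- do.call(rbind, lapply(split(seq_len(nrow(cells)), cells$colony),
    function(idx) {
      data.frame(well = cells$well[idx[1]], colony = cells$colony[idx[1]],
                 n_cells = length(idx),
                 pct_positive = 100 * mean(positive[idx]))
    }))
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "method") <- threshold_method
  out
}
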