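# Focus detection in large colonies and nearest-neighbour periodicity
# statistics: NN distance histograms, Shannon entropy, Jensen-Shannon
# divergence, and Monte-Carlo significance against reference patterns.

#' Detect marker-defined foci in kept colonies
#'
#' Thresholds the pooled log-intensities (Otsu), rasterises the indicator of
#' below-threshold (`polarity = "negative"`, e.g. SOX2-negative regions) or
#' above-threshold cells onto a grid of spacing `grid_h`, finds 8-connected
#' components, drops components smaller than `min_area`, and returns the
#' component centroids as a point pattern per colony. Components touching the
#' outer 5% annulus are excluded: the peripheral ring is a boundary feature of
#' the signalling gradient, not a focus.
#'
#' @param colony_set a [assign_colonies()] result (filtered or not).
#' @param channel intensity column name.
#' @param polarity `"negative"` (foci are low-marker regions, the default,
#'   following the SOX2-negative definition) or `"positive"`.
#' @param min_area minimum component area (um^2).
#' @param grid_h raster spacing (micrometres).
#' @param exclude_outer fraction of the colony radius treated as the
#'   peripheral band.
#' @return A named list of `point_pattern` objects, one per kept colony
#'   (possibly with zero points - an empty pattern is not an error).
#' @export
detect_foci <- function(colony_set, channel, polarity = c("negative", "positive"),
                        min_area = 5000, grid_h = 50, exclude_outer = 0.05) {
  stopifnot(inherits(colony_set, "colony_set"))
  polarity <- match.arg(polarity)
  cells <- kept_cells(colony_set, channel)
  if (nrow(cells) == 0L) stop("no kept colonies")
  v <- cells[[channel]]
  if (any(v <= 0)) v <- v + 1e-9
  thr <- otsu_threshold(log(v))
  hit <- if (polarity == "negative") log(v) < thr else log(v) >= thr
  col <- colony_set$colonies
  out <- list()
  for (id in sort(unique(cells$colony))) {
    m <- cells$colony == id
    R <- col$radius[col$colony == id]
    xx <- cells$rel_x[m]; yy <- cells$rel_y[m]; hh <- hit[m]
    n_side <- 2L * ceiling(R / grid_h) + 1L
    ctr <- ceiling(R / grid_h) + 1L
    ix <- round(xx / grid_h) + ctr
    iy <- round(yy / grid_h) + ctr
    grid <- matrix(FALSE, n_side, n_side)
    sel <- hh & ix >= 1L & ix <= n_side & iy >= 1L & iy <= n_side
    grid[cbind(ix[sel], iy[sel])] <- TRUE
    lab <- label_components(grid)
    pts <- NULL
    if (max(lab) > 0L) {
      for (k in seq_len(max(lab))) {
        cidx <- which(lab == k, arr.ind = TRUE)
        area <- nrow(cidx) * grid_h^2
        if (area < min_area) next
        px <- (cidx[, 1] - ctr) * grid_h
        py <- (cidx[, 2] - ctr) * grid_h
        if (max(sqrt(px^2 + py^2)) > (1 - exclude_outer) * R) next
        pts <- rbind(pts, c(mean(px), mean(py)))
      }
    }
    pp <- structure(list(
      points = if (is.null(pts)) data.frame(x = numeric(0), y = numeric(0))
               else data.frame(x = pts[, 1], y = pts[, 2]),
      radius = R, source = "observed"), class = "point_pattern")
    out[[as.character(id)]] <- pp
  }
  attr(out, "threshold") <- exp(thr)
  out
}

# 8-connectivity component labelling of a logical matrix (BFS)
label_components <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  cl <- 0L
  nr <- nrow(m); nc <- ncol(m)
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!m[i0, j0] || lab[i0, j0] != 0L) next
    cl <- cl + 1L
    queue <- matrix(c(i0, j0), 1L)
    lab[i0, j0] <- cl
    while (nrow(queue) > 0L) {
      i <- queue[1L, 1L]; j <- queue[1L, 2L]
      queue <- queue[-1L, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
        if (m[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cl
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

#' Nearest-neighbour distances, histogram and entropy of a point pattern
#'
#' For each point, the Euclidean distance to its nearest other point; the
#' distances are histogrammed on fixed bins (default 20 equal bins spanning
#' `[0, radius/2]`) and the Shannon entropy (bits) of the normalised histogram
#' is reported. Fixed common bins keep histograms comparable across patterns.
#'
#' @param pattern a `point_pattern` with at least 2 points.
#' @param n_bins number of histogram bins.
#' @param bin_max upper edge of the histogram (micrometres); defaults to
#'   `radius / 2`. Distances beyond it are counted in the last bin.
#' @return An `nn_stats` object: `distances`, `breaks`, `counts`, `p`
#'   (normalised histogram) and `entropy` (bits).
#' @examples
#' pp <- generate_point_pattern(pattern_spec("uniform-random", n_points = 30,
#'                                           radius = 1500, seed = 2))
#' nn_distances(pp)
#' @export
nn_distances <- function(pattern, n_bins = 20, bin_max = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- nrow(pattern$points)
  if (n < 2L) stop("statistic error: nearest-neighbour statistics need >= 2 points")
  d <- as.matrix(stats::dist(pattern$points))
  diag(d) <- Inf
  nn <- unname(apply(d, 1L, min))
  if (is.null(bin_max)) bin_max <- pattern$radius / 2
  breaks <- seq(0, bin_max, length.out = n_bins + 1L)
  counts <- graphics::hist(pmin(nn, bin_max - 1e-12), breaks = breaks,
                           plot = FALSE)$counts
  p <- counts / sum(counts)
  structure(list(distances = nn, breaks = breaks, counts = counts, p = p,
                 entropy = shannon_entropy(p), n = n,
                 radius = pattern$radius, source = pattern$source),
            class = "nn_stats")
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @export
print.nn_stats <- function(x, ...) {
  cat(sprintf("<nn_stats> %s: n = %d, mean NN = %.1f um, entropy = %.3f bits\n",
              x$source, x$n, mean(x$distances), x$entropy))
  invisible(x)
}

# Jensen-Shannon divergence (bits) between two probability vectors
jsd_bits <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    sel <- a > 0
    sum(a[sel] * log2(a[sel] / b[sel]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Jensen-Shannon divergence between two NN-distance histograms
#'
#' Base-2 JSD between the normalised histograms of two [nn_distances()]
#' results; symmetric, bounded in \[0, 1\] bit, 0 iff the histograms are
#' identical. The two histograms must share bin edges.
#'
#' @param obs,ref `nn_stats` objects with identical `breaks`.
#' @return JSD in bits.
#' @export
compare_distributions <- function(obs, ref) {
  stopifnot(inherits(obs, "nn_stats"), inherits(ref, "nn_stats"))
  if (length(obs$breaks) != length(ref$breaks) ||
      any(abs(obs$breaks - ref$breaks) > 1e-9))
    stop("input error: histograms have mismatched bins")
  jsd_bits(obs$p, ref$p)
}

#' Monte-Carlo test of a point pattern against a reference null
#'
#' Generates `n_null` null patterns with matched point count and domain
#' radius (via [generate_point_pattern()]), pools their NN distances into a
#' reference histogram, and uses the JSD of a pattern's histogram to the
#' pooled-null histogram as the test statistic. The p-value is the add-one
#' Monte-Carlo estimate
#' `p = (1 + #\{JSD_null_i >= JSD_obs\}) / (n_null + 1)`.
#'
#' @param obs a `point_pattern` (>= 2 points).
#' @param null_kind `"uniform-random"`, `"jittered-hex"` or `"rd-maxima"`.
#' @param n_null number of null patterns (>= 99).
#' @param seed integer seed (drives all null generation; fixed seed gives an
#'   identical p-value).
#' @param n_bins,bin_max histogram binning, as in [nn_distances()].
#' @param jitter jitter SD for the jittered-hex null (micrometres).
#' @param field `rd_sim` for the rd-maxima null.
#' @return An `nn_test` object: the observed `nn_stats`, `jsd_obs`,
#'   `jsd_null` (vector), `p_value`, `n_null` and the binning.
#' @examples
#' obs <- generate_point_pattern(pattern_spec("uniform-random", n_points = 20,
#'                                            radius = 1000, seed = 4))
#' tst <- mc_test(obs, n_null = 99, seed = 9)
#' tst$p_value
#' @export
mc_test <- function(obs, null_kind = c("uniform-random", "jittered-hex",
                                       "rd-maxima"),
                    n_null = 999, seed = 1L, n_bins = 20, bin_max = NULL,
                    jitter = 0, field = NULL) {
  stopifnot(inherits(obs, "point_pattern"))
  null_kind <- match.arg(null_kind)
  if (n_null < 99) stop("n_null must be >= 99")
  n <- nrow(obs$points)
  if (n < 2L) stop("statistic error: need >= 2 observed points")
  R <- obs$radius
  if (is.null(bin_max)) bin_max <- R / 2
  obs_stats <- nn_distances(obs, n_bins = n_bins, bin_max = bin_max)

  null_counts <- matrix(0L, n_null, n_bins)
  breaks <- obs_stats$breaks
  for (i in seq_len(n_null)) {
    sp <- pattern_spec(null_kind, n_points = n, radius = R, jitter = jitter,
                       field = field, seed = seed + i)
    pat <- generate_point_pattern(sp)
    if (nrow(pat$points) != n)
      stop("test error: matched-count generation failure for null ", i)
    st <- nn_distances(pat, n_bins = n_bins, bin_max = bin_max)
    null_counts[i, ] <- st$counts
  }
  pooled <- colSums(null_counts)
  pooled_p <- pooled / sum(pooled)
  jsd_obs <- jsd_bits(obs_stats$p, pooled_p)
  jsd_null <- apply(null_counts, 1L, function(cnt) {
    jsd_bits(cnt / sum(cnt), pooled_p)
  })
  p_val <- (1 + sum(jsd_null >= jsd_obs)) / (n_null + 1)
  structure(list(obs = obs_stats, jsd_obs = jsd_obs, jsd_null = jsd_null,
                 p_value = p_val, n_null = n_null, null_kind = null_kind,
                 breaks = breaks, seed = seed),
            class = "nn_test")
}

#' @export
print.nn_test <- function(x, ...) {
  cat(sprintf("<nn_test> observed vs %s null (n_null = %d)\n",
              x$null_kind, x$n_null))
  cat(sprintf("  JSD(obs, pooled null) = %.4f bits; Monte-Carlo p = %.4g\n",
              x$jsd_obs, x$p_value))
  invisible(x)
}

#' @export
plot.nn_test <- function(x, ...) {
  graphics::hist(x$jsd_null, breaks = 30, main = "null JSD distribution",
                 xlab = "JSD (bits)", ...)
  graphics::abline(v = x$jsd_obs, col = 2, lwd = 2)
  invisible(x)
}
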