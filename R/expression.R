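# Embryoid-body assay expression analysis: delta-delta-Ct relative expression
# and k-means clustering of cell lines into Strong/Intermediate/Weak
# responders per gene.

#' Delta-delta-Ct log2 fold changes
#'
#' Computes relative expression by the delta-delta cycle threshold method:
#' within each (line, day, replicate), `dCt = Ct_gene - Ct_reference`; then
#' `ddCt = dCt - mean dCt(line, baseline day)` per (line, gene); the log2 fold
#' change is `-ddCt` and the fold change `2^(-ddCt)`. Replicate-level values
#' are retained alongside the per-(line, gene, day) means. Day-0 mean log2FC
#' is 0 by construction. A plate-wide constant added to every Ct of a
#' (line, day, replicate) cancels in `dCt`.
#'
#' @param ct `data.frame(line, gene, day, replicate, ct)` including the
#'   reference gene for every (line, day, replicate) and baseline-day rows
#'   for every line.
#' @param reference_gene housekeeping gene name (default `"GAPDH"`).
#' @param baseline_day baseline day (default 0).
#' @return A `log2fc` object: `data.frame(line, gene, day, replicate, dct,
#'   ddct, log2fc, fold_change)` (reference gene excluded), with the
#'   per-(line, gene, day) means in `attr(, "means")`.
#' @examples
#' sp <- qpcr_spec(lines = c("A", "B"), genes = "T", noise_sd = 0,
#'                 planted_log2fc = function(g, cl, d) d)
#' fc <- ddct_log2fc(generate_qpcr(sp))
#' @export
ddct_log2fc <- function(ct, reference_gene = "GAPDH", baseline_day = 0) {
  need <- c("line", "gene", "day", "replicate", "ct")
  stopifnot(is.data.frame(ct), all(need %in% names(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("input error: Ct values must be finite and > 0")
  ref <- ct[ct$gene == reference_gene, ]
  tgt <- ct[ct$gene != reference_gene, ]
  if (nrow(ref) == 0L)
    stop("input error: reference gene '", reference_gene, "' absent")
  key <- function(d) paste(d$line, d$day, d$replicate)
  ref_ct <- ref$ct[match(key(tgt), key(ref))]
  if (any(is.na(ref_ct))) {
    miss <- tgt[is.na(ref_ct), ][1L, ]
    stop("input error: reference gene missing for line ", miss$line,
         ", day ", miss$day, ", replicate ", miss$replicate)
  }
  tgt$dct <- tgt$ct - ref_ct
  base_key <- paste(tgt$line, tgt$gene)
  bsel <- tgt$day == baseline_day
  if (!any(bsel)) stop("input error: no baseline-day rows")
  base_mean <- tapply(tgt$dct[bsel], base_key[bsel], mean)
  b <- base_mean[base_key]
  if (any(is.na(b))) {
    miss <- tgt[is.na(b), ][1L, ]
    stop("input error: baseline day ", baseline_day, " missing for line ",
         miss$line, ", gene ", miss$gene)
  }
  tgt$ddct <- tgt$dct - as.numeric(b)
  tgt$log2fc <- -tgt$ddct
  tgt$fold_change <- 2^tgt$log2fc
  means <- stats::aggregate(log2fc ~ line + gene + day, data = tgt, FUN = mean)
  out <- tgt[order(tgt$line, tgt$gene, tgt$day, tgt$replicate), ]
  rownames(out) <- NULL
  attr(out, "means") <- means
  attr(out, "reference_gene") <- reference_gene
  attr(out, "baseline_day") <- baseline_day
  class(out) <- c("log2fc", "data.frame")
  out
}

#' Wide per-line feature matrix of mean log2 fold changes
#'
#' @param fc a [ddct_log2fc()] result.
#' @param gene gene to extract.
#' @param days days used as features (default all non-baseline days).
#' @return Matrix lines x days of mean log2FC.
#' @export
log2fc_features <- function(fc, gene, days = NULL) {
  means <- attr(fc, "means")
  m <- means[means$gene == gene, ]
  if (is.null(days)) days <- sort(unique(m$day[m$day != attr(fc, "baseline_day")]))
  lines <- sort(unique(m$line))
  M <- matrix(NA_real_, length(lines), length(days),
              dimnames = list(lines, paste0("day", days)))
  for (i in seq_along(days)) {
    mi <- m[m$day == days[i], ]
    M[match(mi$line, lines), i] <- mi$log2fc
  }
  if (any(is.na(M)))
    stop("incomplete day trajectories for gene ", gene)
  M
}

#' Cluster cell lines into Strong/Intermediate/Weak responders
#'
#' Unsupervised k-means (k = 3) on each line's mean log2 fold-change
#' trajectory (days 1..3 by default, unstandardised - the clusters separate by
#' expression magnitude). Clusters are named `Strong`, `Intermediate` and
#' `Weak` in descending order of their centre's mean log2FC, so the labels are
#' content-based and invariant to line order.
#'
#' @param fc a [ddct_log2fc()] result.
#' @param gene gene to cluster on.
#' @param seed integer seed (k-means restarts are seeded; fixed seed gives
#'   deterministic labels).
#' @param n_init number of random restarts (`nstart`).
#' @param days feature days; default all non-baseline days.
#' @return A `responder_clusters` object: `data.frame(line, label)` plus the
#'   fitted centres and the total within-cluster sum of squares.
#' @examples
#' sp <- qpcr_spec(lines = sprintf("L%d", 1:6), genes = "T",
#'                 line_cluster = rep(1:3, each = 2), noise_sd = 0.1,
#'                 planted_log2fc = function(g, cl, d) c(4, 1, -2)[cl] * (d > 0))
#' fc <- ddct_log2fc(generate_qpcr(sp))
#' cluster_responders(fc, "T", seed = 1)
#' @export
cluster_responders <- function(fc, gene, seed = 1L, n_init = 50, days = NULL) {
  M <- log2fc_features(fc, gene, days)
  if (nrow(M) < 3L)
    stop("clustering error: need >= 3 lines with complete trajectories")
  if (nrow(unique(M)) == 1L)
    stop("degenerate input: identical feature vectors across all lines")
  set.seed(seed)
  k <- min(3L, nrow(unique(M)))
  if (k == nrow(M)) {
    # k equals the number of lines: every line is its own cluster
    km <- list(cluster = seq_len(k), centers = M, tot.withinss = 0)
  } else {
    km <- stats::kmeans(M, centers = k, nstart = n_init, iter.max = 100L)
  }
  ord <- order(rowMeans(km$centers), decreasing = TRUE)
  lab_names <- c("Strong", "Intermediate", "Weak")[seq_len(k)]
  relabel <- character(k)
  relabel[ord] <- lab_names
  labels <- factor(relabel[km$cluster], levels = c("Strong", "Intermediate", "Weak"))
  centres <- km$centers[ord, , drop = FALSE]
  rownames(centres) <- lab_names
  structure(list(assignments = data.frame(line = rownames(M), label = labels),
                 centres = centres, tot_withinss = km$tot.withinss,
                 gene = gene, features = M),
            class = "responder_clusters")
}

#' @export
print.responder_clusters <- function(x, ...) {
  cat(sprintf("<responder_clusters> gene %s (k-means, k = %d)\n",
              x$gene, nrow(x$centres)))
  for (lv in levels(x$assignments$label)) {
    memb <- x$assignments$line[x$assignments$label == lv]
    if (length(memb))
      cat(sprintf("  %-12s %s\n", lv, paste(memb, collapse = ", ")))
  }
  invisible(x)
}
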