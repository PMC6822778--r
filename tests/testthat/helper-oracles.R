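# Independent brute-force oracles used to validate the package implementations.

# DBSCAN oracle: dense neighbour graph at radius eps; core points have degree
# >= min_samples - 1 (self excluded); clusters = connected components over
# core points, numbered by smallest core index; border points attach to the
# lowest-numbered reachable cluster.
oracle_dbscan <- function(x, y, eps, min_samples) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  adj <- d <= eps
  diag(adj) <- FALSE
  core <- rowSums(adj) >= (min_samples - 1)
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    comp <- i
    repeat {
      grow <- which(core & labels == 0L &
                      apply(adj[, comp, drop = FALSE], 1, any))
      grow <- setdiff(grow, comp)
      if (length(grow) == 0L) break
      comp <- c(comp, grow)
    }
    labels[comp] <- cl
  }
  for (i in which(!core)) {
    cls <- labels[adj[i, ] & core]
    cls <- cls[cls > 0L]
    if (length(cls)) labels[i] <- min(cls)
  }
  labels
}

# exhaustive k = 3 partition optimum: minimal total within-cluster SS
oracle_kmeans3_wss <- function(M) {
  n <- nrow(M)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    ks <- unique(assign)
    if (length(ks) == 3L) {
      wss <- 0
      for (k in ks) {
        rows <- M[assign == k, , drop = FALSE]
        ctr <- colMeans(rows)
        wss <- wss + sum(sweep(rows, 2, ctr)^2)
      }
      best <- min(best, wss)
    }
    # increment base-3 counter
    i <- n
    while (i > 0L && assign[i] == 3L) { assign[i] <- 1L; i <- i - 1L }
    if (i == 0L) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# naive Otsu: for every candidate split of the sorted data recompute the
# between-class variance from scratch
oracle_otsu <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- -Inf
  thr <- NA_real_
  for (k in 1:(n - 1)) {
    if (xs[k] == xs[k + 1]) next
    a <- xs[1:k]; b <- xs[(k + 1):n]
    bcv <- (length(a) / n) * (length(b) / n) * (mean(a) - mean(b))^2
    if (bcv > best) { best <- bcv; thr <- (xs[k] + xs[k + 1]) / 2 }
  }
  thr
}

# direct evaluation of the Jensen-Shannon divergence sum, base 2
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log2(q[i] / m[i])
  }
  s
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sij <- ch2(as.vector(tab))
  si <- ch2(rowSums(tab)); sj <- ch2(colSums(tab))
  N <- ch2(sum(tab))
  (sij - si * sj / N) / ((si + sj) / 2 - si * sj / N)
}
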