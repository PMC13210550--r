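#' Column z-score standardization
#'
#' Centres and scales each column to mean 0, SD 1 (n - 1 denominator).
#' Constant columns cannot be scaled; they are dropped with a warning.
#' Column means and SDs are kept as attributes so the transform can be
#' inverted or applied to new rows.
#'
#' @param x numeric matrix or data frame with >= 2 rows.
#' @return matrix of class `std_matrix` with attributes `center` and
#'   `scale` (and `dropped`, the removed constant columns, if any).
#' @export
zscore_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to standardize")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  const <- scl == 0 | !is.finite(scl)
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[const], collapse = ", "))
  }
  z <- scale(x[, !const, drop = FALSE], center = ctr[!const],
             scale = scl[!const])
  out <- z[, , drop = FALSE]
  attr(out, "center") <- ctr[!const]
  attr(out, "scale") <- scl[!const]
  attr(out, "dropped") <- colnames(x)[const]
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  class(out) <- c("std_matrix", class(out))
  out
}

sqdist_to <- function(x, centers) {
  # n x k matrix of squared Euclidean distances
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, `+`) - 2 * x %*% t(centers)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k > 1) for (j in 2:k) {
    d2 <- apply(sqdist_to(x, centers[seq_len(j - 1), , drop = FALSE]),
                1, min)
    d2 <- pmax(d2, 0)
    pick <- if (sum(d2) == 0) sample.int(n, 1) else
      sample.int(n, 1, prob = d2)
    centers[j, ] <- x[pick, ]
  }
  centers
}

lloyd <- function(x, centers, max_iter) {
  n <- nrow(x); k <- nrow(centers)
  trace <- numeric(0)
  assign <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- sqdist_to(x, centers)
    new_assign <- max.col(-d2, ties.method = "first")
    # refill any emptied cluster with the worst-fit point
    for (j in which(tabulate(new_assign, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(n), new_assign)])
      new_assign[far] <- j
      d2[far, ] <- Inf; d2[far, j] <- 0
    }
    wss <- sum(d2[cbind(seq_len(n), new_assign)])
    trace <- c(trace, wss)
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  }
  # recompute final WSS against the updated centers
  d2 <- sqdist_to(x, centers)
  wss <- sum(d2[cbind(seq_len(n), assign)])
  trace <- c(trace, wss)
  list(assign = assign, centers = centers, wss = wss, trace = trace)
}

#' K-means clustering with k-means++ restarts
#'
#' The multi-trait clustering protocol: Lloyd's algorithm started from
#' k-means++ seedings, repeated `n_restarts` times (default 25), keeping
#' the solution with the lowest total within-cluster sum of squares.
#' Each run records its WSS trace, which is checked to be non-increasing
#' across iterations. The mean silhouette width
#' (via [cluster::silhouette()]) is attached when `2 <= k <= n - 1`.
#' A warning is issued when there are fewer than `2 * k` rows, as
#' silhouettes on so few points are fragile.
#'
#' @param x numeric matrix (typically a [zscore_matrix()]).
#' @param k number of clusters, `1 <= k <= nrow(x)`.
#' @param n_restarts independent k-means++ starts (default 25).
#' @param max_iter Lloyd iteration cap per run (default 300).
#' @param seed optional integer seed for the restart stream.
#' @return An object of class `cluster_result`: list with `k`,
#'   `assignments`, `centroids`, `tot_withinss`, `silhouette`,
#'   `wss_trace` (best run), `restart_wss`, `n_restarts`.
#' @export
kmeans_fit <- function(x, k, n_restarts = 25, max_iter = 300,
                       seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must lie in [1, nrow(x)]")
  if (n < 2 * k) warning("fewer than 2*k rows; cluster statistics are fragile")
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  restart_wss <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    run <- lloyd(x, kmeanspp_init(x, k), max_iter)
    if (any(diff(run$trace) > 1e-8 * (1 + run$trace[1])))
      stop("internal error: WSS increased during Lloyd iterations")
    restart_wss[r] <- run$wss
    if (is.null(best) || run$wss < best$wss) best <- run
  }
  sil <- NA_real_
  if (k >= 2 && k <= n - 1) {
    s <- cluster::silhouette(best$assign, stats::dist(x))
    sil <- mean(s[, "sil_width"])
  }
  out <- list(k = k,
              assignments = stats::setNames(best$assign, rownames(x)),
              centroids = best$centers,
              tot_withinss = best$wss,
              silhouette = sil,
              wss_trace = best$trace,
              restart_wss = restart_wss,
              n_restarts = n_restarts)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("k-means (k = %d, %d restarts): WSS = %.4g, mean silhouette = %s\n",
              x$k, x$n_restarts, x$tot_withinss,
              ifelse(is.na(x$silhouette), "NA",
                     sprintf("%.3f", x$silhouette))))
  print(x$assignments)
  invisible(x)
}

#' Select k by silhouette, with the elbow curve for inspection
#'
#' Fits [kmeans_fit()] for every k in `k_range` and returns the k that
#' maximizes the mean silhouette width (ties resolved to the smaller
#' k). The elbow curve (total WSS against k) is returned alongside for
#' visual confirmation.
#'
#' @inheritParams kmeans_fit
#' @param k_range integer candidates within `[2, nrow(x) - 1]`.
#' @return list with `k_best`, `elbow` (data frame `k`, `wss`),
#'   `silhouette` (data frame `k`, `mean_silhouette`), and `fits`.
#' @export
select_k <- function(x, k_range = NULL, n_restarts = 25, max_iter = 300,
                     seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(k_range)) k_range <- 2:(n - 1)
  if (length(k_range) == 0) stop("empty k range")
  if (any(k_range < 2 | k_range > n - 1))
    stop("k_range must lie within [2, nrow(x) - 1]")
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(k_range, function(k)
    kmeans_fit(x, k, n_restarts = n_restarts, max_iter = max_iter))
  sils <- vapply(fits, `[[`, 1, "silhouette")
  wss <- vapply(fits, `[[`, 1, "tot_withinss")
  k_best <- k_range[which.max(sils)]   # which.max takes the first maximum
  list(k_best = k_best,
       elbow = data.frame(k = k_range, wss = wss),
       silhouette = data.frame(k = k_range, mean_silhouette = sils),
       fits = stats::setNames(fits, paste0("k", k_range)))
}

#' Principal component projection
#'
#' Eigendecomposition of the covariance of the (already standardized)
#' input; on z-scored data this is the correlation-structure PCA. The
#' sign of each component is fixed by making its largest-magnitude
#' loading positive, so projections are reproducible.
#'
#' @param x numeric matrix, usually a [zscore_matrix()].
#' @param n_components number of components to return (<= rank).
#' @return list with `scores` (centred), `explained` (variance
#'   fractions, non-increasing), `loadings`.
#' @export
pca_project <- function(x, n_components = 2) {
  x <- as.matrix(x)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-10)
  if (n_components > rank)
    stop("n_components exceeds the matrix rank (", rank, ")")
  keep <- seq_len(n_components)
  load <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  for (j in keep) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  list(scores = scores, explained = ev[keep] / sum(ev), loadings = load)
}

#' Genotype-level multi-trait profile matrix
#'
#' Collapses a trial table to one row per genotype: the mean of each
#' indicator over all years and blocks. This is the matrix fed to
#' clustering and TOPSIS.
#'
#' @param table a `trait_table`.
#' @param indicators indicator columns to keep (default: all numeric
#'   columns after genotype/year/block).
#' @return numeric matrix, genotypes x indicators.
#' @export
genotype_profile <- function(table, indicators = NULL) {
  if (is.null(indicators))
    indicators <- setdiff(names(table), c("genotype", "year", "block",
                                          "plant"))
  g <- factor(table$genotype)
  m <- sapply(indicators, function(j) tapply(table[[j]], g, mean))
  m <- matrix(m, nrow = nlevels(g),
              dimnames = list(levels(g), indicators))
  m
}
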