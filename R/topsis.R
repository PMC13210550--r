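#' Proportion normalization of a decision matrix
#'
#' First stage of the entropy-weighting procedure: each entry is divided
#' by its column sum,
#' \deqn{p_{ij} = x_{ij} / \sum_{i=1}^n x_{ij},}
#' so every column becomes a probability vector. Strict positivity is
#' required: with zero or negative entries the proportions (and the
#' entropies computed from them) are undefined. Callers with z-scored or
#' otherwise signed data should rescale first (see the `rescale` flag of
#' [topsis_rank()]).
#'
#' @param x n x m numeric matrix, all entries > 0, n >= 2.
#' @return matrix of column-wise proportions (columns sum to 1).
#' @export
proportion_normalize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 alternatives")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("decision matrix must be strictly positive; ",
         "rescale signed/zero data before normalizing ",
         "(e.g. min-max to [0.05, 1])")
  sweep(x, 2, colSums(x), `/`)
}

#' Entropy-based objective indicator weights
#'
#' Stages two to four of the entropy-weight method. Per indicator j the
#' Shannon entropy of its proportion column,
#' \deqn{e_j = -\frac{1}{\ln n} \sum_{i=1}^n p_{ij} \ln p_{ij}}
#' (with the convention \eqn{0 \cdot \ln 0 = 0}), the dispersion
#' \eqn{d_j = 1 - e_j}, and the normalized weight
#' \eqn{w_j = d_j / \sum_j d_j}. Indicators whose values differ more
#' across alternatives carry more information and receive larger
#' weights; a perfectly uniform column has maximal entropy and zero
#' weight.
#'
#' @param p proportion matrix from [proportion_normalize()] (or a raw
#'   strictly positive matrix, which is normalized first).
#' @return An object of class `entropy_weights`: list with `p`, `e`,
#'   `d`, `w` (weights sum to 1).
#' @export
entropy_weights <- function(p) {
  p <- as.matrix(p)
  if (any(abs(colSums(p) - 1) > 1e-8)) p <- proportion_normalize(p)
  n <- nrow(p)
  if (n < 2) stop("need at least 2 alternatives")
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- -colSums(plogp) / log(n)
  e <- pmin(pmax(e, 0), 1)       # clamp tiny FP excursions
  d <- 1 - e
  if (sum(d) == 0)
    stop("degenerate weights: every indicator column is uniform")
  w <- d / sum(d)
  structure(list(p = p, e = e, d = d, w = w), class = "entropy_weights")
}

#' @export
print.entropy_weights <- function(x, digits = 3, ...) {
  cat("Entropy weights over", length(x$w), "indicators\n")
  print(round(rbind(entropy = x$e, dispersion = x$d, weight = x$w),
              digits))
  invisible(x)
}

#' Entropy-weighted TOPSIS ranking of alternatives
#'
#' Ranks the rows of a strictly positive decision matrix by closeness to
#' the ideal solution. The weighted normalized matrix is
#' \eqn{v_{ij} = w_j p_{ij}} with entropy weights (or user-supplied
#' `weights`). The ideal solution \eqn{V^+} takes, per indicator, the
#' maximum weighted value for benefit-type indicators and the minimum
#' for cost-type indicators; the anti-ideal \eqn{V^-} is defined
#' conversely. With Euclidean distances \eqn{D_i^\pm} to the two
#' solutions, the closeness coefficient is
#' \deqn{C_i = D_i^- / (D_i^+ + D_i^-) \in [0, 1],}
#' larger meaning better overall multi-trait performance. Ranks are
#' dense: ties in \eqn{C_i} share a rank.
#'
#' Note that under entropy weights, duplicating an indicator column
#' changes the weight vector and hence can change \eqn{C_i}; closeness
#' is only invariant to duplication when weights are held fixed
#' externally. Rescaling any raw column by a positive constant leaves
#' everything unchanged (proportions are scale-free).
#'
#' @param x n x m decision matrix; row names are the alternatives,
#'   column names must match the schema indicators.
#' @param schema a [trait_schema()] supplying benefit/cost directions.
#' @param weights optional fixed weight vector (sums to 1); default
#'   computes entropy weights from `x`.
#' @param rescale if `TRUE`, min-max rescale each column to
#'   `[0.05, 1]` first, allowing signed (e.g. z-scored) input.
#' @return An object of class `topsis`: list with `v`, `ideal`,
#'   `anti_ideal`, `d_pos`, `d_neg`, `closeness`, `rank`, `weights`
#'   (the [entropy_weights()] object or supplied vector), `schema`.
#' @examples
#' x <- generate_decision_fixture(5, dominant = "A", seed = 1)
#' topsis_rank(x)
#' @export
topsis_rank <- function(x, schema = trait_schema(), weights = NULL,
                        rescale = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- schema$indicator
  miss <- setdiff(colnames(x), schema$indicator)
  if (length(miss))
    stop("columns not in schema: ", paste(miss, collapse = ", "))
  dir <- schema$direction[match(colnames(x), schema$indicator)]
  if (rescale) {
    x <- apply(x, 2, function(col) {
      rng <- range(col)
      if (diff(rng) == 0) rep(0.525, length(col)) else
        0.05 + 0.95 * (col - rng[1]) / diff(rng)
    })
  }
  p <- proportion_normalize(x)
  if (is.null(weights)) {
    ew <- entropy_weights(p)
    w <- ew$w
  } else {
    if (length(weights) != ncol(x) || any(weights < 0))
      stop("weights must be non-negative, one per indicator")
    w <- weights / sum(weights)
    ew <- w
  }
  v <- sweep(p, 2, w, `*`)
  ideal <- ifelse(dir == "benefit", apply(v, 2, max), apply(v, 2, min))
  anti <- ifelse(dir == "benefit", apply(v, 2, min), apply(v, 2, max))
  d_pos <- sqrt(rowSums(sweep(v, 2, ideal)^2))
  d_neg <- sqrt(rowSums(sweep(v, 2, anti)^2))
  if (all(d_pos + d_neg == 0))
    stop("undefined closeness: all alternatives identical")
  closeness <- d_neg / (d_pos + d_neg)
  # dense ranks, ties share a rank
  rk <- match(closeness, sort(unique(closeness), decreasing = TRUE))
  structure(list(v = v, ideal = ideal, anti_ideal = anti,
                 d_pos = d_pos, d_neg = d_neg,
                 closeness = stats::setNames(closeness, rownames(x)),
                 rank = stats::setNames(rk, rownames(x)),
                 weights = ew, schema = schema),
            class = "topsis")
}

#' @export
print.topsis <- function(x, ...) {
  cat("Entropy-weighted TOPSIS ranking\n")
  df <- data.frame(alternative = names(x$closeness),
                   d_pos = round(x$d_pos, 4), d_neg = round(x$d_neg, 4),
                   closeness = round(x$closeness, 4), rank = x$rank)
  print.data.frame(df[order(df$rank), ], row.names = FALSE)
  invisible(x)
}

#' @export
summary.topsis <- function(object, ...) {
  w <- if (inherits(object$weights, "entropy_weights"))
    object$weights$w else object$weights
  cat("Indicator weights (2 dp for display; full precision retained):\n")
  print(round(w, 2))
  print(object)
  invisible(object)
}

#' @export
plot.topsis <- function(x, ...) {
  ord <- order(x$closeness, decreasing = TRUE)
  graphics::barplot(x$closeness[ord], ylim = c(0, 1),
                    ylab = "closeness coefficient C",
                    main = "TOPSIS closeness", ...)
  invisible(x)
}

#' Build the genotype x indicator decision matrix from a trial table
#'
#' Aggregates a multi-year trial to per-genotype indicator means (over
#' all years and blocks) in schema column order — the matrix consumed by
#' [topsis_rank()].
#'
#' @param table a `trait_table`.
#' @param schema a [trait_schema()].
#' @return numeric matrix, genotypes x indicators.
#' @export
decision_matrix <- function(table, schema = trait_schema()) {
  ind <- intersect(schema$indicator, names(table))
  if (!length(ind)) stop("no schema indicators found in table")
  genotype_profile(table, ind)
}
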