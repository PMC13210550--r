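#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries of two
#' symmetric zero-diagonal distance matrices, with significance from
#' simultaneous row/column permutations of the second matrix:
#' \deqn{p = (\#\{r_{perm} \ge r_{obs}\} + 1) / (n_{perm} + 1)}
#' (one-tailed "greater", the usual framing for positive association;
#' `alternative = "two.sided"` doubles the smaller tail). The +1
#' correction means p can never be exactly zero.
#'
#' @param d1,d2 symmetric numeric matrices (or `dist` objects) of the
#'   same dimension >= 4, zero diagonal.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional integer seed for the permutation stream.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An object of class `mantel_result`: list with `r`, `p.value`,
#'   `n_perm`, `alternative`, `seed`.
#' @examples
#' x <- matrix(rnorm(20), 10)
#' d <- as.matrix(dist(x))
#' mantel_test(d, d)$r   # 1
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  check_dist <- function(d, nm) {
    if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
      stop(nm, " must be a symmetric square matrix")
    if (any(abs(diag(d)) > 1e-8)) stop(nm, " must have a zero diagonal")
  }
  check_dist(d1, "d1"); check_dist(d2, "d2")
  n <- nrow(d1)
  if (n != nrow(d2)) stop("d1 and d2 must have the same dimension")
  if (n < 4) stop("need at least 4 objects")
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  r_obs <- stats::cor(v1, d2[lt])
  r_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    stats::cor(v1, d2[idx, idx][lt])
  }, numeric(1))
  p <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  if (alternative == "two.sided") {
    p_lo <- (sum(r_perm <= r_obs) + 1) / (n_perm + 1)
    p <- min(1, 2 * min(p, p_lo))
  }
  structure(list(r = r_obs, p.value = p, n_perm = n_perm,
                 alternative = alternative, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, %s)\n",
              x$r, x$p.value, x$n_perm, x$alternative))
  invisible(x)
}
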