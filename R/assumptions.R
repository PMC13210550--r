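#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS distance between the sample's empirical CDF and the normal
#' distribution with mean and SD estimated from the same sample. Because
#' parameters are estimated, the classic KS null distribution does not
#' apply; the p-value is obtained by Monte-Carlo simulation of the null
#' (standard-normal samples of the same size, statistic recomputed with
#' re-estimated parameters). The null distribution depends only on the
#' sample size, so it is simulated once per `n` (fixed internal seed,
#' caller RNG state untouched) and cached for the session; the p-value
#' is simulation-based with a resolution of about `1/n_rep`.
#'
#' @param x numeric sample, length >= 4, non-constant.
#' @param n_rep Monte-Carlo replicates for the null (default 10000).
#' @return list with `statistic` and `p.value`.
#' @examples
#' lilliefors_ks(rnorm(50))$p.value
#' @export
lilliefors_ks <- function(x, n_rep = 10000) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0) stop("constant sample: SD is zero")
  stat <- lillie_stat(x)
  null <- lillie_null(n, n_rep)
  list(statistic = stat,
       p.value = (sum(null >= stat) + 1) / (n_rep + 1))
}

lillie_stat <- function(x) {
  n <- length(x)
  u <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  i <- seq_len(n)
  max(i / n - u, u - (i - 1) / n)
}

.lillie_cache <- new.env(parent = emptyenv())

lillie_null <- function(n, n_rep) {
  key <- paste0("n", n, "_r", n_rep)
  if (!is.null(.lillie_cache[[key]])) return(.lillie_cache[[key]])
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(1485773L)
  null <- vapply(seq_len(n_rep),
                 function(i) lillie_stat(stats::rnorm(n)), numeric(1))
  .lillie_cache[[key]] <- null
  null
}

#' Median-based Levene (Brown-Forsythe) test of variance homogeneity
#'
#' One-way ANOVA F statistic on the absolute deviations of each
#' observation from its group median; this median-centred form is robust
#' to non-normality. The p-value comes from the F distribution with
#' (k - 1, N - k) degrees of freedom.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return list with `statistic`, `p.value`, `df`.
#' @export
levene_median <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 observations")
  dev <- lapply(groups, function(g) abs(g - stats::median(g)))
  k <- length(dev)
  ns <- vapply(dev, length, 1L)
  N <- sum(ns)
  means <- vapply(dev, mean, 1)
  grand <- sum(ns * means) / N
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum(vapply(seq_len(k),
                     function(i) sum((dev[[i]] - means[i])^2), 1))
  df <- c(k - 1L, N - k)
  if (ss_b <= .Machine$double.eps * abs(grand + 1))
    return(list(statistic = 0, p.value = 1, df = df))
  if (ss_w == 0)
    return(list(statistic = Inf, p.value = 0, df = df))
  f <- (ss_b / df[1]) / (ss_w / df[2])
  list(statistic = f, p.value = stats::pf(f, df[1], df[2],
                                          lower.tail = FALSE), df = df)
}

sample_skewness <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

sample_kurtosis <- function(x) {      # excess kurtosis
  m <- mean(x); v <- mean((x - m)^2)
  mean((x - m)^4) / v^2 - 3
}

#' Screen a trait for ANOVA distributional assumptions
#'
#' For each genotype x year cell: Lilliefors KS statistic and
#' Monte-Carlo p, sample skewness and excess kurtosis, and a normality
#' pass flag. A cell passes when `p >= 0.05`, or when it is marginal
#' (`0.01 < p < 0.05`) but `|skewness| < 2` and `|kurtosis| < 7`.
#' Variance homogeneity across all cells is assessed with the
#' median-based Levene test.
#'
#' @param table a `trait_table` (or data frame with `genotype`, `year`
#'   columns).
#' @param response indicator column name.
#' @param n_rep Monte-Carlo replicates for the Lilliefors p-values.
#' @return An `assumption_report`: list with `groups` (per-cell data
#'   frame) and `levene` (statistic, p.value).
#' @export
assumption_screen <- function(table, response, n_rep = 10000) {
  stopifnot(response %in% names(table))
  y <- table[[response]]
  cell <- interaction(table$genotype, table$year, drop = TRUE, sep = " x ")
  split_y <- split(y, cell)
  rows <- lapply(names(split_y), function(nm) {
    g <- split_y[[nm]]
    ks <- lilliefors_ks(g, n_rep = n_rep)
    sk <- sample_skewness(g); ku <- sample_kurtosis(g)
    data.frame(group = nm, n = length(g),
               ks_stat = ks$statistic, ks_p = ks$p.value,
               skewness = sk, kurtosis = ku,
               pass_normality = ks$p.value >= 0.05 ||
                 (ks$p.value > 0.01 && abs(sk) < 2 && abs(ku) < 7),
               stringsAsFactors = FALSE)
  })
  lev <- levene_median(split_y)
  out <- list(response = response, groups = do.call(rbind, rows),
              levene = lev)
  class(out) <- "assumption_report"
  out
}

#' @export
print.assumption_report <- function(x, ...) {
  cat("Assumption screen for '", x$response, "'\n", sep = "")
  cat("  cells passing normality:", sum(x$groups$pass_normality), "/",
      nrow(x$groups), "\n")
  cat(sprintf("  Levene (median-based): F = %.3f, p = %.4f\n",
              x$levene$statistic, x$levene$p.value))
  invisible(x)
}
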