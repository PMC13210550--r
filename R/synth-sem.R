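#' Ground truth for a linear-Gaussian path model
#'
#' Defines a DAG with standardized path coefficients from which unit
#' variance data can be simulated: exogenous variables are standard
#' normal, and each endogenous variable is the coefficient-weighted sum
#' of its (unit-variance) parents plus a Gaussian residual whose SD is
#' chosen so the variable has unit variance in expectation. With that
#' construction the planted coefficients are the standardized
#' coefficients an OLS refit should recover.
#'
#' @param paths data frame with columns `parent`, `child`, `coefficient`
#'   (standardized).
#' @param n sample size for simulation.
#' @param seed integer RNG seed.
#' @return An object of class `sem_ground_truth` with elements `paths`,
#'   `variables`, `order` (topological), `residual_sd` (per endogenous
#'   variable), `n`, `seed`.
#' @seealso [generate_sem_dataset()], [yield_path_truth()]
#' @export
sem_ground_truth <- function(paths, n = 10000, seed = 1) {
  stopifnot(is.data.frame(paths),
            all(c("parent", "child", "coefficient") %in% names(paths)))
  vars <- unique(c(paths$parent, paths$child))
  ord <- topo_sort(vars, paths[c("parent", "child")])
  endo <- unique(paths$child)
  res_var <- numeric(0)
  # implied covariance among the unit-variance variables, built in
  # topological order, gives each child's systematic variance
  S <- diag(length(vars)); dimnames(S) <- list(vars, vars)
  for (v in ord) {
    if (!v %in% endo) next
    pa <- paths$parent[paths$child == v]
    b <- paths$coefficient[paths$child == v]
    sys <- as.numeric(t(b) %*% S[pa, pa, drop = FALSE] %*% b)
    if (sys > 1 + 1e-8)
      stop("planted coefficients for '", v,
           "' imply variance > 1; reduce them")
    res_var[v] <- max(0, 1 - sys)
    S[v, vars] <- S[vars, v] <- as.numeric(S[vars, pa, drop = FALSE] %*% b)
    S[v, v] <- 1
  }
  structure(list(paths = paths, variables = vars, order = ord,
                 residual_sd = sqrt(res_var), n = as.integer(n),
                 seed = as.integer(seed)),
            class = "sem_ground_truth")
}

# Kahn's algorithm; errors on cycles
topo_sort <- function(vars, edges) {
  indeg <- stats::setNames(integer(length(vars)), vars)
  tab <- table(factor(edges$child, levels = vars))
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- names(indeg)[indeg == 0]
  while (length(avail)) {
    v <- sort(avail)[1]          # deterministic order
    avail <- setdiff(avail, v)
    out <- c(out, v)
    ch <- edges$child[edges$parent == v]
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) avail <- c(avail, c)
    }
  }
  if (length(out) != length(vars)) stop("graph is cyclic")
  out
}

#' @export
print.sem_ground_truth <- function(x, ...) {
  cat("Linear-Gaussian path-model ground truth:",
      length(x$variables), "variables,", nrow(x$paths), "paths, n =",
      x$n, "\n")
  print.data.frame(x$paths, row.names = FALSE)
  invisible(x)
}

#' Simulate data from a path-model ground truth
#'
#' Variables are generated in topological order; exogenous variables are
#' i.i.d. standard normal, endogenous variables follow the linear model
#' described in [sem_ground_truth()]. `set.seed(truth$seed)` is applied
#' on entry, so identical truths yield identical samples.
#'
#' @param truth a [sem_ground_truth()].
#' @return data frame with `truth$n` rows, one column per variable.
#' @export
generate_sem_dataset <- function(truth) {
  stopifnot(inherits(truth, "sem_ground_truth"))
  set.seed(truth$seed)
  n <- truth$n
  dat <- matrix(NA_real_, n, length(truth$variables),
                dimnames = list(NULL, truth$variables))
  endo <- unique(truth$paths$child)
  for (v in truth$order) {
    if (v %in% endo) {
      pa <- truth$paths$parent[truth$paths$child == v]
      b <- truth$paths$coefficient[truth$paths$child == v]
      dat[, v] <- dat[, pa, drop = FALSE] %*% b +
        stats::rnorm(n, 0, truth$residual_sd[[v]])
    } else {
      dat[, v] <- stats::rnorm(n)
    }
  }
  as.data.frame(dat)
}

#' Reference yield path model
#'
#' The package's default mediation structure for forage yield formation:
#' the genotype x year interaction drives stem diameter (-0.52) and ADF
#' (0.70); genotype drives plant height (-0.24); stem diameter (0.29),
#' ADF (-0.29) and plant height (0.54) feed hay yield; plant height also
#' feeds total hay yield (0.79). Genotype and the interaction are
#' represented as continuous unit-variance scores so every path carries
#' a single standardized coefficient.
#'
#' @param n sample size.
#' @param seed RNG seed.
#' @return a [sem_ground_truth()].
#' @export
yield_path_truth <- function(n = 10000, seed = 1) {
  paths <- data.frame(
    parent = c("gxy", "gxy", "genotype", "stem_diameter", "adf",
               "plant_height", "plant_height"),
    child = c("stem_diameter", "adf", "plant_height", "hay_yield",
              "hay_yield", "hay_yield", "total_hay_yield"),
    coefficient = c(-0.52, 0.70, -0.24, 0.29, -0.29, 0.54, 0.79),
    stringsAsFactors = FALSE
  )
  sem_ground_truth(paths, n = n, seed = seed)
}
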