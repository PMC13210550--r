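#' Specify a piecewise structural equation model
#'
#' A path model is a DAG given as one formula (or `"child ~ parent +
#' parent"` line) per endogenous variable. Variables never appearing on
#' a left-hand side are exogenous. The component equations are fitted
#' separately by OLS ([sem_fit()]); global fit is judged through the
#' d-separation basis set and Fisher's C rather than a joint covariance
#' model.
#'
#' @param ... formulas or character equation lines, or a single list of
#'   them.
#' @return An object of class `path_model`: list with `edges` (data
#'   frame `parent`, `child`), `variables`, `endogenous`, `exogenous`,
#'   `order` (topological).
#' @examples
#' m <- path_model(stem_diameter ~ gxy,
#'                 hay_yield ~ stem_diameter + plant_height)
#' basis_set(m)
#' @export
path_model <- function(...) {
  eqs <- list(...)
  if (length(eqs) == 1 && is.list(eqs[[1]]) && !inherits(eqs[[1]], "formula"))
    eqs <- eqs[[1]]
  parse_eq <- function(e) {
    if (is.character(e)) e <- stats::as.formula(e)
    if (!inherits(e, "formula") || length(e) != 3)
      stop("each equation must be 'child ~ parent + ...'")
    child <- all.vars(e[[2]])
    parents <- all.vars(e[[3]])
    if (length(child) != 1 || length(parents) < 1)
      stop("each endogenous variable needs exactly one LHS and >= 1 parent")
    data.frame(parent = parents, child = child, stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, lapply(eqs, parse_eq))
  if (anyDuplicated(edges)) stop("duplicate edge specified")
  vars <- unique(c(edges$parent, edges$child))
  ord <- topo_sort(vars, edges)       # errors on cycles
  endo <- unique(edges$child)
  structure(list(edges = edges, variables = vars, endogenous = endo,
                 exogenous = setdiff(vars, endo), order = ord),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat("Path model:", length(x$variables), "variables,",
      nrow(x$edges), "edges\n")
  for (v in x$endogenous) {
    pa <- x$edges$parent[x$edges$child == v]
    cat(" ", v, "~", paste(pa, collapse = " + "), "\n")
  }
  cat("  exogenous:", paste(x$exogenous, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a ground truth to its path model
#' @param truth a [sem_ground_truth()].
#' @return a [path_model()].
#' @export
as_path_model <- function(truth) {
  stopifnot(inherits(truth, "sem_ground_truth"))
  eqs <- lapply(unique(truth$paths$child), function(v) {
    pa <- truth$paths$parent[truth$paths$child == v]
    stats::as.formula(paste(v, "~", paste(pa, collapse = "+")))
  })
  path_model(eqs)
}

parents_of <- function(model, v)
  model$edges$parent[model$edges$child == v]

#' D-separation basis set of a path model
#'
#' For every pair of non-adjacent variables, one conditional
#' independence claim: the pair is independent given the union of both
#' variables' parents. The topologically later variable of the pair is
#' designated the regression response (ties resolved lexicographically
#' via the deterministic topological order). A saturated DAG yields an
#' empty basis set.
#'
#' @param model a [path_model()].
#' @return list of claims, each a list with `response`, `other`,
#'   `conditioning` (character vector, possibly empty).
#' @export
basis_set <- function(model) {
  stopifnot(inherits(model, "path_model"))
  vars <- model$order
  adj <- paste(model$edges$parent, model$edges$child)
  claims <- list()
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (i >= j) next
    a <- vars[i]; b <- vars[j]      # b is topologically later
    if (paste(a, b) %in% adj || paste(b, a) %in% adj) next
    cond <- setdiff(union(parents_of(model, a), parents_of(model, b)),
                    c(a, b))
    claims[[length(claims) + 1]] <-
      list(response = b, other = a, conditioning = sort(cond))
  }
  claims
}

#' Fisher's C combination of independence-claim p-values
#'
#' \deqn{C = -2 \sum_i \ln p_i} over the k basis-set claim p-values;
#' under the hypothesis that the model has no missing paths, C follows
#' a chi-square distribution with `2k` degrees of freedom, and a
#' non-significant upper-tail p indicates acceptable fit. p-values of
#' exactly zero (numerical underflow) are floored at 1e-300 with a
#' warning by default, or rejected with `zero_p = "error"`. An empty
#' claim list is a saturated model: C = 0, df = 0, p = 1 (with a
#' warning).
#'
#' @param claim_p numeric vector of p-values in (0, 1].
#' @param zero_p `"floor"` (default) or `"error"` for p = 0 entries.
#' @return list with `C`, `df`, `p.value`.
#' @examples
#' fishers_c(c(0.5, 0.5, 0.5))  # C = 4.159, df = 6
#' @export
fishers_c <- function(claim_p, zero_p = c("floor", "error")) {
  zero_p <- match.arg(zero_p)
  if (length(claim_p) == 0) {
    warning("saturated model: no independence claims to test")
    return(list(C = 0, df = 0L, p.value = 1))
  }
  if (any(claim_p < 0 | claim_p > 1)) stop("p-values must lie in (0, 1]")
  if (any(claim_p == 0)) {
    if (zero_p == "error") stop("claim p-value of 0 gives infinite C")
    warning("claim p-value(s) of 0 floored at 1e-300")
    claim_p[claim_p == 0] <- 1e-300
  }
  C <- -2 * sum(log(claim_p))
  df <- 2L * length(claim_p)
  list(C = C, df = df,
       p.value = stats::pchisq(C, df, lower.tail = FALSE))
}

# p-value for one independence claim: partial F test of the claim
# variable (a dummy block if it is a factor) in the conditional
# regression. If the designated response is categorical but the other
# variable is numeric, the regression is flipped.
claim_p_value <- function(claim, data) {
  resp <- claim$response; other <- claim$other
  if (!is.numeric(data[[resp]])) {
    if (!is.numeric(data[[other]])) {
      # two categorical variables: unconditional chi-square association
      if (length(claim$conditioning))
        stop("cannot test a conditional independence claim between two ",
             "categorical variables: ", resp, ", ", other)
      tab <- table(data[[resp]], data[[other]])
      return(suppressWarnings(stats::chisq.test(tab,
                                                correct = FALSE)$p.value))
    }
    tmp <- resp; resp <- other; other <- tmp
  }
  rhs0 <- if (length(claim$conditioning))
    paste(claim$conditioning, collapse = " + ") else "1"
  f0 <- stats::as.formula(paste(resp, "~", rhs0))
  f1 <- stats::as.formula(paste(resp, "~", rhs0, "+", other))
  reduced <- stats::lm(f0, data = data)
  full <- stats::lm(f1, data = data)
  stats::anova(reduced, full)[2, "Pr(>F)"]
}

#' Fit a piecewise structural equation model
#'
#' Fits one OLS regression per endogenous variable on its parents,
#' standardizes each numeric-parent coefficient as
#' \eqn{\beta = b \cdot SD(parent)/SD(child)}, tests every basis-set
#' independence claim by the partial F test of the claim variable in
#' its conditional regression, and combines the claim p-values into
#' Fisher's C. Categorical parents enter as dummy blocks; their edges
#' carry a block partial-F p-value and no single standardized
#' coefficient.
#'
#' @param model a [path_model()].
#' @param data data frame containing every model variable.
#' @return An object of class `sem_fit`: list with `model`, `edges`
#'   (data frame `parent`, `child`, `b`, `beta`, `p`), `claims` (data
#'   frame `response`, `other`, `conditioning`, `p`), `C`, `df`,
#'   `p.value`, `n`.
#' @examples
#' truth <- yield_path_truth(n = 2000, seed = 7)
#' fit <- sem_fit(as_path_model(truth), generate_sem_dataset(truth))
#' coef(fit)
#' @export
sem_fit <- function(model, data) {
  stopifnot(inherits(model, "path_model"))
  miss <- setdiff(model$variables, names(data))
  if (length(miss))
    stop("variable(s) missing from data: ", paste(miss, collapse = ", "))
  edge_rows <- list()
  for (v in model$endogenous) {
    pa <- parents_of(model, v)
    if (nrow(data) <= length(pa) + 2)
      stop("too few observations to fit '", v, "'")
    f <- stats::as.formula(paste(v, "~", paste(pa, collapse = " + ")))
    fit <- stats::lm(f, data = data)
    if (fit$rank < length(fit$coefficients)) {
      alias <- names(which(is.na(stats::coef(fit))))
      stop("rank-deficient design for '", v, "': collinear term(s) ",
           paste(alias, collapse = ", "))
    }
    cf <- summary(fit)$coefficients
    sd_child <- stats::sd(data[[v]])
    for (p_var in pa) {
      if (is.numeric(data[[p_var]])) {
        b <- cf[p_var, "Estimate"]
        edge_rows[[length(edge_rows) + 1]] <- data.frame(
          parent = p_var, child = v, b = b,
          beta = b * stats::sd(data[[p_var]]) / sd_child,
          p = cf[p_var, "Pr(>|t|)"], stringsAsFactors = FALSE)
      } else {
        # dummy block: partial F for the whole factor
        reduced <- stats::lm(stats::as.formula(
          paste(v, "~", paste(setdiff(pa, p_var), collapse = " + "),
                if (length(pa) == 1) "1" else "")), data = data)
        pF <- stats::anova(reduced, fit)[2, "Pr(>F)"]
        edge_rows[[length(edge_rows) + 1]] <- data.frame(
          parent = p_var, child = v, b = NA_real_, beta = NA_real_,
          p = pF, stringsAsFactors = FALSE)
      }
    }
  }
  claims <- basis_set(model)
  claim_df <- data.frame(
    response = vapply(claims, `[[`, "", "response"),
    other = vapply(claims, `[[`, "", "other"),
    conditioning = vapply(claims, function(cl)
      paste(cl$conditioning, collapse = "+"), ""),
    p = vapply(claims, claim_p_value, numeric(1), data = data),
    stringsAsFactors = FALSE)
  fc <- if (nrow(claim_df)) fishers_c(claim_df$p) else
    suppressWarnings(fishers_c(numeric(0)))
  structure(list(model = model, edges = do.call(rbind, edge_rows),
                 claims = claim_df, C = fc$C, df = fc$df,
                 p.value = fc$p.value, n = nrow(data)),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("Piecewise SEM (n = %d): Fisher's C = %.2f, df = %d, p = %.3f\n",
              x$n, x$C, x$df, x$p.value))
  df <- x$edges
  df$b <- round(df$b, 4); df$beta <- round(df$beta, 4)
  df$p <- signif(df$p, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.sem_fit <- function(object, ...) {
  print(object)
  if (nrow(object$claims)) {
    cat("\nIndependence claims (basis set):\n")
    cl <- object$claims
    cl$p <- signif(cl$p, 3)
    print.data.frame(cl, row.names = FALSE)
  } else cat("\nSaturated model: empty basis set\n")
  invisible(object)
}

#' @export
coef.sem_fit <- function(object, standardized = TRUE, ...) {
  val <- if (standardized) object$edges$beta else object$edges$b
  stats::setNames(val, paste(object$edges$parent, object$edges$child,
                             sep = "->"))
}

#' Direct, indirect and total effect decomposition
#'
#' Enumerates every directed path between each (source, target) pair of
#' the fitted DAG. The direct effect is the standardized coefficient of
#' the direct edge (0 when absent); the indirect effect is the sum over
#' all multi-edge paths of the products of the standardized
#' coefficients along the path; the total effect is their sum. Requires
#' every edge on a contributing path to carry a scalar standardized
#' coefficient (i.e. numeric parents).
#'
#' @param fit a [sem_fit()].
#' @param source,target optional variable names to restrict the table.
#' @return data frame with `source`, `target`, `direct`, `indirect`,
#'   `total`; only pairs connected by at least one directed path appear.
#' @export
decompose_effects <- function(fit, source = NULL, target = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  ed <- fit$edges
  vars <- fit$model$variables
  for (v in c(source, target))
    if (!v %in% vars) stop("variable '", v, "' not in model")
  beta_of <- function(a, b) {
    i <- which(ed$parent == a & ed$child == b)
    if (!length(i)) NULL else ed$beta[i]
  }
  paths_between <- function(a, b) {
    out <- list()
    walk <- function(node, acc) {
      if (node == b && length(acc)) { out[[length(out) + 1]] <<- acc; return() }
      for (ch in ed$child[ed$parent == node])
        walk(ch, c(acc, beta_of(node, ch)))
    }
    walk(a, numeric(0))
    out
  }
  src <- if (is.null(source)) vars else source
  tgt <- if (is.null(target)) vars else target
  rows <- list()
  for (a in src) for (b in tgt) {
    if (a == b) next
    paths <- paths_between(a, b)
    if (!length(paths)) next
    lens <- vapply(paths, length, 1L)
    if (any(vapply(paths, anyNA, TRUE)))
      stop("path from '", a, "' to '", b,
           "' crosses a categorical edge without a scalar coefficient")
    direct <- sum(vapply(paths[lens == 1], prod, 1))
    indirect <- sum(vapply(paths[lens > 1], prod, 1))
    rows[[length(rows) + 1]] <- data.frame(
      source = a, target = b, direct = direct, indirect = indirect,
      total = direct + indirect, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("effect_decomposition", "data.frame")
  out
}

#' @export
print.effect_decomposition <- function(x, ...) {
  df <- x
  class(df) <- "data.frame"
  df$direct <- round(df$direct, 4); df$indirect <- round(df$indirect, 4)
  df$total <- round(df$total, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
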