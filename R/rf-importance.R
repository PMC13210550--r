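#' Random-forest importance configuration
#'
#' Defaults follow the standard regression-forest protocol: 1000 trees,
#' `mtry = floor(m/3)` candidate variables per split, terminal node size
#' 5, seed 123, and 1000 permutations for both the model-level and the
#' per-variable significance nulls. Permutation refits may use a reduced
#' `ntree_null` — a scaled-down mode for desk-scale runs that keeps the
#' estimator identical and only widens Monte-Carlo error.
#'
#' @param ntree trees in the forest (>= 1).
#' @param mtry candidates per split; `NULL` means `floor(m/3)`.
#' @param nodesize minimum terminal node size.
#' @param seed RNG seed applied before fitting.
#' @param n_perm_model,n_perm_variable permutation counts (>= 99).
#' @param ntree_null trees for permutation refits (default `ntree`).
#' @return list of class `rf_config`.
#' @export
rf_config <- function(ntree = 1000, mtry = NULL, nodesize = 5,
                      seed = 123, n_perm_model = 1000,
                      n_perm_variable = 1000, ntree_null = NULL) {
  if (ntree < 1) stop("ntree must be >= 1")
  if (n_perm_model < 99 || n_perm_variable < 99)
    stop("permutation counts must be >= 99")
  structure(list(ntree = ntree, mtry = mtry, nodesize = nodesize,
                 seed = seed, n_perm_model = n_perm_model,
                 n_perm_variable = n_perm_variable,
                 ntree_null = if (is.null(ntree_null)) ntree else ntree_null),
            class = "rf_config")
}

rf_xy <- function(data, response) {
  if (!response %in% names(data)) stop("response '", response, "' not found")
  x <- data[setdiff(names(data), c(response, "genotype", "year", "block",
                                   "plant"))]
  x <- x[vapply(x, is.numeric, TRUE)]
  if (anyNA(x) || anyNA(data[[response]]))
    stop("missing values are not allowed")
  if (nrow(x) < 20) stop("need at least 20 records")
  list(x = as.data.frame(x), y = data[[response]])
}

rf_backend_fit <- function(x, y, cfg, importance = TRUE, ntree = cfg$ntree) {
  m <- ncol(x)
  mtry <- if (is.null(cfg$mtry)) max(1, floor(m / 3)) else cfg$mtry
  if (mtry > m) stop("mtry exceeds the number of predictors")
  randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry,
                             nodesize = cfg$nodesize,
                             importance = importance)
}

rf_pct_inc_mse <- function(fit) {
  imp <- randomForest::importance(fit, type = 1, scale = TRUE)
  v <- imp[, 1]
  v[!is.finite(v)] <- 0   # constant predictors: zero, not NaN
  stats::setNames(v, rownames(imp))
}

rf_pseudo_r2 <- function(fit) fit$rsq[length(fit$rsq)]  # OOB 1 - MSE/var(y)

#' Out-of-bag permutation importance of a regression forest
#'
#' Fits a random forest of the response on all numeric predictor
#' columns (design columns `genotype`/`year`/`block` are excluded) and
#' reports the out-of-bag permutation importance %IncMSE — the
#' percentage increase in out-of-bag mean squared error when a
#' predictor's values are permuted — together with the model's OOB
#' pseudo-R-squared. Deterministic for a fixed `cfg$seed`.
#'
#' @param data data frame of predictors plus the response column.
#' @param response response column name (e.g. `"hay_yield"`).
#' @param cfg an [rf_config()].
#' @return An object of class `rf_importance`: list with `importance`
#'   (data frame `predictor`, `pct_inc_mse`, descending), `pseudo_r2`,
#'   `variance_explained` (= 100 x pseudo-R2), `fit`, `cfg`, `response`.
#' @export
fit_importance <- function(data, response, cfg = rf_config()) {
  xy <- rf_xy(data, response)
  set.seed(cfg$seed)
  fit <- rf_backend_fit(xy$x, xy$y, cfg)
  imp <- rf_pct_inc_mse(fit)
  ord <- order(imp, decreasing = TRUE)
  out <- list(importance = data.frame(predictor = names(imp)[ord],
                                      pct_inc_mse = as.numeric(imp[ord]),
                                      stringsAsFactors = FALSE),
              pseudo_r2 = rf_pseudo_r2(fit),
              variance_explained = 100 * rf_pseudo_r2(fit),
              fit = fit, cfg = cfg, response = response)
  class(out) <- "rf_importance"
  out
}

#' @export
print.rf_importance <- function(x, ...) {
  cat(sprintf("Random-forest importance for '%s': pseudo-R2 = %.3f (%.2f%% variance explained)\n",
              x$response, x$pseudo_r2, x$variance_explained))
  df <- x$importance
  df$pct_inc_mse <- round(df$pct_inc_mse, 3)
  # share of total importance: the "contribution percentage" convention
  pos <- pmax(df$pct_inc_mse, 0)
  df$contribution_pct <- round(100 * pos / sum(pos), 1)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Permutation test of whole-model significance
#'
#' Compares the observed out-of-bag pseudo-R-squared against a null
#' distribution from refitting the forest to permutations of the
#' response; `p = (#[null >= observed] + 1) / (n_perm + 1)`, never
#' exactly zero.
#'
#' @inheritParams fit_importance
#' @param n_perm number of response permutations.
#' @param ntree_null trees per null refit (default `cfg$ntree_null`).
#' @return list with `pseudo_r2`, `p.value`, `n_perm`, `null` (the null
#'   pseudo-R2 draws).
#' @export
model_significance <- function(data, response, cfg = rf_config(),
                               n_perm = cfg$n_perm_model,
                               ntree_null = cfg$ntree_null) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  xy <- rf_xy(data, response)
  set.seed(cfg$seed)
  obs <- rf_pseudo_r2(rf_backend_fit(xy$x, xy$y, cfg, importance = FALSE))
  null <- vapply(seq_len(n_perm), function(i) {
    rf_pseudo_r2(rf_backend_fit(xy$x, sample(xy$y), cfg,
                                importance = FALSE, ntree = ntree_null))
  }, numeric(1))
  list(pseudo_r2 = obs,
       p.value = (sum(null >= obs) + 1) / (n_perm + 1),
       n_perm = n_perm, null = null)
}

#' Per-variable permutation significance of %IncMSE
#'
#' For each predictor, a null distribution of its %IncMSE is generated
#' by permuting that predictor's column and refitting the forest
#' `n_perm` times; `p = (#[null >= observed] + 1) / (n_perm + 1)`.
#' Predictors with p below 0.05 are conventionally deemed significantly
#' important.
#'
#' @inheritParams model_significance
#' @param predictors subset of predictors to test (default: all).
#' @return data frame with `predictor`, `pct_inc_mse`, `p`, sorted by
#'   descending importance.
#' @export
variable_significance <- function(data, response, cfg = rf_config(),
                                  n_perm = cfg$n_perm_variable,
                                  predictors = NULL,
                                  ntree_null = cfg$ntree_null) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  xy <- rf_xy(data, response)
  set.seed(cfg$seed)
  obs <- rf_pct_inc_mse(rf_backend_fit(xy$x, xy$y, cfg))
  if (is.null(predictors)) predictors <- names(xy$x)
  bad <- setdiff(predictors, names(xy$x))
  if (length(bad)) stop("unknown predictor(s): ", paste(bad, collapse = ", "))
  p <- vapply(predictors, function(v) {
    null <- vapply(seq_len(n_perm), function(i) {
      xp <- xy$x
      xp[[v]] <- sample(xp[[v]])
      rf_pct_inc_mse(rf_backend_fit(xp, xy$y, cfg,
                                    ntree = ntree_null))[[v]]
    }, numeric(1))
    (sum(null >= obs[[v]]) + 1) / (n_perm + 1)
  }, numeric(1))
  out <- data.frame(predictor = predictors,
                    pct_inc_mse = as.numeric(obs[predictors]),
                    p = as.numeric(p), stringsAsFactors = FALSE)
  out[order(-out$pct_inc_mse), ]
}
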