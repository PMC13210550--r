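#' Read and validate a trial table from CSV
#'
#' Expects a header `genotype,year,block,<indicator...>` (UTF-8, "."
#' decimal separator). Indicator cells must parse as plain numbers: a
#' stray thousands separator ("1,204") or any other non-numeric cell is
#' an error naming the row, never a silent coercion. Duplicate
#' (genotype, year, block) keys are rejected.
#'
#' @param path CSV file path.
#' @return a `trait_table`.
#' @export
validate_input <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("genotype", "year", "block")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  ind <- setdiff(names(raw), need)
  if (!length(ind)) stop("no indicator columns found")
  key <- do.call(paste, c(raw[need], sep = "|"))
  if (anyDuplicated(key))
    stop("duplicate (genotype, year, block) row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  for (j in ind) {
    num <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(num) & nzchar(raw[[j]]))
    if (length(bad))
      stop("non-numeric value in column '", j, "', row(s) ",
           paste(bad, collapse = ", "), " (e.g. \"", raw[[j]][bad[1]],
           "\")")
    if (anyNA(num))
      stop("missing value in column '", j, "'")
    raw[[j]] <- num
  }
  raw$genotype <- factor(raw$genotype)
  raw$year <- factor(raw$year)
  raw$block <- factor(raw$block)
  class(raw) <- c("trait_table", "data.frame")
  raw
}

#' Write a trait table as CSV
#'
#' Inverse of [validate_input()]: plain CSV, "." decimals, no quoting
#' of numerics, row names suppressed.
#'
#' @param table a `trait_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default piecewise SEM for a trial table
#'
#' Genotype and year enter every component equation as categorical
#' dummies; plant height, stem diameter and ADF mediate between the
#' design factors and hay yield, with the cross-path from plant height
#' to stem diameter.
#'
#' @return a [path_model()].
#' @export
default_trial_sem <- function() {
  path_model(
    plant_height ~ genotype + year,
    stem_diameter ~ genotype + year + plant_height,
    adf ~ genotype + year,
    hay_yield ~ genotype + year + plant_height + stem_diameter + adf
  )
}

#' Pipeline configuration
#'
#' @param input path to a trial CSV, or a `trait_table` directly.
#' @param out_dir directory for stage artifacts (created if absent).
#' @param response terminal response indicator (default `"hay_yield"`).
#' @param schema a [trait_schema()] or path to a schema file.
#' @param k_range candidate cluster counts (default `2:(n_genotypes-1)`).
#' @param seed base seed; per-stage seeds are derived as documented
#'   offsets and echoed in the report.
#' @param rf_ntree,rf_n_perm forest size and permutation count for the
#'   importance stage (lower both for a scaled-down run).
#' @param sem_model a [path_model()] for the SEM stage.
#' @param topsis_rescale min-max rescale TOPSIS input columns (only
#'   needed for signed data).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, out_dir, response = "hay_yield",
                            schema = trait_schema(), k_range = NULL,
                            seed = 1, rf_ntree = 1000, rf_n_perm = 1000,
                            sem_model = default_trial_sem(),
                            topsis_rescale = FALSE) {
  if (is.character(schema)) schema <- read_schema(schema)
  structure(list(input = input, out_dir = out_dir, response = response,
                 schema = schema, k_range = k_range, seed = seed,
                 rf_ntree = rf_ntree, rf_n_perm = rf_n_perm,
                 sem_model = sem_model, topsis_rescale = topsis_rescale),
            class = "pipeline_config")
}

#' Run the full evaluation pipeline
#'
#' Executes, in order: input validation, assumption screening, per-year
#' and factorial ANOVA, genotype clustering, entropy-TOPSIS ranking,
#' random-forest importance, and the piecewise SEM. Each stage writes
#' its tabular artifact under `config$out_dir`; a stage failure aborts
#' with the stage named. Warnings raised inside stages are collected
#' into the report.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `run_report`: list of stage outputs plus
#'   a `provenance` block (config echo, seeds, package version) and
#'   collected `warnings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  art <- function(name) file.path(config$out_dir, name)

  table <- stage("validate", {
    if (inherits(config$input, "trait_table")) config$input
    else validate_input(config$input)
  })
  ind <- intersect(config$schema$indicator, names(table))
  if (!config$response %in% ind)
    stop("stage 'validate' failed: response '", config$response,
         "' not among indicators", call. = FALSE)

  screen <- stage("assumptions", {
    s <- lapply(ind, function(j) assumption_screen(table, j))
    names(s) <- ind
    flat <- do.call(rbind, lapply(s, function(r)
      cbind(response = r$response, r$groups,
            levene_p = r$levene$p.value)))
    utils::write.csv(flat, art("assumptions.csv"), row.names = FALSE)
    s
  })

  anova_res <- stage("anova", {
    tw <- lapply(ind, function(j) twoway_anova(table, j))
    names(tw) <- ind
    flat <- do.call(rbind, lapply(ind, function(j)
      cbind(response = j, as.data.frame(tw[[j]]))))
    utils::write.csv(flat, art("anova_twoway.csv"), row.names = FALSE)
    ow <- do.call(rbind, lapply(ind, function(j)
      cbind(response = j, oneway_by_year(table, j))))
    utils::write.csv(ow, art("anova_oneway_by_year.csv"),
                     row.names = FALSE)
    list(twoway = tw, oneway_by_year = ow)
  })

  clustering <- stage("clustering", {
    prof <- genotype_profile(table, ind)
    z <- zscore_matrix(prof)
    sel <- select_k(z, k_range = config$k_range, seed = config$seed + 1)
    fit <- sel$fits[[paste0("k", sel$k_best)]]
    utils::write.csv(data.frame(genotype = names(fit$assignments),
                                cluster = fit$assignments),
                     art("clusters.csv"), row.names = FALSE)
    list(k_best = sel$k_best, selection = sel, fit = fit, profile = prof)
  })

  topsis <- stage("topsis", {
    dm <- decision_matrix(table, config$schema)
    res <- topsis_rank(dm, config$schema, rescale = config$topsis_rescale)
    utils::write.csv(data.frame(alternative = names(res$closeness),
                                d_pos = res$d_pos, d_neg = res$d_neg,
                                closeness = res$closeness,
                                rank = res$rank),
                     art("topsis.csv"), row.names = FALSE)
    if (inherits(res$weights, "entropy_weights"))
      utils::write.csv(data.frame(indicator = names(res$weights$w),
                                  entropy = res$weights$e,
                                  dispersion = res$weights$d,
                                  weight = res$weights$w),
                       art("topsis_weights.csv"), row.names = FALSE)
    res
  })

  importance <- stage("importance", {
    cfg <- rf_config(ntree = config$rf_ntree, seed = config$seed + 2,
                     n_perm_model = max(99, config$rf_n_perm),
                     n_perm_variable = max(99, config$rf_n_perm))
    imp <- fit_importance(table[c("genotype", "year", "block", ind)],
                          config$response, cfg)
    ms <- model_significance(table[c(ind)], config$response, cfg,
                             n_perm = cfg$n_perm_model)
    utils::write.csv(imp$importance, art("importance.csv"),
                     row.names = FALSE)
    list(importance = imp, model = ms)
  })

  sem <- stage("sem", {
    fit <- sem_fit(config$sem_model, table)
    utils::write.csv(fit$edges, art("sem_edges.csv"), row.names = FALSE)
    utils::write.csv(data.frame(C = fit$C, df = fit$df, p = fit$p.value),
                     art("sem_fit.csv"), row.names = FALSE)
    fit
  })

  report <- list(
    table = table, assumptions = screen, anova = anova_res,
    clustering = clustering, topsis = topsis, importance = importance,
    sem = sem,
    provenance = list(config = config, seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("bromeval")),
                      timestamp = format(Sys.time(), tz = "UTC")),
    warnings = warnings_log
  )
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Multi-year genotype evaluation report\n")
  cat("  records:", nrow(x$table), " genotypes:",
      nlevels(x$table$genotype), " years:", nlevels(x$table$year), "\n")
  cat("  clustering: k =", x$clustering$k_best, "\n")
  top <- names(sort(x$topsis$rank))[1]
  cat(sprintf("  TOPSIS rank 1: %s (C = %.3f)\n", top,
              x$topsis$closeness[[top]]))
  cat(sprintf("  RF: pseudo-R2 = %.3f, model p = %.3g\n",
              x$importance$importance$pseudo_r2,
              x$importance$model$p.value))
  cat(sprintf("  SEM: Fisher's C = %.2f (df = %d), p = %.3f\n",
              x$sem$C, x$sem$df, x$sem$p.value))
  if (length(x$warnings))
    cat("  warnings:", length(x$warnings), "(see $warnings)\n")
  invisible(x)
}
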