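#' Two-way fixed-effects factorial ANOVA with partial eta-squared
#'
#' Fits `response ~ genotype * year` on a balanced complete factorial
#' (equal replication in every cell; blocks are the replicates) with
#' sum-to-zero contrasts and returns the fixed-effects ANOVA table
#' augmented with the effect size
#' \deqn{\eta^2_p = SS_{term} / (SS_{term} + SS_{error}).}
#' Sequential and partial sums of squares coincide for balanced data.
#'
#' @param table a `trait_table` (columns `genotype`, `year`, `response`).
#' @param response indicator column name.
#' @return An `anova_table`: data frame with columns `term`, `SS`, `df`,
#'   `MS`, `F`, `p`, `partial_eta2`.
#' @examples
#' tab <- generate_trial(default_effect_spec(), seed = 1)
#' twoway_anova(tab, "hay_yield")
#' @export
twoway_anova <- function(table, response) {
  stopifnot(response %in% names(table))
  g <- factor(table$genotype); y <- factor(table$year)
  counts <- table(g, y)
  if (any(counts == 0)) stop("missing cells: design must be complete")
  if (length(unique(as.vector(counts))) != 1)
    stop("unbalanced design: equal replication per cell is required")
  if (counts[1] < 2) stop("replication required to estimate error")
  dat <- data.frame(.y = table[[response]], genotype = g, year = y)
  fit <- stats::lm(.y ~ genotype * year, data = dat,
                   contrasts = list(genotype = "contr.sum",
                                    year = "contr.sum"))
  a <- stats::anova(fit)
  terms <- c("genotype", "year", "genotype:year", "Residuals")
  a <- a[terms, ]
  ss_err <- a["Residuals", "Sum Sq"]
  out <- data.frame(
    term = c("genotype", "year", "genotype:year", "residual"),
    SS = a[["Sum Sq"]], df = a[["Df"]],
    MS = a[["Mean Sq"]], F = a[["F value"]], p = a[["Pr(>F)"]],
    partial_eta2 = c(a[["Sum Sq"]][1:3] /
                       (a[["Sum Sq"]][1:3] + ss_err), NA),
    stringsAsFactors = FALSE
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Two-way fixed-effects ANOVA\n")
  df <- x
  class(df) <- "data.frame"
  df$SS <- signif(df$SS, 5); df$MS <- signif(df$MS, 5)
  df$F <- round(df$F, 3); df$p <- signif(df$p, 4)
  df$partial_eta2 <- round(df$partial_eta2, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA per year
#'
#' Runs a separate one-way genotype ANOVA for each year, the per-year
#' screen that precedes the pooled factorial analysis.
#'
#' @inheritParams twoway_anova
#' @return data frame with columns `year`, `F`, `df1`, `df2`, `p`.
#' @export
oneway_by_year <- function(table, response) {
  years <- levels(factor(table$year))
  rows <- lapply(years, function(yy) {
    sub <- table[table$year == yy, ]
    a <- stats::anova(stats::lm(sub[[response]] ~ factor(sub$genotype)))
    data.frame(year = yy, F = a[1, "F value"], df1 = a[1, "Df"],
               df2 = a[2, "Df"], p = a[1, "Pr(>F)"])
  })
  do.call(rbind, rows)
}

#' Protected LSD pairwise comparisons with compact letter display
#'
#' Fisher's least significant difference after a one-way ANOVA on
#' balanced groups:
#' \deqn{LSD = t_{1-\alpha/2,\,df_e} \sqrt{2\,MSE/n}}
#' A pair differs when the absolute mean difference exceeds the LSD.
#' With `protect = TRUE` (the default) pairwise declarations are made
#' only when the omnibus F test is itself significant at `alpha`;
#' otherwise all pairs are reported non-significant and share one
#' letter. Letters are assigned by the insert-and-split sweep over the
#' significance graph, with groups processed in ascending mean order so
#' the display is deterministic.
#'
#' @param table data frame holding the response and grouping columns.
#' @param response numeric response column name.
#' @param group grouping factor column name.
#' @param alpha significance level (default 0.05).
#' @param protect require a significant omnibus F first (protected LSD).
#' @return An object of class `lsd`: list with `pairs` (data frame of
#'   `a`, `b`, `diff`, `lsd`, `significant`), `letters` (named character
#'   vector), `means`, `omnibus_p`, `lsd`, `alpha`.
#' @export
lsd_pairwise <- function(table, response, group, alpha = 0.05,
                         protect = TRUE) {
  y <- table[[response]]
  g <- factor(table[[group]])
  ns <- table(g)
  if (length(unique(as.vector(ns))) != 1)
    stop("unequal group sizes: LSD requires a balanced layout")
  n_per <- as.vector(ns)[1]
  fit <- stats::lm(y ~ g)
  a <- stats::anova(fit)
  omnibus_p <- a[1, "Pr(>F)"]
  mse <- a["Residuals", "Mean Sq"]
  dfe <- a["Residuals", "Df"]
  lsd <- stats::qt(1 - alpha / 2, dfe) * sqrt(2 * mse / n_per)
  means <- sort(tapply(y, g, mean))          # ascending for tie-breaks
  cmb <- utils::combn(names(means), 2)
  diffs <- means[cmb[2, ]] - means[cmb[1, ]]
  sig <- abs(diffs) > lsd
  if (protect && omnibus_p >= alpha) sig[] <- FALSE
  pairs <- data.frame(a = cmb[1, ], b = cmb[2, ],
                      diff = as.numeric(diffs), lsd = lsd,
                      significant = as.logical(sig),
                      stringsAsFactors = FALSE)
  out <- list(pairs = pairs, letters = cld_letters(names(means), pairs),
              means = means, omnibus_p = omnibus_p, lsd = lsd,
              alpha = alpha)
  class(out) <- "lsd"
  out
}

# insert-and-split compact letter display: start from one class holding
# all groups; every significant pair splits the classes containing both;
# absorb subset classes; letter classes ordered by their best member.
cld_letters <- function(groups_asc, pairs) {
  sets <- list(groups_asc)
  sig <- pairs[pairs$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$a[i]; b <- sig$b[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    keep <- rep(TRUE, length(new_sets))
    for (j in seq_along(new_sets)) for (k in seq_along(new_sets)) {
      if (j != k && keep[k] &&
          all(new_sets[[j]] %in% new_sets[[k]]) &&
          (length(new_sets[[j]]) < length(new_sets[[k]]) || j > k))
        keep[j] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  # order letter classes by the position of their first (lowest-mean) member
  first_pos <- vapply(sets, function(s) min(match(s, groups_asc)), 1)
  sets <- sets[order(first_pos)]
  lab <- stats::setNames(rep("", length(groups_asc)), groups_asc)
  for (i in seq_along(sets))
    lab[sets[[i]]] <- paste0(lab[sets[[i]]], letters[i])
  lab
}

#' @export
print.lsd <- function(x, ...) {
  cat(sprintf("Protected LSD (alpha = %.2f): omnibus p = %.4g, LSD = %.4g\n",
              x$alpha, x$omnibus_p, x$lsd))
  disp <- data.frame(group = names(x$means),
                     mean = as.numeric(x$means),
                     letters = x$letters[names(x$means)])
  print.data.frame(disp[order(-disp$mean), ], row.names = FALSE)
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample SD (n - 1 denominator) divided by the mean; the standard
#' inter-annual stability measure for yield and quality traits.
#'
#' @param x numeric vector with non-zero mean.
#' @return SD/mean ratio.
#' @export
cv <- function(x) {
  m <- mean(x)
  if (m == 0) stop("mean is zero: CV undefined")
  stats::sd(x) / m
}

#' Independent two-sample t-test
#'
#' Pooled-variance Student t by default (appropriate for the balanced
#' trial layout); set `var_equal = FALSE` for Welch.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pool the variances (Student) or not (Welch).
#' @return list with `statistic` and `p.value`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations")
  if (stats::sd(c(a, b)) == 0)
    return(list(statistic = 0, p.value = 1))
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}
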