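#' Specify ground-truth effects for a balanced multi-year trial
#'
#' An `effect_spec` describes the generating model of a balanced
#' genotype x year x block field trial with additive effects:
#' \deqn{x_{gybj} = \mu_j + G_{gj} + Y_{yj} + (GY)_{gyj} + B_{bj} +
#'   \epsilon,\qquad \epsilon \sim N(0, \sigma_j^2)}
#' for indicator \eqn{j}. Block effects \eqn{B_{bj}} are drawn once per
#' (block, indicator) from \eqn{N(0, \mathrm{blocksd}_j^2)}; residuals are
#' i.i.d. Gaussian. Effects are specified directly per level (no
#' sum-to-zero constraint is imposed here; the ANOVA layer owns coding).
#'
#' @param genotypes,years character vectors of factor levels.
#' @param n_blocks number of blocks (replicates), >= 1.
#' @param baseline named numeric vector of per-indicator grand means.
#' @param genotype_effects,year_effects matrices (levels x indicators) of
#'   additive effects, or `NULL` for all-zero.
#' @param interaction_effects matrix with rownames `"genotype:year"`
#'   covering the full grid, or `NULL` for all-zero.
#' @param block_sd,residual_sd non-negative; scalar or per-indicator
#'   (named) vector, recycled across indicators.
#' @return An object of class `effect_spec`.
#' @seealso [generate_trial()], [default_effect_spec()]
#' @export
effect_spec <- function(genotypes, years, n_blocks = 4, baseline,
                        genotype_effects = NULL, year_effects = NULL,
                        interaction_effects = NULL,
                        block_sd = 0, residual_sd) {
  if (length(genotypes) < 1 || length(years) < 1 || n_blocks < 1)
    stop("invalid spec: design counts must be >= 1")
  if (is.null(names(baseline)) || !is.numeric(baseline))
    stop("invalid spec: baseline must be a named numeric vector")
  ind <- names(baseline)
  expand_sd <- function(s, what) {
    if (any(s < 0)) stop("invalid spec: ", what, " must be non-negative")
    if (length(s) == 1) s <- stats::setNames(rep(s, length(ind)), ind)
    if (is.null(names(s))) names(s) <- ind
    s[ind]
  }
  fill <- function(m, rows, what) {
    if (is.null(m))
      return(matrix(0, length(rows), length(ind),
                    dimnames = list(rows, ind)))
    if (nrow(m) == 0 || ncol(m) == 0)
      stop("invalid spec: empty ", what, " matrix")
    if (!all(rows %in% rownames(m)))
      stop("invalid spec: ", what, " must cover the full factorial grid")
    out <- matrix(0, length(rows), length(ind), dimnames = list(rows, ind))
    keep <- intersect(colnames(m), ind)
    out[rows, keep] <- m[rows, keep, drop = FALSE]
    out
  }
  gy_rows <- as.vector(outer(genotypes, years, paste, sep = ":"))
  spec <- list(
    genotypes = as.character(genotypes), years = as.character(years),
    n_blocks = as.integer(n_blocks), indicators = ind,
    baseline = baseline,
    genotype_effects = fill(genotype_effects, as.character(genotypes),
                            "genotype_effects"),
    year_effects = fill(year_effects, as.character(years), "year_effects"),
    interaction_effects = fill(interaction_effects, gy_rows,
                               "interaction_effects"),
    block_sd = expand_sd(block_sd, "block_sd"),
    residual_sd = expand_sd(residual_sd, "residual_sd")
  )
  class(spec) <- "effect_spec"
  spec
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("Trial effect specification\n")
  cat("  design   :", length(x$genotypes), "genotypes x",
      length(x$years), "years x", x$n_blocks, "blocks\n")
  cat("  indicators:", length(x$indicators), "\n")
  cat("  residual sd range:", paste(signif(range(x$residual_sd), 3),
                                    collapse = " - "), "\n")
  invisible(x)
}

#' Default study conditions: 5 genotypes x 3 years x 4 blocks
#'
#' Returns the package's reference generating model: four candidate
#' smooth-brome accessions plus a control cultivar, evaluated over three
#' production years in four blocks. Two genotypes ("3-12", "4-4") are
#' planted as high performers (taller, thicker-stemmed, higher yielding,
#' higher CP/RFV, lower fibre) and the control plus two accessions as
#' lower performers; the third year carries the largest positive year
#' effect; a genotype x year interaction perturbs yield and fibre.
#' Baselines and dispersions are typical of perennial grass trials on
#' the indicator's own unit scale, with baselines chosen far above the
#' noise so generated values stay strictly positive.
#'
#' @param effect_scale multiplier applied to all genotype, year and
#'   interaction effects (0 gives a null trial with noise only).
#' @param residual_scale multiplier on the residual standard deviations.
#' @return an [effect_spec()].
#' @export
default_effect_spec <- function(effect_scale = 1, residual_scale = 1) {
  genotypes <- c("1-10", "2-10", "3-12", "4-4", "WUSU")
  years <- c("2023", "2024", "2025")
  baseline <- c(
    plant_height = 95, stem_diameter = 3.6, leaf_length = 21,
    leaf_width = 0.9, grass_height = 62, tillers_per_plant = 16,
    dry_fresh_ratio = 0.38, hay_yield = 5600, fresh_yield = 14500,
    ash = 8.2, cp = 13.5, adf = 33, ndf = 56, cf = 2.6, rfv = 104
  )
  # relative residual noise ~2.5% of baseline
  residual_sd <- 0.025 * baseline * residual_scale
  # genotype profile: -1 poor ... +1 good, applied with trait-scaled gains
  prof <- c("1-10" = -0.8, "2-10" = -0.2, "3-12" = 0.7, "4-4" = 1,
            "WUSU" = -0.7)
  gain <- c(
    plant_height = 6, stem_diameter = 0.25, leaf_length = 1.4,
    leaf_width = 0.05, grass_height = 4, tillers_per_plant = 1.2,
    dry_fresh_ratio = 0.012, hay_yield = 420, fresh_yield = 1000,
    ash = -0.35, cp = 0.8, adf = -1.6, ndf = -2.2, cf = 0.12, rfv = 7
  )
  g_eff <- outer(prof, gain) * effect_scale
  # year trajectory: establishment, intermediate, peak third year
  ytraj <- c("2023" = -0.6, "2024" = 0, "2025" = 1)
  ygain <- c(
    plant_height = 7, stem_diameter = 0.3, leaf_length = 1.6,
    leaf_width = 0.06, grass_height = 5, tillers_per_plant = 1.6,
    dry_fresh_ratio = 0.015, hay_yield = 520, fresh_yield = 1200,
    ash = -0.3, cp = 0.7, adf = -1.4, ndf = -1.9, cf = 0.1, rfv = 6
  )
  y_eff <- outer(ytraj, ygain) * effect_scale
  # interaction: high performers pull further ahead in the peak year,
  # mostly through yield and fibre
  gy_rows <- as.vector(outer(genotypes, years, paste, sep = ":"))
  gy <- matrix(0, length(gy_rows), length(baseline),
               dimnames = list(gy_rows, names(baseline)))
  bump <- c(hay_yield = 180, fresh_yield = 420, adf = -0.8, ndf = -1,
            stem_diameter = 0.12, rfv = 3)
  for (g in genotypes) {
    gy[paste(g, "2025", sep = ":"), names(bump)] <-
      prof[[g]] * bump * effect_scale
    gy[paste(g, "2023", sep = ":"), names(bump)] <-
      -0.5 * prof[[g]] * bump * effect_scale
  }
  effect_spec(genotypes, years, n_blocks = 4, baseline = baseline,
              genotype_effects = g_eff, year_effects = y_eff,
              interaction_effects = gy,
              block_sd = 0.012 * baseline, residual_sd = residual_sd)
}

#' Generate a balanced trial table from an effect specification
#'
#' Draws one plot-level record per (genotype, year, block) cell. Random
#' stream order under `set.seed(seed)`: first the block-effect matrix
#' (blocks x indicators, column-major), then residuals in the row order
#' of the expanded genotype-within-year-within-block grid, one indicator
#' column at a time. The same seed therefore reproduces the table
#' bit-identically.
#'
#' @param spec an [effect_spec()].
#' @param seed integer RNG seed.
#' @return A `trait_table`: data frame with factor columns `genotype`,
#'   `year`, `block` and one numeric column per indicator.
#' @examples
#' tab <- generate_trial(default_effect_spec(), seed = 1)
#' head(tab)
#' @export
generate_trial <- function(spec, seed) {
  stopifnot(inherits(spec, "effect_spec"))
  set.seed(seed)
  ind <- spec$indicators
  grid <- expand.grid(genotype = spec$genotypes, year = spec$years,
                      block = paste0("B", seq_len(spec$n_blocks)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  blk <- matrix(stats::rnorm(spec$n_blocks * length(ind)),
                spec$n_blocks, length(ind))
  blk <- sweep(blk, 2, spec$block_sd, `*`)
  gy_key <- paste(grid$genotype, grid$year, sep = ":")
  bi <- match(grid$block, paste0("B", seq_len(spec$n_blocks)))
  vals <- matrix(NA_real_, n, length(ind), dimnames = list(NULL, ind))
  for (j in seq_along(ind)) {
    mu <- spec$baseline[[j]] +
      spec$genotype_effects[grid$genotype, j] +
      spec$year_effects[grid$year, j] +
      spec$interaction_effects[gy_key, j] +
      blk[bi, j]
    vals[, j] <- mu + stats::rnorm(n, 0, spec$residual_sd[[j]])
  }
  if (any(vals <= 0))
    stop("generated non-positive indicator value(s); ",
         "raise baselines or lower noise (values are not truncated)")
  out <- cbind(
    data.frame(genotype = factor(grid$genotype, levels = spec$genotypes),
               year = factor(grid$year, levels = spec$years),
               block = factor(grid$block)),
    as.data.frame(vals)
  )
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Generate a strictly positive decision matrix fixture
#'
#' Builds an alternatives x indicators matrix of positive values at
#' indicator-typical magnitudes, optionally forcing one alternative to
#' dominate: strictly largest on every benefit column and strictly
#' smallest on every cost column.
#'
#' @param n_alternatives number of alternatives (rows), >= 2.
#' @param schema a [trait_schema()] giving columns and directions.
#' @param dominant optional row name (one of `LETTERS[1:n]`) to plant as
#'   the dominant alternative.
#' @param seed integer RNG seed.
#' @return numeric matrix with alternative row names.
#' @export
generate_decision_fixture <- function(n_alternatives, schema = trait_schema(),
                                      dominant = NULL, seed = 1) {
  if (n_alternatives < 2) stop("need at least 2 alternatives")
  set.seed(seed)
  ids <- if (n_alternatives <= 26) LETTERS[seq_len(n_alternatives)] else
    paste0("A", seq_len(n_alternatives))
  typ <- c(plant_height = 95, stem_diameter = 3.6, leaf_length = 21,
           leaf_width = 0.9, grass_height = 62, tillers_per_plant = 16,
           dry_fresh_ratio = 0.38, hay_yield = 5600, fresh_yield = 14500,
           ash = 8.2, cp = 13.5, adf = 33, ndf = 56, cf = 2.6, rfv = 104)
  scale <- typ[schema$indicator]
  scale[is.na(scale)] <- 10
  x <- matrix(stats::runif(n_alternatives * nrow(schema), 0.75, 1.25),
              n_alternatives, nrow(schema),
              dimnames = list(ids, schema$indicator))
  x <- sweep(x, 2, scale, `*`)
  if (!is.null(dominant)) {
    if (!dominant %in% ids) stop("dominant must be one of: ",
                                 paste(ids, collapse = ", "))
    for (j in seq_len(ncol(x))) {
      others <- x[setdiff(ids, dominant), j]
      x[dominant, j] <- if (schema$direction[j] == "benefit")
        max(others) * 1.15 else min(others) * 0.85
    }
  }
  stopifnot(all(x > 0))
  x
}
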