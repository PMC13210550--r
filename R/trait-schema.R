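#' Indicator schema for multi-trait forage evaluation
#'
#' The evaluation works on a fixed panel of 15 indicators: six agronomic
#' traits (plant height, stem diameter, leaf length, leaf width, grass
#' height, tillers per plant), three yield-related measures (dry-to-fresh
#' ratio, hay yield, fresh forage yield) and six nutritional indicators
#' (ash, crude protein, acid detergent fibre, neutral detergent fibre,
#' crude fat, relative feed value). Each indicator carries a direction:
#' `"benefit"` (more is better) or `"cost"` (less is better). The cost
#' set is ADF, NDF and ash; all other indicators are benefit-type.
#'
#' @param indicators optional character vector of indicator names to keep,
#'   in the order given; defaults to the full 15-indicator panel.
#' @return An object of class `trait_schema`: a data frame with columns
#'   `indicator`, `direction` and `unit`.
#' @examples
#' sch <- trait_schema()
#' cost_indicators(sch)
#' @export
trait_schema <- function(indicators = NULL) {
  full <- data.frame(
    indicator = c("plant_height", "stem_diameter", "leaf_length",
                  "leaf_width", "grass_height", "tillers_per_plant",
                  "dry_fresh_ratio", "hay_yield", "fresh_yield",
                  "ash", "cp", "adf", "ndf", "cf", "rfv"),
    direction = "benefit",
    unit = c("cm", "mm", "cm", "cm", "cm", "count", "ratio",
             "kg/hm2", "kg/hm2", "%", "%", "%", "%", "%", "index"),
    stringsAsFactors = FALSE
  )
  full$direction[full$indicator %in% c("adf", "ndf", "ash")] <- "cost"
  if (!is.null(indicators)) {
    miss <- setdiff(indicators, full$indicator)
    if (length(miss))
      stop("unknown indicator(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(indicators))
      stop("indicator names must be unique")
    full <- full[match(indicators, full$indicator), , drop = FALSE]
    rownames(full) <- NULL
  }
  class(full) <- c("trait_schema", "data.frame")
  full
}

#' @rdname trait_schema
#' @param schema a `trait_schema`.
#' @export
benefit_indicators <- function(schema) {
  stopifnot(inherits(schema, "trait_schema"))
  schema$indicator[schema$direction == "benefit"]
}

#' @rdname trait_schema
#' @export
cost_indicators <- function(schema) {
  stopifnot(inherits(schema, "trait_schema"))
  schema$indicator[schema$direction == "cost"]
}

#' @export
print.trait_schema <- function(x, ...) {
  cat("Trait schema:", nrow(x), "indicators (",
      sum(x$direction == "benefit"), "benefit,",
      sum(x$direction == "cost"), "cost )\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read an indicator direction schema from a plain-text file
#'
#' Parses `indicator,direction` lines (CSV with or without header) into a
#' [trait_schema()]. Directions must be `benefit` or `cost`.
#'
#' @param path file path.
#' @return a `trait_schema`.
#' @export
read_schema <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  if (ncol(raw) < 2) stop("schema file must have indicator,direction columns")
  if (tolower(raw[1, 1]) == "indicator") raw <- raw[-1, , drop = FALSE]
  bad <- !raw[[2]] %in% c("benefit", "cost")
  if (any(bad))
    stop("invalid direction(s): ", paste(unique(raw[[2]][bad]), collapse = ", "))
  sch <- trait_schema()
  keep <- match(raw[[1]], sch$indicator)
  if (anyNA(keep)) {
    # custom indicator set: build a fresh schema
    sch <- data.frame(indicator = raw[[1]], direction = raw[[2]],
                      unit = NA_character_, stringsAsFactors = FALSE)
    class(sch) <- c("trait_schema", "data.frame")
    return(sch)
  }
  sch <- sch[keep, , drop = FALSE]
  sch$direction <- raw[[2]]
  rownames(sch) <- NULL
  sch
}
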