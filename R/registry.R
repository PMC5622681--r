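pkg_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "proteinclaims")
  if (path == "") {
    stop("bundled data file not found: ", file.path(...), call. = FALSE)
  }
  path
}

#' Available jurisdiction rule sets
#'
#' @return Character vector of the bundled jurisdiction ids.
#' @export
list_jurisdictions <- function() {
  c("canada-current", "canada-option1", "canada-option2", "usa", "eu",
    "anz", "codex", "china", "south-korea")
}

#' Load a jurisdiction's claim rules
#'
#' Rules are data, not code: each jurisdiction ships as a JSON parameter
#' file (thresholds, tier names, DV/NRV constants, energy-rule unit), every
#' constant carrying a citation. Users may point `path` at their own file to
#' override a bundled set.
#'
#' @param jurisdiction_id One of [list_jurisdictions()].
#' @param path Optional path to a rules JSON file, overriding the bundle.
#' @return An object of class `jurisdiction_rules` (the parsed parameter
#'   list).
#' @export
#' @examples
#' load_jurisdiction("anz")$tiers
load_jurisdiction <- function(jurisdiction_id, path = NULL) {
  if (is.null(path)) {
    known <- list_jurisdictions()
    if (!jurisdiction_id %in% known) {
      stop("unknown jurisdiction '", jurisdiction_id, "'; available: ",
           paste(known, collapse = ", "), call. = FALSE)
    }
    path <- pkg_extdata("jurisdictions",
                        paste0(jurisdiction_id, ".json"))
  }
  rules <- jsonlite::read_json(path, simplifyVector = FALSE)
  # tiers must be ordered by ascending stringency
  thr <- vapply(rules$tiers, function(t) {
    as.numeric(t$threshold %||% t$threshold_multiplier)
  }, numeric(1))
  if (is.unsorted(thr, strictly = TRUE)) {
    stop("rules file ", path, ": tiers must be in ascending threshold order",
         call. = FALSE)
  }
  if (any(thr <= 0)) {
    stop("rules file ", path, ": thresholds must be > 0", call. = FALSE)
  }
  structure(rules, class = "jurisdiction_rules")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a reference scoring pattern
#'
#' The default is the bundled FAO/WHO 1991 preschool (2-5 y) pattern, the
#' pattern the USA regulations mandate for PDCAAS. The file is marked
#' external-provenance and swappable: pass `path` to use another pattern.
#'
#' @param path Optional path to a pattern JSON file (map of the nine
#'   canonical keys to mg/g protein, plus `population_label`).
#' @return A [scoring_pattern()].
#' @export
load_scoring_pattern <- function(path = NULL) {
  if (is.null(path)) {
    path <- pkg_extdata("patterns", "fao_who_1991_preschool.json")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  scoring_pattern(unlist(raw$requirement),
                  population_label = raw$population_label %||% "unspecified")
}

#' Load the serving-basis registry
#'
#' Regulated RDI / RA / RACC amounts for the food categories covered by the
#' bundled reference data, each entry with its citation. Other foods require
#' user-supplied bases.
#'
#' @param food_category Optional: return just this category's entry
#'   (error if unknown).
#' @return A list of registry entries, or a single entry when
#'   `food_category` is given.
#' @export
#' @examples
#' load_serving_registry("milk")$ra
load_serving_registry <- function(food_category = NULL) {
  reg <- jsonlite::read_json(pkg_extdata("registry", "serving_registry.json"),
                             simplifyVector = FALSE)
  entries <- reg$entries
  names(entries) <- vapply(entries, `[[`, character(1), "food_category")
  if (is.null(food_category)) {
    return(entries)
  }
  hit <- grep(food_category, names(entries), fixed = TRUE)
  if (length(hit) != 1) {
    hit <- which(names(entries) == food_category)
  }
  if (length(hit) != 1) {
    stop("unknown food category '", food_category, "'; available: ",
         paste(names(entries), collapse = "; "), call. = FALSE)
  }
  entries[[hit]]
}

#' @export
print.jurisdiction_rules <- function(x, ...) {
  cat(x$name, sprintf("[%s]\n", x$jurisdiction_id))
  for (t in x$tiers) {
    thr <- t$threshold %||% t$threshold_multiplier
    cat(sprintf("  %-16s >= %s\n", t$tier, thr))
  }
  invisible(x)
}
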