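na_if_null <- function(x) if (is.null(x) || !length(x)) NA else x

food_from_list <- function(rec, where) {
  need <- c("name", "protein_per_100", "bases")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop(where, ": missing required field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  b <- rec$bases
  bases <- serving_bases(
    rdi = na_if_null(b$rdi), ra = na_if_null(b$ra),
    racc = na_if_null(b$racc), serving = na_if_null(b$serving),
    unit_kind = b$unit_kind %||% "mass-g"
  )
  ingredients <- lapply(rec$ingredients, function(ing) {
    ingredient_protein(
      name = ing$name, profile = unlist(ing$profile),
      digestibility = ing$digestibility, protein_share = ing$protein_share
    )
  })
  food(
    name = rec$name, protein_per_100 = rec$protein_per_100, bases = bases,
    ingredients = ingredients, state = rec$state %||% "solid",
    energy_per_serving = na_if_null(rec$energy_per_serving),
    measured_per = na_if_null(rec$measured_per),
    measured_pdcaas = na_if_null(rec$measured_pdcaas),
    companion_rdi_g = na_if_null(rec$companion_rdi_g)
  )
}

food_to_list <- function(x) {
  drop_na <- function(v) if (is.na(v)) NULL else v
  a <- x$bases$amounts
  list(
    name = x$name, state = x$state, protein_per_100 = x$protein_per_100,
    energy_per_serving = drop_na(x$energy_per_serving),
    companion_rdi_g = drop_na(x$companion_rdi_g),
    measured_per = drop_na(x$measured_per),
    measured_pdcaas = drop_na(x$measured_pdcaas),
    bases = c(as.list(Filter(Negate(is.na), a)),
              list(unit_kind = x$bases$unit_kind)),
    ingredients = lapply(x$ingredients, function(ing) {
      list(name = ing$name, digestibility = ing$digestibility,
           protein_share = ing$protein_share,
           profile = as.list(unclass(ing$profile)))
    })
  )
}

csv_columns <- function() {
  c("food", "state", "protein_per_100", "energy_per_serving",
    "rdi", "ra", "racc", "serving", "unit_kind", "companion_rdi_g",
    "measured_per", "measured_pdcaas",
    "ingredient", "digestibility", "protein_share",
    paste0("aa_", amino_acid_keys()))
}

#' Read food definitions from a file
#'
#' Two formats are supported: the versioned JSON schema (a
#' `schema_version` field and a `foods` array) and a flat CSV dialect with
#' one row per ingredient and the food-level columns repeated on every row
#' (RFC 4180 quoting, UTF-8). All type invariants are enforced on load;
#' violations name the offending food and rule.
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`; guessed from the file extension by
#'   default.
#' @return A list of [food()] objects.
#' @export
read_food_definitions <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "json") {
    doc <- tryCatch(
      jsonlite::read_json(path, simplifyVector = FALSE),
      error = function(e) stop("cannot parse ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (is.null(doc$foods)) {
      stop(path, ": no 'foods' array (expected the versioned food-definition ",
           "schema)", call. = FALSE)
    }
    return(lapply(seq_along(doc$foods), function(i) {
      food_from_list(doc$foods[[i]],
                     where = sprintf("%s, foods[%d]", basename(path), i))
    }))
  }
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0) return(list())
  miss <- setdiff(c("food", "protein_per_100"), names(df))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num_or_na <- function(v) if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  lapply(split(df, factor(df$food, levels = unique(df$food))), function(rows) {
    r1 <- rows[1, ]
    bases <- serving_bases(
      rdi = num_or_na(r1$rdi), ra = num_or_na(r1$ra),
      racc = num_or_na(r1$racc), serving = num_or_na(r1$serving),
      unit_kind = if (is.null(r1$unit_kind) || is.na(r1$unit_kind) ||
                      r1$unit_kind == "") "mass-g" else r1$unit_kind
    )
    has_ing <- "ingredient" %in% names(rows) &&
      any(!is.na(rows$ingredient) & rows$ingredient != "")
    ingredients <- if (has_ing) {
      lapply(seq_len(nrow(rows)), function(i) {
        prof <- unlist(rows[i, paste0("aa_", amino_acid_keys())])
        names(prof) <- amino_acid_keys()
        ingredient_protein(rows$ingredient[i], prof,
                           rows$digestibility[i], rows$protein_share[i])
      })
    } else list()
    food(
      name = r1$food, protein_per_100 = num_or_na(r1$protein_per_100),
      bases = bases, ingredients = ingredients,
      state = if (is.null(r1$state) || is.na(r1$state) || r1$state == "")
        "solid" else r1$state,
      energy_per_serving = num_or_na(r1$energy_per_serving),
      measured_per = num_or_na(r1$measured_per),
      measured_pdcaas = num_or_na(r1$measured_pdcaas),
      companion_rdi_g = num_or_na(r1$companion_rdi_g)
    )
  }) |> unname()
}

#' Write food definitions to a file
#'
#' Inverse of [read_food_definitions()]; a write-then-read round trip
#' reproduces all fields (numerics to better than 1e-12).
#'
#' @param foods List of [food()] objects.
#' @param path Output path.
#' @param format `"json"` or `"csv"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_food_definitions <- function(foods, path,
                                   format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  stopifnot(all(vapply(foods, inherits, logical(1), "food")))
  if (format == "json") {
    doc <- list(schema_version = 1, foods = lapply(foods, food_to_list))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(path))
  }
  rows <- lapply(foods, function(x) {
    a <- x$bases$amounts
    base_row <- data.frame(
      food = x$name, state = x$state, protein_per_100 = x$protein_per_100,
      energy_per_serving = x$energy_per_serving,
      rdi = a[["rdi"]], ra = a[["ra"]], racc = a[["racc"]],
      serving = a[["serving"]], unit_kind = x$bases$unit_kind,
      companion_rdi_g = x$companion_rdi_g,
      measured_per = x$measured_per, measured_pdcaas = x$measured_pdcaas,
      check.names = FALSE
    )
    if (!length(x$ingredients)) {
      base_row$ingredient <- NA_character_
      base_row$digestibility <- NA_real_
      base_row$protein_share <- NA_real_
      for (k in amino_acid_keys()) base_row[[paste0("aa_", k)]] <- NA_real_
      return(base_row)
    }
    do.call(rbind, lapply(x$ingredients, function(ing) {
      r <- base_row
      r$ingredient <- ing$name
      r$digestibility <- ing$digestibility
      r$protein_share <- ing$protein_share
      prof <- unclass(ing$profile)
      for (k in amino_acid_keys()) r[[paste0("aa_", k)]] <- prof[[k]]
      r
    }))
  })
  df <- do.call(rbind, rows)[, csv_columns()]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
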