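#' Canonical indispensable amino acid keys
#'
#' The nine indispensable amino acid classes scored by the PDCAAS method.
#' The sulphur amino acids (methionine + cysteine) and the aromatic amino
#' acids (phenylalanine + tyrosine) are scored as pairs. The set is fixed:
#' profiles and scoring patterns must carry exactly these keys.
#'
#' @return Character vector of the nine keys, in canonical (alphabetical)
#'   order. This order is also the tie-break order when two amino acids are
#'   equally limiting.
#' @export
#' @examples
#' amino_acid_keys()
amino_acid_keys <- function() {
  c("His", "Ile", "Leu", "Lys", "Met+Cys", "Phe+Tyr", "Thr", "Trp", "Val")
}

# validate a named numeric vector against the canonical key set
check_aa_map <- function(x, what, positive = FALSE) {
  keys <- amino_acid_keys()
  if (!is.numeric(x) || is.null(names(x))) {
    stop(what, " must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(keys, names(x))
  extra <- setdiff(names(x), keys)
  if (length(missing)) {
    stop(what, " is missing amino acid entries: ",
         paste(missing, collapse = ", "),
         " (missing entries are an error, never imputed as zero)",
         call. = FALSE)
  }
  if (length(extra)) {
    stop(what, " has unknown amino acid keys: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  x <- x[keys]
  if (any(!is.finite(x))) {
    stop(what, " has non-finite values", call. = FALSE)
  }
  if (positive) {
    if (any(x <= 0)) stop(what, " values must all be > 0", call. = FALSE)
  } else if (any(x < 0)) {
    stop(what, " values must all be >= 0", call. = FALSE)
  }
  x
}

#' Amino acid profile of a protein source
#'
#' Indispensable amino acid content of a protein, in mg amino acid per g
#' protein, over the fixed nine-key set of [amino_acid_keys()].
#'
#' @param content Named numeric vector: mg amino acid per g protein for each
#'   of the nine canonical keys. All keys must be present; absent entries are
#'   an error (a silent zero would force a spurious limiting amino acid).
#' @return An object of class `aa_profile` (named numeric vector in canonical
#'   key order).
#' @export
#' @examples
#' aa_profile(c(His = 26, Ile = 46, Leu = 78, Lys = 64, `Met+Cys` = 26,
#'              `Phe+Tyr` = 88, Thr = 36, Trp = 11, Val = 50))
aa_profile <- function(content) {
  content <- check_aa_map(content, "amino acid profile", positive = FALSE)
  structure(content, class = "aa_profile")
}

#' Reference amino acid scoring pattern
#'
#' Amino acid requirements of a reference population, in mg per g protein,
#' used as the denominator of the amino acid score.
#'
#' @param requirement Named numeric vector over the nine canonical keys; all
#'   values strictly positive.
#' @param population_label Text describing the reference population
#'   (e.g. "preschool children 2-5 y, FAO/WHO 1991").
#' @return An object of class `scoring_pattern`.
#' @export
scoring_pattern <- function(requirement, population_label = "unspecified") {
  requirement <- check_aa_map(requirement, "scoring pattern", positive = TRUE)
  structure(requirement, class = "scoring_pattern",
            population_label = as.character(population_label)[1])
}

#' @export
print.aa_profile <- function(x, ...) {
  cat("Amino acid profile (mg/g protein)\n")
  print(unclass(x))
  invisible(x)
}

#' @export
print.scoring_pattern <- function(x, ...) {
  cat("Scoring pattern:", attr(x, "population_label"), "(mg/g protein)\n")
  print(unclass(x))
  invisible(x)
}
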