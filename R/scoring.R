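#' Amino acid score of a protein against a scoring pattern
#'
#' The ratio of each indispensable amino acid's content (mg/g protein) to
#' the reference population's requirement is computed; the score is the
#' minimum ratio and the limiting amino acid is the arg-min. Ties are broken
#' by canonical (alphabetical) key order and reported.
#'
#' @param profile An [aa_profile()].
#' @param pattern A [scoring_pattern()].
#' @return List with `score` (dimensionless, >= 0), `limiting_aa` (key),
#'   `ratios` (all nine ratios) and `tied` (keys sharing the minimum, length
#'   > 1 only on a tie).
#' @export
amino_acid_score <- function(profile, pattern) {
  if (!inherits(profile, "aa_profile")) profile <- aa_profile(profile)
  if (!inherits(pattern, "scoring_pattern")) {
    pattern <- scoring_pattern(pattern)
  }
  ratios <- unclass(profile) / unclass(pattern)
  tied <- names(ratios)[ratios == min(ratios)]
  list(score = unname(min(ratios)), limiting_aa = tied[1],
       ratios = ratios, tied = tied)
}

new_quality_result <- function(variant, raw_score, limiting_aa,
                               digestibility_used, tied = limiting_aa) {
  structure(
    list(method_variant = variant, raw_score = raw_score,
         pdcaas = min(raw_score, 1), limiting_aa = limiting_aa,
         tied = tied, digestibility_used = digestibility_used),
    class = "quality_result"
  )
}

#' PDCAAS of a single protein source
#'
#' The amino acid score (lowest content-to-requirement ratio) multiplied by
#' the source's true fecal nitrogen digestibility; values above 1 are
#' truncated at 1.
#'
#' @param profile An [aa_profile()].
#' @param pattern A [scoring_pattern()].
#' @param digestibility True fecal nitrogen digestibility, in (0, 1].
#' @return A `quality_result`: `raw_score` (before truncation), `pdcaas`
#'   (truncated at 1), `limiting_aa`, `digestibility_used`,
#'   `method_variant = "single"`.
#' @export
pdcaas_single <- function(profile, pattern, digestibility) {
  digestibility <- as.numeric(digestibility)[1]
  if (!is.finite(digestibility) || digestibility <= 0 || digestibility > 1) {
    stop("digestibility must be in (0, 1]", call. = FALSE)
  }
  s <- amino_acid_score(profile, pattern)
  new_quality_result("single", s$score * digestibility, s$limiting_aa,
                     digestibility, s$tied)
}

#' PDCAAS of a multi-ingredient protein mixture
#'
#' Two weighting conventions are implemented, selected by `variant`. With
#' ingredient protein shares \eqn{w_i}, amino acid contents \eqn{aa_{i,a}}
#' (mg/g protein), digestibilities \eqn{d_i} and pattern requirements
#' \eqn{ref_a}:
#'
#' * `"1991"`: the mixture profile is the share-weighted amino acid content,
#'   \eqn{m_a = \sum_i w_i\, aa_{i,a}}; the mixture digestibility is
#'   \eqn{D = \sum_i w_i d_i}; the raw score is
#'   \eqn{\min_a(m_a / ref_a) \times D}.
#' * `"2007"`: the digestible amino acid content is weighted first,
#'   \eqn{g_a = \sum_i w_i\, aa_{i,a}\, d_i}; the weighted digestibility
#'   \eqn{D} is then applied to the score computed on the
#'   digestibility-normalised profile:
#'   \eqn{\min_a\!\big(g_a / (ref_a\, D)\big) \times D}, which simplifies to
#'   \eqn{\min_a(g_a / ref_a)}.
#'
#' The two variants coincide whenever all ingredient digestibilities are
#' equal (in particular for any single-ingredient food). Truncation at 1 is
#' applied to the mixture score only, never per ingredient.
#'
#' @param ingredients Non-empty list of [ingredient_protein()] objects whose
#'   protein shares sum to 1 (tolerance 1e-9).
#' @param pattern A [scoring_pattern()].
#' @param variant `"1991"` (default; the variant the USA regulations cite)
#'   or `"2007"`.
#' @return A `quality_result` with `method_variant` `"multi-1991"` or
#'   `"multi-2007"` and `digestibility_used` the share-weighted mean
#'   digestibility.
#' @export
pdcaas_multi <- function(ingredients, pattern, variant = c("1991", "2007")) {
  variant <- match.arg(variant)
  if (!length(ingredients)) {
    stop("ingredient list must be non-empty", call. = FALSE)
  }
  ok <- vapply(ingredients, inherits, logical(1), "ingredient_protein")
  if (!all(ok)) {
    stop("ingredients must all be ingredient_protein objects", call. = FALSE)
  }
  w <- vapply(ingredients, `[[`, numeric(1), "protein_share")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("ingredient protein shares sum to ", format(sum(w)),
         ", must sum to 1", call. = FALSE)
  }
  d <- vapply(ingredients, `[[`, numeric(1), "digestibility")
  aa <- vapply(ingredients, function(i) unclass(i$profile),
               numeric(length(amino_acid_keys())))  # 9 x n matrix
  if (!inherits(pattern, "scoring_pattern")) {
    pattern <- scoring_pattern(pattern)
  }
  ref <- unclass(pattern)
  D <- sum(w * d)
  if (variant == "1991") {
    m <- as.numeric(aa %*% w)
    ratios <- m / ref
    raw <- min(ratios) * D
  } else {
    g <- as.numeric(aa %*% (w * d))
    ratios <- g / (ref * D)
    raw <- min(ratios) * D
  }
  names(ratios) <- amino_acid_keys()
  tied <- names(ratios)[ratios == min(ratios)]
  new_quality_result(paste0("multi-", variant), raw, tied[1], D, tied)
}

#' Convert a PDCAAS to a PER
#'
#' The CFIA conversion: PER = PDCAAS x 2.5, where 2.5 is the standardised
#' PER of the casein control in the rat growth bioassay. The input must
#' already be truncated to \[0, 1\], so the output lies in \[0, 2.5\].
#'
#' @param pdcaas Truncated PDCAAS in \[0, 1\] (numeric, or a
#'   `quality_result` whose `pdcaas` element is used).
#' @param casein_per The casein reference PER (default 2.5).
#' @return PER, dimensionless.
#' @export
#' @examples
#' per_from_pdcaas(1.0)    # 2.5, the casein-equivalent case
#' per_from_pdcaas(0.458)  # 1.145
per_from_pdcaas <- function(pdcaas, casein_per = 2.5) {
  if (inherits(pdcaas, "quality_result")) pdcaas <- pdcaas$pdcaas
  pdcaas <- as.numeric(pdcaas)
  if (any(!is.finite(pdcaas)) || any(pdcaas < 0) || any(pdcaas > 1)) {
    stop("pdcaas must be in [0, 1]; truncate before converting",
         call. = FALSE)
  }
  pdcaas * casein_per
}

#' Protein rating of a food
#'
#' The Canadian claim metric: PER multiplied by the grams of protein in the
#' food's Reasonable Daily Intake. Returned unrounded; the tables print it
#' to one decimal.
#'
#' @param per Protein efficiency ratio, >= 0.
#' @param protein_g g protein at the RDI basis, >= 0.
#' @return The rating, dimensionless.
#' @export
#' @examples
#' protein_rating(2.32, 2.7) # 6.264, printed 6.3
protein_rating <- function(per, protein_g) {
  per <- as.numeric(per)
  protein_g <- as.numeric(protein_g)
  if (any(per < 0) || any(protein_g < 0)) {
    stop("per and protein_g must be >= 0", call. = FALSE)
  }
  per * protein_g
}

#' PDCAAS-corrected protein and its percent of the Daily Value
#'
#' @param pdcaas Truncated PDCAAS in \[0, 1\].
#' @param protein_g g protein at the stated basis.
#' @param dv_g Protein Daily Value in g (50 g for >= 4 y through adults;
#'   13 g for 1-3 y in the USA).
#' @param basis Which basis `protein_g` was measured at (annotation only).
#' @return List of class `corrected_protein`: `grams` (pdcaas x protein_g),
#'   `percent_dv` (grams / dv_g x 100), `basis`, `dv_g`.
#' @export
#' @examples
#' corrected_protein(0.52, 5, 50)   # 2.6 g, 5.2 %DV
corrected_protein <- function(pdcaas, protein_g, dv_g = 50, basis = "ra") {
  if (inherits(pdcaas, "quality_result")) pdcaas <- pdcaas$pdcaas
  pdcaas <- as.numeric(pdcaas)[1]
  protein_g <- as.numeric(protein_g)[1]
  dv_g <- as.numeric(dv_g)[1]
  if (!is.finite(dv_g) || dv_g <= 0) stop("dv_g must be > 0", call. = FALSE)
  if (pdcaas < 0 || pdcaas > 1) {
    stop("pdcaas must be in [0, 1]", call. = FALSE)
  }
  if (protein_g < 0) stop("protein_g must be >= 0", call. = FALSE)
  grams <- pdcaas * protein_g
  structure(list(grams = grams, percent_dv = grams / dv_g * 100,
                 basis = basis, dv_g = dv_g),
            class = "corrected_protein")
}

#' PDCAAS of a food object
#'
#' Returns the measured PDCAAS override when the food carries one (as the
#' worked regulatory examples do), otherwise computes it from the
#' ingredient list.
#'
#' @param x A [food()].
#' @param pattern Scoring pattern; defaults to the bundled 1991 preschool
#'   pattern. Only consulted when computing from ingredients.
#' @param variant Mixture weighting variant, see [pdcaas_multi()].
#' @param prefer_measured Use `measured_pdcaas` when present (default TRUE).
#' @return A `quality_result`. The measured override is reported with
#'   `method_variant = "measured"` and no limiting amino acid.
#' @export
food_pdcaas <- function(x, pattern = NULL, variant = c("1991", "2007"),
                        prefer_measured = TRUE) {
  stopifnot(inherits(x, "food"))
  variant <- match.arg(variant)
  if (prefer_measured && !is.na(x$measured_pdcaas)) {
    return(structure(
      list(method_variant = "measured", raw_score = x$measured_pdcaas,
           pdcaas = x$measured_pdcaas, limiting_aa = NA_character_,
           tied = NA_character_, digestibility_used = NA_real_),
      class = "quality_result"
    ))
  }
  if (!length(x$ingredients)) {
    stop("food '", x$name,
         "' has no ingredient profiles and no measured PDCAAS",
         call. = FALSE)
  }
  if (is.null(pattern)) pattern <- load_scoring_pattern()
  pdcaas_multi(x$ingredients, pattern, variant)
}

#' PER of a food object
#'
#' The measured PER when present; otherwise derived from the food's PDCAAS
#' through the CFIA conversion (PER = PDCAAS x 2.5).
#'
#' @inheritParams food_pdcaas
#' @return List with `per` and `source` (`"measured"` or
#'   `"derived-from-pdcaas"`).
#' @export
food_per <- function(x, pattern = NULL, variant = c("1991", "2007")) {
  stopifnot(inherits(x, "food"))
  if (!is.na(x$measured_per)) {
    return(list(per = x$measured_per, source = "measured"))
  }
  q <- food_pdcaas(x, pattern, match.arg(variant))
  list(per = per_from_pdcaas(q$pdcaas), source = "derived-from-pdcaas")
}

#' @export
print.quality_result <- function(x, ...) {
  cat(sprintf("PDCAAS (%s): %.3f", x$method_variant, x$pdcaas))
  if (x$raw_score > 1) cat(sprintf(" (raw %.3f, truncated)", x$raw_score))
  cat("\n")
  if (!is.na(x$limiting_aa)) {
    cat("  limiting amino acid:", x$limiting_aa)
    if (length(x$tied) > 1) {
      cat(" (tied:", paste(x$tied, collapse = ", "), ")")
    }
    cat("\n")
  }
  if (!is.na(x$digestibility_used)) {
    cat(sprintf("  digestibility used: %.3f\n", x$digestibility_used))
  }
  invisible(x)
}

#' @export
print.corrected_protein <- function(x, ...) {
  cat(sprintf("Corrected protein: %.2f g per %s (%.1f%% of %g g DV)\n",
              x$grams, toupper(x$basis), x$percent_dv, x$dv_g))
  invisible(x)
}
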