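#' One protein-contributing ingredient of a food
#'
#' Couples an amino acid profile with the ingredient's true fecal nitrogen
#' digestibility and its share of the food's total protein. These are the
#' per-ingredient quantities the multi-ingredient PDCAAS weights.
#'
#' @param name Ingredient name.
#' @param profile An [aa_profile()] (or named numeric vector coerced to one).
#' @param digestibility True fecal nitrogen digestibility, a fraction in
#'   (0, 1].
#' @param protein_share This ingredient's fraction of the food's total
#'   protein, in \[0, 1\]. Across a food the shares must sum to 1.
#' @return An object of class `ingredient_protein`.
#' @export
ingredient_protein <- function(name, profile, digestibility, protein_share) {
  if (!inherits(profile, "aa_profile")) profile <- aa_profile(profile)
  digestibility <- as.numeric(digestibility)[1]
  protein_share <- as.numeric(protein_share)[1]
  if (!is.finite(digestibility) || digestibility <= 0 || digestibility > 1) {
    stop("digestibility must be a fraction in (0, 1], got ", digestibility,
         call. = FALSE)
  }
  if (!is.finite(protein_share) || protein_share < 0 || protein_share > 1) {
    stop("protein_share must be in [0, 1], got ", protein_share,
         call. = FALSE)
  }
  structure(
    list(name = as.character(name)[1], profile = profile,
         digestibility = digestibility, protein_share = protein_share),
    class = "ingredient_protein"
  )
}

#' Serving bases of a food
#'
#' The regulated quantities a claim rule can be evaluated against: the
#' Canadian Reasonable Daily Intake (RDI, a whole day's assumed intake), the
#' Canadian reference amount (RA, one eating occasion), the USA reference
#' amount customarily consumed (RACC), and the label serving. Amounts are in
#' g for solids and mL for liquids; the unit kind is explicit, never
#' inferred from magnitude, because some rules branch on solid vs liquid.
#'
#' @param rdi,ra,racc,serving Amounts in g or mL; `NA` when absent. At least
#'   one must be present.
#' @param unit_kind `"mass-g"` or `"volume-mL"`.
#' @return An object of class `serving_bases`.
#' @export
serving_bases <- function(rdi = NA, ra = NA, racc = NA, serving = NA,
                          unit_kind = c("mass-g", "volume-mL")) {
  unit_kind <- match.arg(unit_kind)
  amounts <- c(rdi = as.numeric(rdi)[1], ra = as.numeric(ra)[1],
               racc = as.numeric(racc)[1], serving = as.numeric(serving)[1])
  present <- !is.na(amounts)
  if (!any(present)) {
    stop("at least one serving basis must be present", call. = FALSE)
  }
  if (any(amounts[present] <= 0)) {
    stop("serving basis amounts must be > 0", call. = FALSE)
  }
  structure(list(amounts = amounts, unit_kind = unit_kind),
            class = "serving_bases")
}

#' Define a food
#'
#' The central domain object: a food's protein composition plus the serving
#' bases, energy and state that claim rules consume. Protein mass at any
#' basis is always derived from `protein_per_100` (single source of truth;
#' there is no independently stored per-basis protein).
#'
#' @param name Food name.
#' @param protein_per_100 g protein per 100 g (solids) or per 100 mL
#'   (liquids).
#' @param bases A [serving_bases()] object.
#' @param ingredients List of [ingredient_protein()] objects; may be empty
#'   when a measured PER or PDCAAS override is supplied instead. Non-empty
#'   lists must have protein shares summing to 1 (tolerance 1e-9).
#' @param state `"solid"` or `"liquid"`.
#' @param energy_per_serving kcal per label serving; `NA` when unknown.
#' @param measured_per Optional measured protein efficiency ratio, overriding
#'   the PDCAAS-derived value.
#' @param measured_pdcaas Optional measured PDCAAS in \[0, 1\], overriding the
#'   value computed from the ingredient list.
#' @param companion_rdi_g Optional RDI (g or mL) that replaces this food's own
#'   RDI when it is evaluated together with a declared companion food (the
#'   regulated case: a breakfast cereal's RDI switches from 28 g to 30 g when
#'   combined with 125 mL milk). `NA` means no combination is declared.
#' @return An object of class `food`.
#' @export
food <- function(name, protein_per_100, bases, ingredients = list(),
                 state = c("solid", "liquid"), energy_per_serving = NA,
                 measured_per = NA, measured_pdcaas = NA,
                 companion_rdi_g = NA) {
  state <- match.arg(state)
  if (!inherits(bases, "serving_bases")) {
    stop("bases must be a serving_bases object", call. = FALSE)
  }
  protein_per_100 <- as.numeric(protein_per_100)[1]
  if (!is.finite(protein_per_100) || protein_per_100 < 0) {
    stop("protein_per_100 must be >= 0", call. = FALSE)
  }
  measured_pdcaas <- as.numeric(measured_pdcaas)[1]
  if (!is.na(measured_pdcaas) &&
      (measured_pdcaas < 0 || measured_pdcaas > 1)) {
    stop("measured_pdcaas must be in [0, 1]", call. = FALSE)
  }
  measured_per <- as.numeric(measured_per)[1]
  if (!is.na(measured_per) && measured_per < 0) {
    stop("measured_per must be >= 0", call. = FALSE)
  }
  if (length(ingredients)) {
    ok <- vapply(ingredients, inherits, logical(1), "ingredient_protein")
    if (!all(ok)) {
      stop("ingredients must all be ingredient_protein objects",
           call. = FALSE)
    }
    shares <- vapply(ingredients, `[[`, numeric(1), "protein_share")
    if (abs(sum(shares) - 1) > 1e-9) {
      stop("food '", name, "': ingredient protein shares sum to ",
           format(sum(shares)), ", must sum to 1", call. = FALSE)
    }
  }
  energy_per_serving <- as.numeric(energy_per_serving)[1]
  if (!is.na(energy_per_serving) && energy_per_serving < 0) {
    stop("energy_per_serving must be >= 0", call. = FALSE)
  }
  structure(
    list(name = as.character(name)[1], protein_per_100 = protein_per_100,
         bases = bases, ingredients = ingredients, state = state,
         energy_per_serving = energy_per_serving,
         measured_per = measured_per, measured_pdcaas = measured_pdcaas,
         companion_rdi_g = as.numeric(companion_rdi_g)[1]),
    class = "food"
  )
}

#' Grams of protein in a serving basis of a food
#'
#' @param x A [food()].
#' @param basis One of `"rdi"`, `"ra"`, `"racc"`, `"serving"`, or a numeric
#'   amount in the food's unit (g or mL).
#' @param paper_rounding Round the result half-up to 1 decimal, as the
#'   regulatory tables print protein grams, before any downstream use.
#' @return g protein at that basis (`protein_per_100 * amount / 100`).
#'   An absent basis is an explicit error, never a silent fallback.
#' @export
#' @examples
#' cereal <- food("cereal", protein_per_100 = 5 / 55 * 100,
#'                bases = serving_bases(rdi = 28, ra = 55))
#' protein_at_basis(cereal, "ra")                        # 5
#' protein_at_basis(cereal, "rdi", paper_rounding = TRUE) # 2.5
protein_at_basis <- function(x, basis, paper_rounding = FALSE) {
  stopifnot(inherits(x, "food"))
  if (is.numeric(basis)) {
    amount <- basis[1]
  } else {
    basis <- match.arg(basis, c("rdi", "ra", "racc", "serving"))
    amount <- x$bases$amounts[[basis]]
    if (is.na(amount)) {
      stop("food '", x$name, "' has no ", toupper(basis), " basis",
           call. = FALSE)
    }
  }
  maybe_round(x$protein_per_100 * amount / 100, paper_rounding)
}

#' @export
print.food <- function(x, ...) {
  a <- x$bases$amounts
  unit <- if (x$bases$unit_kind == "mass-g") "g" else "mL"
  cat("Food:", x$name, sprintf("(%s)\n", x$state))
  cat(sprintf("  protein: %.2f g/100 %s\n", x$protein_per_100, unit))
  for (b in names(a)) {
    if (!is.na(a[[b]])) {
      cat(sprintf("  %s: %g %s -> %.2f g protein\n", toupper(b), a[[b]],
                  unit, x$protein_per_100 * a[[b]] / 100))
    }
  }
  if (!is.na(x$energy_per_serving)) {
    cat(sprintf("  energy: %g kcal/serving\n", x$energy_per_serving))
  }
  if (length(x$ingredients)) {
    cat("  ingredients:",
        paste(vapply(x$ingredients, `[[`, character(1), "name"),
              collapse = ", "), "\n")
  }
  if (!is.na(x$measured_per)) cat("  measured PER:", x$measured_per, "\n")
  if (!is.na(x$measured_pdcaas)) {
    cat("  measured PDCAAS:", x$measured_pdcaas, "\n")
  }
  invisible(x)
}
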