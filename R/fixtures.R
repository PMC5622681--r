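#' Worked-example foods
#'
#' The package's regulatory worked examples: two high-density breakfast
#' cereals (soy- and chickpea-based, 5 g protein per 55 g reference
#' amount), 125 mL of 2% milk, and four reformulated market foods (bread,
#' low-density breakfast cereal, pancake mix, tricolour pasta), each
#' carrying its measured PER and/or PDCAAS and the regulated serving bases.
#' Per-100 protein densities are chosen so that every arithmetically
#' consistent printed value in the source tables is reproduced from the one
#' density (see the methods vignette for the derivation).
#'
#' @return List with `foods` (named list of [food()] objects) and
#'   `expected` (data frame of the printed metric and tier each framework
#'   reports for these foods, used by the test suite).
#' @export
#' @examples
#' wx <- worked_examples()
#' names(wx$foods)
worked_examples <- function() {
  cereal_bases <- serving_bases(rdi = 28, ra = 55, racc = 55, serving = 55)
  foods <- list(
    soy_cereal = food(
      "soy-based breakfast cereal", protein_per_100 = 5 / 55 * 100,
      bases = cereal_bases, measured_per = 2.0, companion_rdi_g = 30
    ),
    chickpea_cereal = food(
      "chickpea-based breakfast cereal", protein_per_100 = 5 / 55 * 100,
      bases = cereal_bases, measured_per = 2.32, measured_pdcaas = 0.52,
      companion_rdi_g = 30
    ),
    milk_125 = food(
      "2% milk (125 mL, as consumed with cereal)",
      protein_per_100 = 4.3 / 125 * 100,
      bases = serving_bases(rdi = 125, ra = 125, racc = 125, serving = 125,
                            unit_kind = "volume-mL"),
      state = "liquid", measured_per = 2.5, measured_pdcaas = 1.0
    ),
    bread = food(
      "bread (pulse and wheat blend)", protein_per_100 = 17.7 / 125 * 100,
      bases = serving_bases(rdi = 125, ra = 75, racc = 50, serving = 50),
      measured_pdcaas = 0.458
    ),
    low_density_cereal = food(
      "low-density breakfast cereal", protein_per_100 = 18.4,
      bases = serving_bases(rdi = 30, ra = 30, racc = 40, serving = 30),
      measured_pdcaas = 0.671, companion_rdi_g = 30
    ),
    pancake_mix = food(
      "pancake mix", protein_per_100 = 30.4 / 110 * 100,
      bases = serving_bases(ra = 75, racc = 110, serving = 110),
      measured_pdcaas = 0.901
    ),
    pasta = food(
      "tricolour pasta (dry)", protein_per_100 = 14.8,
      bases = serving_bases(rdi = 85, ra = 55, racc = 55, serving = 55),
      measured_pdcaas = 0.549
    )
  )
  expected <- data.frame(
    food = c("chickpea_cereal", "chickpea_cereal", "chickpea_cereal",
             "bread", "bread", "bread", "bread",
             "low_density_cereal", "low_density_cereal",
             "low_density_cereal",
             "low_density_cereal", "low_density_cereal",
             "pancake_mix", "pancake_mix", "pancake_mix", "pancake_mix",
             "pasta", "pasta", "pasta", "pasta"),
    companion = c("milk_125", "milk_125", "milk_125",
                  rep(NA_character_, 7),
                  "milk_125", "milk_125",
                  rep(NA_character_, 8)),
    jurisdiction = c("canada-current", "canada-option1", "canada-option2",
                     "canada-current", "usa", "canada-option1",
                     "canada-option2",
                     "usa", "canada-option1", "canada-option2",
                     "canada-option1", "canada-option2",
                     "canada-current", "usa", "canada-option1",
                     "canada-option2",
                     "canada-current", "usa", "canada-option1",
                     "canada-option2"),
    printed_metric = c(17.1, 9.3, 13.8,
                       20.3, 6.5, 10.6, 9.7,
                       9.9, 5.5, 7.4,
                       9.8, 16.0,
                       46.7, 54.8, 20.7, 37.4,
                       17.3, 8.9, 8.1, 8.9),
    tier = c("none", "good-source", "good-source",
             "good-source", "none", "excellent-source", "source",
             "none", "good-source", "source",
             "good-source", "good-source",
             "excellent-source", "excellent-source", "excellent-source",
             "excellent-source",
             "none", "none", "good-source", "source"),
    stringsAsFactors = FALSE
  )
  list(foods = foods, expected = expected)
}

check_range <- function(r, what, lo = -Inf, hi = Inf) {
  if (!is.numeric(r) || length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
    stop(what, " must be a finite non-empty range c(lo, hi)", call. = FALSE)
  }
  if (r[1] < lo || r[2] > hi) {
    stop(what, " must lie within [", lo, ", ", hi, "]", call. = FALSE)
  }
  r
}

#' Specification for the synthetic food generator
#'
#' Bundles the seed and the sampling ranges for [generate_synthetic_foods()].
#' The same seed and spec always generate identical foods.
#'
#' @param seed Integer RNG seed.
#' @param n_foods Number of foods to generate.
#' @param n_ingredients_range Integer range for ingredients per food.
#' @param digestibility_range Range within (0, 1] for true fecal nitrogen
#'   digestibility.
#' @param aa_multiplier_range Multiplicative range applied per amino acid to
#'   the base scoring pattern when drawing profiles; spanning 1 yields foods
#'   on both sides of an amino acid score of 1.
#' @param protein_per_100_range g protein per 100 g (or mL) range.
#' @param energy_density_range kcal per 100 g range.
#' @return An object of class `synthetic_food_spec`.
#' @export
synthetic_food_spec <- function(seed = 1L, n_foods = 100L,
                                n_ingredients_range = c(1L, 4L),
                                digestibility_range = c(0.5, 1),
                                aa_multiplier_range = c(0.3, 2),
                                protein_per_100_range = c(1, 40),
                                energy_density_range = c(50, 500)) {
  if (n_foods < 0) stop("n_foods must be >= 0", call. = FALSE)
  check_range(n_ingredients_range, "n_ingredients_range", lo = 1)
  check_range(digestibility_range, "digestibility_range", lo = 1e-12, hi = 1)
  check_range(aa_multiplier_range, "aa_multiplier_range", lo = 0)
  check_range(protein_per_100_range, "protein_per_100_range", lo = 0)
  check_range(energy_density_range, "energy_density_range", lo = 0)
  structure(
    list(seed = as.integer(seed), n_foods = as.integer(n_foods),
         n_ingredients_range = as.integer(n_ingredients_range),
         digestibility_range = digestibility_range,
         aa_multiplier_range = aa_multiplier_range,
         protein_per_100_range = protein_per_100_range,
         energy_density_range = energy_density_range),
    class = "synthetic_food_spec"
  )
}

# run code under a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate synthetic foods for property testing
#'
#' Draws foods with random multi-ingredient amino acid profiles (the base
#' scoring pattern scaled by per-amino-acid multipliers), digestibilities,
#' protein densities, serving bases and energy densities. Output is
#' deterministic under the spec's seed, every generated food satisfies all
#' type invariants, and ingredient protein shares sum to 1.
#'
#' @param spec A [synthetic_food_spec()].
#' @param pattern Base amino acid pattern profiles are scaled from
#'   (default: the bundled preschool pattern).
#' @return List of [food()] objects, length `spec$n_foods`.
#' @export
generate_synthetic_foods <- function(spec, pattern = load_scoring_pattern()) {
  stopifnot(inherits(spec, "synthetic_food_spec"))
  if (spec$n_foods == 0) return(list())
  base <- unclass(pattern)
  keys <- amino_acid_keys()
  runif2 <- function(n, r) stats::runif(n, r[1], r[2])
  with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_foods), function(i) {
      n_ing <- sample(seq(spec$n_ingredients_range[1],
                          spec$n_ingredients_range[2]), 1)
      raw_shares <- runif2(n_ing, c(0.05, 1))
      shares <- raw_shares / sum(raw_shares)
      ingredients <- lapply(seq_len(n_ing), function(j) {
        mult <- runif2(length(keys), spec$aa_multiplier_range)
        prof <- base * mult
        names(prof) <- keys
        ingredient_protein(
          name = sprintf("synthetic-ingredient-%d-%d", i, j),
          profile = prof,
          digestibility = runif2(1, spec$digestibility_range),
          protein_share = shares[j]
        )
      })
      state <- sample(c("solid", "liquid"), 1)
      serving <- stats::runif(1, 20, 300)
      energy_density <- runif2(1, spec$energy_density_range)
      food(
        name = sprintf("synthetic-food-%d", i),
        protein_per_100 = runif2(1, spec$protein_per_100_range),
        bases = serving_bases(
          rdi = stats::runif(1, 20, 300), ra = stats::runif(1, 20, 300),
          racc = stats::runif(1, 20, 300), serving = serving,
          unit_kind = if (state == "liquid") "volume-mL" else "mass-g"
        ),
        ingredients = ingredients, state = state,
        energy_per_serving = energy_density * serving / 100
      )
    })
  })
}
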