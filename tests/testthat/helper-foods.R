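# shared builders for small test objects

aa_keys <- amino_acid_keys()

# a named vector over the nine canonical keys with constant value
flat_aa <- function(value = 50) {
  stats::setNames(rep(value, length(aa_keys)), aa_keys)
}

# the bundled preschool pattern, loaded once per test run
test_pattern <- load_scoring_pattern()

# a named vector from the pattern scaled by per-key multipliers
scaled_profile <- function(mult) {
  v <- unclass(test_pattern) * mult
  stats::setNames(v, aa_keys)
}

# minimal solid food with every basis present
simple_food <- function(protein_per_100 = 10, rdi = 100, ra = 50,
                        racc = 50, serving = 50, energy = NA, ...) {
  food("test food", protein_per_100 = protein_per_100,
       bases = serving_bases(rdi = rdi, ra = ra, racc = racc,
                             serving = serving),
       energy_per_serving = energy, ...)
}

# random profile/pattern value in a sensible mg/g range
runif_aa <- function(lo = 5, hi = 120) {
  stats::setNames(stats::runif(length(aa_keys), lo, hi), aa_keys)
}

# random ingredient list of length n with shares summing to 1
random_ingredients <- function(n, d_range = c(0.5, 1)) {
  shares <- stats::runif(n)
  shares <- shares / sum(shares)
  lapply(seq_len(n), function(i) {
    ingredient_protein(paste0("ing", i), runif_aa(),
                       stats::runif(1, d_range[1], d_range[2]), shares[i])
  })
}
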