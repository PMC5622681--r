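new_claim_result <- function(jurisdiction_id, tier, metric_value, basis_used,
                             threshold_applied, trace,
                             components = numeric(0)) {
  structure(
    list(jurisdiction_id = jurisdiction_id, tier = tier,
         metric_value = metric_value, basis_used = basis_used,
         threshold_applied = threshold_applied, trace = trace,
         components = components),
    class = "claim_result"
  )
}

# award the highest tier whose (inclusive >=) threshold the metric meets;
# tiers arrive in ascending stringency order
award_tier <- function(metric, tiers) {
  awarded <- "none"
  threshold <- NA_real_
  for (t in tiers) {
    if (metric >= t$threshold) {
      awarded <- t$tier
      threshold <- t$threshold
    }
  }
  list(tier = awarded, threshold = threshold)
}

fmt <- function(x) format(x, digits = 6, trim = TRUE)

# protein at the rating basis for the current Canadian framework:
# RDI, falling back to RA when no RDI exists (flagged), and switching to the
# declared combined RDI when a companion is being evaluated
rating_basis <- function(x, combined, trace) {
  if (combined && !is.na(x$companion_rdi_g)) {
    amount <- x$companion_rdi_g
    trace <- c(trace, paste0(x$name, ": combined-consumption RDI ",
                             fmt(amount), " used"))
  } else if (!is.na(x$bases$amounts[["rdi"]])) {
    amount <- x$bases$amounts[["rdi"]]
  } else if (!is.na(x$bases$amounts[["ra"]])) {
    amount <- x$bases$amounts[["ra"]]
    trace <- c(trace, paste0(x$name,
                             ": no RDI exists; reference amount ",
                             fmt(amount), " used in its place"))
  } else {
    stop("food '", x$name, "' has neither an RDI nor a reference amount",
         call. = FALSE)
  }
  list(amount = amount, trace = trace)
}

#' Evaluate the current Canadian protein-rating claim
#'
#' Protein rating = PER x grams of protein in the RDI. A rating >= 20 is a
#' good source, >= 40 an excellent source (two tiers; "source" and "good
#' source" are equivalent under this framework). A declared companion food
#' (the regulated case is breakfast cereal plus 125 mL milk) contributes the
#' sum of the two ratings, with the cereal's RDI switched to its declared
#' combined-consumption RDI.
#'
#' @param x A [food()] with a PER, measured or derived via the CFIA
#'   conversion from its PDCAAS.
#' @param companion Optional companion [food()]. Requires the main food to
#'   declare a `companion_rdi_g`.
#' @param paper_rounding Round protein grams and per-food ratings half-up to
#'   1 decimal before summing/comparison, as the regulatory tables do.
#' @param rules A `jurisdiction_rules` object (default: the bundled set).
#' @return A `claim_result`.
#' @export
evaluate_canada_current <- function(x, companion = NULL,
                                    paper_rounding = FALSE,
                                    rules = load_jurisdiction("canada-current")) {
  stopifnot(inherits(x, "food"))
  combined <- !is.null(companion)
  if (combined && is.na(x$companion_rdi_g)) {
    stop("food '", x$name, "' declares no combined-consumption RDI; ",
         "companion combination is restricted to declared pairs",
         call. = FALSE)
  }
  trace <- character(0)
  foods <- if (combined) list(x, companion) else list(x)
  ratings <- numeric(0)
  for (f in foods) {
    b <- rating_basis(f, combined, trace)
    trace <- b$trace
    grams <- maybe_round(protein_at_basis(f, b$amount), paper_rounding)
    per <- food_per(f)
    rating <- maybe_round(protein_rating(per$per, grams), paper_rounding)
    trace <- c(trace, sprintf(
      "%s: PER %s (%s) x %s g protein per %s = rating %s",
      f$name, fmt(per$per), per$source, fmt(grams), fmt(b$amount),
      fmt(rating)))
    ratings <- c(ratings, rating)
  }
  total <- sum(ratings)
  if (combined) {
    trace <- c(trace, sprintf("combined rating = %s = %s",
                              paste(fmt(ratings), collapse = " + "),
                              fmt(total)))
  }
  a <- award_tier(total, rules$tiers)
  trace <- c(trace, sprintf("rating %s vs thresholds (>=20 good, >=40 excellent) -> %s",
                            fmt(total), a$tier))
  new_claim_result(rules$jurisdiction_id, a$tier, total, "rdi",
                   a$threshold, trace, ratings)
}

#' Evaluate the proposed Canadian Option 1 claim (absolute protein)
#'
#' Protein quality is not considered: the metric is total grams of protein
#' per reference amount, summed over the food and an optional companion.
#' Tiers: >= 5 g good source, >= 10 g excellent source.
#'
#' @inheritParams evaluate_canada_current
#' @return A `claim_result`.
#' @export
evaluate_canada_option1 <- function(x, companion = NULL,
                                    paper_rounding = FALSE,
                                    rules = load_jurisdiction("canada-option1")) {
  stopifnot(inherits(x, "food"))
  foods <- c(list(x), if (!is.null(companion)) list(companion))
  trace <- character(0)
  grams <- vapply(foods, function(f) {
    g <- protein_at_basis(f, "ra", paper_rounding)
    trace <<- c(trace, sprintf("%s: %s g protein per RA (%s)",
                               f$name, fmt(g), fmt(f$bases$amounts[["ra"]])))
    g
  }, numeric(1))
  total <- sum(grams)
  a <- award_tier(total, rules$tiers)
  trace <- c(trace, sprintf("total %s g per RA vs thresholds (>=5 good, >=10 excellent) -> %s",
                            fmt(total), a$tier))
  new_claim_result(rules$jurisdiction_id, a$tier, total, "ra",
                   a$threshold, trace, grams)
}

#' Evaluate the proposed Canadian Option 2 claim (PDCAAS-corrected %DV)
#'
#' The metric is PDCAAS-corrected protein per reference amount, expressed as
#' percent of the 50 g protein Daily Value; for declared combinations the
#' corrected protein levels are summed before taking the %DV. Three tiers:
#' >= 5% DV (2.5 g) source, >= 10% (5 g) good source, >= 20% (10 g)
#' excellent source.
#'
#' @inheritParams evaluate_canada_current
#' @param paper_rounding Round the final %DV half-up to 1 decimal before
#'   threshold comparison, the precision the regulatory tables print.
#'   Corrected grams are never rounded before summing.
#' @param dv_g Protein Daily Value in g (default 50).
#' @param variant Mixture PDCAAS variant when computing from ingredients.
#' @return A `claim_result`.
#' @export
evaluate_canada_option2 <- function(x, companion = NULL, dv_g = 50,
                                    paper_rounding = FALSE,
                                    variant = c("1991", "2007"),
                                    rules = load_jurisdiction("canada-option2")) {
  stopifnot(inherits(x, "food"))
  variant <- match.arg(variant)
  foods <- c(list(x), if (!is.null(companion)) list(companion))
  trace <- character(0)
  corrected <- vapply(foods, function(f) {
    q <- food_pdcaas(f, variant = variant)
    g <- protein_at_basis(f, "ra")
    cp <- corrected_protein(q$pdcaas, g, dv_g)$grams
    trace <<- c(trace, sprintf(
      "%s: PDCAAS %s (%s) x %s g per RA = %s g corrected",
      f$name, fmt(q$pdcaas), q$method_variant, fmt(g), fmt(cp)))
    cp
  }, numeric(1))
  total_g <- sum(corrected)
  pct <- maybe_round(total_g / dv_g * 100, paper_rounding)
  trace <- c(trace, sprintf("total corrected %s g / %s g DV = %s %%DV",
                            fmt(total_g), fmt(dv_g), fmt(pct)))
  a <- award_tier(pct, rules$tiers)
  trace <- c(trace, sprintf(
    "%s %%DV vs thresholds (>=5 source, >=10 good, >=20 excellent) -> %s",
    fmt(pct), a$tier))
  new_claim_result(rules$jurisdiction_id, a$tier, pct, "ra",
                   a$threshold, trace, corrected / dv_g * 100)
}

#' Evaluate the USA protein content claim
#'
#' PDCAAS-corrected protein per reference amount customarily consumed
#' (RACC), as percent of the protein DV: 50 g for children >= 4 y through
#' adults, 13 g for children 1-3 y. Tiers: >= 10% DV good source, >= 20%
#' excellent source. Foods for infants (<= 12 months) require the PER
#' bioassay and cannot be evaluated here.
#'
#' @inheritParams evaluate_canada_option2
#' @param age_group `"4y-adult"` (DV 50 g) or `"1-3y"` (DV 13 g);
#'   `"infant"` is rejected.
#' @return A `claim_result`.
#' @export
evaluate_usa <- function(x, age_group = c("4y-adult", "1-3y"),
                         paper_rounding = FALSE,
                         variant = c("1991", "2007"),
                         rules = load_jurisdiction("usa")) {
  stopifnot(inherits(x, "food"))
  if (identical(age_group, "infant")) {
    stop("foods intended for infants (<= 12 months) require the PER ",
         "bioassay and are not evaluable with PDCAAS", call. = FALSE)
  }
  age_group <- match.arg(age_group)
  dv_g <- if (age_group == "1-3y") {
    rules$constants$dv_g_1_3y$value
  } else {
    rules$constants$dv_g$value
  }
  q <- food_pdcaas(x, variant = match.arg(variant))
  g <- protein_at_basis(x, "racc")
  cp <- corrected_protein(q$pdcaas, g, dv_g, basis = "racc")
  pct <- maybe_round(cp$percent_dv, paper_rounding)
  trace <- c(
    sprintf("%s: PDCAAS %s (%s) x %s g per RACC = %s g corrected",
            x$name, fmt(q$pdcaas), q$method_variant, fmt(g), fmt(cp$grams)),
    sprintf("%s g / %s g DV (%s) = %s %%DV", fmt(cp$grams), fmt(dv_g),
            age_group, fmt(pct)))
  a <- award_tier(pct, rules$tiers)
  trace <- c(trace, sprintf(
    "%s %%DV vs thresholds (>=10 good, >=20 excellent) -> %s",
    fmt(pct), a$tier))
  new_claim_result(rules$jurisdiction_id, a$tier, pct, "racc",
                   a$threshold, trace, pct)
}

#' Evaluate the EU protein content claim
#'
#' The EU metric is the percent of a serving's energy provided by protein
#' (protein grams x 4 kcal/g over total kcal). Tiers: >= 12% source,
#' >= 20% high in protein.
#'
#' @inheritParams evaluate_canada_current
#' @param kcal_per_g Energy conversion factor for protein (default the
#'   Atwater 4 kcal/g; the rules file carries it as a cited constant).
#' @return A `claim_result`.
#' @export
evaluate_eu <- function(x, paper_rounding = FALSE,
                        rules = load_jurisdiction("eu"),
                        kcal_per_g = rules$constants$protein_kcal_per_g$value) {
  stopifnot(inherits(x, "food"))
  if (is.na(x$energy_per_serving) || x$energy_per_serving <= 0) {
    stop("food '", x$name,
         "' has no (positive) energy per serving; the EU rule needs it",
         call. = FALSE)
  }
  g <- protein_at_basis(x, "serving", paper_rounding)
  pct <- maybe_round(g * kcal_per_g / x$energy_per_serving * 100,
                     paper_rounding)
  trace <- c(
    sprintf("%s: %s g protein x %s kcal/g = %s kcal from protein",
            x$name, fmt(g), fmt(kcal_per_g), fmt(g * kcal_per_g)),
    sprintf("%s / %s kcal per serving = %s%% of energy",
            fmt(g * kcal_per_g), fmt(x$energy_per_serving), fmt(pct)))
  a <- award_tier(pct, rules$tiers)
  trace <- c(trace, sprintf(
    "%s%% energy vs thresholds (>=12 source, >=20 high) -> %s",
    fmt(pct), a$tier))
  new_claim_result(rules$jurisdiction_id, a$tier, pct, "serving",
                   a$threshold, trace, pct)
}

#' Evaluate the Australia / New Zealand protein content claim
#'
#' Absolute protein per serving: >= 5 g permits a general protein claim,
#' >= 10 g a good-source claim.
#'
#' @inheritParams evaluate_canada_current
#' @return A `claim_result`.
#' @export
evaluate_anz <- function(x, paper_rounding = FALSE,
                         rules = load_jurisdiction("anz")) {
  stopifnot(inherits(x, "food"))
  g <- protein_at_basis(x, "serving", paper_rounding)
  trace <- sprintf("%s: %s g protein per serving", x$name, fmt(g))
  a <- award_tier(g, rules$tiers)
  trace <- c(trace, sprintf(
    "%s g vs thresholds (>=5 general, >=10 good source) -> %s",
    fmt(g), a$tier))
  new_claim_result(rules$jurisdiction_id, a$tier, g, "serving",
                   a$threshold, trace, g)
}

#' Evaluate the Codex / China / South Korea NRV-based claim
#'
#' These frameworks compare protein to a daily Nutrient Reference Value
#' (NRV: Codex 50 g, South Korea 55 g, China 60 g) through several routes,
#' any one of which qualifies the food ("or" semantics):
#' per 100 g for solids (>= 10% NRV), per 100 mL for liquids (>= 5% NRV),
#' per 100 kcal (Codex, South Korea) or per 420 kJ (China) (>= 5% NRV), and
#' per serving (Codex, South Korea only; >= 10% NRV). A food meeting twice
#' the source level on any route is a high source. Every evaluable route's
#' value is recorded in the trace; routes lacking data are skipped, and it
#' is an error only if no route at all can be evaluated.
#'
#' @inheritParams evaluate_canada_current
#' @param region `"codex"`, `"china"` or `"south-korea"`, naming the bundled
#'   rules file to use (ignored when `rules` is supplied directly).
#' @param kj_per_kcal Energy unit conversion (default 4.184).
#' @return A `claim_result`; `metric_value` is the best route's percent of
#'   the NRV relative to its own threshold being 100% x (value/threshold) is
#'   not used -- the raw percent of NRV of the best qualifying route is
#'   reported, with the route named in `basis_used`.
#' @export
evaluate_nrv_family <- function(x, region = c("codex", "china", "south-korea"),
                                paper_rounding = FALSE,
                                rules = NULL, kj_per_kcal = 4.184) {
  stopifnot(inherits(x, "food"))
  if (is.null(rules)) rules <- load_jurisdiction(match.arg(region))
  nrv <- rules$constants$nrv_g$value
  trace <- character(0)
  evaluated <- list()
  for (r in rules$routes) {
    amount <- NA_real_
    if (r$route == "per-100g") {
      if (x$state == "solid") amount <- x$protein_per_100
    } else if (r$route == "per-100mL") {
      if (x$state == "liquid") amount <- x$protein_per_100
    } else if (r$route == "per-energy") {
      serv <- x$bases$amounts[["serving"]]
      if (!is.na(x$energy_per_serving) && x$energy_per_serving > 0 &&
          !is.na(serv)) {
        g_serv <- protein_at_basis(x, "serving")
        amount <- if (identical(rules$energy_rule_unit, "kJ-420")) {
          g_serv * 420 / (x$energy_per_serving * kj_per_kcal)
        } else {
          g_serv * 100 / x$energy_per_serving
        }
      }
    } else if (r$route == "per-serving") {
      if (!is.na(x$bases$amounts[["serving"]])) {
        amount <- protein_at_basis(x, "serving")
      }
    }
    if (is.na(amount)) next
    pct <- maybe_round(amount / nrv * 100, paper_rounding)
    evaluated[[r$route]] <- list(pct = pct, threshold = r$threshold_pct_nrv)
    trace <- c(trace, sprintf(
      "route %s: %s g protein = %s%% of %s g NRV (source needs >=%s%%)",
      r$route, fmt(amount), fmt(pct), fmt(nrv), fmt(r$threshold_pct_nrv)))
  }
  if (!length(evaluated)) {
    stop("food '", x$name, "': no NRV route evaluable (missing state/",
         "energy/serving data)", call. = FALSE)
  }
  mult <- vapply(rules$tiers, function(t) as.numeric(t$threshold_multiplier),
                 numeric(1))
  names(mult) <- vapply(rules$tiers, `[[`, character(1), "tier")
  tier <- "none"; best_route <- NA_character_
  best_pct <- NA_real_; thr_applied <- NA_real_
  for (i in seq_along(mult)) {
    hits <- Filter(function(e) e$pct >= e$threshold * mult[i], evaluated)
    if (length(hits)) {
      tier <- names(mult)[i]
      # report the route with the largest margin over its threshold
      margin <- vapply(hits, function(e) e$pct / e$threshold, numeric(1))
      best_route <- names(hits)[which.max(margin)]
      best_pct <- hits[[which.max(margin)]]$pct
      thr_applied <- hits[[which.max(margin)]]$threshold * mult[i]
    }
  }
  if (tier == "none") {
    first <- evaluated[[1]]
    best_route <- names(evaluated)[1]
    best_pct <- first$pct
    thr_applied <- first$threshold
  }
  trace <- c(trace, sprintf("any-route semantics -> %s", tier))
  new_claim_result(rules$jurisdiction_id, tier, best_pct,
                   paste0("nrv:", best_route), thr_applied, trace,
                   vapply(evaluated, `[[`, numeric(1), "pct"))
}

#' Evaluate a food against every configured jurisdiction
#'
#' Jurisdictions that lack required data (no energy, no serving basis, no
#' quality score, no declared companion pair) return a `claim_result` with
#' tier `"none"` and the reason in the trace rather than failing the batch.
#' The companion is only passed to the frameworks with a combination rule
#' (canada-current, canada-option1, canada-option2).
#'
#' @inheritParams evaluate_canada_current
#' @param jurisdictions Character vector of jurisdiction ids (default: all
#'   bundled ones).
#' @return A list of `claim_result` objects (class `claim_result_list`),
#'   one per jurisdiction.
#' @export
evaluate_all <- function(x, companion = NULL,
                         jurisdictions = list_jurisdictions(),
                         paper_rounding = FALSE) {
  stopifnot(inherits(x, "food"))
  res <- lapply(jurisdictions, function(j) {
    tryCatch({
      switch(j,
        "canada-current" = evaluate_canada_current(x, companion,
                                                   paper_rounding),
        "canada-option1" = evaluate_canada_option1(x, companion,
                                                   paper_rounding),
        "canada-option2" = evaluate_canada_option2(x, companion,
                                                   paper_rounding = paper_rounding),
        "usa" = evaluate_usa(x, paper_rounding = paper_rounding),
        "eu" = evaluate_eu(x, paper_rounding),
        "anz" = evaluate_anz(x, paper_rounding),
        "codex" = ,
        "china" = ,
        "south-korea" = evaluate_nrv_family(x, j, paper_rounding),
        stop("unknown jurisdiction '", j, "'", call. = FALSE)
      )
    }, error = function(e) {
      new_claim_result(j, "none", NA_real_, NA_character_, NA_real_,
                       paste("not evaluable:", conditionMessage(e)))
    })
  })
  structure(res, class = "claim_result_list", food = x$name)
}

#' @export
print.claim_result <- function(x, ...) {
  cat(sprintf("[%s] tier: %s", x$jurisdiction_id, x$tier))
  if (!is.na(x$metric_value)) {
    cat(sprintf("  (metric %.3f on %s, threshold %s)", x$metric_value,
                x$basis_used,
                if (is.na(x$threshold_applied)) "-" else x$threshold_applied))
  }
  cat("\n")
  for (step in x$trace) cat("   ", step, "\n")
  invisible(x)
}

#' @export
print.claim_result_list <- function(x, ...) {
  cat("Claim evaluation:", attr(x, "food"), "\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Flatten claim results into a data frame
#'
#' @param x A `claim_result_list` from [evaluate_all()].
#' @param ... Unused.
#' @return A data frame with one row per jurisdiction: id, tier, metric,
#'   basis, threshold.
#' @export
as.data.frame.claim_result_list <- function(x, ...) {
  data.frame(
    jurisdiction = vapply(x, `[[`, character(1), "jurisdiction_id"),
    tier = vapply(x, `[[`, character(1), "tier"),
    metric = vapply(x, `[[`, numeric(1), "metric_value"),
    basis = vapply(x, `[[`, character(1), "basis_used"),
    threshold = vapply(x, `[[`, numeric(1), "threshold_applied"),
    row.names = NULL
  )
}
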