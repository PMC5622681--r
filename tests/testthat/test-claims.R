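wx <- worked_examples()

test_that("current Canadian framework reproduces the cereal-plus-milk example", {
  f <- wx$foods
  r <- evaluate_canada_current(f$chickpea_cereal, f$milk_125,
                               paper_rounding = TRUE)
  expect_equal(r$components, c(6.3, 10.8))
  expect_equal(r$metric_value, 17.1)
  expect_identical(r$tier, "none")
  expect_true(any(grepl("combined-consumption RDI", r$trace)))

  # alone at the 28 g RDI the table prints a rating of 5.8
  alone <- evaluate_canada_current(f$chickpea_cereal, paper_rounding = TRUE)
  expect_equal(alone$metric_value, 5.8)
  soy <- evaluate_canada_current(f$soy_cereal, paper_rounding = TRUE)
  expect_equal(soy$metric_value, 5.0)

  # inclusive thresholds: exactly 20 is a good source, exactly 40 excellent
  at20 <- food("boundary", 20, serving_bases(rdi = 100), measured_per = 1)
  expect_identical(evaluate_canada_current(at20)$tier, "good-source")
  at40 <- food("boundary", 40, serving_bases(rdi = 100), measured_per = 1)
  expect_identical(evaluate_canada_current(at40)$tier, "excellent-source")

  # combination requires a declared pair
  expect_error(evaluate_canada_current(f$bread, f$milk_125),
               "declares no combined-consumption RDI")
  # no RDI and no RA is an error; RA-only falls back with a trace flag
  expect_error(
    evaluate_canada_current(food("x", 10, serving_bases(racc = 50),
                                 measured_per = 2)),
    "neither an RDI nor a reference amount")
  fb <- evaluate_canada_current(wx$foods$pancake_mix)
  expect_true(any(grepl("no RDI exists", fb$trace)))
})

test_that("Option 1 sums grams per reference amount with inclusive tiers", {
  f <- wx$foods
  r <- evaluate_canada_option1(f$chickpea_cereal, f$milk_125,
                               paper_rounding = TRUE)
  expect_equal(r$metric_value, 9.3)
  expect_identical(r$tier, "good-source")
  expect_equal(sum(r$components), r$metric_value, tolerance = 1e-12)

  ten <- food("x", 20, serving_bases(ra = 50))
  expect_identical(evaluate_canada_option1(ten)$tier, "excellent-source")
  five <- food("x", 10, serving_bases(ra = 50))
  expect_identical(evaluate_canada_option1(five)$tier, "good-source")
  under <- food("x", 9.8, serving_bases(ra = 50))
  expect_identical(evaluate_canada_option1(under)$tier, "none")
  expect_error(evaluate_canada_option1(food("x", 10,
                                            serving_bases(rdi = 50))),
               "no RA")
})

test_that("Option 2 computes corrected %DV of 50 g with three inclusive tiers", {
  f <- wx$foods
  r <- evaluate_canada_option2(f$chickpea_cereal, f$milk_125,
                               paper_rounding = TRUE)
  expect_equal(sum(r$components) / 100 * 50, 6.9, tolerance = 1e-12)
  expect_equal(r$metric_value, 13.8)
  expect_identical(r$tier, "good-source")

  # corrected 2.5 g is exactly 5 %DV: lowest tier, inclusive
  src <- food("x", 5, serving_bases(ra = 50), measured_pdcaas = 1)
  r <- evaluate_canada_option2(src)
  expect_equal(r$metric_value, 5)
  expect_identical(r$tier, "source")
  none <- food("x", 0, serving_bases(ra = 50), measured_pdcaas = 1)
  expect_identical(evaluate_canada_option2(none)$tier, "none")
  expect_error(evaluate_canada_option2(food("x", 10,
                                            serving_bases(ra = 50))),
               "no ingredient profiles")
})

test_that("USA framework handles both DVs and rejects infant foods", {
  f <- wx$foods
  r <- evaluate_usa(f$bread, paper_rounding = TRUE)
  expect_equal(r$metric_value, 6.5)
  expect_identical(r$tier, "none")
  r <- evaluate_usa(f$pancake_mix, paper_rounding = TRUE)
  expect_equal(r$metric_value, 54.8)
  expect_identical(r$tier, "excellent-source")

  # exactly 5 g corrected against DV 50 is 10 %DV: good source, inclusive
  b <- food("x", 10, serving_bases(racc = 50), measured_pdcaas = 1)
  r <- evaluate_usa(b)
  expect_equal(r$metric_value, 10)
  expect_identical(r$tier, "good-source")

  # toddler DV of 13 g raises the %DV for the same food
  r13 <- evaluate_usa(b, age_group = "1-3y")
  expect_equal(r13$metric_value, 5 / 13 * 100, tolerance = 1e-12)
  expect_error(evaluate_usa(b, age_group = "infant"), "infant")
})

test_that("EU framework scores percent of energy from protein", {
  # 6 g protein (24 kcal) in a 200 kcal serving: exactly 12%
  f <- food("x", 12, serving_bases(serving = 50), energy_per_serving = 200)
  r <- evaluate_eu(f)
  expect_equal(r$metric_value, 12)
  expect_identical(r$tier, "source")
  # 10 g protein (40 kcal) in 200 kcal: 20%, high in protein
  f <- food("x", 20, serving_bases(serving = 50), energy_per_serving = 200)
  r <- evaluate_eu(f)
  expect_equal(r$metric_value, 20)
  expect_identical(r$tier, "high-source")
  f <- food("x", 0, serving_bases(serving = 50), energy_per_serving = 200)
  expect_identical(evaluate_eu(f)$tier, "none")
  expect_error(evaluate_eu(food("x", 10, serving_bases(serving = 50))),
               "energy")
})

test_that("ANZ framework uses absolute grams per serving", {
  f <- food("x", 10, serving_bases(serving = 50))
  expect_identical(evaluate_anz(f)$tier, "general")      # exactly 5 g
  f <- food("x", 20, serving_bases(serving = 50))
  expect_identical(evaluate_anz(f)$tier, "good-source")  # exactly 10 g
  f <- food("x", 9.98, serving_bases(serving = 50))
  expect_identical(evaluate_anz(f)$tier, "none")         # 4.99 g
  expect_error(evaluate_anz(food("x", 10, serving_bases(ra = 50))),
               "no SERVING")
})

test_that("NRV family evaluates every applicable route with OR semantics", {
  # solid, 10 g/100 g, codex NRV 50: 20% per 100 g, at 2x source level
  solid <- food("x", 10, serving_bases(serving = 100))
  r <- evaluate_nrv_family(solid, "codex")
  expect_identical(r$tier, "high-source")
  expect_true(any(grepl("per-100g", r$trace)))

  # liquid at 1.25 g/100 mL: 2.5% of NRV, below the 5% liquid threshold
  liquid <- food("x", 1.25, serving_bases(serving = 100,
                                          unit_kind = "volume-mL"),
                 state = "liquid")
  r <- evaluate_nrv_family(liquid, "codex")
  expect_identical(r$tier, "none")

  # china: NRV 60 g, 420 kJ energy unit, no per-serving route
  china_rules <- load_jurisdiction("china")
  expect_equal(china_rules$constants$nrv_g$value, 60)
  expect_false("per-serving" %in%
                 vapply(china_rules$routes, `[[`, character(1), "route"))
  # 8 g/100 g solid: 16% of 50 g NRV (codex source) but 13.3% of 60 g
  # (china source too); drop to 5.5 g/100g: 11% codex = source, 9.2% china = none
  mid <- food("x", 5.5, serving_bases(serving = 100))
  expect_identical(evaluate_nrv_family(mid, "codex")$tier, "source")
  expect_identical(evaluate_nrv_family(mid, "china")$tier, "none")

  # energy route: 420 kJ unit vs 100 kcal unit
  energetic <- food("x", 4, serving_bases(serving = 100),
                    energy_per_serving = 100)
  rc <- evaluate_nrv_family(energetic, "codex")
  expect_true(any(grepl("per-energy", rc$trace)))

  # a liquid without serving or energy data still has its per-100 mL route
  liquid_no_data <- food("x", 2, serving_bases(ra = 100,
                                               unit_kind = "volume-mL"),
                         state = "liquid")
  r <- evaluate_nrv_family(liquid_no_data, "china")
  expect_identical(r$tier, "none")  # 3.3% of the 60 g NRV, below 5%
  expect_length(r$components, 1)
  expect_true(grepl("per-100mL", names(r$components)))
})

test_that("evaluate_all returns one result per jurisdiction, never failing the batch", {
  f <- wx$foods$pasta
  res <- evaluate_all(f)
  expect_length(res, length(list_jurisdictions()))
  expect_identical(vapply(res, `[[`, character(1), "jurisdiction_id"),
                   list_jurisdictions())
  by_id <- setNames(res, list_jurisdictions())
  expect_identical(by_id[["canada-current"]]$tier, "none")
  expect_identical(by_id[["usa"]]$tier, "none")
  expect_identical(by_id[["canada-option1"]]$tier, "good-source")
  expect_identical(by_id[["canada-option2"]]$tier, "source")
  # pasta has no energy data: EU not evaluable, reported not errored
  expect_identical(by_id[["eu"]]$tier, "none")
  expect_true(any(grepl("not evaluable", by_id[["eu"]]$trace)))

  expect_identical(evaluate_all(f, jurisdictions = character(0)),
                   structure(list(), class = "claim_result_list",
                             food = f$name))

  bread <- evaluate_all(wx$foods$bread, paper_rounding = TRUE)
  bread_o1 <- bread[[which(list_jurisdictions() == "canada-option1")]]
  expect_equal(bread_o1$metric_value, 10.6)
  expect_identical(bread_o1$tier, "excellent-source")
})

test_that("every printed worked-example verdict is reproduced", {
  f <- wx$foods
  ex <- wx$expected
  for (i in seq_len(nrow(ex))) {
    fd <- f[[ex$food[i]]]
    comp <- if (!is.na(ex$companion[i])) f[[ex$companion[i]]] else NULL
    r <- switch(ex$jurisdiction[i],
      "canada-current" = evaluate_canada_current(fd, comp),
      "canada-option1" = evaluate_canada_option1(fd, comp),
      "canada-option2" = evaluate_canada_option2(fd, comp),
      "usa" = evaluate_usa(fd))
    expect_equal(round_half_up(r$metric_value, 1), ex$printed_metric[i],
                 info = paste(ex$food[i], ex$jurisdiction[i]))
    expect_identical(r$tier, ex$tier[i],
                     info = paste(ex$food[i], ex$jurisdiction[i]))
  }
})

test_that("traces are complete and replay to the reported metric", {
  f <- wx$foods
  checks <- list(
    evaluate_canada_current(f$chickpea_cereal, f$milk_125),
    evaluate_canada_option1(f$chickpea_cereal, f$milk_125),
    evaluate_canada_option2(f$bread),
    evaluate_usa(f$pancake_mix),
    evaluate_anz(f$pasta)
  )
  for (r in checks) {
    expect_gt(length(r$trace), 0)
    expect_equal(sum(r$components), r$metric_value, tolerance = 1e-9)
  }
})

test_that("raising protein content never lowers the awarded tier", {
  tier_rank <- c(none = 0, source = 1, general = 1, `good-source` = 2,
                 `excellent-source` = 3, `high-source` = 3)
  evaluators <- list(
    function(f) evaluate_canada_current(f),
    function(f) evaluate_canada_option1(f),
    function(f) evaluate_canada_option2(f),
    function(f) evaluate_usa(f),
    function(f) evaluate_eu(f),
    function(f) evaluate_anz(f),
    function(f) evaluate_nrv_family(f, "codex"),
    function(f) evaluate_nrv_family(f, "china"),
    function(f) evaluate_nrv_family(f, "south-korea")
  )
  set.seed(2024)
  for (i in 1:15) {
    lo <- runif(1, 1, 25)
    f1 <- food("lo", lo, serving_bases(rdi = 80, ra = 60, racc = 60,
                                       serving = 60),
               measured_pdcaas = runif(1), energy_per_serving = 250)
    f1$measured_per <- per_from_pdcaas(f1$measured_pdcaas)
    f2 <- f1
    f2$protein_per_100 <- lo * runif(1, 1, 3)
    for (ev in evaluators) {
      t1 <- tier_rank[[ev(f1)$tier]]
      t2 <- tier_rank[[ev(f2)$tier]]
      expect_gte(t2, t1)
    }
  }
})
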