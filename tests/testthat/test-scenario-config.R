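test_that("prop_param parses all encodings losslessly and in range", {
  cases <- list(
    list(text = "25%", value = 0.25),
    list(text = "0.528%", value = 0.00528),
    list(text = "39.3%", value = 0.393),
    list(text = "1/78", value = 1 / 78),
    list(text = "0.013", value = 0.013),
    list(text = "98.0%", value = 0.98)
  )
  for (cs in cases) {
    p <- prop_param("x", cs$text)
    expect_identical(p$text, cs$text)
    expect_equal(prop_value(p), cs$value)
  }
  # a percentage string and its decimal form are the identical fraction
  expect_identical(
    prop_param("a", "0.528%")[c("num", "den")],
    prop_param("a", "0.00528")[c("num", "den")]
  )
  expect_error(prop_param("awareness", "1.5"), "outside \\[0, 1\\]")
  expect_error(prop_param("awareness", "150%"), "outside")
  expect_error(prop_param("awareness", "abc"), "cannot parse")
  expect_error(prop_param("bad", "1/0"), "cannot parse")
})

test_that("paper fixtures carry the published parameter columns", {
  fx <- paper_fixtures()
  expect_named(fx, c("base", "best", "worst"))

  stage_vals <- function(s) unname(vapply(s$stages, prop_value, 0))
  expect_equal(stage_vals(fx$base$supply), c(0.25, 0.15, 0.03, 0.013))
  expect_equal(stage_vals(fx$best$supply), c(0.55, 0.50, 0.25, 1 / 78))
  expect_identical(fx$best$supply$stages$medical_pass$text, "1/78")
  expect_identical(fx$base$supply$stages$medical_pass$text, "0.013")
  expect_identical(fx$base$supply$population_base, 4307710)
  expect_identical(fx$base$supply$births_per_donor, 25)
  # worst case flips only the three demand rates
  expect_equal(
    prop_value(fx$worst$demand_segments$same_sex_couples$seeking_chain$wishing_children),
    0.25)
  expect_equal(
    prop_value(fx$worst$demand_segments$single_women$seeking_chain$seeking_donation),
    0.01)
  expect_equal(
    prop_value(fx$worst$demand_segments$heterosexual_couples$seeking_chain$seeking_donation),
    0.03)
  expect_identical(fx$worst$supply, fx$base$supply)
  # demand bases
  sw <- fx$base$demand_segments$single_women
  expect_identical(sw$base_population, 5567965)
  expect_equal(prop_value(sw$base_chain$single_fraction), 0.393)
  expect_identical(fx$base$demand_segments$same_sex_couples$base_count, 29380)
  expect_identical(fx$base$demand_segments$heterosexual_couples$base_count,
                   3335815)
})

test_that("write/load round-trip is the identity for every fixture", {
  fx <- paper_fixtures()
  for (nm in names(fx)) {
    expect_identical(load_scenario(write_scenario(fx[[nm]])), fx[[nm]])
  }
  expect_identical(load_scenarios(write_scenarios(fx)), fx)
  # canonical-form idempotence: write . load . write == write
  txt <- write_scenario(fx$base)
  expect_identical(write_scenario(load_scenario(txt)), txt)
  # rational encoding survives a round-trip exactly
  rt <- load_scenario(write_scenario(fx$best))
  expect_identical(rt$supply$stages$medical_pass$text, "1/78")
  expect_identical(rt$supply$stages$medical_pass$num, 1)
  expect_identical(rt$supply$stages$medical_pass$den, 78)
})

test_that("the packaged config file equals the in-code fixtures", {
  path <- system.file("extdata", "paper_scenarios.cfg", package = "donorgap")
  expect_true(nzchar(path))
  expect_identical(read_scenario_collection(path), paper_fixtures())
  # worst-case text carries the liberal demand rates
  txt <- write_scenario(paper_fixtures()$worst)
  expect_match(txt, "wishing_children = 25%", fixed = TRUE)
  expect_match(txt, "seeking.seeking_donation = 1%", fixed = TRUE)
  expect_match(txt, "seeking_donation = 3%", fixed = TRUE)
})

test_that("malformed configs give diagnostics naming line or key, never a partial spec", {
  base_txt <- write_scenario(paper_fixtures()$base)
  expect_error(load_scenario(sub("25%", "150%", base_txt, fixed = TRUE)),
               "outside")
  expect_error(load_scenario("supply.population_base = 10"),
               "before any \\[scenario")
  expect_error(load_scenario("[scenario:x]\nsupply.population_base 10"),
               "line 2")
  expect_error(
    load_scenario(sub("supply.population_base = 4307710\n", "", base_txt,
                      fixed = TRUE)),
    "missing required key 'supply.population_base'")
  expect_error(load_scenario("[scenario:x]\nnonsense.key = 1"),
               "unknown key")
  expect_error(
    load_scenario(paste0(base_txt, "\n", write_scenario(paper_fixtures()$base))),
    "duplicate scenario")
  # selection errors
  expect_error(load_scenario(write_scenarios(paper_fixtures())),
               "pass `name`")
  expect_error(load_scenario(base_txt, name = "nope"), "not found")
})

test_that("spec constructors validate their invariants", {
  expect_error(supply_spec(100, list(), 25), "non-empty")
  expect_error(supply_spec(100, list(prop_param("a", "10%")), 0),
               "births_per_donor")
  expect_error(
    demand_segment_spec("x", base_count = 10, base_population = 10,
                        recipient_eligibility = prop_param("e", "98%")),
    "exactly one")
  expect_error(
    demand_segment_spec("x", recipient_eligibility = prop_param("e", "98%")),
    "exactly one")
  expect_error(
    demand_segment_spec("x", base_population = 100,
                        recipient_eligibility = prop_param("e", "98%")),
    "base_chain")
  expect_error(scenario_spec("s", paper_fixtures()$base$supply, list()),
               "at least one")
})

test_that("parameter paths address every proportion and reject unknowns", {
  sc <- paper_fixtures()$base
  paths <- list_parameters(sc)
  expect_true(all(c("supply.awareness",
                    "demand.single_women.base.single_fraction",
                    "demand.same_sex_couples.seeking.wishing_children",
                    "demand.heterosexual_couples.recipient_eligibility")
                  %in% paths))
  for (p in paths) {
    sc2 <- set_scenario_parameter(sc, p, 0.5)
    expect_equal(prop_value(donorgap:::get_scenario_parameter(sc2, p)), 0.5)
  }
  expect_error(set_scenario_parameter(sc, "supply.nope", 0.5),
               "unknown parameter path")
  expect_error(set_scenario_parameter(sc, "demand.nope.seeking.x", 0.5),
               "unknown parameter path")
})
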