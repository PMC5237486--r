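fx <- paper_fixtures()

test_that("base-case segment demands reproduce the published demand column", {
  segs <- fx$base$demand_segments
  expect_identical(segment_demand(segs$single_women)$reported, 1287)
  expect_identical(segment_demand(segs$heterosexual_couples)$reported, 2260)
  expect_identical(segment_demand(segs$same_sex_couples)$reported, 4319)
  expect_equal(segment_demand(segs$single_women)$expected,
               5567965 * 0.393 * 0.0006 * 0.98)

  d <- total_demand(fx$base)
  expect_identical(d$total, 7866)
  expect_identical(d$total, sum(d$per_segment$reported))
  expect_identical(total_demand(fx$best)$total, 7866)
})

test_that("the calibrated same-sex base is the only-just-consistent count", {
  # oracle: brute-force scan over integer bases; the bases reproducing both
  # the base-case (15%) and worst-case (25%) published cells form a narrow
  # interval that contains the pinned 29,380
  rha <- function(x) floor(x + 0.5)
  b <- 29000:30000
  ok <- b[rha(b * 0.15 * 0.98) == 4319 & rha(b * 0.25 * 0.98) == 7198]
  expect_identical(range(ok), c(29378L, 29381L))
  expect_true(29380 %in% ok)
  # the percentage-derived route differs and warns
  expect_warning(alt <- same_sex_base_from_fraction(5567965, "0.528%"),
                 "29399")
  expect_equal(round(alt), 29399)
  expect_warning(
    expect_equal(round(same_sex_base_from_fraction(5567965, "0.528%",
                                                   count_as = "women")),
                 14699))
})

test_that("worst-case demand recomputes to the documented reconciliation values", {
  d <- total_demand(fx$worst)
  rep <- setNames(d$per_segment$reported, d$per_segment$label)
  expect_identical(rep[["same_sex_couples"]], 7198)   # matches the table
  # published 21,447 and 3,767 are NOT reproducible from the printed
  # parameters; the model reports its own exact recomputation
  expect_identical(rep[["single_women"]], 21444)
  expect_identical(rep[["heterosexual_couples"]], 3766)
  expect_identical(d$total, 32408)  # vs the printed 32,412
})

test_that("degenerate and single-segment demands behave", {
  seg <- fx$base$demand_segments$same_sex_couples
  seg$recipient_eligibility <- prop_param("recipient_eligibility", "0%")
  expect_identical(segment_demand(seg)$reported, 0)
  one <- total_demand(list(fx$base$demand_segments$single_women))
  expect_identical(one$total, 1287)
  zeroed <- lapply(fx$base$demand_segments, function(s) {
    s$recipient_eligibility <- prop_param("recipient_eligibility", "0")
    s
  })
  expect_identical(total_demand(zeroed)$total, 0)
})

test_that("demand properties: permutation invariance and monotonicity", {
  segs <- fx$base$demand_segments
  expect_identical(total_demand(segs[c(3, 1, 2)])$total,
                   total_demand(segs)$total)
  withr::with_seed(77, {
    for (rep in 1:20) {
      seg <- segs$heterosexual_couples
      j <- sample(seq_along(seg$seeking_chain), 1)
      p <- prop_value(seg$seeking_chain[[j]])
      seg$seeking_chain[[j]] <- prop_param(seg$seeking_chain[[j]]$name,
                                           min(1, p * runif(1, 1, 20)))
      expect_gte(segment_demand(seg)$reported,
                 segment_demand(segs$heterosexual_couples)$reported)
    }
  })
})

test_that("demand_fraction matches its formatting contract", {
  d_base <- total_demand(fx$base)
  d_worst <- total_demand(fx$worst)
  expect_equal(demand_fraction(d_base, 5567965), 7866 / 5567965)
  # the published worst-case cell (0.58%) reproduces at 2 significant
  # figures from the printed total
  expect_identical(format_demand_fraction(32412 / 5567965), "0.58%")
  # the published base-case cell prints 0.1%, which no rounding rule
  # consistent with 0.58% yields; the exact value formats as 0.14%
  expect_identical(format_demand_fraction(demand_fraction(d_base, 5567965)),
                   "0.14%")
  expect_identical(format_demand_fraction(0), "0%")
  expect_error(demand_fraction(d_worst, 0), "positive")
})

test_that("calibrate_rate_from_ratio inverts the demand product", {
  ratios <- c(same_sex_couples = 5, single_women = 2,
              heterosexual_couples = 2)
  sw <- fx$base$demand_segments$single_women
  sw$seeking_chain <- list()
  p <- calibrate_rate_from_ratio(4319, ratios, "same_sex_couples",
                                 "single_women", sw)
  # independent closed form: (4319 * 2/5) / (5,567,965 * 0.393 * 0.98)
  expect_equal(p, (4319 * 2 / 5) / (5567965 * 0.393 * 0.98))
  expect_equal(p, 8.056e-4, tolerance = 1e-3)
  # feeding the solved rate back reproduces the ratio-implied demand
  sw$seeking_chain <- list(prop_param("seeking_donation", p))
  # (the rate is canonicalized on a 1e-9 grid when stored, hence the
  # loose-ish tolerance)
  expect_equal(segment_demand(sw)$expected, 4319 * 2 / 5, tolerance = 1e-5)
  # the solved rate does NOT equal the published 0.06% (documented:
  # the published calibration is not algebraically recoverable)
  expect_gt(abs(p - 0.0006) / 0.0006, 0.3)

  # symmetry: identical segments and equal ratio terms return the
  # reference segment's own rate (up to reporting-level rounding)
  ref <- fx$base$demand_segments$single_women
  ref_demand <- segment_demand(ref)$reported
  ref_norate <- ref
  ref_norate$seeking_chain <- list()
  p_sym <- calibrate_rate_from_ratio(ref_demand, c(a = 3, b = 3), "a", "b",
                                     ref_norate)
  expect_equal(p_sym, 0.0006, tolerance = 1e-3)

  # infeasibility: implied demand above the segment maximum
  expect_error(
    calibrate_rate_from_ratio(4319, c(a = 5, b = 1e6), "a", "b",
                              ref_norate),
    "infeasible")
})
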