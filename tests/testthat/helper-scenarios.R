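# Small hand-built scenarios used across test files.

# a minimal scenario whose numbers are easy to track by hand:
# supply 1000 * 0.5 * 0.2 = 100 donors -> 1000 donations (10 births each);
# one direct-count segment 400 * 0.25 * 0.5 = 50 requests.
tiny_scenario <- function(name = "tiny", aware = "50%", seek = "25%") {
  scenario_spec(
    name,
    supply_spec(1000,
                list(prop_param("awareness", aware),
                     prop_param("willingness", "20%")),
                births_per_donor = 10),
    list(demand_segment_spec(
      "grp",
      base_count = 400,
      seeking_chain = list(prop_param("seek", seek)),
      recipient_eligibility = prop_param("recipient_eligibility", "50%")
    ))
  )
}

# random valid supply spec for property tests (proportions on a 1e-3 grid
# so rational parsing is exact)
random_supply <- function(n_stages = 3) {
  supply_spec(
    population_base = sample(1e3:1e6, 1),
    stages = lapply(seq_len(n_stages), function(i) {
      prop_param(paste0("s", i), sample(0:1000, 1) / 1000)
    }),
    births_per_donor = sample(1:40, 1)
  )
}

expect_funnel_cells <- function(result, reported, donors, donations) {
  expect_equal(result$stage_counts$reported, reported)
  expect_identical(result$donors, donors)
  expect_identical(result$donations, donations)
}
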