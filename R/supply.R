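#' Run the supply funnel
#'
#' Multiplies the male population base through the ordered stage
#' proportions, carrying full (exact rational) precision: the expected
#' count after stage k is `population_base * prod(p_1..p_k)`, with no
#' intermediate integerization. Reported per-stage counts round half away
#' from zero for display; the donor count is the rounded final stage
#' (donors are whole people), and donation capacity is
#' `donors * births_per_donor` exactly.
#'
#' @param spec a [supply_spec()].
#' @return An object of class `supply_result`: list with `stage_counts`
#'   (data.frame of stage, expected, reported), `donors`, `donations`,
#'   `population_base`, `births_per_donor`.
#' @examples
#' fx <- paper_fixtures()
#' run_funnel(fx$base$supply)   # 63 donors, 1,575 donations
#' @export
run_funnel <- function(spec) {
  stopifnot(inherits(spec, "supply_spec"))
  acc <- rat(spec$population_base)
  k <- length(spec$stages)
  expected <- numeric(k)
  reported <- numeric(k)
  for (i in seq_len(k)) {
    acc <- rat_mul(acc, prop_rat(spec$stages[[i]]))
    expected[i] <- rat_value(acc)
    reported[i] <- rat_round(acc)
  }
  donors <- reported[k]
  structure(
    list(
      stage_counts = data.frame(stage = names(spec$stages),
                                expected = expected, reported = reported,
                                stringsAsFactors = FALSE),
      donors = donors,
      donations = donors * spec$births_per_donor,
      population_base = spec$population_base,
      births_per_donor = spec$births_per_donor
    ),
    class = "supply_result"
  )
}

#' @export
print.supply_result <- function(x, ...) {
  cat("<supply_result>\n")
  cat(sprintf("  population base: %s\n",
              format(x$population_base, big.mark = ",")))
  for (i in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  after %-28s %12s  (expected %.3f)\n",
                x$stage_counts$stage[i],
                format(x$stage_counts$reported[i], big.mark = ","),
                x$stage_counts$expected[i]))
  }
  cat(sprintf("  donors: %s (%s of base)\n",
              format(x$donors, big.mark = ","),
              format_donor_fraction(x$donors / x$population_base)))
  cat(sprintf("  donations (%d live births/donor): %s\n",
              as.integer(x$births_per_donor),
              format(x$donations, big.mark = ",")))
  invisible(x)
}

#' Donors as a fraction of the population base
#'
#' @param result a `supply_result` from [run_funnel()].
#' @param population_base positive integer base; defaults to the base the
#'   funnel was run with.
#' @return the fraction `donors / population_base` (numeric). Use
#'   [format_donor_fraction()] for the conventional 4-decimal-place
#'   percent display (e.g. `"0.0015%"`).
#' @export
donor_fraction <- function(result, population_base = result$population_base) {
  stopifnot(inherits(result, "supply_result"))
  if (!is.numeric(population_base) || length(population_base) != 1L ||
      population_base <= 0) {
    stop("population_base must be a positive count", call. = FALSE)
  }
  result$donors / population_base
}

#' @describeIn donor_fraction format a fraction as percent with 4 decimal
#'   places, e.g. `0.0000146 -> "0.0015%"`.
#' @param x numeric fraction.
#' @export
format_donor_fraction <- function(x) sprintf("%.4f%%", 100 * x)
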