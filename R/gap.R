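#' Supply-demand gap in donation units
#'
#' @param demand_total non-negative integer total donor-insemination
#'   requests.
#' @param supply_donations non-negative integer donation capacity.
#' @return signed integer `demand_total - supply_donations`; positive is a
#'   shortfall, negative an oversupply.
#' @export
compute_gap <- function(demand_total, supply_donations) {
  stopifnot(is.numeric(demand_total), demand_total >= 0,
            is.numeric(supply_donations), supply_donations >= 0)
  demand_total - supply_donations
}

#' Whole donors needed to close (or spare within) a gap
#'
#' A shortfall must be fully covered by whole donors, so it divides by the
#' births cap and rounds up; a surplus counts only complete spare donors,
#' so it rounds down (6,291/25 = 251.64 -> 252 required; 87,059/25 =
#' 3,482.36 -> 3,482 spare).
#'
#' @param gap signed integer from [compute_gap()].
#' @param births_per_donor positive integer births cap.
#' @return signed integer: positive = additional donors required,
#'   negative = surplus donors, zero iff `gap == 0`... (a gap smaller than
#'   one donation cannot occur with integer inputs).
#' @export
donors_to_balance <- function(gap, births_per_donor) {
  stopifnot(is.numeric(gap), length(gap) == 1L,
            is.numeric(births_per_donor), births_per_donor >= 1,
            births_per_donor == floor(births_per_donor))
  if (gap > 0) ceiling(gap / births_per_donor)
  else if (gap < 0) -floor(-gap / births_per_donor)
  else 0
}

#' Gap analysis for a scenario
#'
#' Runs the supply funnel and demand model and combines them into a
#' `gap_result`.
#'
#' @param demand a `demand_result`, or an integer demand total (e.g. a
#'   published total used as a direct input).
#' @param supply a `supply_result`.
#' @return object of class `gap_result`: `demand_total`,
#'   `supply_donations`, `gap`, `donors_to_balance`, `births_per_donor`.
#' @export
gap_result <- function(demand, supply) {
  stopifnot(inherits(supply, "supply_result"))
  demand_total <- if (inherits(demand, "demand_result")) demand$total
                  else demand
  g <- compute_gap(demand_total, supply$donations)
  structure(
    list(demand_total = demand_total, supply_donations = supply$donations,
         gap = g,
         donors_to_balance = donors_to_balance(g, supply$births_per_donor),
         births_per_donor = supply$births_per_donor),
    class = "gap_result"
  )
}

#' @export
print.gap_result <- function(x, ...) {
  paren <- function(v) {
    if (v < 0) paste0("(", format(-v, big.mark = ","), ")")
    else format(v, big.mark = ",")
  }
  cat("<gap_result>\n")
  cat(sprintf("  demand:            %12s requests\n",
              format(x$demand_total, big.mark = ",")))
  cat(sprintf("  supply:            %12s donations\n",
              format(x$supply_donations, big.mark = ",")))
  cat(sprintf("  gap (demand-supply): %10s donations%s\n", paren(x$gap),
              if (x$gap < 0) " [oversupply]" else ""))
  cat(sprintf("  donors to balance: %12s\n", paren(x$donors_to_balance)))
  invisible(x)
}

#' Run a full scenario
#'
#' Convenience wrapper: supply funnel, demand model and gap analysis in
#' one call.
#'
#' @param scenario a [scenario_spec()].
#' @return list with components `scenario`, `supply` (`supply_result`),
#'   `demand` (`demand_result`), `gap` (`gap_result`), of class
#'   `scenario_result`.
#' @examples
#' res <- run_scenario(paper_fixtures()$base)
#' res$gap$donors_to_balance  # 252
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  supply <- run_funnel(scenario$supply)
  demand <- total_demand(scenario$demand_segments)
  structure(
    list(scenario = scenario, supply = supply, demand = demand,
         gap = gap_result(demand, supply)),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("== scenario \"%s\" ==\n", x$scenario$name))
  print(x$supply)
  print(x$demand)
  print(x$gap)
  invisible(x)
}

#' Break-even value of a single supply proportion
#'
#' Finds the smallest value v in `[0, 1]` of one supply-funnel proportion
#' at which donation capacity first meets total demand, all else fixed.
#' Because donors are integerized before the capacity multiplication, the
#' supply curve is a monotone step function of v; the search runs on a
#' grid (default step 1e-4, binary search over the monotone curve) and the
#' exact root of the continuous relaxation (donations without donor
#' rounding, linear in v) is reported alongside.
#'
#' @param scenario a [scenario_spec()].
#' @param parameter_path a `supply.<stage>` path (see [list_parameters()]);
#'   demand-side paths are rejected.
#' @param step grid resolution in `(0, 1]`.
#' @return object of class `break_even`: `feasible` (logical), `value`
#'   (smallest feasible grid point, or `NA` if infeasible),
#'   `relaxation_value` (continuous-relaxation root, possibly > 1),
#'   `current_value`, `demand_total`, `donations_at_value`,
#'   `donations_at_one`, `parameter_path`, `step`.
#' @examples
#' # base scenario cannot break even on awareness alone:
#' break_even_parameter(paper_fixtures()$base, "supply.awareness")$feasible
#' @export
break_even_parameter <- function(scenario, parameter_path, step = 1e-4) {
  stopifnot(inherits(scenario, "scenario_spec"),
            is.numeric(step), step > 0, step <= 1)
  parts <- strsplit(parameter_path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || parts[1] != "supply") {
    # get_scenario_parameter() gives the not-found diagnostic
    get_scenario_parameter(scenario, parameter_path)
    stop(sprintf("'%s' is not a supply-funnel proportion; break-even is defined for supply.<stage> paths",
                 parameter_path), call. = FALSE)
  }
  current <- get_scenario_parameter(scenario, parameter_path)
  demand_total <- total_demand(scenario$demand_segments)$total
  donations_at <- function(v) {
    run_funnel(set_scenario_parameter(scenario, parameter_path, v)$supply)$donations
  }
  grid <- seq(0, 1, by = step)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)

  out <- function(feasible, value) {
    # continuous relaxation: donations are linear in v, so the root is
    # demand / (base * prod(other stages) * births)
    slope <- donations_at_one_relaxed(scenario, parts[2])
    structure(
      list(feasible = feasible, value = value,
           relaxation_value = if (slope > 0) demand_total / slope else Inf,
           current_value = prop_value(current),
           demand_total = demand_total,
           donations_at_value = if (feasible) donations_at(value) else
             donations_at(1),
           donations_at_one = donations_at(1),
           parameter_path = parameter_path, step = step),
      class = "break_even"
    )
  }

  if (demand_total == 0) return(out(TRUE, 0))
  if (donations_at(1) < demand_total) return(out(FALSE, NA_real_))
  # binary search for the first feasible grid point on the monotone curve
  lo <- 1L                 # grid[lo] known/assumed infeasible unless v=0 works
  hi <- length(grid)       # grid[hi] known feasible
  if (donations_at(grid[1]) >= demand_total) return(out(TRUE, grid[1]))
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (donations_at(grid[mid]) >= demand_total) hi <- mid else lo <- mid
  }
  out(TRUE, grid[hi])
}

# donations at v = 1 under the continuous relaxation (no donor rounding):
# base * prod(all other stage proportions) * births_per_donor
donations_at_one_relaxed <- function(scenario, stage_name) {
  acc <- rat(scenario$supply$population_base)
  for (nm in names(scenario$supply$stages)) {
    if (nm != stage_name) acc <- rat_mul(acc, prop_rat(scenario$supply$stages[[nm]]))
  }
  rat_value(acc) * scenario$supply$births_per_donor
}

#' @export
print.break_even <- function(x, ...) {
  cat(sprintf("<break_even> %s (current %.6g)\n", x$parameter_path,
              x$current_value))
  if (x$feasible) {
    cat(sprintf("  supply meets demand (%s) from v = %.6g (grid step %g); relaxation root %.6g\n",
                format(x$demand_total, big.mark = ","), x$value, x$step,
                x$relaxation_value))
  } else {
    cat(sprintf("  infeasible: even at v = 1 supply is %s donations vs demand %s (relaxation root %.4g > 1)\n",
                format(x$donations_at_one, big.mark = ","),
                format(x$demand_total, big.mark = ","), x$relaxation_value))
  }
  invisible(x)
}
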