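#' One-way deterministic parameter sweep
#'
#' Re-runs the full deterministic pipeline (supply funnel, demand model,
#' gap) at each grid value of one parameter, all else fixed -- the
#' generalization of a published three-column scenario contrast to an
#' arbitrary grid.
#'
#' @param scenario a [scenario_spec()].
#' @param parameter_path any path from [list_parameters()].
#' @param grid strictly increasing fractions in `[0, 1]`.
#' @return object of class `sweep_result`: `parameter_path` and `outputs`,
#'   a data.frame with columns `value`, `donors`, `donations`,
#'   `demand_total`, `gap`, `donors_to_balance`.
#' @examples
#' one_way_sweep(paper_fixtures()$base, "supply.awareness",
#'               c(0.25, 0.55))$outputs$donors  # 63 139
#' @export
one_way_sweep <- function(scenario, parameter_path, grid) {
  stopifnot(inherits(scenario, "scenario_spec"),
            is.numeric(grid), length(grid) >= 1L,
            all(grid >= 0), all(grid <= 1))
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  get_scenario_parameter(scenario, parameter_path)  # validates the path
  rows <- lapply(grid, function(v) {
    res <- run_scenario(set_scenario_parameter(scenario, parameter_path, v))
    data.frame(value = v, donors = res$supply$donors,
               donations = res$supply$donations,
               demand_total = res$demand$total, gap = res$gap$gap,
               donors_to_balance = res$gap$donors_to_balance)
  })
  structure(
    list(parameter_path = parameter_path,
         outputs = do.call(rbind, rows)),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s over %d grid points\n", x$parameter_path,
              nrow(x$outputs)))
  print(x$outputs, row.names = FALSE)
  invisible(x)
}

#' Stochastic (binomial-thinning) model run
#'
#' The deterministic funnel is the expectation of a chained-binomial
#' process in which each man independently passes each gate: replicate r
#' draws the count surviving stage k as
#' `Binomial(n = count at stage k-1, p = stage proportion)`, and each
#' demand segment is thinned analogously through its chains. Donor counts
#' per replicate are integers by construction and are *not* put through
#' the half-away rounding rule, so the Monte Carlo mean targets the
#' pre-rounding expectation (62.1 in the base scenario), not the rounded
#' point estimate (63).
#'
#' @param scenario a [scenario_spec()].
#' @param n_reps number of replicates (>= 1).
#' @param seed integer seed; required, so every stochastic run is
#'   reproducible and logged.
#' @param keep_draws keep the per-replicate draws in the result?
#' @return object of class `mc_summary`: `n_reps`, `seed`, `summary`
#'   (data.frame with rows donors / donations / demand_total / gap and
#'   columns mean, sd, lo95, hi95), and with `keep_draws` also `draws`
#'   (per-replicate outputs) and `stage_draws` (per-replicate supply stage
#'   counts).
#' @examples
#' stochastic_funnel(paper_fixtures()$base, n_reps = 1000, seed = 7)
#' @export
stochastic_funnel <- function(scenario, n_reps, seed, keep_draws = FALSE) {
  stopifnot(inherits(scenario, "scenario_spec"),
            is.numeric(n_reps), length(n_reps) == 1L, n_reps >= 1,
            n_reps == floor(n_reps))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("a single integer `seed` is required for stochastic runs",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    thin <- function(n, chain) {
      for (p in chain) n <- stats::rbinom(n_reps, n, prop_value(p))
      n
    }
    stage_counts <- matrix(0, n_reps, length(scenario$supply$stages),
                           dimnames = list(NULL,
                                           names(scenario$supply$stages)))
    n <- rep(scenario$supply$population_base, n_reps)
    for (j in seq_along(scenario$supply$stages)) {
      n <- thin(n, scenario$supply$stages[j])
      stage_counts[, j] <- n
    }
    donors <- n
    donations <- donors * scenario$supply$births_per_donor
    demand_total <- rep(0, n_reps)
    for (seg in scenario$demand_segments) {
      n <- if (!is.null(seg$base_count)) {
        thin(rep(seg$base_count, n_reps), seg$base_chain)
      } else {
        thin(rep(seg$base_population, n_reps), seg$base_chain)
      }
      n <- thin(n, seg$seeking_chain)
      n <- thin(n, list(seg$recipient_eligibility))
      demand_total <- demand_total + n
    }
  })
  gap <- demand_total - donations
  draws <- data.frame(donors = donors, donations = donations,
                      demand_total = demand_total, gap = gap)
  summarize <- function(x) {
    q <- unname(stats::quantile(x, c(0.025, 0.975)))
    c(mean = mean(x), sd = stats::sd(x), lo95 = q[1], hi95 = q[2])
  }
  sm <- as.data.frame(t(vapply(draws, summarize, numeric(4))))
  sm <- cbind(output = rownames(sm), sm)
  rownames(sm) <- NULL
  structure(
    list(n_reps = as.integer(n_reps), seed = as.integer(seed), summary = sm,
         draws = if (keep_draws) draws,
         stage_draws = if (keep_draws) stage_counts),
    class = "mc_summary"
  )
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("<mc_summary> %d replicates, seed %d\n", x$n_reps, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
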