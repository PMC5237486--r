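#' Supply-side model specification
#'
#' The supply model is a top-down funnel: a male population base is
#' multiplied through an ordered chain of proportions (awareness of the
#' donation program, willingness to donate, presenting for screening,
#' passing medical screening), and the resulting whole-donor count is
#' converted to donation capacity by a births-per-donor policy cap.
#'
#' @param population_base non-negative integer count of age-eligible males.
#' @param stages ordered list of [prop_param()] objects; order is the order
#'   in which the filters apply and is preserved on round-trip.
#' @param births_per_donor positive integer policy cap on live births
#'   (donation-equivalents) per donor.
#' @return An object of class `supply_spec`.
#' @export
supply_spec <- function(population_base, stages, births_per_donor) {
  stopifnot(is.numeric(population_base), length(population_base) == 1L,
            population_base >= 0, population_base == floor(population_base))
  if (!is.list(stages) || length(stages) == 0L) {
    stop("supply stages must be a non-empty list of prop_param", call. = FALSE)
  }
  for (s in stages) {
    if (!inherits(s, "prop_param")) {
      stop("every supply stage must be a prop_param", call. = FALSE)
    }
  }
  names(stages) <- vapply(stages, `[[`, "", "name")
  if (anyDuplicated(names(stages))) {
    stop("supply stage names must be unique", call. = FALSE)
  }
  stopifnot(is.numeric(births_per_donor), length(births_per_donor) == 1L,
            births_per_donor >= 1,
            births_per_donor == floor(births_per_donor))
  structure(
    list(population_base = as.numeric(population_base), stages = stages,
         births_per_donor = as.numeric(births_per_donor)),
    class = "supply_spec"
  )
}

#' Demand-segment specification
#'
#' A demand segment is a recipient group whose requests for donor
#' insemination are derived from either a direct unit count (e.g. a couple
#' count) or a population base thinned through a derivation chain, then
#' through an ordered seeking chain, then a recipient-eligibility fraction.
#' Exactly one of `base_count` and `base_population` must be given.
#'
#' @param label segment label; the three conventional segments are
#'   `"same_sex_couples"`, `"single_women"` and `"heterosexual_couples"`,
#'   but any label is accepted.
#' @param base_count direct unit count (women or couples), or `NULL`.
#' @param base_population population base to which `base_chain` applies,
#'   or `NULL`.
#' @param base_chain ordered list of [prop_param()] deriving at-risk units
#'   from `base_population` (required with `base_population`).
#' @param seeking_chain ordered list of [prop_param()] applied after the
#'   base derivation (e.g. wishing-children, seeking-donation rates); may
#'   be empty.
#' @param recipient_eligibility [prop_param()]: fraction of requesting
#'   women/couples who meet clinical screening criteria.
#' @return An object of class `demand_segment_spec`.
#' @export
demand_segment_spec <- function(label, base_count = NULL,
                                base_population = NULL, base_chain = list(),
                                seeking_chain = list(),
                                recipient_eligibility) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (is.null(base_count) == is.null(base_population)) {
    stop(sprintf(
      "segment '%s': exactly one of base_count / base_population must be set",
      label), call. = FALSE)
  }
  check_chain <- function(chain, what) {
    if (!is.list(chain)) stop(sprintf("segment '%s': %s must be a list",
                                      label, what), call. = FALSE)
    for (p in chain) {
      if (!inherits(p, "prop_param")) {
        stop(sprintf("segment '%s': %s entries must be prop_param",
                     label, what), call. = FALSE)
      }
    }
    names(chain) <- vapply(chain, `[[`, "", "name")
    chain
  }
  if (!is.null(base_count)) {
    stopifnot(is.numeric(base_count), base_count >= 0,
              base_count == floor(base_count))
    base_count <- as.numeric(base_count)
    base_chain <- list()
  } else {
    stopifnot(is.numeric(base_population), base_population >= 0,
              base_population == floor(base_population))
    base_population <- as.numeric(base_population)
    base_chain <- check_chain(base_chain, "base_chain")
    if (length(base_chain) == 0L) {
      stop(sprintf("segment '%s': base_population requires a non-empty base_chain",
                   label), call. = FALSE)
    }
  }
  seeking_chain <- check_chain(seeking_chain, "seeking_chain")
  if (!inherits(recipient_eligibility, "prop_param")) {
    stop(sprintf("segment '%s': recipient_eligibility must be a prop_param",
                 label), call. = FALSE)
  }
  structure(
    list(label = label, base_count = base_count,
         base_population = base_population, base_chain = base_chain,
         seeking_chain = seeking_chain,
         recipient_eligibility = recipient_eligibility),
    class = "demand_segment_spec"
  )
}

#' Scenario specification
#'
#' Bundles one supply funnel specification with one or more demand
#' segments under a scenario name (e.g. `"base"`, `"best"`, `"worst"`).
#'
#' @param name scenario name, unique within a collection.
#' @param supply a [supply_spec()].
#' @param demand_segments list of [demand_segment_spec()]; at least one.
#' @return An object of class `scenario_spec`.
#' @seealso [paper_fixtures()] for the packaged base/best/worst scenarios,
#'   [load_scenario()] / [write_scenario()] for the config format.
#' @export
scenario_spec <- function(name, supply, demand_segments) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!inherits(supply, "supply_spec")) {
    stop("supply must be a supply_spec", call. = FALSE)
  }
  if (!is.list(demand_segments) || length(demand_segments) == 0L) {
    stop("at least one demand segment is required", call. = FALSE)
  }
  for (seg in demand_segments) {
    if (!inherits(seg, "demand_segment_spec")) {
      stop("demand_segments entries must be demand_segment_spec", call. = FALSE)
    }
  }
  names(demand_segments) <- vapply(demand_segments, `[[`, "", "label")
  if (anyDuplicated(names(demand_segments))) {
    stop("demand segment labels must be unique", call. = FALSE)
  }
  structure(
    list(name = name, supply = supply, demand_segments = demand_segments),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> \"%s\"\n", x$name))
  cat(sprintf("  supply: base %s, %d stages (%s), %d births/donor\n",
              format(x$supply$population_base, big.mark = ","),
              length(x$supply$stages),
              paste(names(x$supply$stages), collapse = " > "),
              as.integer(x$supply$births_per_donor)))
  for (seg in x$demand_segments) {
    base <- if (!is.null(seg$base_count)) {
      sprintf("count %s", format(seg$base_count, big.mark = ","))
    } else {
      sprintf("population %s x %s",
              format(seg$base_population, big.mark = ","),
              paste(vapply(seg$base_chain, `[[`, "", "text"), collapse = " x "))
    }
    cat(sprintf("  demand[%s]: %s; seeking %s; eligibility %s\n",
                seg$label, base,
                paste(vapply(seg$seeking_chain, `[[`, "", "text"),
                      collapse = " x "),
                seg$recipient_eligibility$text))
  }
  invisible(x)
}

# ---- parameter paths ------------------------------------------------------

#' List the addressable parameters of a scenario
#'
#' Parameter paths name a single proportion inside a scenario and are used
#' by [one_way_sweep()], [break_even_parameter()] and
#' [set_scenario_parameter()]. Paths have the form
#' `supply.<stage>`, `demand.<segment>.base.<name>`,
#' `demand.<segment>.seeking.<name>` or
#' `demand.<segment>.recipient_eligibility`.
#'
#' @param scenario a [scenario_spec()].
#' @return character vector of valid paths.
#' @export
list_parameters <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  out <- paste0("supply.", names(scenario$supply$stages))
  for (seg in scenario$demand_segments) {
    pre <- paste0("demand.", seg$label, ".")
    if (length(seg$base_chain)) {
      out <- c(out, paste0(pre, "base.", names(seg$base_chain)))
    }
    if (length(seg$seeking_chain)) {
      out <- c(out, paste0(pre, "seeking.", names(seg$seeking_chain)))
    }
    out <- c(out, paste0(pre, "recipient_eligibility"))
  }
  out
}

#' Replace one proportion of a scenario
#'
#' @inheritParams list_parameters
#' @param path a parameter path (see [list_parameters()]).
#' @param value new proportion: numeric in `[0, 1]` or an encoding string
#'   such as `"25%"` or `"1/78"`.
#' @return the modified `scenario_spec`.
#' @export
set_scenario_parameter <- function(scenario, path, value) {
  stopifnot(inherits(scenario, "scenario_spec"),
            is.character(path), length(path) == 1L)
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  bad <- function() {
    stop(sprintf("unknown parameter path '%s'; see list_parameters()", path),
         call. = FALSE)
  }
  if (length(parts) == 2L && parts[1] == "supply") {
    if (!parts[2] %in% names(scenario$supply$stages)) bad()
    scenario$supply$stages[[parts[2]]] <-
      prop_with_value(scenario$supply$stages[[parts[2]]], value)
    return(scenario)
  }
  if (parts[1] == "demand" && length(parts) >= 3L) {
    if (!parts[2] %in% names(scenario$demand_segments)) bad()
    seg <- scenario$demand_segments[[parts[2]]]
    if (length(parts) == 3L && parts[3] == "recipient_eligibility") {
      seg$recipient_eligibility <- prop_with_value(seg$recipient_eligibility,
                                                   value)
    } else if (length(parts) == 4L && parts[3] == "base" &&
               parts[4] %in% names(seg$base_chain)) {
      seg$base_chain[[parts[4]]] <- prop_with_value(seg$base_chain[[parts[4]]],
                                                    value)
    } else if (length(parts) == 4L && parts[3] == "seeking" &&
               parts[4] %in% names(seg$seeking_chain)) {
      seg$seeking_chain[[parts[4]]] <-
        prop_with_value(seg$seeking_chain[[parts[4]]], value)
    } else {
      bad()
    }
    scenario$demand_segments[[parts[2]]] <- seg
    return(scenario)
  }
  bad()
}

get_scenario_parameter <- function(scenario, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2L && parts[1] == "supply" &&
      parts[2] %in% names(scenario$supply$stages)) {
    return(scenario$supply$stages[[parts[2]]])
  }
  if (parts[1] == "demand" && length(parts) >= 3L &&
      parts[2] %in% names(scenario$demand_segments)) {
    seg <- scenario$demand_segments[[parts[2]]]
    if (length(parts) == 3L && parts[3] == "recipient_eligibility") {
      return(seg$recipient_eligibility)
    }
    if (length(parts) == 4L && parts[3] == "base" &&
        parts[4] %in% names(seg$base_chain)) {
      return(seg$base_chain[[parts[4]]])
    }
    if (length(parts) == 4L && parts[3] == "seeking" &&
        parts[4] %in% names(seg$seeking_chain)) {
      return(seg$seeking_chain[[parts[4]]])
    }
  }
  stop(sprintf("unknown parameter path '%s'; see list_parameters()", path),
       call. = FALSE)
}
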