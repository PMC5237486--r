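# Rendering of results as delimited text and Markdown. The renderer never
# recomputes model quantities: every number comes from a result field.

supply_row_labels <- c(
  awareness = "Number of men aware of program",
  willingness = "Number of men willing to donate",
  presenting = "Number of men presenting for screening",
  medical_pass = "Number of men that pass overall medical screening process"
)

demand_row_labels <- c(
  same_sex_couples = "Number of female same-sex couples eligible for IVF with donor sperm",
  single_women = "Number of single women eligible for IVF with donor sperm",
  heterosexual_couples = "Number of heterosexual couples eligible for IVF with donor sperm"
)

label_or <- function(map, key, fallback) {
  if (key %in% names(map)) unname(map[key]) else fallback
}

# negative values render parenthesized with the oversupply footnote marker
paren_cell <- function(v) {
  if (v < 0) paste0("(", format(-v, big.mark = ","), ")^a^")
  else format(v, big.mark = ",")
}

md_table <- function(df) {
  fmt_row <- function(cells) paste0("| ", paste(cells, collapse = " | "), " |")
  c(fmt_row(names(df)),
    fmt_row(rep("---", ncol(df))),
    vapply(seq_len(nrow(df)),
           function(i) fmt_row(vapply(df[i, ], as.character, "")), ""))
}

#' Tabular views of model results
#'
#' `as.data.frame()` methods give value-preserving delimited-text views;
#' the `*_markdown()` functions render display tables with the published
#' row labels and the parenthesized-negative oversupply convention.
#'
#' @param x a `supply_result`, `demand_result` or `gap_result`.
#' @param ... unused.
#' @return a data.frame (or, for the markdown renderers, a character
#'   vector of lines).
#' @name result-tables
NULL

#' @rdname result-tables
#' @export
as.data.frame.supply_result <- function(x, ...) {
  data.frame(
    row = c("population_base", x$stage_counts$stage, "donations"),
    expected = c(x$population_base, x$stage_counts$expected, x$donations),
    reported = c(x$population_base, x$stage_counts$reported, x$donations)
  )
}

#' @rdname result-tables
#' @export
as.data.frame.demand_result <- function(x, ...) {
  data.frame(
    row = c(x$per_segment$label, "total"),
    expected = c(x$per_segment$expected, x$total),
    reported = c(x$per_segment$reported, x$total)
  )
}

#' @rdname result-tables
#' @export
as.data.frame.gap_result <- function(x, ...) {
  data.frame(
    row = c("demand_total", "supply_donations", "gap", "donors_to_balance"),
    value = c(x$demand_total, x$supply_donations, x$gap, x$donors_to_balance)
  )
}

#' @rdname result-tables
#' @param scenario_name heading for the rendered table.
#' @export
supply_markdown <- function(x, scenario_name = "") {
  stopifnot(inherits(x, "supply_result"))
  rows <- data.frame(
    Row = c(
      "Male population base",
      vapply(x$stage_counts$stage, function(s)
        label_or(supply_row_labels, s, paste0("Number after ", s)), ""),
      sprintf("Total number of donations available for insemination (eligible donors permitted %d live births each)",
              as.integer(x$births_per_donor))
    ),
    Value = c(
      format(x$population_base, big.mark = ","),
      vapply(seq_len(nrow(x$stage_counts)), function(i) {
        v <- format(x$stage_counts$reported[i], big.mark = ",")
        # final stage mirrors the published "(% of population base)" cell
        if (i == nrow(x$stage_counts)) {
          paste0(v, " (", format_donor_fraction(donor_fraction(x)), ")")
        } else v
      }, ""),
      format(x$donations, big.mark = ",")
    )
  )
  c(sprintf("### Supply%s",
            if (nzchar(scenario_name)) paste0(" (", scenario_name, ")") else ""),
    "", md_table(rows))
}

#' @rdname result-tables
#' @param population_base female population base for the percent-of-base
#'   cell; `NA` omits it.
#' @export
demand_markdown <- function(x, scenario_name = "", population_base = NA) {
  stopifnot(inherits(x, "demand_result"))
  total_cell <- format(x$total, big.mark = ",")
  if (!is.na(population_base)) {
    total_cell <- paste0(
      total_cell, " (",
      format_demand_fraction(demand_fraction(x, population_base)), ")")
  }
  rows <- data.frame(
    Row = c(
      vapply(x$per_segment$label, function(s)
        label_or(demand_row_labels, s, paste0("Demand from ", s)), ""),
      "Total demand for donor sperm"
    ),
    Value = c(
      vapply(x$per_segment$reported,
             function(v) format(v, big.mark = ","), ""),
      total_cell
    )
  )
  c(sprintf("### Demand%s",
            if (nzchar(scenario_name)) paste0(" (", scenario_name, ")") else ""),
    "", md_table(rows))
}

#' @rdname result-tables
#' @export
gap_markdown <- function(x, scenario_name = "") {
  stopifnot(inherits(x, "gap_result"))
  rows <- data.frame(
    Row = c(
      "Difference between donor insemination requests (demand) and donated sperm (supply)",
      "Number of additional donors required to meet donor insemination demand"
    ),
    Value = c(paren_cell(x$gap), paren_cell(x$donors_to_balance))
  )
  out <- c(sprintf("### Supply-demand gap%s",
                   if (nzchar(scenario_name)) paste0(" (", scenario_name, ")")
                   else ""),
           "", md_table(rows))
  if (x$gap < 0 || x$donors_to_balance < 0) {
    out <- c(out, "", "^a^ oversupply of donors")
  }
  out
}

# value-preserving TSV writer: reals carry 17 significant digits so
# read.delim() recovers them bit-for-bit
write_result_tsv <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]]) && any(df[[j]] != floor(df[[j]]))) {
      df[[j]] <- sprintf("%.17g", df[[j]])
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a scenario from a config file and write its report
#'
#' Reads the scenario, runs supply, demand and gap analysis, and writes
#' `supply.tsv`/`.md`, `demand.tsv`/`.md`, `gap.tsv`/`.md` and a
#' `provenance.dcf` sidecar (package version, config digest, timestamp)
#' into `output_dir`. Fails before writing anything if the scenario is
#' missing.
#'
#' @param config_path scenario collection file.
#' @param scenario_name scenario to run.
#' @param output_dir directory (created if needed).
#' @param seed optional seed recorded in provenance (deterministic runs
#'   record none).
#' @return a `run_report`: list with `scenario_name`, `supply`, `demand`,
#'   `gap`, `provenance`, `files`; invisibly.
#' @export
run_command <- function(config_path, scenario_name, output_dir, seed = NA) {
  scenario <- read_scenario_file(config_path, name = scenario_name)
  res <- run_scenario(scenario)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  files <- c(supply_tsv = file.path(output_dir, "supply.tsv"),
             demand_tsv = file.path(output_dir, "demand.tsv"),
             gap_tsv = file.path(output_dir, "gap.tsv"),
             supply_md = file.path(output_dir, "supply.md"),
             demand_md = file.path(output_dir, "demand.md"),
             gap_md = file.path(output_dir, "gap.md"),
             provenance = file.path(output_dir, "provenance.dcf"))
  write_result_tsv(as.data.frame(res$supply), files[["supply_tsv"]])
  write_result_tsv(as.data.frame(res$demand), files[["demand_tsv"]])
  write_result_tsv(as.data.frame(res$gap), files[["gap_tsv"]])
  writeLines(supply_markdown(res$supply, scenario_name), files[["supply_md"]])
  fem_base <- if (!is.null(res$scenario$demand_segments$single_women$base_population)) {
    res$scenario$demand_segments$single_women$base_population
  } else NA
  writeLines(demand_markdown(res$demand, scenario_name, fem_base),
             files[["demand_md"]])
  writeLines(gap_markdown(res$gap, scenario_name), files[["gap_md"]])

  provenance <- data.frame(
    package = "donorgap",
    version = as.character(utils::packageVersion("donorgap")),
    scenario = scenario_name,
    config = normalizePath(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    seed = as.character(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  write.dcf(provenance, files[["provenance"]])

  report <- structure(
    list(scenario_name = scenario_name, supply = res$supply,
         demand = res$demand, gap = res$gap, provenance = provenance,
         files = files),
    class = "run_report"
  )
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> scenario \"%s\"\n", x$scenario_name))
  print(x$supply)
  print(x$demand)
  print(x$gap)
  cat("files:\n")
  for (f in x$files) cat("  ", f, "\n", sep = "")
  invisible(x)
}

#' Sweep a parameter from a config file and write the table
#'
#' @inheritParams run_command
#' @param parameter_path see [list_parameters()].
#' @param grid strictly increasing fractions in `[0, 1]`.
#' @return the `sweep_result`, invisibly; writes `sweep.tsv` and
#'   `sweep.md`.
#' @export
sweep_command <- function(config_path, scenario_name, parameter_path, grid,
                          output_dir) {
  scenario <- read_scenario_file(config_path, name = scenario_name)
  sw <- one_way_sweep(scenario, parameter_path, grid)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_result_tsv(sw$outputs, file.path(output_dir, "sweep.tsv"))
  writeLines(c(sprintf("### Sweep of %s (%s)", parameter_path, scenario_name),
               "", md_table(sw$outputs)),
             file.path(output_dir, "sweep.md"))
  invisible(sw)
}
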