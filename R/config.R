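#' Scenario configuration format
#'
#' Scenarios are stored in a flat, human-readable key/value dialect, one
#' document per scenario collection. The format exists to preserve
#' proportion encodings losslessly: a value written as `1/78` stays the
#' exact rational `1/78`, `0.013` stays a 3-digit decimal, `39.3%` stays a
#' percentage -- a guarantee no floating-point round-trip gives, and one
#' the published tables depend on.
#'
#' ```
#' [scenario:base]
#' supply.population_base = 4307710
#' supply.births_per_donor = 25
#' supply.stage.awareness = 25% | proportion of men aware of program
#' supply.stage.medical_pass = 0.013
#' segment.same_sex_couples.base_count = 29380
#' segment.same_sex_couples.seeking.wishing_children = 15%
#' segment.same_sex_couples.recipient_eligibility = 98%
#' segment.single_women.base_population = 5567965
#' segment.single_women.base.single_fraction = 39.3%
#' ...
#' ```
#'
#' Rules: `#` starts a comment; blank lines are ignored; `[scenario:NAME]`
#' opens a scenario; keys are dotted paths whose `stage.`/`base.`/
#' `seeking.` order defines the funnel/chain order; an optional
#' `| free text` suffix carries the parameter's source note; integer
#' values may use `,` or `_` as digit separators.
#'
#' @name scenario-config
NULL

#' Parse scenario configuration text
#'
#' @param text configuration text: a single string (possibly with
#'   newlines) or a character vector of lines.
#' @param name scenario to return when the text holds several; by default
#'   the text must hold exactly one.
#' @return a validated [scenario_spec()]. Malformed text raises a parse
#'   error naming the offending line/key; out-of-range or missing
#'   parameters raise validation errors naming the parameter -- never a
#'   partially built spec.
#' @seealso [load_scenarios()] for whole collections, [write_scenario()]
#'   for the inverse.
#' @export
load_scenario <- function(text, name = NULL) {
  col <- load_scenarios(text)
  if (is.null(name)) {
    if (length(col) != 1L) {
      stop(sprintf("text defines %d scenarios (%s); pass `name` to pick one",
                   length(col), paste(names(col), collapse = ", ")),
           call. = FALSE)
    }
    return(col[[1L]])
  }
  if (!name %in% names(col)) {
    stop(sprintf("scenario '%s' not found (have: %s)", name,
                 paste(names(col), collapse = ", ")), call. = FALSE)
  }
  col[[name]]
}

#' @describeIn load_scenario parse a whole collection into a named list of
#'   `scenario_spec`.
#' @export
load_scenarios <- function(text) {
  stopifnot(is.character(text))
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
           else text
  scenarios <- list()
  current <- NULL    # name of open section
  entries <- list()  # per-scenario ordered list of (key, value, note, line)

  flush <- function() {
    if (!is.null(current)) {
      if (current %in% names(scenarios)) {
        stop(sprintf("duplicate scenario name '%s'", current), call. = FALSE)
      }
      scenarios[[current]] <<- build_scenario(current, entries)
    }
    entries <<- list()
  }

  for (i in seq_along(lines)) {
    line <- sub("^\\s*#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    m <- regmatches(line, regexec("^\\[scenario:([^]]+)\\]$", line))[[1L]]
    if (length(m) == 2L) {
      flush()
      current <- trimws(m[2])
      if (!nzchar(current)) {
        stop(sprintf("line %d: empty scenario name", i), call. = FALSE)
      }
      next
    }
    if (!grepl("=", line, fixed = TRUE)) {
      stop(sprintf("line %d: expected `key = value`, got \"%s\"", i, line),
           call. = FALSE)
    }
    if (is.null(current)) {
      stop(sprintf("line %d: `%s` appears before any [scenario:...] header",
                   i, line), call. = FALSE)
    }
    kv <- regmatches(line, regexec("^([^=]+)=(.*)$", line))[[1L]]
    key <- trimws(kv[2])
    rhs <- trimws(kv[3])
    note <- ""
    if (grepl("|", rhs, fixed = TRUE)) {
      pp <- regmatches(rhs, regexec("^([^|]*)\\|(.*)$", rhs))[[1L]]
      rhs <- trimws(pp[2])
      note <- trimws(pp[3])
    }
    if (!nzchar(key) || !nzchar(rhs)) {
      stop(sprintf("line %d: empty key or value in \"%s\"", i, line),
           call. = FALSE)
    }
    entries[[length(entries) + 1L]] <- list(key = key, value = rhs,
                                            note = note, line = i)
  }
  flush()
  if (length(scenarios) == 0L) {
    stop("no [scenario:...] sections found", call. = FALSE)
  }
  scenarios
}

parse_count <- function(entry) {
  v <- gsub("[,_]", "", entry$value)
  if (!grepl("^[0-9]+$", v)) {
    stop(sprintf("line %d: key '%s' needs a non-negative integer, got \"%s\"",
                 entry$line, entry$key, entry$value), call. = FALSE)
  }
  as.numeric(v)
}

build_scenario <- function(name, entries) {
  keys <- vapply(entries, `[[`, "", "key")
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1L]
    stop(sprintf("scenario '%s': duplicate key '%s'", name, dup),
         call. = FALSE)
  }
  take1 <- function(key, required = TRUE) {
    hit <- which(keys == key)
    if (length(hit) == 0L) {
      if (required) stop(sprintf("scenario '%s': missing required key '%s'",
                                 name, key), call. = FALSE)
      return(NULL)
    }
    entries[[hit]]
  }
  props_under <- function(prefix) {
    hit <- which(startsWith(keys, prefix))
    lapply(hit, function(j) {
      e <- entries[[j]]
      prop_param(substring(e$key, nchar(prefix) + 1L), e$value, e$note)
    })
  }

  # reject keys outside the dialect before anything else, so typos are
  # reported as such rather than as missing required keys
  for (j in seq_along(keys)) {
    k <- keys[j]
    ok <- k %in% c("supply.population_base", "supply.births_per_donor") ||
      startsWith(k, "supply.stage.") || startsWith(k, "segment.")
    if (!ok) {
      stop(sprintf("line %d: unknown key '%s'", entries[[j]]$line, k),
           call. = FALSE)
    }
  }

  supply <- supply_spec(
    population_base = parse_count(take1("supply.population_base")),
    stages = props_under("supply.stage."),
    births_per_donor = parse_count(take1("supply.births_per_donor"))
  )

  seg_keys <- keys[startsWith(keys, "segment.")]
  labels <- unique(vapply(strsplit(seg_keys, ".", fixed = TRUE),
                          function(p) if (length(p) >= 3L) p[2] else
                            stop(sprintf("scenario '%s': malformed segment key '%s'",
                                         name, paste(p, collapse = ".")),
                                 call. = FALSE),
                          ""))
  if (length(labels) == 0L) {
    stop(sprintf("scenario '%s': no demand segments defined", name),
         call. = FALSE)
  }
  segments <- lapply(labels, function(lab) {
    pre <- paste0("segment.", lab, ".")
    known <- c(paste0(pre, c("base_count", "base_population",
                             "recipient_eligibility")))
    for (k in keys[startsWith(keys, pre)]) {
      if (!k %in% known && !startsWith(k, paste0(pre, "base.")) &&
          !startsWith(k, paste0(pre, "seeking."))) {
        stop(sprintf("scenario '%s': unknown segment key '%s'", name, k),
             call. = FALSE)
      }
    }
    count <- take1(paste0(pre, "base_count"), required = FALSE)
    popn <- take1(paste0(pre, "base_population"), required = FALSE)
    elig <- take1(paste0(pre, "recipient_eligibility"))
    demand_segment_spec(
      label = lab,
      base_count = if (!is.null(count)) parse_count(count),
      base_population = if (!is.null(popn)) parse_count(popn),
      base_chain = props_under(paste0(pre, "base.")),
      seeking_chain = props_under(paste0(pre, "seeking.")),
      recipient_eligibility = prop_param("recipient_eligibility",
                                         elig$value, elig$note)
    )
  })

  scenario_spec(name, supply, segments)
}

#' Serialize scenarios to configuration text
#'
#' Emits canonical text that [load_scenario()] inverts exactly: proportion
#' encodings and source notes round-trip field-for-field.
#'
#' @param spec a [scenario_spec()].
#' @return a single string of configuration text.
#' @export
write_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  out <- character()
  emit <- function(key, value, note = "") {
    if (grepl("[|\n]", note)) {
      stop(sprintf("source note of '%s' may not contain '|' or newlines", key),
           call. = FALSE)
    }
    out[[length(out) + 1L]] <<- if (nzchar(note)) {
      sprintf("%s = %s | %s", key, value, note)
    } else {
      sprintf("%s = %s", key, value)
    }
  }
  fmt_count <- function(x) format(x, scientific = FALSE)
  out[[1L]] <- sprintf("[scenario:%s]", spec$name)
  emit("supply.population_base", fmt_count(spec$supply$population_base))
  emit("supply.births_per_donor", fmt_count(spec$supply$births_per_donor))
  for (p in spec$supply$stages) {
    emit(paste0("supply.stage.", p$name), p$text, p$source_note)
  }
  for (seg in spec$demand_segments) {
    pre <- paste0("segment.", seg$label, ".")
    if (!is.null(seg$base_count)) {
      emit(paste0(pre, "base_count"), fmt_count(seg$base_count))
    } else {
      emit(paste0(pre, "base_population"), fmt_count(seg$base_population))
      for (p in seg$base_chain) {
        emit(paste0(pre, "base.", p$name), p$text, p$source_note)
      }
    }
    for (p in seg$seeking_chain) {
      emit(paste0(pre, "seeking.", p$name), p$text, p$source_note)
    }
    emit(paste0(pre, "recipient_eligibility"),
         seg$recipient_eligibility$text, seg$recipient_eligibility$source_note)
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @describeIn write_scenario serialize a named list of scenarios into one
#'   collection document.
#' @param specs list of [scenario_spec()].
#' @export
write_scenarios <- function(specs) {
  stopifnot(is.list(specs), length(specs) >= 1L)
  paste(vapply(specs, write_scenario, ""), collapse = "\n")
}

#' Read / write scenario files
#'
#' @param path file path.
#' @param name optional scenario name to select (see [load_scenario()]).
#' @return `read_scenario_file()`: a `scenario_spec`;
#'   `read_scenario_collection()`: a named list of them.
#' @export
read_scenario_file <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  load_scenario(readLines(path, warn = FALSE), name = name)
}

#' @rdname read_scenario_file
#' @export
read_scenario_collection <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  load_scenarios(readLines(path, warn = FALSE))
}

#' @rdname read_scenario_file
#' @param specs a `scenario_spec` or list of them.
#' @export
write_scenario_file <- function(specs, path) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  writeLines(sub("\n$", "", write_scenarios(specs)), path)
  invisible(path)
}
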