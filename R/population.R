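#' Generate a synthetic census-like population table
#'
#' Stands in for the age-by-sex census extract that real analyses start
#' from: each sex's requested total is allocated across age bands covering
#' ages 0-99 by a single multinomial draw, so per-sex totals are conserved
#' exactly and the table is fully determined by the seed. Optionally the
#' allocation can be confined to an age range per sex (all other bands
#' zero), which is how the packaged census emulation pins an exact
#' published base such as 4,307,710 males aged 21-40.
#'
#' @param seed integer seed (required; tables are deterministic given it).
#' @param total_by_sex named numeric, e.g. `c(male = 4307710, female = 5567965)`;
#'   names must be among `"male"`, `"female"`.
#' @param band_width band width in years (must divide 100).
#' @param age_range_by_sex optional named list of `c(lo, hi)` half-open
#'   ranges confining each sex's allocation; must align with band
#'   boundaries.
#' @return a `population_table`: data.frame with columns `sex`, `age_lo`,
#'   `age_hi` (half-open band `[age_lo, age_hi)`), `count`, carrying the
#'   generator metadata as attributes.
#' @examples
#' tab <- generate_population(1, c(male = 1000, female = 1200))
#' sum(tab$count[tab$sex == "male"])  # exactly 1000
#' @export
generate_population <- function(seed, total_by_sex, band_width = 1,
                                age_range_by_sex = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(total_by_sex), length(total_by_sex) >= 1L,
            all(total_by_sex >= 0),
            all(total_by_sex == floor(total_by_sex)),
            is.numeric(band_width), length(band_width) == 1L,
            band_width >= 1, band_width == floor(band_width))
  if (100 %% band_width != 0) {
    stop("band_width must divide 100", call. = FALSE)
  }
  sexes <- names(total_by_sex)
  if (is.null(sexes) || !all(sexes %in% c("male", "female"))) {
    stop("total_by_sex must be named with 'male' and/or 'female'",
         call. = FALSE)
  }
  lo <- seq(0, 100 - band_width, by = band_width)
  hi <- lo + band_width
  rows <- withr::with_seed(as.integer(seed), {
    lapply(sexes, function(sx) {
      counts <- numeric(length(lo))
      allowed <- rep(TRUE, length(lo))
      if (!is.null(age_range_by_sex) && sx %in% names(age_range_by_sex)) {
        rng <- age_range_by_sex[[sx]]
        stopifnot(length(rng) == 2L, rng[1] < rng[2])
        if (rng[1] %% band_width != 0 || rng[2] %% band_width != 0) {
          stop(sprintf("age range for '%s' does not align with band width %d",
                       sx, band_width), call. = FALSE)
        }
        allowed <- lo >= rng[1] & hi <= rng[2]
      }
      total <- total_by_sex[[sx]]
      if (total > 0) {
        counts[allowed] <- as.numeric(
          stats::rmultinom(1, total, prob = rep(1, sum(allowed)))
        )
      }
      data.frame(sex = sx, age_lo = lo, age_hi = hi, count = counts,
                 stringsAsFactors = FALSE)
    })
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(tab, class = c("population_table", "data.frame"),
            seed = as.integer(seed), band_width = band_width,
            total_by_sex = total_by_sex)
}

#' Census-emulating population table
#'
#' The packaged emulation of the census inputs the published model uses:
#' 4,307,710 males confined to ages `[21, 41)` and 5,567,965 females
#' confined to `[20, 45)`, so [extract_base()] over those ranges returns
#' the published bases exactly. Synthetic: within-range age structure is a
#' uniform multinomial allocation, not real census data.
#'
#' @param seed integer seed.
#' @return a `population_table`.
#' @export
paper_population <- function(seed = 1) {
  generate_population(
    seed,
    total_by_sex = c(male = 4307710, female = 5567965),
    band_width = 1,
    age_range_by_sex = list(male = c(21, 41), female = c(20, 45))
  )
}

#' Extract a population base from a table
#'
#' Sums the bands of one sex fully inside the half-open interval
#' `[age_lo, age_hi)`. The interval must align with band boundaries; there
#' is no silent pro-rating of partially covered bands.
#'
#' @param table a `population_table`.
#' @param sex `"male"` or `"female"`.
#' @param age_lo,age_hi half-open interval bounds (years).
#' @return integer count (0 for an empty interval).
#' @examples
#' extract_base(paper_population(1), "male", 21, 41)  # 4307710
#' @export
extract_base <- function(table, sex, age_lo, age_hi) {
  stopifnot(inherits(table, "population_table"),
            is.numeric(age_lo), is.numeric(age_hi), age_lo <= age_hi)
  sex <- match.arg(sex, c("male", "female"))
  if (age_lo == age_hi) return(0)
  sub <- table[table$sex == sex, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("table has no rows for sex '%s'", sex), call. = FALSE)
  }
  bounds <- sort(unique(c(sub$age_lo, sub$age_hi)))
  if (!(age_lo %in% bounds) || !(age_hi %in% bounds)) {
    stop(sprintf(
      "interval [%g, %g) does not align with band boundaries (width %g); refusing to pro-rate",
      age_lo, age_hi, attr(table, "band_width")), call. = FALSE)
  }
  sum(sub$count[sub$age_lo >= age_lo & sub$age_hi <= age_hi])
}

#' Read / write population tables as delimited text
#'
#' Tab-separated with the fixed header `sex age_lo age_hi count`.
#'
#' @param table a `population_table`.
#' @param path file path.
#' @return `write_population_table()` returns `path` invisibly;
#'   `read_population_table()` returns a `population_table` (generator
#'   metadata, if absent from the file, is `NA`).
#' @export
write_population_table <- function(table, path) {
  stopifnot(inherits(table, "population_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_table
#' @export
read_population_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_lo", "age_hi", "count")
  if (!identical(names(tab), need)) {
    stop(sprintf("population table must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (any(tab$count < 0)) stop("negative counts in population table",
                               call. = FALSE)
  structure(tab, class = c("population_table", "data.frame"),
            seed = NA_integer_,
            band_width = unique(tab$age_hi - tab$age_lo)[1L],
            total_by_sex = tapply(tab$count, tab$sex, sum))
}
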