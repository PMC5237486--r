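#' Lossless proportion parameter
#'
#' Model proportions (awareness, willingness to donate, medical-pass
#' fraction, segment seeking rates, recipient eligibility, ...) are stored
#' losslessly, exactly as printed in their source: a percentage string
#' (`"25%"`, `"0.528%"`), a decimal (`"0.013"`), or a rational (`"1/78"`).
#' The printed encoding is kept for round-tripping through configuration
#' files, and an exact rational (numerator/denominator) is kept for
#' arithmetic, so funnel expectations that land exactly on .5 round the
#' way the published tables do.
#'
#' @param name short identifier (snake_case), e.g. `"awareness"`.
#' @param value the proportion, as a string in one of the encodings above,
#'   or a plain numeric in `[0, 1]` (canonicalized to a decimal string).
#' @param source_note free-text provenance, e.g. `"program awareness, base case"`.
#' @return An object of class `prop_param`.
#' @examples
#' prop_param("awareness", "25%")
#' prop_param("medical_pass", "1/78")
#' prop_value(prop_param("same_sex_fraction", "0.528%"))  # 0.00528
#' @export
prop_param <- function(name, value, source_note = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.numeric(value)) {
    stopifnot(length(value) == 1L, is.finite(value))
    # canonicalize on a 1e-9 grid so denominators stay small enough for
    # exact integer arithmetic
    value <- format(round(value, 9), digits = 15, scientific = FALSE)
  }
  stopifnot(is.character(value), length(value) == 1L)
  text <- trimws(value)
  r <- parse_fraction_text(text)
  if (is.null(r)) {
    stop(sprintf("parameter '%s': cannot parse proportion from \"%s\"",
                 name, text), call. = FALSE)
  }
  if (rat_value(r) > 1) {
    stop(sprintf("parameter '%s': proportion %s is outside [0, 1]",
                 name, text), call. = FALSE)
  }
  structure(
    list(name = name, num = r$num, den = r$den, text = text,
         source_note = as.character(source_note)),
    class = "prop_param"
  )
}

# Parse "25%", "0.528%", "1/78", "0.013" into an exact rational, or NULL.
parse_fraction_text <- function(text) {
  if (grepl("^[0-9]+(\\.[0-9]+)?%$", text)) {
    r <- rat_from_decimal_text(sub("%$", "", text))
    return(rat_mul(r, rat(1, 100)))
  }
  if (grepl("^[0-9]+/[0-9]+$", text)) {
    ab <- as.numeric(strsplit(text, "/", fixed = TRUE)[[1]])
    if (ab[2] == 0) return(NULL)
    return(rat(ab[1], ab[2]))
  }
  rat_from_decimal_text(text)
}

#' @describeIn prop_param The proportion as a plain numeric.
#' @param x a `prop_param`.
#' @export
prop_value <- function(x) {
  stopifnot(inherits(x, "prop_param"))
  x$num / x$den
}

prop_rat <- function(x) rat(x$num, x$den)

#' @export
print.prop_param <- function(x, ...) {
  note <- if (nzchar(x$source_note)) paste0("  [", x$source_note, "]") else ""
  cat(sprintf("<prop_param> %s = %s (%.6g)%s\n",
              x$name, x$text, prop_value(x), note))
  invisible(x)
}

# replace the value of a prop_param, keeping name and note; `value` may be
# a numeric (1e-9 grid) or an encoding string
prop_with_value <- function(p, value) {
  if (is.numeric(value)) {
    stopifnot(length(value) == 1L, value >= 0, value <= 1)
    r <- rat_from_numeric(value)
    text <- format(value, digits = 15, scientific = FALSE)
    p$num <- r$num
    p$den <- r$den
    p$text <- text
    p
  } else {
    prop_param(p$name, value, p$source_note)
  }
}
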