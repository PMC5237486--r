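# Exact rational arithmetic on integer-valued doubles.
#
# Scenario proportions are decimal strings of a few digits or small
# rationals such as 1/78, so numerators and denominators stay far below
# 2^53 when reduced after every multiplication; all arithmetic here is
# therefore exact. Published funnel tables are sensitive to half-way
# rounding (e.g. a stage expectation of exactly x.5), which binary
# floating point cannot guarantee to hit.

gcd2 <- function(a, b) {
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

rat <- function(num, den = 1) {
  stopifnot(den > 0, num >= 0, num == floor(num), den == floor(den))
  g <- gcd2(num, den)
  if (g > 1) {
    num <- num / g
    den <- den / g
  }
  list(num = num, den = den)
}

rat_mul <- function(x, y) {
  # cross-reduce before multiplying to keep magnitudes small
  g1 <- gcd2(x$num, y$den)
  g2 <- gcd2(y$num, x$den)
  rat((x$num / g1) * (y$num / g2), (x$den / g2) * (y$den / g1))
}

rat_value <- function(x) x$num / x$den

# round half away from zero, exactly (arguments are non-negative here)
rat_round <- function(x) {
  (2 * x$num + x$den) %/% (2 * x$den)
}

# Exact rational from a decimal string such as "0.013", "39.3", "25".
# Returns NULL if the string is not a plain decimal numeral.
rat_from_decimal_text <- function(s) {
  if (!grepl("^[0-9]+(\\.[0-9]+)?$", s)) return(NULL)
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  int <- as.numeric(parts[1])
  if (length(parts) == 2L) {
    frac <- as.numeric(parts[2])
    den <- 10^nchar(parts[2])
    rat(int * den + frac, den)
  } else {
    rat(int)
  }
}

# Rational approximation of an arbitrary numeric in [0, 1] on a 1e-9 grid;
# exact for any value with at most 9 decimal digits (all config-style and
# sweep-grid values in practice).
rat_from_numeric <- function(v) {
  stopifnot(is.finite(v), v >= 0)
  rat(round(v * 1e9), 1e9)
}

# round half away from zero for plain numerics (used where exactness is
# not required, e.g. Monte Carlo summaries)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
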