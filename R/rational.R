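# Exact rational scalars stored as length-2 doubles c(num, den), den > 0,
# gcd(num, den) == 1.  Magnitudes stay far below 2^53 for the network sizes
# this package targets, so double-backed integer arithmetic is exact.

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' @noRd
rat <- function(num, den = 1) {
  if (den == 0) stop("rational with zero denominator")
  if (num != trunc(num) || den != trunc(den))
    stop("rat() expects integer-valued numerator and denominator")
  if (den < 0) { num <- -num; den <- -den }
  if (num == 0) return(c(0, 1))
  g <- rat_gcd(num, den)
  c(num / g, den / g)
}

# Combine with overflow fallback: symbolic objects built from a mechanism
# only ever hold small integer coefficients, but the sampling pipeline
# substitutes decimal rationals whose products can exceed 2^53.  Past that
# point exactness is impossible in doubles, so the value degrades to a
# 12-significant-digit rational; sampled assignments are re-checked
# numerically downstream, so this only affects display precision.
rat_mk <- function(num, den) {
  if (abs(num) < 2^53 && abs(den) < 2^53) return(rat(num, den))
  rat_from_double(signif(num / den, 12))
}

rat_add <- function(a, b) rat_mk(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
rat_sub <- function(a, b) rat_mk(a[1] * b[2] - b[1] * a[2], a[2] * b[2])
rat_mul <- function(a, b) rat_mk(a[1] * b[1], a[2] * b[2])
rat_div <- function(a, b) {
  if (b[1] == 0) stop("division by zero rational")
  rat_mk(a[1] * b[2], a[2] * b[1])
}
rat_neg <- function(a) c(-a[1], a[2])
rat_eq  <- function(a, b) a[1] == b[1] && a[2] == b[2]
rat_sign <- function(a) sign(a[1])
rat_num <- function(a) a[1] / a[2]

# Exact rational from a double: uses the shortest decimal representation R
# prints (up to 15 significant digits), so round-trips values like
# 1.17511584853 exactly.
rat_from_double <- function(x) {
  if (x == trunc(x) && abs(x) < 2^53) return(rat(x))
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  if (!grepl("^-?[0-9]*\\.?[0-9]+$", s))
    stop("cannot convert ", x, " to an exact rational")
  dot <- regexpr(".", s, fixed = TRUE)
  if (dot < 0) return(rat(as.numeric(s)))
  dec <- nchar(s) - dot
  rat(as.numeric(sub(".", "", s, fixed = TRUE)), 10^dec)
}

# Canonical symbol ordering: alphabetic prefix, then numeric suffix
# (so k2 < k10, and j* < k* < x*; the eigen variable "lambda" sorts by name).
sym_order_key <- function(names) {
  pre <- sub("[0-9]+$", "", names)
  suf <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", names)))
  suf[!grepl("[0-9]+$", names)] <- -1L
  order(pre, suf)
}

sym_sort <- function(names) names[sym_order_key(names)]
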