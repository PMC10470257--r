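# Sparse multivariate polynomials with exact rational coefficients.
#
# A "spoly" is a list of terms keyed by a canonical monomial string.  Each
# term holds the coefficient as c(num, den) and the exponent map as a named
# integer vector.  All arithmetic is exact; no floating point ever enters a
# coefficient.  Symbols are free-form tokens, conventionally k<i> (rate
# constants), x<i> (concentrations), j<i> (convex current parameters) and
# lambda (the characteristic-polynomial variable).

mono_key <- function(exps) {
  exps <- exps[exps != 0L]
  if (length(exps) == 0L) return("1")
  exps <- exps[sym_order_key(names(exps))]
  paste(ifelse(exps == 1L, names(exps),
               paste0(names(exps), "^", exps)), collapse = "*")
}

new_spoly <- function(terms) {
  keep <- vapply(terms, function(t) t$coef[1] != 0, logical(1))
  terms <- terms[keep]
  structure(list(terms = terms), class = "spoly")
}

#' Zero polynomial
#' @return A `spoly` with no terms.
#' @keywords internal
#' @export
sp_zero <- function() new_spoly(list())

#' Constant polynomial with exact rational value num/den
#' @param num,den integer-valued numerator and denominator.
#' @keywords internal
#' @export
sp_const <- function(num, den = 1) {
  c0 <- rat(num, den)
  if (c0[1] == 0) return(sp_zero())
  t <- list(list(coef = c0, exps = integer(0)))
  names(t) <- "1"
  new_spoly(t)
}

#' Single-variable monomial `name^exp`
#' @param name symbol token.
#' @param exp nonnegative integer exponent.
#' @keywords internal
#' @export
sp_var <- function(name, exp = 1L) {
  stopifnot(is.character(name), length(name) == 1L, exp >= 0)
  if (exp == 0) return(sp_const(1))
  e <- as.integer(exp); names(e) <- name
  t <- list(list(coef = c(1, 1), exps = e))
  names(t) <- mono_key(e)
  new_spoly(t)
}

#' is_spoly: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
is_spoly <- function(x) inherits(x, "spoly")

#' as_spoly: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
as_spoly <- function(x) {
  if (is_spoly(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    if (x == trunc(x)) return(sp_const(x))
    r <- rat_from_double(x)
    return(sp_const(r[1], r[2]))
  }
  stop("cannot coerce to spoly: ", paste(class(x), collapse = "/"))
}

#' sp_add: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
sp_add <- function(a, b) {
  a <- as_spoly(a); b <- as_spoly(b)
  terms <- a$terms
  for (key in names(b$terms)) {
    tb <- b$terms[[key]]
    if (is.null(terms[[key]])) {
      terms[[key]] <- tb
    } else {
      terms[[key]]$coef <- rat_add(terms[[key]]$coef, tb$coef)
    }
  }
  new_spoly(terms)
}

#' sp_neg: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
sp_neg <- function(a) {
  a <- as_spoly(a)
  new_spoly(lapply(a$terms, function(t) { t$coef <- rat_neg(t$coef); t }))
}

#' sp_sub: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
sp_sub <- function(a, b) sp_add(a, sp_neg(b))

mono_mul <- function(e1, e2) {
  if (length(e1) == 0L) return(e2)
  if (length(e2) == 0L) return(e1)
  all <- union(names(e1), names(e2))
  v <- integer(length(all)); names(v) <- all
  v[names(e1)] <- v[names(e1)] + e1
  v[names(e2)] <- v[names(e2)] + e2
  v[v != 0L]
}

#' sp_mul: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
sp_mul <- function(a, b) {
  a <- as_spoly(a); b <- as_spoly(b)
  terms <- list()
  for (ta in a$terms) for (tb in b$terms) {
    e <- mono_mul(ta$exps, tb$exps)
    key <- mono_key(e)
    c0 <- rat_mul(ta$coef, tb$coef)
    if (is.null(terms[[key]])) {
      terms[[key]] <- list(coef = c0, exps = e)
    } else {
      terms[[key]]$coef <- rat_add(terms[[key]]$coef, c0)
    }
  }
  new_spoly(terms)
}

#' sp_pow: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
sp_pow <- function(a, n) {
  n <- as.integer(n)
  stopifnot(n >= 0)
  out <- sp_const(1)
  base <- as_spoly(a)
  while (n > 0) {
    if (n %% 2L == 1L) out <- sp_mul(out, base)
    base <- sp_mul(base, base)
    n <- n %/% 2L
  }
  out
}

#' sp_scale: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
sp_scale <- function(a, num, den = 1) sp_mul(a, sp_const(num, den))

#' @export
Ops.spoly <- function(e1, e2) {
  if (.Generic %in% c("+", "-") && missing(e2)) {
    return(if (.Generic == "-") sp_neg(e1) else e1)
  }
  switch(.Generic,
    "+" = sp_add(e1, e2),
    "-" = sp_sub(e1, e2),
    "*" = sp_mul(e1, e2),
    "^" = sp_pow(e1, e2),
    "==" = sp_equal(e1, e2),
    "!=" = !sp_equal(e1, e2),
    stop("operation '", .Generic, "' not defined for spoly"))
}

#' sp_equal: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
sp_equal <- function(a, b) {
  a <- as_spoly(a); b <- as_spoly(b)
  if (length(a$terms) != length(b$terms)) return(FALSE)
  if (!setequal(names(a$terms), names(b$terms))) return(FALSE)
  for (key in names(a$terms))
    if (!rat_eq(a$terms[[key]]$coef, b$terms[[key]]$coef)) return(FALSE)
  TRUE
}

#' sp_is_zero: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
sp_is_zero <- function(a) length(as_spoly(a)$terms) == 0L

#' sp_vars: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
sp_vars <- function(a) {
  v <- unique(unlist(lapply(as_spoly(a)$terms, function(t) names(t$exps))))
  if (is.null(v)) character(0) else sym_sort(v)
}

#' sp_total_degree: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
sp_total_degree <- function(a) {
  a <- as_spoly(a)
  if (length(a$terms) == 0L) return(0L)
  max(vapply(a$terms, function(t) sum(t$exps), numeric(1)))
}

#' sp_degree_in: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
sp_degree_in <- function(a, var) {
  a <- as_spoly(a)
  if (length(a$terms) == 0L) return(0L)
  max(vapply(a$terms, function(t) {
    if (var %in% names(t$exps)) t$exps[[var]] else 0L
  }, numeric(1)))
}

#' sp_is_linear: symbolic polynomial operation
#' @param ... see source; exact-rational sparse polynomial API.
#' @export
sp_is_linear <- function(a) sp_total_degree(a) <= 1L

#' Partial derivative of a polynomial
#' @keywords internal
#' @export
sp_deriv <- function(a, var) {
  a <- as_spoly(a)
  terms <- list()
  for (t in a$terms) {
    if (!(var %in% names(t$exps))) next
    e <- t$exps[[var]]
    t$coef <- rat_mul(t$coef, c(e, 1))
    t$exps[[var]] <- e - 1L
    t$exps <- t$exps[t$exps != 0L]
    key <- mono_key(t$exps)
    if (is.null(terms[[key]])) terms[[key]] <- t
    else terms[[key]]$coef <- rat_add(terms[[key]]$coef, t$coef)
  }
  new_spoly(terms)
}

#' Exact substitution of symbols by polynomials or rationals
#' @param subs named list; values are spoly or numeric scalars.
#' @keywords internal
#' @export
sp_subs <- function(a, subs) {
  a <- as_spoly(a)
  subs <- lapply(subs, as_spoly)
  out <- sp_zero()
  for (t in a$terms) {
    piece <- sp_const(t$coef[1], t$coef[2])
    for (v in names(t$exps)) {
      e <- t$exps[[v]]
      rep <- if (v %in% names(subs)) subs[[v]] else sp_var(v)
      piece <- sp_mul(piece, sp_pow(rep, e))
    }
    out <- sp_add(out, piece)
  }
  out
}

#' Numeric evaluation
#' @param vals named numeric vector covering every symbol of `a`.
#' @keywords internal
#' @export
sp_eval <- function(a, vals) {
  a <- as_spoly(a)
  acc <- 0
  for (t in a$terms) {
    m <- rat_num(t$coef)
    for (v in names(t$exps)) {
      if (is.na(vals[v])) stop("sp_eval: no value for symbol ", v)
      m <- m * vals[[v]]^t$exps[[v]]
    }
    acc <- acc + m
  }
  acc
}

#' Decompose a (linear) polynomial into coefficients and a constant
#' @return list(coef = named list of c(num, den), const = c(num, den)).
#' @keywords internal
#' @export
sp_linear_parts <- function(a) {
  a <- as_spoly(a)
  if (!sp_is_linear(a)) stop("polynomial is not linear")
  coef <- list(); const <- c(0, 1)
  for (t in a$terms) {
    if (length(t$exps) == 0L) const <- rat_add(const, t$coef)
    else coef[[names(t$exps)]] <- t$coef
  }
  list(coef = coef, const = const)
}

# Canonical printing: terms in graded lexicographic order (ascending total
# degree, then the monomial key), coefficients as integers or num/den.
#' @export
format.spoly <- function(x, ...) {
  if (length(x$terms) == 0L) return("0")
  deg <- vapply(x$terms, function(t) sum(t$exps), numeric(1))
  keys <- names(x$terms)
  # graded lexicographic: ascending total degree, then symbol order with
  # numeric suffixes compared numerically (k2 before k10)
  gkey <- vapply(x$terms, function(t) {
    e <- t$exps
    if (length(e) == 0L) return("")
    e <- e[sym_order_key(names(e))]
    paste(sprintf("%s%09d^%02d", sub("[0-9]+$", "", names(e)),
                  ifelse(grepl("[0-9]+$", names(e)),
                         as.integer(sub("^.*?([0-9]+)$", "\\1", names(e))), 0L),
                  e), collapse = " ")
  }, character(1))
  ord <- order(deg, gkey)
  out <- ""
  first <- TRUE
  for (i in ord) {
    t <- x$terms[[i]]
    co <- t$coef
    mono <- keys[i]
    mag <- if (co[2] == 1) format(abs(co[1]), scientific = FALSE)
           else paste0(format(abs(co[1]), scientific = FALSE), "/",
                       format(co[2], scientific = FALSE))
    body <- if (mono == "1") mag
            else if (mag == "1") mono
            else paste0(mag, "*", mono)
    if (first) {
      out <- if (co[1] < 0) paste0("-", body) else body
      first <- FALSE
    } else {
      out <- paste0(out, if (co[1] < 0) " - " else " + ", body)
    }
  }
  out
}

#' @export
print.spoly <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.spoly <- function(x, ...) format(x)
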