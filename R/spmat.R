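# Small dense matrices of spoly entries, stored as R list-matrices.
# Sizes stay tiny (<= ~6 x ~6 for the matrices that are expanded
# symbolically), so cofactor expansion is adequate for determinants.

#' spm: list-matrix of symbolic polynomials
#' @param ... see source.
#' @export
spm <- function(nrow, ncol) {
  m <- matrix(rep(list(sp_zero()), nrow * ncol), nrow = nrow, ncol = ncol)
  m
}

spm_nrow <- function(m) nrow(m)
spm_ncol <- function(m) ncol(m)

# Lift an integer/numeric matrix to constants.
#' spm_from_numeric: list-matrix of symbolic polynomials
#' @param ... see source.
#' @export
spm_from_numeric <- function(a) {
  m <- spm(nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    m[[i, j]] <- sp_const(a[i, j])
  m
}

#' spm_add: list-matrix of symbolic polynomials
#' @param ... see source.
#' @export
spm_add <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  m <- spm(nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    m[[i, j]] <- sp_add(a[[i, j]], b[[i, j]])
  m
}

#' spm_sub: list-matrix of symbolic polynomials
#' @param ... see source.
#' @export
spm_sub <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  m <- spm(nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    m[[i, j]] <- sp_sub(a[[i, j]], b[[i, j]])
  m
}

#' spm_mul: list-matrix of symbolic polynomials
#' @param ... see source.
#' @export
spm_mul <- function(a, b) {
  stopifnot(ncol(a) == nrow(b))
  m <- spm(nrow(a), ncol(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(b))) {
    acc <- sp_zero()
    for (r in seq_len(ncol(a)))
      acc <- sp_add(acc, sp_mul(a[[i, r]], b[[r, j]]))
    m[[i, j]] <- acc
  }
  m
}

#' spm_trace: list-matrix of symbolic polynomials
#' @param ... see source.
#' @export
spm_trace <- function(a) {
  stopifnot(nrow(a) == ncol(a))
  acc <- sp_zero()
  for (i in seq_len(nrow(a))) acc <- sp_add(acc, a[[i, i]])
  acc
}

# Determinant by cofactor expansion along the row with most zero entries.
#' spm_det: list-matrix of symbolic polynomials
#' @param ... see source.
#' @export
spm_det <- function(a) {
  n <- nrow(a)
  stopifnot(n == ncol(a))
  if (n == 1L) return(a[[1, 1]])
  if (n == 2L)
    return(sp_sub(sp_mul(a[[1, 1]], a[[2, 2]]), sp_mul(a[[1, 2]], a[[2, 1]])))
  zeros <- vapply(seq_len(n), function(i)
    sum(vapply(seq_len(n), function(j) sp_is_zero(a[[i, j]]), logical(1))),
    numeric(1))
  row <- which.max(zeros)
  acc <- sp_zero()
  for (j in seq_len(n)) {
    if (sp_is_zero(a[[row, j]])) next
    minor <- a[-row, -j, drop = FALSE]
    term <- sp_mul(a[[row, j]], spm_det(minor))
    if ((row + j) %% 2L == 1L) term <- sp_neg(term)
    acc <- sp_add(acc, term)
  }
  acc
}

# Sum of all m x m principal minors (elementary symmetric function e_m of
# the eigenvalues).
#' spm_principal_minor_sum: list-matrix of symbolic polynomials
#' @param ... see source.
#' @export
spm_principal_minor_sum <- function(a, m) {
  n <- nrow(a)
  stopifnot(n == ncol(a), m >= 1, m <= n)
  acc <- sp_zero()
  for (idx in utils::combn(n, m, simplify = FALSE))
    acc <- sp_add(acc, spm_det(a[idx, idx, drop = FALSE]))
  acc
}

# det(lambda I - A), expanded.
#' spm_charpoly: list-matrix of symbolic polynomials
#' @param ... see source.
#' @export
spm_charpoly <- function(a, sym = "lambda") {
  n <- nrow(a)
  stopifnot(n == ncol(a))
  m <- spm(n, n)
  lam <- sp_var(sym)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    e <- sp_neg(a[[i, j]])
    if (i == j) e <- sp_add(e, lam)
    m[[i, j]] <- e
  }
  spm_det(m)
}

#' spm_equal: list-matrix of symbolic polynomials
#' @param ... see source.
#' @export
spm_equal <- function(a, b) {
  if (!all(dim(a) == dim(b))) return(FALSE)
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    if (!sp_equal(a[[i, j]], b[[i, j]])) return(FALSE)
  TRUE
}

#' spm_eval: list-matrix of symbolic polynomials
#' @param ... see source.
#' @export
spm_eval <- function(a, vals) {
  out <- matrix(0, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    out[i, j] <- sp_eval(a[[i, j]], vals)
  out
}

#' spm_format: list-matrix of symbolic polynomials
#' @param ... see source.
#' @export
spm_format <- function(a) {
  apply(a, c(1, 2), function(e) format(e[[1]]))
}
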