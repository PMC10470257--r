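# Algorithm 2: Clarke's stoichiometric network analysis.
#
# Steady-state fluxes form the pointed polyhedral cone
# {v >= 0 : S v = 0}; its extreme rays ("extreme currents") are the
# columns of E, and any steady flux is E j with j >= 0.  On the cone,
# the Jacobian factorizes as J = S diag(E j) K [diag(h)]; the diagonal
# concentration factor does not affect stability and is dropped, leaving
# the current matrix V(J) = S diag(E j) K, linear in j.

#' Extend the stoichiometric matrix with dual-pair rows
#'
#' Adds, for each rate-equality pair (i, j), a row with +1 in column i and
#' -1 in column j.  Extreme currents of the extended matrix automatically
#' satisfy the dual-pair flux equalities.
#'
#' @param S stoichiometric matrix.
#' @param dual_pairs list of 0-based reaction-index pairs.
#' @return integer matrix with `nrow(S) + length(dual_pairs)` rows.
#' @export
extend_stoich <- function(S, dual_pairs) {
  if (length(dual_pairs) == 0L) return(S)
  extra <- matrix(0L, length(dual_pairs), ncol(S))
  for (i in seq_along(dual_pairs)) {
    p <- dual_pairs[[i]]
    extra[i, p[1] + 1L] <- 1L
    extra[i, p[2] + 1L] <- -1L
  }
  rn <- c(rownames(S), vapply(dual_pairs, function(p)
    sprintf("dual(%d,%d)", p[1], p[2]), character(1)))
  out <- rbind(S, extra)
  rownames(out) <- rn
  out
}

vec_gcd <- function(v) {
  g <- 0
  for (x in v) g <- rat_gcd(g, x)
  if (g == 0) 1 else g
}

#' Extreme currents of the steady-state flux cone
#'
#' Enumerates the extreme rays of `{v >= 0 : S v = 0}` by the double
#' description method on exact integers, starting from the rays of the
#' nonnegative orthant and intersecting one kernel hyperplane at a time.
#' Adjacency is decided by the combinatorial support test.  Columns are
#' normalized to coprime nonnegative integers and ordered
#' lexicographically.
#'
#' @param S integer matrix (plain or extended stoichiometric matrix).
#' @return integer matrix, `ncol(S)` rows by one column per extreme ray;
#'   zero columns mean the network admits no steady-state flux.
#' @export
extreme_currents <- function(S) {
  r <- ncol(S)
  rays <- diag(1, r)                       # columns are rays
  for (row in seq_len(nrow(S))) {
    if (ncol(rays) == 0L) break
    a <- S[row, ]
    s <- as.numeric(a %*% rays)
    P <- which(s > 0); N <- which(s < 0); Z <- which(s == 0)
    if (length(P) == 0L && length(N) == 0L) next
    supp <- lapply(seq_len(ncol(rays)), function(i) which(rays[, i] != 0))
    new_cols <- list()
    for (p in P) for (n in N) {
      u <- union(supp[[p]], supp[[n]])
      adjacent <- TRUE
      for (o in seq_len(ncol(rays))) {
        if (o == p || o == n) next
        if (all(supp[[o]] %in% u)) { adjacent <- FALSE; break }
      }
      if (!adjacent) next
      v <- s[p] * rays[, n] - s[n] * rays[, p]
      v <- v / vec_gcd(v)
      new_cols[[length(new_cols) + 1L]] <- v
    }
    rays <- cbind(rays[, Z, drop = FALSE],
                  if (length(new_cols)) do.call(cbind, new_cols))
    if (is.null(rays)) rays <- matrix(0, r, 0)
  }
  if (ncol(rays) == 0L) return(matrix(0L, r, 0L))
  # normalize, dedupe, canonical lexicographic column order
  for (i in seq_len(ncol(rays))) rays[, i] <- rays[, i] / vec_gcd(rays[, i])
  keys <- apply(rays, 2L, paste, collapse = ",")
  rays <- rays[, !duplicated(keys), drop = FALSE]
  ord <- do.call(order, lapply(seq_len(nrow(rays)), function(i) -rays[i, ]))
  rays <- rays[, ord, drop = FALSE]
  storage.mode(rays) <- "integer"
  colnames(rays) <- paste0("j", seq_len(ncol(rays)) - 1L)
  rownames(rays) <- colnames(S)
  rays
}

# diag(E j) as a list of spoly, one per reaction.
current_diagonal <- function(E) {
  lapply(seq_len(nrow(E)), function(r) {
    acc <- sp_zero()
    for (c in seq_len(ncol(E)))
      if (E[r, c] != 0L)
        acc <- sp_add(acc, sp_scale(sp_var(paste0("j", c - 1L)), E[r, c]))
    acc
  })
}

#' Clarke's current matrix V(J) = S diag(E j) K
#'
#' Always built from the ORIGINAL stoichiometric and kinetic matrices;
#' only E changes when the extended matrix supplied the rays.
#'
#' @param S stoichiometric matrix (species x reactions).
#' @param E extreme currents matrix (reactions x rays).
#' @param K reaction order matrix (reactions x species).
#' @return list-matrix (`spm`) of entries homogeneous linear in j.
#' @export
current_matrix <- function(S, E, K) {
  if (ncol(S) != nrow(E) || nrow(E) != nrow(K) || nrow(S) != ncol(K))
    stop("dimension mismatch: S ", nrow(S), "x", ncol(S),
         ", E ", nrow(E), "x", ncol(E), ", K ", nrow(K), "x", ncol(K))
  d <- current_diagonal(E)
  n <- nrow(S)
  V <- spm(n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- sp_zero()
    for (r in seq_len(ncol(S))) {
      if (S[i, r] == 0L || K[r, j] == 0L) next
      acc <- sp_add(acc, sp_scale(d[[r]], S[i, r] * K[r, j]))
    }
    V[[i, j]] <- acc
  }
  V
}

#' Dual-pair flux equalities over the current parameters
#'
#' For each pair (a, b): `row_a(E) j = row_b(E) j`; identically satisfied
#' equalities are dropped (always the case when E came from the extended
#' matrix).
#'
#' @param E extreme currents matrix.
#' @param dual_pairs list of 0-based reaction-index pairs.
#' @return list of constraints `poly = 0` (see [constraint()]).
#' @export
dual_pair_equalities <- function(E, dual_pairs) {
  out <- list()
  for (p in dual_pairs) {
    diff <- E[p[1] + 1L, ] - E[p[2] + 1L, ]
    poly <- sp_zero()
    for (c in seq_along(diff))
      if (diff[c] != 0)
        poly <- sp_add(poly, sp_scale(sp_var(paste0("j", c - 1L)), diff[c]))
    if (!sp_is_zero(poly))
      out[[length(out) + 1L]] <- constraint(poly, "=")
  }
  out
}

#' Tagged constraint `poly REL 0`
#'
#' @param poly an `spoly`.
#' @param rel one of `">"`, `">="`, `"="`, `"<"`, `"<="`; `<`/`<=` are
#'   normalized by negating the polynomial.
#' @export
constraint <- function(poly, rel = ">") {
  poly <- as_spoly(poly)
  if (rel == "<") { poly <- sp_neg(poly); rel <- ">" }
  if (rel == "<=") { poly <- sp_neg(poly); rel <- ">=" }
  stopifnot(rel %in% c(">", ">=", "="))
  structure(list(poly = poly, rel = rel), class = "constraint")
}

#' @export
format.constraint <- function(x, ...) {
  paste(format(x$poly), x$rel, "0")
}

#' @export
print.constraint <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

has_negative_monomial <- function(p) {
  any(vapply(as_spoly(p)$terms, function(t) t$coef[1] < 0, logical(1)))
}

#' Instability conditions on a current matrix
#'
#' Three heuristics screen V(J) for the possibility of an eigenvalue with
#' positive real part:
#' \describe{
#'   \item{trace-determinant}{2x2 only; branches `det < 0` and
#'     `det > 0 & trace > 0`.}
#'   \item{mineurs}{For each order m up to `max_order`, the
#'     characteristic-polynomial coefficient `c_{n-m} = (-1)^m e_m(V)`
#'     (e_m = sum of m x m principal minors).  Only coefficients whose
#'     expansion contains a negative monomial can become negative for
#'     positive j, so only those are emitted, as `c_{n-m} < 0`.  With
#'     `sum_mineurs = FALSE` each principal minor is screened
#'     individually.}
#'   \item{characteristic-polynomial}{`char(lambda) < 0` with a fresh
#'     symbol `lambda > 0` adjoined; satisfiability guarantees a real
#'     positive eigenvalue.}
#' }
#'
#' @param V current matrix (`spm`).
#' @param heuristic one of `"trace-determinant"`, `"mineurs"`,
#'   `"characteristic-polynomial"`.
#' @param max_order mineurs search stop (option "max-mineur-search-stop").
#' @param sum_mineurs screen the sum of minors (TRUE) or each minor.
#' @return object of class `instability_conditions`: list with `heuristic`,
#'   `branches` (each a list of constraints; alternative disjuncts) and
#'   `stable` (TRUE when no candidate condition exists).
#' @export
instability_conditions <- function(V, heuristic = "mineurs",
                                   max_order = 5L, sum_mineurs = TRUE) {
  n <- nrow(V)
  branches <- list()
  if (heuristic == "trace-determinant") {
    if (n != 2L)
      stop("trace-determinant heuristic needs a 2x2 current matrix; got ",
           n, "x", n)
    pl <- symbolic_plane(V)
    branches <- list(
      list(constraint(sp_neg(pl$determinant), ">")),
      list(constraint(pl$determinant, ">"), constraint(pl$trace, ">")))
  } else if (heuristic == "mineurs") {
    for (m in seq_len(min(n, max_order))) {
      sgn <- if (m %% 2L == 0L) 1 else -1
      if (sum_mineurs) {
        coef <- sp_scale(spm_principal_minor_sum(V, m), sgn)
        if (has_negative_monomial(coef))
          branches[[length(branches) + 1L]] <-
            list(constraint(sp_neg(coef), ">"))
      } else {
        for (idx in utils::combn(n, m, simplify = FALSE)) {
          coef <- sp_scale(spm_det(V[idx, idx, drop = FALSE]), sgn)
          if (has_negative_monomial(coef))
            branches[[length(branches) + 1L]] <-
              list(constraint(sp_neg(coef), ">"))
        }
      }
    }
  } else if (heuristic == "characteristic-polynomial") {
    ch <- spm_charpoly(V)
    branches <- list(list(constraint(sp_neg(ch), ">"),
                          constraint(sp_var("lambda"), ">")))
  } else {
    stop("unknown instability heuristic: ", heuristic)
  }
  structure(list(heuristic = heuristic, branches = branches,
                 stable = length(branches) == 0L),
            class = "instability_conditions")
}

default_sna_options <- function(opts = list()) {
  defaults <- list(
    "dual-pairs-in-ec" = FALSE,
    "instability-heuristic" = "mineurs",
    "sum-mineurs" = TRUE,
    "max-mineur-search-stop" = 5L,
    "simplification-tries" = 10000L,
    "num-samples" = 10L,
    "samples-folder" = NULL)
  for (k in names(opts)) defaults[[k]] <- opts[[k]]
  defaults
}

#' Run the stoichiometric network analysis pipeline
#'
#' Computes extreme currents (optionally from the extended matrix), the
#' current matrix, instability conditions under the chosen heuristic, and
#' samples current parameters that satisfy them.  Each sample is converted
#' to rate constants and numerically eigen-checked; false positives of the
#' heuristics are flagged, never hidden.
#'
#' @param network a `reaction_network`.
#' @param options named list; honored keys: "dual-pairs-in-ec",
#'   "instability-heuristic", "sum-mineurs", "max-mineur-search-stop",
#'   "simplification-tries", "num-samples", "samples-folder".
#' @param seed optional integer seed.
#' @return list report: matrices, conditions, verdict, samples,
#'   false-positive count.
#' @export
run_sna <- function(network, options = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  opts <- default_sna_options(options %||% network$options[["sna"]] %||% list())
  S <- stoich_matrix(network)
  K <- reaction_order_matrix(network)
  use_ext <- isTRUE(opts[["dual-pairs-in-ec"]])
  S_used <- if (use_ext) extend_stoich(S, network$dual_pairs) else S
  E <- extreme_currents(S_used)
  report <- list(algorithm = "sna", network = network$name,
                 extended = use_ext, S = S, K = K, E = E)
  if (ncol(E) == 0L) {
    report$verdict <- "network admits no steady-state flux"
    return(report)
  }
  V <- current_matrix(S, E, K)
  report$V <- V
  conds <- instability_conditions(
    V, opts[["instability-heuristic"]],
    max_order = opts[["max-mineur-search-stop"]],
    sum_mineurs = isTRUE(opts[["sum-mineurs"]]))
  report$conditions <- conds
  if (conds$stable) {
    report$verdict <- "stable (no negative characteristic terms); no unstable steady states found"
    return(report)
  }
  eqs <- if (use_ext) list() else dual_pair_equalities(E, network$dual_pairs)
  positivity <- lapply(seq_len(ncol(E)) - 1L, function(c)
    constraint(sp_var(paste0("j", c)), ">"))
  res <- sample_condition_branches(
    branches = conds$branches, base = c(positivity, eqs),
    network = network, E = E,
    n = opts[["num-samples"]], tries = opts[["simplification-tries"]])
  report$samples <- res$samples
  report$branch_used <- res$branch
  report$false_positives <- res$false_positives
  report$verdict <- if (length(res$samples) == 0L)
    "no unstable steady states found (sampling failed)"
  else "unstable steady states sampled"
  if (!is.null(opts[["samples-folder"]]) && length(res$samples))
    write_samples(res$samples, opts[["samples-folder"]])
  report
}
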