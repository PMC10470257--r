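# Linear equality/strict-inequality systems are solved into nested
# intervals by Fourier-Motzkin elimination (the role Reduce/redlog plays in
# the original method); nonlinear systems are first linearized by a
# substitution heuristic.  Samples drawn from the intervals are always
# re-checked against the original constraints before release.

sp_scale_rat <- function(p, num, den = 1) sp_mul(p, sp_const(num, den))

constraint_subs <- function(con, subs) constraint(sp_subs(con$poly, subs), con$rel)

# Evaluate a constant constraint; NULL if not constant.
constant_violation <- function(con) {
  p <- con$poly
  if (length(sp_vars(p))) return(NULL)
  val <- sp_eval(p, numeric(0))
  ok <- switch(con$rel,
               ">"  = val > 0,
               ">=" = val >= 0,
               "="  = val == 0)
  if (ok) "ok" else "violated"
}

#' Solve a linear constraint system into nested intervals
#'
#' Equality constraints are used first to eliminate pivot variables
#' (preferring variables outside `order`); the remaining strict/weak
#' inequalities are reduced by Fourier-Motzkin elimination from the last
#' variable of `order` to the first.  Each variable ends up with lists of
#' lower- and upper-bound expressions in the variables ordered before it.
#'
#' @param constraints list of [constraint()] objects, all degree <= 1.
#' @param order character vector: the variable nesting order.
#' @return object of class `interval_solution`: list with `order`,
#'   `bounds` (per variable: `lower`, `lower_strict`, `upper`,
#'   `upper_strict`), `equalities` (pivot variable -> expression),
#'   `feasible`, and `constraints` (the originals, for re-checking).
#' @export
linear_solve_intervals <- function(constraints, order) {
  for (con in constraints)
    if (!sp_is_linear(con$poly))
      stop("nonlinear constraint passed to linear_solve_intervals: ",
           format(con), " (linearize first)")
  equalities <- list()
  ineqs <- list()
  eq_queue <- Filter(function(c) c$rel == "=", constraints)
  ineqs <- Filter(function(c) c$rel != "=", constraints)
  infeasible <- FALSE

  while (length(eq_queue)) {
    con <- eq_queue[[1]]; eq_queue <- eq_queue[-1]
    st <- constant_violation(con)
    if (!is.null(st)) {
      if (st == "violated") infeasible <- TRUE
      next
    }
    parts <- sp_linear_parts(con$poly)
    vars <- sym_sort(names(parts$coef))
    outside <- setdiff(vars, order)
    pivot <- if (length(outside)) outside[1] else rev(vars[order(match(vars, order))])[1]
    c0 <- parts$coef[[pivot]]
    # pivot = -(poly - c0*pivot)/c0
    rest <- sp_sub(con$poly, sp_scale_rat(sp_var(pivot), c0[1], c0[2]))
    expr <- sp_scale_rat(sp_neg(rest), c0[2], c0[1])
    equalities[[pivot]] <- expr
    subs <- stats::setNames(list(expr), pivot)
    eq_queue <- lapply(eq_queue, constraint_subs, subs = subs)
    ineqs <- lapply(ineqs, constraint_subs, subs = subs)
    equalities <- lapply(equalities, sp_subs, subs = subs)
  }

  elim_order <- intersect(order, setdiff(order, names(equalities)))
  bounds <- stats::setNames(vector("list", length(elim_order)), elim_order)
  current <- ineqs
  for (v in rev(elim_order)) {
    lower <- list(); lower_strict <- logical(0)
    upper <- list(); upper_strict <- logical(0)
    keep <- list()
    for (con in current) {
      st <- constant_violation(con)
      if (!is.null(st)) { if (st == "violated") infeasible <- TRUE; next }
      parts <- sp_linear_parts(con$poly)
      if (!v %in% names(parts$coef)) { keep[[length(keep) + 1L]] <- con; next }
      cv <- parts$coef[[v]]
      rest <- sp_sub(con$poly, sp_scale_rat(sp_var(v), cv[1], cv[2]))
      bound <- sp_scale_rat(sp_neg(rest), cv[2], cv[1])
      if (cv[1] > 0) {          # cv * v + rest REL 0  ->  v REL bound
        lower[[length(lower) + 1L]] <- bound
        lower_strict <- c(lower_strict, con$rel == ">")
      } else {
        upper[[length(upper) + 1L]] <- bound
        upper_strict <- c(upper_strict, con$rel == ">")
      }
    }
    # combine every lower/upper pair into a constraint on earlier variables
    for (li in seq_along(lower)) for (ui in seq_along(upper)) {
      strict <- lower_strict[li] || upper_strict[ui]
      keep[[length(keep) + 1L]] <-
        constraint(sp_sub(upper[[ui]], lower[[li]]),
                   if (strict) ">" else ">=")
    }
    sim <- simplify_bounds(lower, lower_strict, is_lower = TRUE)
    lower <- sim$exprs; lower_strict <- sim$strict
    sim <- simplify_bounds(upper, upper_strict, is_lower = FALSE)
    upper <- sim$exprs; upper_strict <- sim$strict
    bounds[[v]] <- list(lower = lower, lower_strict = lower_strict,
                        upper = upper, upper_strict = upper_strict)
    current <- keep
  }
  for (con in current) {
    st <- constant_violation(con)
    if (!is.null(st) && st == "violated") infeasible <- TRUE
    if (is.null(st))
      stop("constraint involves a variable outside the elimination order: ",
           format(con))
  }
  structure(list(order = elim_order, bounds = bounds,
                 equalities = equalities, feasible = !infeasible,
                 constraints = constraints),
            class = "interval_solution")
}

# Drop duplicate bound expressions and dominated constant bounds.
simplify_bounds <- function(exprs, strict, is_lower) {
  if (length(exprs) == 0L) return(list(exprs = exprs, strict = strict))
  keys <- vapply(exprs, format, character(1))
  keep <- !duplicated(keys)
  # among duplicates, strict dominates weak
  for (k in unique(keys[duplicated(keys)])) {
    idx <- which(keys == k)
    strict[idx[1]] <- any(strict[idx])
  }
  exprs <- exprs[keep]; strict <- strict[keep]
  isconst <- vapply(exprs, function(e) length(sp_vars(e)) == 0L, logical(1))
  if (sum(isconst) > 1L) {
    vals <- vapply(exprs[isconst], sp_eval, numeric(1), vals = numeric(0))
    best <- if (is_lower) which.max(vals) else which.min(vals)
    drop <- which(isconst)[-best]
    exprs <- exprs[-drop]; strict <- strict[-drop]
  }
  list(exprs = exprs, strict = strict)
}

#' @export
format.interval_solution <- function(x, ...) {
  out <- character(0)
  for (v in names(x$equalities))
    out <- c(out, paste0(v, " = ", format(x$equalities[[v]])))
  for (v in x$order) {
    b <- x$bounds[[v]]
    lo <- if (length(b$lower) == 0L) "-inf"
          else if (length(b$lower) == 1L) format(b$lower[[1]])
          else paste0("max(", paste(vapply(b$lower, format, character(1)),
                                    collapse = ", "), ")")
    hi <- if (length(b$upper) == 0L) "inf"
          else if (length(b$upper) == 1L) format(b$upper[[1]])
          else paste0("min(", paste(vapply(b$upper, format, character(1)),
                                    collapse = ", "), ")")
    out <- c(out, paste0(v, " in (", lo, ", ", hi, ")"))
  }
  if (!x$feasible) out <- c(out, "infeasible")
  paste(out, collapse = "\n")
}

#' @export
print.interval_solution <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

count_nonlinear_symbol_use <- function(constraints) {
  counts <- integer(0)
  for (con in constraints) {
    for (t in con$poly$terms) {
      if (sum(t$exps) < 2L) next
      for (v in names(t$exps)) {
        if (is.na(counts[v])) counts[v] <- 0L
        counts[v] <- counts[v] + 1L
      }
    }
  }
  counts
}

# Reduce a univariate polynomial inequality to linear bounds via its real
# roots.  Keeps the rightmost feasible interval (current/rate parameters
# are positive and typically unbounded above); returns NULL when the
# constraint is infeasible on the reals.
reduce_univariate <- function(con) {
  v <- sp_vars(con$poly)
  stopifnot(length(v) == 1L)
  deg <- sp_degree_in(con$poly, v)
  coefs <- numeric(deg + 1L)
  for (t in con$poly$terms) {
    e <- if (length(t$exps)) t$exps[[1]] else 0L
    coefs[e + 1L] <- rat_num(t$coef)
  }
  roots <- polyroot(coefs)
  real <- sort(unique(round(Re(roots)[abs(Im(roots)) <
                                        1e-9 * (1 + Mod(roots))], 12)))
  pts <- c(-Inf, real, Inf)
  feas <- logical(length(pts) - 1L)
  f <- function(x) sum(coefs * x^(0:deg))
  for (i in seq_len(length(pts) - 1L)) {
    mid <- if (is.infinite(pts[i]) && is.infinite(pts[i + 1L])) 0
           else if (is.infinite(pts[i])) pts[i + 1L] - 1
           else if (is.infinite(pts[i + 1L])) pts[i] + 1
           else (pts[i] + pts[i + 1L]) / 2
    val <- f(mid)
    feas[i] <- if (con$rel == ">") val > 0 else val >= 0
  }
  if (!any(feas)) return(NULL)
  i <- max(which(feas))       # rightmost feasible component
  out <- list()
  if (is.finite(pts[i])) {
    r <- rat_from_double(pts[i])
    out[[length(out) + 1L]] <-
      constraint(sp_sub(sp_var(v), sp_const(r[1], r[2])), con$rel)
  }
  if (is.finite(pts[i + 1L])) {
    r <- rat_from_double(pts[i + 1L])
    out[[length(out) + 1L]] <-
      constraint(sp_sub(sp_const(r[1], r[2]), sp_var(v)), con$rel)
  }
  out
}

#' Linearize a polynomial constraint system by random substitution
#'
#' Repeatedly: (i) rewrite nonlinear constraints involving a single
#' variable into linear bounds via their real roots; (ii) find the symbol
#' occurring in the most nonlinear monomials (ties broken by canonical
#' symbol order), substitute a pseudo-random positive value for it
#' (log-uniform on `[1e-3, 1e3]`, or the value given in `fixed`), and
#' simplify -- until every constraint is linear or the try budget is
#' exhausted.
#'
#' @param constraints list of [constraint()] objects.
#' @param tries maximum substitution attempts ("simplification-tries").
#' @param fixed named numeric vector of prescribed substitution values.
#' @return list with `constraints` (now linear), `assignments` (named
#'   numeric: substituted values), `success`, `attempts`.
#' @export
nonlinear_to_linear <- function(constraints, tries = 10000L, fixed = NULL) {
  attempt <- 0L
  original <- constraints
  repeat {
    constraints <- original
    assignments <- numeric(0)
    failed <- FALSE
    repeat {
      # univariate polynomial constraints -> linear bounds
      nl <- which(vapply(constraints, function(c)
        !sp_is_linear(c$poly), logical(1)))
      uni <- nl[vapply(constraints[nl], function(c)
        length(sp_vars(c$poly)) == 1L && c$rel != "=", logical(1))]
      if (length(uni)) {
        replaced <- list()
        for (i in seq_along(constraints)) {
          if (i %in% uni) {
            red <- reduce_univariate(constraints[[i]])
            if (is.null(red)) { failed <- TRUE; break }
            replaced <- c(replaced, red)
          } else replaced <- c(replaced, constraints[i])
        }
        if (failed) break
        constraints <- replaced
        next
      }
      counts <- count_nonlinear_symbol_use(constraints)
      if (length(counts) == 0L) break              # all linear
      ord <- sym_sort(names(counts))
      counts <- counts[ord]
      var <- names(counts)[which.max(counts)]
      attempt <- attempt + 1L
      if (attempt > tries)
        return(list(constraints = constraints, assignments = assignments,
                    success = FALSE, attempts = attempt - 1L))
      val <- if (!is.null(fixed) && var %in% names(fixed)) fixed[[var]]
             else signif(runif_log(1), 4)   # short decimals keep rationals small
      r <- rat_from_double(val)
      subs <- stats::setNames(list(sp_const(r[1], r[2])), var)
      constraints <- lapply(constraints, constraint_subs, subs = subs)
      assignments[var] <- val
      bad <- vapply(constraints, function(c)
        identical(constant_violation(c), "violated"), logical(1))
      if (any(bad)) { failed <- TRUE; break }
      constraints <- constraints[vapply(constraints, function(c)
        is.null(constant_violation(c)), logical(1))]
    }
    if (!failed)
      return(list(constraints = constraints, assignments = assignments,
                  success = TRUE, attempts = attempt))
    if (attempt >= tries)
      return(list(constraints = constraints, assignments = assignments,
                  success = FALSE, attempts = attempt))
    if (length(assignments) == 0L && !length(count_nonlinear_symbol_use(original)))
      return(list(constraints = original, assignments = numeric(0),
                  success = FALSE, attempts = attempt))
  }
}

check_assignment <- function(constraints, vals, tol = 1e-9) {
  for (con in constraints) {
    v <- sp_eval(con$poly, vals)
    scale <- max(1, abs(v))
    ok <- switch(con$rel,
                 ">"  = v > 0,
                 ">=" = v >= -tol * scale,
                 "="  = abs(v) <= tol * scale)
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Draw assignments from an interval solution
#'
#' Variables are drawn in nesting order: bounded intervals uniformly, a
#' half-open interval `(lb, inf)` as `lb` plus a log-uniform offset on
#' `[1e-2, 1e2]`.  Strict bounds are respected by a relative margin of
#' 1e-9.  Every assignment is re-checked against the original constraints
#' before release.
#'
#' @param solution an `interval_solution`.
#' @param n number of assignments.
#' @param retry resample budget per assignment.
#' @return list of named numeric vectors (possibly shorter than `n` when
#'   the retry budget runs out; zero-length for an infeasible solution).
#' @export
sample_from_intervals <- function(solution, n, retry = 100L) {
  if (!solution$feasible) return(list())
  out <- list()
  margin <- 1e-9
  for (i in seq_len(n)) {
    got <- FALSE
    for (att in seq_len(retry)) {
      vals <- numeric(0)
      ok <- TRUE
      for (v in solution$order) {
        b <- solution$bounds[[v]]
        lo <- -Inf; hi <- Inf
        for (e in b$lower) lo <- max(lo, sp_eval(e, vals))
        for (e in b$upper) hi <- min(hi, sp_eval(e, vals))
        if (lo > hi || (lo == hi && (any(b$lower_strict) || any(b$upper_strict)))) {
          ok <- FALSE; break
        }
        if (is.finite(lo) && is.finite(hi)) {
          m <- margin * max(1, abs(lo), abs(hi))
          if (hi - lo <= 2 * m) {
            # degenerate (boundary) interval: only weak bounds admit it
            if (any(b$lower_strict) || any(b$upper_strict)) { ok <- FALSE; break }
            val <- (lo + hi) / 2
          } else val <- stats::runif(1, lo + m, hi - m)
        } else if (is.finite(lo)) {
          val <- lo + runif_log(1, 1e-2, 1e2)
        } else if (is.finite(hi)) {
          val <- hi - runif_log(1, 1e-2, 1e2)
        } else {
          val <- runif_log(1, 1e-2, 1e2)
        }
        vals[v] <- val
      }
      if (!ok) next
      for (v in names(solution$equalities))
        vals[v] <- sp_eval(solution$equalities[[v]], vals)
      if (check_assignment(solution$constraints, vals)) {
        out[[length(out) + 1L]] <- vals
        got <- TRUE
        break
      }
    }
    if (!got) break
  }
  out
}

#' Convert a current-space sample to concrete rate constants
#'
#' Computes the steady flux `v = E j`, draws concentrations uniformly on
#' `[0.001, 0.01]` (arbitrary units) with enantiomer partners assigned
#' equal values, and sets `k_i = v_i / prod_s x_s^{K[i,s]}`.  Zero
#' velocities give `k_i = 0`, flagged (the reaction drops out of the
#' model).  Dual-pair rate equality is enforced exactly.
#'
#' @param E extreme currents matrix.
#' @param j named or plain numeric current vector (`j0`, `j1`, ...).
#' @param network a `reaction_network`.
#' @param algorithm tag recorded in the sample.
#' @return object of class `rate_sample`.
#' @export
currents_to_rates <- function(E, j, network, algorithm = "sna") {
  nrays <- ncol(E)
  jv <- numeric(nrays)
  if (!is.null(names(j))) {
    for (c in seq_len(nrays)) jv[c] <- j[[paste0("j", c - 1L)]]
  } else jv <- as.numeric(j)[seq_len(nrays)]
  v <- as.numeric(E %*% jv)
  K <- reaction_order_matrix(network)
  nsp <- length(network$species)
  x <- stats::runif(nsp, 0.001, 0.01)
  for (p in network$enantiomeric_pairs) x[p[2] + 1L] <- x[p[1] + 1L]
  k <- vapply(seq_along(v), function(i) {
    denom <- prod(x^K[i, ])
    v[i] / denom
  }, numeric(1))
  zero_vel <- which(v == 0)
  # force exact dual-pair equality (guards against roundoff in the division)
  for (g in network$dual_groups) {
    vals <- k[g + 1L]
    if (diff(range(vals)) > 1e-8 * max(abs(vals), 1))
      warning("dual-pair rate constants differ beyond roundoff for group (",
              paste(g, collapse = ","), ")")
    k[g + 1L] <- vals[1]
  }
  structure(list(
    model = network$name,
    algorithm = algorithm,
    rate_constants = stats::setNames(k, paste0("k", seq_along(k) - 1L)),
    initial_concentrations = stats::setNames(x, network$species),
    currents = stats::setNames(jv, paste0("j", seq_len(nrays) - 1L)),
    flags = list(zero_velocity = zero_vel - 1L,
                 unstable = NA, frank = NA)
  ), class = "rate_sample")
}

#' Numeric Jacobian of the mass-action system at a state
#'
#' @param network a `reaction_network`.
#' @param k rate constants (one per reaction).
#' @param x concentrations.
#' @return numeric species x species matrix.
#' @export
numeric_jacobian <- function(network, k, x) {
  S <- stoich_matrix(network)
  K <- reaction_order_matrix(network)
  n <- nrow(S)
  J <- matrix(0, n, n)
  vflux <- k * apply(K, 1L, function(ord) prod(x^ord))
  for (t in seq_len(n)) {
    # d v_r / d x_t = K[r,t] * v_r / x_t  (mass action, x_t > 0)
    dv <- ifelse(K[, t] > 0, K[, t] * vflux / x[t], 0)
    J[, t] <- as.numeric(S %*% dv)
  }
  J
}

# Antisymmetric restriction of the Jacobian: basis e_L - e_D per pair.
antisymmetric_block <- function(J, pairs) {
  m <- length(pairs)
  M <- matrix(0, m, m)
  for (p in seq_len(m)) for (q in seq_len(m)) {
    Lp <- pairs[[p]][1] + 1L
    Lq <- pairs[[q]][1] + 1L; Dq <- pairs[[q]][2] + 1L
    M[p, q] <- J[Lp, Lq] - J[Lp, Dq]
  }
  M
}

#' Eigen-check a rate sample for instability and frankness
#'
#' The sampled state is a steady state by construction (`v = E j`).  The
#' sample is unstable when the numeric Jacobian has an eigenvalue with
#' positive real part; it is "frank" when the Jacobian restricted to the
#' antisymmetric (enantiomer-swap odd) subspace has one -- the mode that
#' actually breaks mirror symmetry.
#'
#' @param network a `reaction_network`.
#' @param sample a `rate_sample`.
#' @param tol positive-real-part threshold.
#' @return the sample with `flags$unstable` and `flags$frank` filled in.
#' @export
eigen_check_sample <- function(network, sample, tol = 1e-9) {
  k <- sample$rate_constants
  x <- sample$initial_concentrations
  J <- numeric_jacobian(network, as.numeric(k), as.numeric(x))
  ev <- eigen(J, only.values = TRUE)$values
  sample$flags$unstable <- max(Re(ev)) > tol
  M <- antisymmetric_block(J, network$enantiomeric_pairs)
  evM <- eigen(M, only.values = TRUE)$values
  sample$flags$frank <- max(Re(evM)) > tol
  sample
}

#' Fraction of frank samples
#'
#' @param samples list of eigen-checked `rate_sample` objects.
#' @param network a `reaction_network` (used to fill in missing flags).
#' @return list with `n_frank`, `n_total` and `proportion` (`NA` for an
#'   empty sample list: 0/0 is undefined, not 0).
#' @export
frank_proportion <- function(samples, network) {
  if (length(samples) == 0L)
    return(list(n_frank = 0L, n_total = 0L, proportion = NA_real_))
  flags <- vapply(samples, function(s) {
    if (is.na(s$flags$frank)) s <- eigen_check_sample(network, s)
    isTRUE(s$flags$frank)
  }, logical(1))
  list(n_frank = sum(flags), n_total = length(flags),
       proportion = sum(flags) / length(flags))
}

# Shared branch-sampling driver used by algorithms 2, 5 and 6.  A random
# substitution can land in an infeasible corner of the constraint set, so
# each branch gets several fresh linearization attempts.
sample_condition_branches <- function(branches, base, network, E, n,
                                      tries = 10000L, algorithm = "sna",
                                      fixed = NULL, attempts = 40L) {
  jvars <- paste0("j", seq_len(ncol(E)) - 1L)
  for (bi in seq_along(branches)) {
    constr <- c(base, branches[[bi]])
    for (att in seq_len(attempts)) {
      res <- tryCatch({
        nl <- nonlinear_to_linear(constr, tries = tries, fixed = fixed)
        if (!nl$success) NULL else {
          vars <- sym_sort(unique(unlist(lapply(nl$constraints, function(c)
            sp_vars(c$poly)))))
          ord <- c(intersect(jvars, vars), intersect("lambda", vars))
          sol <- linear_solve_intervals(nl$constraints, ord)
          if (!sol$feasible) NULL else {
            draws <- sample_from_intervals(sol, n)
            if (length(draws) == 0L) NULL
            else list(nl = nl, sol = sol, draws = draws)
          }
        }
      }, error = function(e) NULL)
      if (is.null(res)) next
      samples <- lapply(res$draws, function(d) {
        full <- c(d, res$nl$assignments)
        missing <- setdiff(jvars, names(full))
        if (length(missing)) full[missing] <- 0
        s <- currents_to_rates(E, full, network, algorithm = algorithm)
        eigen_check_sample(network, s)
      })
      fp <- sum(!vapply(samples, function(s) isTRUE(s$flags$unstable),
                        logical(1)))
      return(list(samples = samples, branch = bi, false_positives = fp,
                  solution = res$sol, assignments = res$nl$assignments))
    }
  }
  list(samples = list(), branch = NA_integer_, false_positives = 0L,
       solution = NULL, assignments = numeric(0))
}

#' Write samples as .simu.json files
#'
#' One JSON document per sample, `<model>-<i>.simu.json`.
#'
#' @param samples list of `rate_sample` objects.
#' @param folder output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
write_samples <- function(samples, folder) {
  dir.create(folder, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    path <- file.path(folder, sprintf("%s-%03d.simu.json",
                                      gsub("[^A-Za-z0-9_-]", "_", s$model), i))
    jsonlite::write_json(list(
      model = s$model, algorithm = s$algorithm,
      rate_constants = as.list(s$rate_constants),
      initial_concentrations = as.list(s$initial_concentrations),
      currents = as.list(s$currents),
      flags = list(unstable = s$flags$unstable, frank = s$flags$frank,
                   zero_velocity = I(s$flags$zero_velocity))),
      path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a .simu.json sample file
#' @param path file written by [write_samples()].
#' @return a `rate_sample`.
#' @export
read_sample <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    model = d$model, algorithm = d$algorithm,
    rate_constants = unlist(d$rate_constants),
    initial_concentrations = unlist(d$initial_concentrations),
    currents = unlist(d$currents),
    flags = list(zero_velocity = d$flags$zero_velocity,
                 unstable = d$flags$unstable, frank = d$flags$frank)
  ), class = "rate_sample")
}
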