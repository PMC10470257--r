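# Algorithms 3-6: six-category classification, the Frank inequality on the
# Jacobian and on the current matrix, and the multi-pair block reduction.
#
# The Frank inequality J11 - J12 > 0 (equivalently V11 - V12 > 0) is the
# necessary condition for an unstable mode that is odd under the
# enantiomer swap -- the mode that breaks mirror symmetry.

category_names <- c(
  R1 = "synthesis", R2 = "fo-decomposition", R3 = "autocatalytic",
  R4 = "so-decomposition", R5 = "no-enantioselective", R6 = "inhibition")

# Category of a single reaction with respect to enantiomers L (species 0)
# and D (species 1).  Returns "achiral" for reactions touching neither
# enantiomer (pure context), NA when the reaction involves L or D but
# matches no template.
classify_reaction_category <- function(rx, L, D) {
  cf <- function(ms, sp) if (sp %in% names(ms)) ms[[sp]] else 0L
  a <- cf(rx$reactants, L); b <- cf(rx$products, L)
  cc <- cf(rx$reactants, D); d <- cf(rx$products, D)
  sig <- c(a, b, cc, d)
  if (all(sig == 0L)) return("achiral")
  if (identical(sig, c(0L, 1L, 0L, 0L)) ||
      identical(sig, c(0L, 0L, 0L, 1L))) return("R1")
  if (identical(sig, c(1L, 0L, 0L, 0L)) ||
      identical(sig, c(0L, 0L, 1L, 0L))) return("R2")
  if (identical(sig, c(1L, 2L, 0L, 0L)) ||
      identical(sig, c(0L, 0L, 1L, 2L))) return("R3")
  if (identical(sig, c(2L, 1L, 0L, 0L)) ||
      identical(sig, c(0L, 0L, 2L, 1L))) return("R4")
  if (identical(sig, c(1L, 1L, 0L, 1L)) ||
      identical(sig, c(0L, 1L, 1L, 1L))) return("R5")
  if (a == 1L && cc == 1L && b <= 1L && d <= 1L && b + d < 2L) return("R6")
  NA_character_
}

#' Classify every reaction into the six SMSB categories
#'
#' Templates over the first enantiomeric pair (L, D) and arbitrary achiral
#' context: R1 synthesis (X -> L + X'), R2 first-order decomposition
#' (L + X -> X'), R3 autocatalysis (L + X -> 2L + X'), R4 second-order
#' decomposition (2L + X -> L + X'), R5 limited-enantioselectivity
#' (L + X -> L + D + X'), R6 inhibition (L + D + X -> ... ).  Reactions
#' touching neither enantiomer are pure context ("achiral") and carry no
#' category sum.  A chiral reaction matching no template makes the
#' analysis impossible.
#'
#' @param network a `reaction_network`.
#' @return list with `ok`; on success `labels` (per rate-equality group:
#'   category + 0-based reaction indices); on failure `failed_reaction`
#'   (0-based index) and `message`.
#' @export
classify_six_categories <- function(network) {
  L <- network$species[1]; D <- network$species[2]
  cats <- character(length(network$reactions))
  for (i in seq_along(network$reactions)) {
    cats[i] <- classify_reaction_category(network$reactions[[i]], L, D)
    if (is.na(cats[i]))
      return(list(ok = FALSE, failed_reaction = i - 1L,
                  message = paste0("reaction ", i - 1L, " ('",
                                   format_reaction(network$reactions[[i]]),
                                   "') matches none of the six categories; ",
                                   "the analysis is impossible")))
  }
  reps <- rate_representatives(network)
  labels <- list()
  for (r in sort(unique(reps))) {
    members <- which(reps == r) - 1L
    mcats <- unique(cats[members + 1L])
    mcats <- setdiff(mcats, "achiral")
    if (length(mcats) == 0L) next
    if (length(mcats) > 1L)
      return(list(ok = FALSE, failed_reaction = members[1],
                  message = paste0("rate-equality group (",
                                   paste(members, collapse = ","),
                                   ") mixes categories ",
                                   paste(mcats, collapse = "/"))))
    labels[[length(labels) + 1L]] <-
      list(category = mcats, name = category_names[[mcats]],
           reactions = members, rate = r)
  }
  list(ok = TRUE, labels = labels, categories = cats)
}

#' Linear rate-constant constraints of the six-category analysis
#'
#' Builds, over the dual-merged rate symbols: the category balance
#' equality (synthesis P, fo-decomposition D, autocatalysis A,
#' so-decomposition DE, LES E, inhibition C weighted by stoichiometry):
#' `-P + D - A + DE - E + C = 0`; and the two Frank-type inequalities
#' `J11 - J12 > 0`, `J11 + J12 < 0` evaluated at the normalized symmetric
#' steady state (every concentration scaled to 1), which makes them
#' concentration-free and linear in k.
#'
#' @param network a `reaction_network`.
#' @param classification result of [classify_six_categories()].
#' @return list with `balance` (equality constraint), `frank`
#'   (constraint `J11 - J12 > 0`), `antifrank` (constraint
#'   `-(J11 + J12) > 0`), `positivity`, and `rate_order` (non-synthesis
#'   representative symbols; synthesis rates are determined by the
#'   balance).
#' @export
six_category_constraints <- function(network, classification =
                                       classify_six_categories(network)) {
  if (!classification$ok)
    stop("six-category classification failed: ", classification$message)
  balance <- sp_zero()
  synth_syms <- character(0)
  rep_syms <- character(0)
  for (lab in classification$labels) {
    ksym <- sp_var(paste0("k", lab$rate))
    rep_syms <- c(rep_syms, paste0("k", lab$rate))
    w <- switch(lab$category,
                R1 = -1, R2 = 1, R3 = -1, R4 = 1, R5 = -1, R6 = NA)
    if (lab$category == "R6") {
      # inhibition weighted by the reactant stoichiometric coefficient of
      # the enantiomer (1 for L + D -> ...)
      rx <- network$reactions[[lab$reactions[1] + 1L]]
      coefL <- rx$reactants[[network$species[1]]]
      w <- coefL
    }
    if (lab$category == "R1") synth_syms <- c(synth_syms, paste0("k", lab$rate))
    balance <- sp_add(balance, sp_scale(ksym, w))
  }
  odes <- network_odes(network, merge_duals = TRUE)
  J <- jacobian_matrix(odes)
  ones <- stats::setNames(rep(list(sp_const(1)),
                              length(network$species)),
                          conc_symbols(network))
  J11 <- sp_subs(J[[1, 1]], ones)
  J12 <- sp_subs(J[[1, 2]], ones)
  frank <- constraint(sp_sub(J11, J12), ">")
  antifrank <- constraint(sp_neg(sp_add(J11, J12)), ">")
  positivity <- lapply(rep_syms, function(s) constraint(sp_var(s), ">"))
  list(balance = constraint(balance, "="),
       frank = frank, antifrank = antifrank,
       positivity = positivity,
       rate_order = setdiff(sym_sort(rep_syms), synth_syms),
       balance_formula_note = paste(
         "category balance implemented with the worked-instance sign of the",
         "inhibition term (+C); the displayed generic formula (-C) disagrees",
         "with the worked instance and is flagged here"))
}

#' Algorithm 3: six-category analysis with sampling
#'
#' @param network a `reaction_network`.
#' @param n_samples number of rate sets to draw.
#' @param seed optional integer seed.
#' @return report list: classification, constraints, interval solution,
#'   samples (rate sets at the normalized symmetric steady state, all
#'   concentrations 1), false-positive count.
#' @export
run_six_categories <- function(network, n_samples = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cls <- classify_six_categories(network)
  report <- list(algorithm = "six-categories", network = network$name,
                 classification = cls)
  if (!cls$ok) {
    report$verdict <- cls$message
    return(report)
  }
  cons <- six_category_constraints(network, cls)
  report$constraints <- cons
  all_cons <- c(cons$positivity, list(cons$balance, cons$frank,
                                      cons$antifrank))
  sol <- linear_solve_intervals(all_cons, cons$rate_order)
  report$solution <- sol
  if (!sol$feasible) {
    report$verdict <- "Frank/balance system infeasible: no SMSB states"
    return(report)
  }
  draws <- sample_from_intervals(sol, n_samples)
  reps <- rate_representatives(network)
  samples <- lapply(draws, function(d) {
    k <- vapply(reps, function(r) {
      sym <- paste0("k", r)
      if (sym %in% names(d)) d[[sym]] else 0
    }, numeric(1))
    s <- structure(list(
      model = network$name, algorithm = "six-categories",
      rate_constants = stats::setNames(k, paste0("k", seq_along(k) - 1L)),
      initial_concentrations = stats::setNames(rep(1, length(network$species)),
                                               network$species),
      currents = numeric(0),
      flags = list(zero_velocity = integer(0), unstable = NA, frank = NA)
    ), class = "rate_sample")
    eigen_check_sample(network, s)
  })
  report$samples <- samples
  report$false_positives <- sum(!vapply(samples, function(s)
    isTRUE(s$flags$unstable), logical(1)))
  report$verdict <- if (length(samples)) "symmetry-breaking states sampled"
                    else "sampling failed"
  report
}

#' Algorithm 4: the Frank inequality on the Jacobian (report only)
#'
#' Emits, over dual-merged rate symbols at the mirror-symmetric state
#' (x1 = x0 for the first pair): the steady-state equation, the
#' determinant nondegeneracy condition, and the Frank inequality
#' `J11 - J12 > 0`.  All are nonlinear in (k, x) and explicitly labeled
#' non-sampleable.
#'
#' @param network a `reaction_network`.
#' @return report list with `steady_state` (spoly, = 0),
#'   `det_nonzero` (spoly, != 0), `frank_inequality` (constraint),
#'   `sampleable = FALSE`.
#' @export
frank_inequality_jacobian <- function(network) {
  odes <- network_odes(network, merge_duals = TRUE)
  J <- jacobian_matrix(odes)
  sym_state <- list(x1 = sp_var("x0"))
  ss <- sp_subs(odes[[1]], sym_state)
  J11 <- sp_subs(J[[1, 1]], sym_state)
  J12 <- sp_subs(J[[1, 2]], sym_state)
  J21 <- sp_subs(J[[2, 1]], sym_state)
  J22 <- sp_subs(J[[2, 2]], sym_state)
  detJ <- sp_sub(sp_mul(J11, J22), sp_mul(J12, J21))
  list(algorithm = "frank-ineq-nonlinear", network = network$name,
       steady_state = ss,
       det_nonzero = detJ,
       frank_inequality = constraint(sp_sub(J11, J12), ">"),
       sampleable = FALSE,
       note = paste("all conditions are nonlinear in (k, x);",
                    "no sampling is attempted"))
}

#' The Frank inequality on a current matrix
#'
#' @param V current matrix (`spm`); species 0, 1 are the enantiomeric pair.
#' @return constraint `V[0,0] - V[0,1] > 0`, linear in j.
#' @export
frank_inequality_current <- function(V) {
  constraint(sp_sub(V[[1, 1]], V[[1, 2]]), ">")
}

#' Reduce the current matrix of a multi-pair network
#'
#' Reorders species as (all left enantiomers, all right enantiomers,
#' achiral), verifies the `[A B; B A]` block symmetry of the chiral part,
#' and returns `V' = A - B`, the m x m matrix (m = number of enantiomeric
#' pairs) whose spectrum governs the mirror-symmetry-breaking modes.
#'
#' @param V current matrix built from the extended extreme currents.
#' @param enantiomeric_pairs list of 0-based species index pairs.
#' @return list with `Vprime` (`spm`, m x m), `A`, `B`, and the index
#'   bookkeeping.
#' @export
reduce_multi_pair <- function(V, enantiomeric_pairs) {
  m <- length(enantiomeric_pairs)
  if (m < 1L) stop("need at least one enantiomeric pair")
  left <- vapply(enantiomeric_pairs, function(p) p[1] + 1L, integer(1))
  right <- vapply(enantiomeric_pairs, function(p) p[2] + 1L, integer(1))
  bad <- character(0)
  for (p in seq_len(m)) for (q in seq_len(m)) {
    if (!sp_equal(V[[left[p], left[q]]], V[[right[p], right[q]]]))
      bad <- c(bad, sprintf("V[%d,%d] != V[%d,%d]",
                            left[p] - 1L, left[q] - 1L,
                            right[p] - 1L, right[q] - 1L))
    if (!sp_equal(V[[left[p], right[q]]], V[[right[p], left[q]]]))
      bad <- c(bad, sprintf("V[%d,%d] != V[%d,%d]",
                            left[p] - 1L, right[q] - 1L,
                            right[p] - 1L, left[q] - 1L))
  }
  if (length(bad))
    stop("current matrix violates the [A B; B A] block symmetry ",
         "(missing or incorrect dual pairs?): ",
         paste(bad, collapse = "; "))
  A <- V[left, left, drop = FALSE]
  B <- V[left, right, drop = FALSE]
  list(Vprime = spm_sub(A, B), A = A, B = B,
       left = left - 1L, right = right - 1L)
}

#' Run one of the Frank-based algorithms (3, 4, 5, 6)
#'
#' Algorithm 3: six-category constraints, sampled over rate constants.
#' Algorithm 4: Frank inequality on the Jacobian, report only.
#' Algorithm 5: extreme currents from the extended matrix, the linear
#' Frank inequality `V11 - V12 > 0`, sampled over currents.
#' Algorithm 6: as 5 for multi-pair networks; instability conditions come
#' from the chosen heuristic applied to the reduced matrix `V' = A - B`.
#'
#' @param network a `reaction_network`.
#' @param algorithm integer in 3:6.
#' @param options named option list (see [run_sna()] keys plus
#'   "enantiomeric-pairs" for algorithm 6).
#' @param seed optional integer seed.
#' @return report list; contents depend on the algorithm.
#' @export
run_algorithm <- function(network, algorithm, options = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alg_key <- c("3" = "six-categories", "4" = "frank-ineq-nonlinear",
               "5" = "frank-ineq-linear", "6" = "frank-pseudoquiral")
  opts <- default_sna_options(
    options %||% network$options[[alg_key[[as.character(algorithm)]]]] %||% list())
  if (algorithm == 3L)
    return(run_six_categories(network, n_samples = opts[["num-samples"]]))
  if (algorithm == 4L)
    return(frank_inequality_jacobian(network))

  S <- stoich_matrix(network)
  K <- reaction_order_matrix(network)
  E <- extreme_currents(extend_stoich(S, network$dual_pairs))
  report <- list(network = network$name, E = E)
  if (ncol(E) == 0L) {
    report$verdict <- "network admits no steady-state flux"
    return(report)
  }
  V <- current_matrix(S, E, K)
  report$V <- V
  positivity <- lapply(seq_len(ncol(E)) - 1L, function(c)
    constraint(sp_var(paste0("j", c)), ">"))

  if (algorithm == 5L) {
    report$algorithm <- "frank-ineq-linear"
    fr <- frank_inequality_current(V)
    report$frank_inequality <- fr
    sol <- linear_solve_intervals(c(positivity, list(fr)),
                                  paste0("j", seq_len(ncol(E)) - 1L))
    report$solution <- sol
    base <- positivity
    branch <- list(fr)
    if (!sol$feasible) {
      # The strict system has no interior: fall back to its closure
      # (j >= 0, weak Frank inequality).  Resulting samples sit on the
      # cone boundary -- some velocities are zero, so the corresponding
      # rate constants vanish and those reactions drop out of the model.
      base <- lapply(seq_len(ncol(E)) - 1L, function(c)
        constraint(sp_var(paste0("j", c)), ">="))
      branch <- list(constraint(fr$poly, ">="))
      report$relaxed <- TRUE
      report$verdict_strict <- "Frank inequality strictly infeasible"
    }
    res <- sample_condition_branches(
      branches = list(branch), base = base, network = network,
      E = E, n = opts[["num-samples"]],
      tries = opts[["simplification-tries"]],
      algorithm = "frank-ineq-linear")
    report$samples <- res$samples
    report$false_positives <- res$false_positives
    report$verdict <- if (length(res$samples))
      "symmetry-breaking candidate states sampled"
    else "sampling failed"
    if (!is.null(opts[["samples-folder"]]) && length(res$samples))
      write_samples(res$samples, opts[["samples-folder"]])
    return(report)
  }

  if (algorithm == 6L) {
    report$algorithm <- "frank-pseudoquiral"
    pairs <- opts[["enantiomeric-pairs"]] %||% network$enantiomeric_pairs
    red <- reduce_multi_pair(V, pairs)
    report$reduction <- red
    conds <- instability_conditions(
      red$Vprime, opts[["instability-heuristic"]],
      max_order = opts[["max-mineur-search-stop"]],
      sum_mineurs = isTRUE(opts[["sum-mineurs"]]))
    report$conditions <- conds
    if (conds$stable) {
      report$verdict <- "reduced matrix stable; no SMSB states"
      return(report)
    }
    res <- sample_condition_branches(
      branches = conds$branches, base = positivity, network = network,
      E = E, n = opts[["num-samples"]],
      tries = opts[["simplification-tries"]],
      algorithm = "frank-pseudoquiral")
    report$samples <- res$samples
    report$branch_used <- res$branch
    report$assignments <- res$assignments
    report$interval_solution <- res$solution
    report$false_positives <- res$false_positives
    report$verdict <- if (length(res$samples))
      "symmetry-breaking candidate states sampled"
    else "sampling failed"
    if (!is.null(opts[["samples-folder"]]) && length(res$samples))
      write_samples(res$samples, opts[["samples-folder"]])
    return(report)
  }
  stop("algorithm must be one of 3, 4, 5, 6")
}
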