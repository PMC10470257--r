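# Exact symbolic kinetics under the mass-action law.
#
# Concentrations are named x0..x{n-1} in species order; rate constants
# k0..k{r-1} in reaction order.  When dual-pair rates are merged, every
# member of a rate-equality group uses the symbol of its smallest member.

#' Stoichiometric matrix S
#'
#' `S[s, r] = nu_plus(s, r) - nu_minus(s, r)`.
#'
#' @param network a `reaction_network`.
#' @return integer matrix, species x reactions, with dimnames.
#' @export
stoich_matrix <- function(network) {
  n <- length(network$species); r <- length(network$reactions)
  S <- matrix(0L, n, r, dimnames = list(network$species,
                                        paste0("r", seq_len(r) - 1L)))
  for (j in seq_len(r)) {
    rx <- network$reactions[[j]]
    for (sp in names(rx$reactants))
      S[sp, j] <- S[sp, j] - rx$reactants[[sp]]
    for (sp in names(rx$products))
      S[sp, j] <- S[sp, j] + rx$products[[sp]]
  }
  S
}

#' Reaction order (kinetic) matrix K
#'
#' `K[r, s] = nu_minus(s, r)`, the mass-action kinetic order.
#'
#' @inheritParams stoich_matrix
#' @return nonnegative integer matrix, reactions x species.
#' @export
reaction_order_matrix <- function(network) {
  n <- length(network$species); r <- length(network$reactions)
  K <- matrix(0L, r, n, dimnames = list(paste0("r", seq_len(r) - 1L),
                                        network$species))
  for (j in seq_len(r)) {
    rx <- network$reactions[[j]]
    for (sp in names(rx$reactants))
      K[j, sp] <- rx$reactants[[sp]]
  }
  K
}

conc_symbols <- function(network) paste0("x", seq_along(network$species) - 1L)

rate_symbols <- function(network, merge_duals = FALSE) {
  idx <- if (merge_duals) rate_representatives(network)
         else seq_along(network$reactions) - 1L
  paste0("k", idx)
}

#' Mass-action velocity vector
#'
#' `v_r = k_r * prod_s x_s^{K[r, s]}`.
#'
#' @inheritParams stoich_matrix
#' @param merge_duals substitute the dual-pair representative rate symbol
#'   for every member of a rate-equality group.
#' @return list of `spoly`, one per reaction.
#' @export
velocity_vector <- function(network, merge_duals = FALSE) {
  K <- reaction_order_matrix(network)
  ks <- rate_symbols(network, merge_duals)
  xs <- conc_symbols(network)
  lapply(seq_along(network$reactions), function(j) {
    v <- sp_var(ks[j])
    for (s in seq_along(xs)) {
      if (K[j, s] > 0L) v <- sp_mul(v, sp_var(xs[s], K[j, s]))
    }
    v
  })
}

#' Mass-action ODE right-hand sides, `xdot = S v`
#'
#' @param S stoichiometric matrix.
#' @param v velocity vector (list of `spoly`).
#' @return list of `spoly`, one per species, expanded.
#' @export
ode_system <- function(S, v) {
  stopifnot(ncol(S) == length(v))
  lapply(seq_len(nrow(S)), function(s) {
    acc <- sp_zero()
    for (j in seq_len(ncol(S)))
      if (S[s, j] != 0L) acc <- sp_add(acc, sp_scale(v[[j]], S[s, j]))
    acc
  })
}

#' ODE system of a network
#' @inheritParams velocity_vector
#' @return list of `spoly`.
#' @export
network_odes <- function(network, merge_duals = FALSE) {
  ode_system(stoich_matrix(network), velocity_vector(network, merge_duals))
}

#' Symbolic Jacobian of an ODE system
#'
#' @param odes list of `spoly` right-hand sides.
#' @param n_species number of species (concentration symbols x0..).
#' @return list-matrix (`spm`) of exact partial derivatives.
#' @export
jacobian_matrix <- function(odes, n_species = length(odes)) {
  J <- spm(length(odes), n_species)
  xs <- paste0("x", seq_len(n_species) - 1L)
  for (i in seq_along(odes)) for (j in seq_len(n_species))
    J[[i, j]] <- sp_deriv(odes[[i]], xs[j])
  J
}

#' Numeric mass-action right-hand-side factory
#'
#' @param network a `reaction_network`.
#' @param k numeric rate-constant vector, one per reaction.
#' @return `function(x)` returning dx/dt for a concentration vector.
#' @export
mass_action_rhs <- function(network, k) {
  S <- stoich_matrix(network)
  K <- reaction_order_matrix(network)
  stopifnot(length(k) == ncol(S))
  function(x) {
    v <- k * apply(K, 1L, function(ord) prod(x^ord))
    as.numeric(S %*% v)
  }
}
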