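# Algorithms 3-6: six categories, Frank inequality, multi-pair reduction.

test_that("KN reactions classify into the published categories", {
  net <- kn_network()
  cls <- classify_six_categories(net)
  expect_true(cls$ok)
  got <- lapply(cls$labels, function(l) l$category)
  names(got) <- vapply(cls$labels, function(l)
    paste(l$reactions, collapse = ","), character(1))
  expect_equal(got[["0,1"]], "R1")
  expect_equal(got[["2,3"]], "R2")
  expect_equal(got[["4,5"]], "R3")
  expect_equal(got[["6,7"]], "R4")
  expect_equal(got[["8"]], "R6")
  expect_false(any(vapply(cls$labels, function(l)
    l$category == "R5", logical(1))))
})

test_that("inhibition and LES templates match single reactions", {
  r6 <- parse_reaction("L + D -> P")
  expect_equal(chiralstab:::classify_reaction_category(r6, "L", "D"), "R6")
  r5 <- parse_reaction("A + L -> L + D")
  expect_equal(chiralstab:::classify_reaction_category(r5, "L", "D"), "R5")
  ach <- parse_reaction("A -> B")
  expect_equal(chiralstab:::classify_reaction_category(ach, "L", "D"),
               "achiral")
  bad <- parse_reaction("L + L -> D")
  expect_true(is.na(chiralstab:::classify_reaction_category(bad, "L", "D")))
})

test_that("unclassifiable reaction yields a structured failure", {
  rx <- c(list(list(reactants = c(L = 2L), products = c(D = 1L)),
               list(reactants = c(D = 2L), products = c(L = 1L))))
  net <- reaction_network("bad", c("L", "D"), rx)
  cls <- classify_six_categories(net)
  expect_false(cls$ok)
  expect_equal(cls$failed_reaction, 0L)
  expect_match(cls$message, "impossible")
})

test_that("classification is invariant under L/D relabeling", {
  net <- kn_network()
  swapped <- lapply(net$reactions, function(r) {
    map <- c(L = "D", D = "L")
    names(r$reactants) <- unname(map[names(r$reactants)])
    names(r$products) <- unname(map[names(r$products)])
    r
  })
  net2 <- reaction_network("KN-swapped", c("D", "L"), swapped)
  cls1 <- classify_six_categories(net)
  cls2 <- classify_six_categories(net2)
  expect_equal(vapply(cls1$labels, `[[`, character(1), "category"),
               vapply(cls2$labels, `[[`, character(1), "category"))
})

test_that("six-category constraints reproduce the published KN system", {
  net <- kn_network()
  cons <- six_category_constraints(net)
  expect_true(sp_equal(
    cons$balance$poly,
    sp_neg(kvar(0)) + kvar(2) - kvar(4) + kvar(6) + kvar(8)))
  expect_true(sp_equal(cons$frank$poly,
                       sp_neg(kvar(2)) + kvar(4) - sp_scale(kvar(6), 2)))
  # J11 + J12 < 0  <=>  k2 - k4 + 2 k6 + 2 k8 > 0
  expect_true(sp_equal(
    cons$antifrank$poly,
    kvar(2) - kvar(4) + sp_scale(kvar(6), 2) + sp_scale(kvar(8), 2)))
  expect_equal(cons$rate_order, c("k2", "k4", "k6", "k8"))
})

test_that("KN six-category intervals match the published table", {
  net <- kn_network()
  cons <- six_category_constraints(net)
  sol <- linear_solve_intervals(
    c(cons$positivity, list(cons$balance, cons$frank, cons$antifrank)),
    cons$rate_order)
  expect_true(sol$feasible)
  # k0 = k2 - k4 + k6 + k8 by back-substitution of the balance
  expect_true(sp_equal(sol$equalities[["k0"]],
                       kvar(2) - kvar(4) + kvar(6) + kvar(8)))
  fmt <- function(v, side) vapply(sol$bounds[[v]][[side]], format,
                                  character(1))
  expect_true("k2" %in% fmt("k4", "lower"))        # k4 in (k2, inf)
  expect_length(sol$bounds[["k4"]]$upper, 0L)
  expect_true("-1/2*k2 + 1/2*k4" %in% fmt("k6", "upper"))
  expect_length(sol$bounds[["k2"]]$upper, 0L)
  expect_setequal(setdiff(fmt("k8", "lower"), "0"),
                  c("-k2 + k4 - k6", "-1/2*k2 + 1/2*k4 - k6"))
  expect_length(sol$bounds[["k8"]]$upper, 0L)
})

test_that("removing autocatalysis makes the Frank system infeasible", {
  # KN without the autocatalytic pair: synthesis, decay, so-decomposition,
  # inhibition only
  rx <- kn_network()$reactions[-c(5, 6)]
  net <- reaction_network("KN-noR3", c("L", "D"), rx)
  cons <- six_category_constraints(net)
  sol <- linear_solve_intervals(
    c(cons$positivity, list(cons$balance, cons$frank, cons$antifrank)),
    cons$rate_order)
  expect_false(sol$feasible)
})

test_that("algorithm 4 reports the published nonlinear system", {
  net <- kn_network()
  r4 <- frank_inequality_jacobian(net)
  expect_false(r4$sampleable)
  expect_true(sp_equal(
    r4$steady_state,
    kvar(0) - kvar(2) * xvar(0) + kvar(4) * xvar(0) - kvar(6) * xvar(0)^2L -
      kvar(8) * xvar(0)^2L))
  expect_true(sp_equal(
    r4$frank_inequality$poly,
    sp_neg(kvar(2)) + kvar(4) - sp_scale(kvar(6) * xvar(0), 2)))
  J11s <- sp_neg(kvar(2)) + kvar(4) - sp_scale(kvar(6) * xvar(0), 2) -
    kvar(8) * xvar(0)
  expect_true(sp_equal(r4$det_nonzero,
                       J11s * J11s - kvar(8)^2L * xvar(0)^2L))
})

test_that("Frank inequality on the published extended KN current matrix", {
  net <- kn_network()
  V <- current_matrix(stoich_matrix(net), kn_printed_E_ext(),
                      reaction_order_matrix(net))
  fr <- frank_inequality_current(V)
  expect_true(sp_equal(fr$poly,
                       sp_neg(jvar(0)) - sp_scale(jvar(2), 2) - jvar(3) +
                         jvar(5)))
  # symmetric V with V01 = V00: inequality degenerates to 0 > 0
  W <- spm(2, 2)
  W[[1, 1]] <- jvar(0); W[[1, 2]] <- jvar(0)
  expect_true(sp_is_zero(frank_inequality_current(W)$poly))
})

test_that("multi-pair reduction of the replicator gives the published V'", {
  net <- load_fixture("Replicator-Hochberg-Ribo")
  S <- stoich_matrix(net)
  E <- extreme_currents(extend_stoich(S, net$dual_pairs))
  expect_equal(ncol(E), 2L)
  V <- current_matrix(S, E, reaction_order_matrix(net))
  red <- reduce_multi_pair(V, net$enantiomeric_pairs)
  expect_true(sp_equal(red$Vprime[[1, 1]], sp_neg(jvar(0))))
  expect_true(sp_equal(red$Vprime[[1, 2]], jvar(1)))
  expect_true(sp_equal(red$Vprime[[2, 1]], jvar(1)))
  expect_true(sp_equal(red$Vprime[[2, 2]], sp_neg(jvar(0))))
  expect_true(all(vapply(red$B, sp_is_zero, logical(1))))
  # characteristic polynomial degree collapses from 5 to 2
  expect_equal(sp_degree_in(spm_charpoly(V), "lambda"), 5)
  expect_equal(sp_degree_in(spm_charpoly(red$Vprime), "lambda"), 2)
  pl <- symbolic_plane(red$Vprime)
  expect_true(sp_equal(pl$trace, sp_scale(jvar(0), -2)))
  expect_true(sp_equal(pl$determinant, jvar(0)^2L - jvar(1)^2L))
  expect_true(sp_equal(pl$discriminant, sp_scale(jvar(1)^2L, 4)))
})

test_that("block-symmetry violation is detected and named", {
  V <- spm(2, 2)
  V[[1, 1]] <- jvar(0); V[[2, 2]] <- jvar(1)   # asymmetric diagonals
  expect_error(reduce_multi_pair(V, list(c(0L, 1L))), "block symmetry")
})

test_that("one-pair reduction agrees with the Frank inequality path", {
  net <- kn_network()
  V <- current_matrix(stoich_matrix(net), kn_printed_E_ext(),
                      reaction_order_matrix(net))
  red <- reduce_multi_pair(V, net$enantiomeric_pairs)
  expect_equal(dim(red$Vprime), c(1L, 1L))
  expect_true(sp_equal(red$Vprime[[1, 1]], frank_inequality_current(V)$poly))
  # 1x1 mineurs condition is exactly V'[0,0] > 0
  conds <- instability_conditions(red$Vprime, "mineurs")
  expect_length(conds$branches, 1L)
  expect_true(sp_equal(conds$branches[[1]][[1]]$poly, red$Vprime[[1, 1]]))
})

test_that("block symmetry holds on every multi-pair fixture", {
  for (fx in c("Replicator-Hochberg-Ribo", "Calvin-2-CSTR-LES",
               "Blackmond-Rev-2020")) {
    net <- load_fixture(fx)
    S <- stoich_matrix(net)
    E <- extreme_currents(extend_stoich(S, net$dual_pairs))
    V <- current_matrix(S, E, reaction_order_matrix(net))
    expect_no_error(reduce_multi_pair(V, net$enantiomeric_pairs))
  }
})

test_that("algorithm 6 on the replicator yields the published restrictions", {
  net <- load_fixture("Replicator-Hochberg-Ribo")
  S <- stoich_matrix(net)
  E <- extreme_currents(extend_stoich(S, net$dual_pairs))
  V <- current_matrix(S, E, reaction_order_matrix(net))
  red <- reduce_multi_pair(V, net$enantiomeric_pairs)
  conds <- instability_conditions(red$Vprime, "trace-determinant")
  # first branch: det < 0, canonically -j0^2 + j1^2 > 0
  expect_true(sp_equal(conds$branches[[1]][[1]]$poly,
                       sp_neg(jvar(0)^2L) + jvar(1)^2L))
  # second branch (det > 0 and trace > 0) is infeasible with j0 > 0
  sol <- linear_solve_intervals(
    list(constraint(jvar(0), ">"), constraint(sp_scale(jvar(0), -2), ">")),
    c("j0"))
  expect_false(sol$feasible)
})

test_that("algorithm 5 on KN samples unstable frank states", {
  set.seed(55)
  net <- kn_network()
  r5 <- run_algorithm(net, 5, list("num-samples" = 4L))
  expect_equal(ncol(r5$E), 6L)
  expect_match(r5$verdict, "sampled")
  expect_length(r5$samples, 4L)
  for (s in r5$samples) {
    expect_true(s$flags$unstable)
    expect_true(s$flags$frank)
  }
  expect_equal(r5$false_positives, 0L)
})
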