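# Algorithm 2: extreme currents, current matrix, instability heuristics.

test_that("extended stoichiometric matrix gains one row per dual pair", {
  net <- kn_network()
  S <- stoich_matrix(net)
  Se <- extend_stoich(S, net$dual_pairs)
  expect_equal(dim(Se), c(6L, 9L))
  expect_equal(unname(Se[3, ]), c(1, -1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(Se[6, ]), c(0, 0, 0, 0, 0, 0, 1, -1, 0))
  expect_identical(extend_stoich(S, list()), S)
  # replicator fixture: 5 species + one row per normalized pair
  rep <- load_fixture("Replicator-Hochberg-Ribo")
  Sr <- extend_stoich(stoich_matrix(rep), rep$dual_pairs)
  expect_equal(nrow(Sr), 5L + length(rep$dual_pairs))
})

test_that("KN plain extreme currents equal the published 12-ray set", {
  E <- extreme_currents(stoich_matrix(kn_network()))
  expect_equal(ncol(E), 12L)
  expect_true(same_column_set(unname(E), kn_printed_E_plain()))
})

test_that("KN extended extreme currents equal the published 6-ray set", {
  net <- kn_network()
  Se <- extend_stoich(stoich_matrix(net), net$dual_pairs)
  E <- extreme_currents(Se)
  expect_equal(ncol(E), 6L)
  expect_true(same_column_set(unname(E), kn_printed_E_ext()))
  # published diag(E j) row sums under the published column order
  d <- chiralstab:::current_diagonal(kn_printed_E_ext())
  expect_true(sp_equal(d[[1]], sum_j(c(0, 2, 4))))
  expect_true(sp_equal(d[[3]], sum_j(c(0, 1))))
  expect_true(sp_equal(d[[5]], sum_j(c(1, 3, 5))))
  expect_true(sp_equal(d[[7]], sum_j(c(2, 3))))
  expect_true(sp_equal(d[[9]], sum_j(c(4, 5))))
})

test_that("single reversible exchange gives the single ray (1, 1)", {
  S <- matrix(c(-1L, 1L), 1, 2)
  E <- extreme_currents(S)
  expect_equal(unname(E), matrix(c(1L, 1L), 2, 1))
})

test_that("irreversible sink network admits no steady-state flux", {
  # Ls + L -> LL etc. only consumes; cone = {0}
  E <- extreme_currents(stoich_matrix(load_fixture("APED-dimerization")))
  expect_equal(ncol(E), 0L)
})

test_that("double description agrees with the brute-force oracle", {
  nets <- list(
    plainKN = stoich_matrix(kn_network()),
    extKN = extend_stoich(stoich_matrix(kn_network()),
                          kn_network()$dual_pairs))
  frp <- load_fixture("Frank-Rev-P")
  nets$plainFRP <- stoich_matrix(frp)
  nets$extFRP <- extend_stoich(stoich_matrix(frp), frp$dual_pairs)
  les <- load_fixture("Blanco-et-al-LES-2013")
  nets$extLES <- extend_stoich(stoich_matrix(les), les$dual_pairs)
  rep <- load_fixture("Replicator-Hochberg-Ribo")
  nets$extREP <- extend_stoich(stoich_matrix(rep), rep$dual_pairs)
  bs8 <- load_fixture("Blackmond-Scheme8")
  nets$extBS8 <- extend_stoich(stoich_matrix(bs8), bs8$dual_pairs)
  for (nm in names(nets)) {
    S <- nets[[nm]]
    E <- extreme_currents(S)
    O <- oracle_extreme_rays(S)
    expect_true(same_column_set(unname(E), unname(O)), info = nm)
  }
})

test_that("S_used E = 0 exactly for every fixture", {
  for (fx in list_fixtures()) {
    net <- load_fixture(fx)
    S <- stoich_matrix(net)
    Se <- extend_stoich(S, net$dual_pairs)
    E <- extreme_currents(Se)
    if (ncol(E)) expect_true(all(Se %*% E == 0L), info = fx)
    Ep <- extreme_currents(S)
    if (ncol(Ep)) expect_true(all(S %*% Ep == 0L), info = fx)
  }
})

test_that("extended rays satisfy the plain kernel and dual-pair equalities", {
  net <- kn_network()
  S <- stoich_matrix(net)
  E <- extreme_currents(extend_stoich(S, net$dual_pairs))
  expect_true(all(S %*% E == 0L))
  for (p in net$dual_pairs)
    expect_equal(E[p[1] + 1L, ], E[p[2] + 1L, ])
})

test_that("current matrices reproduce the published V(J) entry-for-entry", {
  net <- kn_network()
  S <- stoich_matrix(net); K <- reaction_order_matrix(net)
  # extended, under the published column order
  V <- current_matrix(S, kn_printed_E_ext(), K)
  e11 <- sp_neg(sum_j(c(0, 2, 3, 4), c(1, 2, 1, 1)))
  e12 <- sp_neg(sum_j(c(4, 5)))
  expect_true(sp_equal(V[[1, 1]], e11))
  expect_true(sp_equal(V[[1, 2]], e12))
  expect_true(sp_equal(V[[2, 1]], e12))
  expect_true(sp_equal(V[[2, 2]], e11))
  # plain, under the published column order
  Vp <- current_matrix(S, kn_printed_E_plain(), K)
  expect_true(sp_equal(Vp[[1, 1]],
                       sp_neg(sum_j(c(0, 10, 4, 5, 8), c(1, 1, 2, 1, 1)))))
  expect_true(sp_equal(Vp[[1, 2]], sp_neg(sum_j(c(10, 11, 8, 9)))))
  expect_true(sp_equal(Vp[[2, 1]], sp_neg(sum_j(c(10, 11, 8, 9)))))
  expect_true(sp_equal(Vp[[2, 2]],
                       sp_neg(sum_j(c(1, 6, 7, 8, 9), c(1, 2, 1, 1, 1)))))
  expect_error(current_matrix(S, kn_printed_E_ext()[1:5, ], K),
               "dimension mismatch")
  # zero E -> zero matrix
  V0 <- current_matrix(S, matrix(0L, 9, 2), K)
  expect_true(all(vapply(V0, sp_is_zero, logical(1))))
})

test_that("dual-pair equalities match the published restrictions", {
  net <- kn_network()
  eqs <- dual_pair_equalities(kn_printed_E_plain(), net$dual_pairs)
  expect_length(eqs, 4L)
  expect_true(sp_equal(eqs[[1]]$poly,
                       sum_j(c(0, 10, 4, 8)) - sum_j(c(1, 6, 8, 9))))
  expect_true(sp_equal(eqs[[2]]$poly, sum_j(c(0, 2)) - sum_j(c(1, 3))))
  expect_true(sp_equal(eqs[[3]]$poly,
                       sum_j(c(11, 2, 5, 9)) - sum_j(c(10, 11, 3, 7))))
  expect_true(sp_equal(eqs[[4]]$poly, sum_j(c(4, 5)) - sum_j(c(6, 7))))
  # extended E: rows of each pair identical -> all equalities drop
  expect_length(dual_pair_equalities(kn_printed_E_ext(), net$dual_pairs), 0L)
  expect_length(dual_pair_equalities(kn_printed_E_plain(), list()), 0L)
})

test_that("mineurs condition equals minus the published determinant", {
  net <- kn_network()
  S <- stoich_matrix(net); K <- reaction_order_matrix(net)
  V <- current_matrix(S, kn_printed_E_plain(), K)
  conds <- instability_conditions(V, "mineurs")
  expect_false(conds$stable)
  expect_length(conds$branches, 1L)        # only the order-2 coefficient
  poly <- conds$branches[[1]][[1]]$poly
  expect_true(sp_equal(poly, sp_neg(spm_det(V))))
  # the published quadratic, typed in literally
  terms <- list(
    c(-1, 0, 1), c(-2, 0, 6), c(-1, 0, 7), c(-1, 0, 8), c(-1, 0, 9),
    c(-1, 1, 10), c(-2, 1, 4), c(-1, 1, 5), c(-1, 1, 8),
    c(1, 10, 10), c(2, 10, 11), c(-2, 10, 6), c(-1, 10, 7),
    c(1, 10, 8), c(1, 10, 9), c(1, 11, 11), c(2, 11, 8), c(2, 11, 9),
    c(-4, 4, 6), c(-2, 4, 7), c(-2, 4, 8), c(-2, 4, 9),
    c(-2, 5, 6), c(-1, 5, 7), c(-1, 5, 8), c(-1, 5, 9),
    c(-2, 6, 8), c(-1, 7, 8), c(1, 8, 9), c(1, 9, 9))
  published <- sp_zero()
  for (t in terms)
    published <- published + sp_scale(jvar(t[2]) * jvar(t[3]), t[1])
  expect_true(sp_equal(poly, published))
})

test_that("all-negative-diagonal matrix is declared stable", {
  V <- spm(3, 3)
  for (i in 1:3) V[[i, i]] <- sp_neg(jvar(0))
  conds <- instability_conditions(V, "mineurs")
  expect_true(conds$stable)
  expect_length(conds$branches, 0L)
})

test_that("heuristic dispatch honors options and preconditions", {
  V <- spm(3, 3)
  for (i in 1:3) V[[i, i]] <- sp_neg(jvar(i - 1))
  expect_error(instability_conditions(V, "trace-determinant"), "2x2")
  expect_error(instability_conditions(V, "frobnicate"), "unknown")
  ch <- instability_conditions(V, "characteristic-polynomial")
  expect_length(ch$branches, 1L)
  expect_length(ch$branches[[1]], 2L)      # char < 0 plus lambda > 0
  expect_true(sp_equal(ch$branches[[1]][[2]]$poly, sp_var("lambda")))
  # individual minors mode emits one branch per negative-monomial minor
  W <- spm(2, 2)
  W[[1, 1]] <- jvar(0); W[[1, 2]] <- jvar(1)
  W[[2, 1]] <- jvar(1); W[[2, 2]] <- sp_neg(jvar(0))
  both <- instability_conditions(W, "mineurs", sum_mineurs = FALSE)
  summed <- instability_conditions(W, "mineurs", sum_mineurs = TRUE)
  expect_gte(length(both$branches), length(summed$branches))
})

test_that("run_sna pipelines: sampled KN, stable toy network", {
  set.seed(1001)
  net <- kn_network()
  rep6 <- run_sna(net, list("dual-pairs-in-ec" = TRUE, "num-samples" = 3L))
  expect_equal(ncol(rep6$E), 6L)
  expect_match(rep6$verdict, "sampled")
  for (s in rep6$samples) {
    expect_true(s$flags$unstable || rep6$false_positives > 0L)
    expect_equal(s$rate_constants[["k0"]], s$rate_constants[["k1"]])
  }
  rep12 <- run_sna(net, list("dual-pairs-in-ec" = FALSE, "num-samples" = 2L))
  expect_equal(ncol(rep12$E), 12L)
  # reversible exchange with in/outflow is stable: all char coefficients
  # positive
  rx <- expand_reversibles(lapply(
    c(" <-> L", " <-> D", "L <-> D"), parse_reaction))
  toy <- reaction_network("toy", c("L", "D"), rx)
  rtoy <- run_sna(toy, list("num-samples" = 2L))
  expect_match(rtoy$verdict, "stable|no unstable")
})
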