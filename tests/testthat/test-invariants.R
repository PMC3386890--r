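test_that("the invariant CSP carries one equation per transition plus non-triviality", {
  enz <- enzymatic_net()
  st <- build_invariant_csp(enz, "eq", 8)
  types <- vapply(st$posted, `[[`, "", "type")
  expect_equal(sum(types == "linear"), 3)
  expect_equal(sum(types == "sum_positive"), 1)
  # a net with no transitions leaves every unit vector a solution
  lone <- reaction_net(c("X", "Y"), character())
  sols <- fd_all_solutions(build_invariant_csp(lone, "eq", 1))
  expect_same_vectors(sols, list(c(X = 0L, Y = 1L), c(X = 1L, Y = 0L),
                                 c(X = 1L, Y = 1L)))
})

test_that("the enzymatic mechanism has exactly its two conserved moieties", {
  basis <- minimal_invariants(enzymatic_net())
  expect_same_vectors(basis$vectors,
                      list(c(E = 1L, AE = 1L), c(A = 1L, AE = 1L, B = 1L)))
  expect_true(basis$complete)
})

test_that("relaxed relations find monotone pools, including {B} for the enzyme", {
  enz <- enzymatic_net()
  le <- minimal_invariants(enz, relation = "le")
  expect_true(inv_key(c(B = 1L)) %in% vapply(le$vectors, inv_key, ""))
  expect_same_vectors(le$vectors, brute_invariants(enz, "le", 2))
  ge <- minimal_invariants(enz, relation = "ge")
  expect_same_vectors(ge$vectors, brute_invariants(enz, "ge", 2))
  # every reported vector satisfies its relation definitionally
  for (v in le$vectors) expect_true(invariant_holds(enz, v, "le"))
  for (v in ge$vectors) expect_true(invariant_holds(enz, v, "ge"))
})

test_that("the complete bound is the product of per-transition lcms", {
  expect_equal(complete_bound(enzymatic_net()), 1)
  expect_equal(complete_bound(parse_reactions("A + B => 4*C")), 4)
  expect_equal(complete_bound(parse_reactions("A + B => 4*C\n2*C => 3*D")), 24)
  expect_equal(complete_bound(parse_reactions("")), 1)
  cc <- minimal_invariants(parse_reactions("A + B => 4*C"), bound = 2)
  expect_false(cc$complete)   # 2 < 4
})

test_that("gcd normalization is defensive: solver output is already normal", {
  expect_equal(normalize_invariant(c(A = 2L, B = 4L)), c(A = 1L, B = 2L))
  expect_equal(normalize_invariant(c(A = 1L)), c(A = 1L))
  expect_error(normalize_invariant(c(A = 0L)), "zero")
  for (seed in 1:25) {
    net <- random_net(sample(2:5, 1), sample(1:4, 1), 3, 0.5, seed)
    basis <- minimal_invariants(net, bound = 4, symmetry = FALSE)
    for (v in basis$vectors) {
      expect_equal(normalize_invariant(v), v)
      expect_true(invariant_holds(net, v, "eq"))
    }
  }
})

test_that("basis supports are pairwise incomparable and output order is reproducible", {
  for (seed in 1:20) {
    net <- random_net(5, 4, 3, 0.5, seed)
    for (rel in c("eq", "le", "ge")) {
      b1 <- minimal_invariants(net, relation = rel, bound = 4)
      b2 <- minimal_invariants(net, relation = rel, bound = 4)
      expect_identical(b1$vectors, b2$vectors)
      supp <- lapply(b1$vectors, names)
      for (i in seq_along(supp)) for (j in seq_along(supp)) {
        if (i == j) next
        expect_false(all(supp[[i]] %in% supp[[j]]))
      }
    }
  }
})

test_that("T-invariants are P-invariants of the transposed net", {
  fixtures <- list(enzymatic_net(), classic_net(2, 3), philosophers_net(2),
                   circular_trains_net(2, 3),
                   random_net(4, 4, 2, 0.6, 7), random_net(5, 3, 3, 0.5, 8))
  for (net in fixtures) {
    bt <- minimal_invariants(net, mode = "T", bound = 4)
    bp <- minimal_invariants(transpose_net(net), mode = "P", bound = 4)
    expect_identical(bt$vectors, bp$vectors)
  }
  # the enzymatic net's only flux cycle is the reversible pair
  bt <- minimal_invariants(enzymatic_net(), mode = "T")
  expect_same_vectors(bt$vectors, list(c(t1 = 1L, t1_rev = 1L)))
})

test_that("conservation reports rank the laws and count free ODE variables", {
  enz <- enzymatic_net()
  rep <- conservation_report(enz, minimal_invariants(enz))
  expect_equal(rep$n_laws, 2)
  expect_equal(rep$rank, 2)
  expect_equal(rep$free_variables, 2)
  expect_true(any(grepl("\\[E\\] \\+ \\[AE\\] = constant", rep$laws)))

  ab <- parse_reactions("A => B")
  expect_equal(conservation_report(ab, minimal_invariants(ab))$free_variables, 1)
  # no laws at all
  nb <- minimal_invariants(parse_reactions("A => 2*A"))
  r0 <- conservation_report(parse_reactions("A => 2*A"), nb)
  expect_equal(r0$n_laws, 0)
  expect_equal(r0$free_variables, 1)
  expect_error(conservation_report(enz, minimal_invariants(enz, relation = "le")),
               "relation")
})

test_that("an isolated place yields its own trivial unit conservation law", {
  net <- parse_reactions("#!places A B LONER\nA => B")
  basis <- minimal_invariants(net)
  expect_true(inv_key(c(LONER = 1L)) %in% vapply(basis$vectors, inv_key, ""))
})

test_that("weighted token sums behave as the invariant relation predicts under firing", {
  set.seed(2024)
  nets <- c(list(enzymatic_net(), philosophers_net(2)),
            lapply(1:8, function(s) random_net(4, 3, 2, 0.6, s)))
  for (net in nets) {
    eqb <- minimal_invariants(net, bound = 4)
    leb <- minimal_invariants(net, relation = "le", bound = 4)
    geb <- minimal_invariants(net, relation = "ge", bound = 4)
    for (rep in 1:10) {
      m0 <- stats::setNames(sample(0:3, n_places(net), replace = TRUE), net$places)
      traj <- simulate_firings(net, m0, steps = 50)
      for (v in eqb$vectors) {
        vals <- as.numeric(traj[, names(v), drop = FALSE] %*% v)
        expect_true(all(vals == vals[1]))
      }
      for (v in leb$vectors) {
        vals <- as.numeric(traj[, names(v), drop = FALSE] %*% v)
        expect_true(all(diff(vals) >= 0))
      }
      for (v in geb$vectors) {
        vals <- as.numeric(traj[, names(v), drop = FALSE] %*% v)
        expect_true(all(diff(vals) <= 0))
      }
    }
  }
})
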