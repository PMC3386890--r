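test_that("parallel-place detection finds classic pairs and nothing in the enzyme net", {
  g <- detect_groups(classic_net(2, 4))
  expect_length(g, 4)
  for (grp in g) {
    expect_length(grp$members, 2)
    expect_true(all(grp$coefficients == 1))
  }
  expect_length(detect_groups(enzymatic_net()), 0)
  # A and B feeding only A + B => 4*C are one group with unit coefficients
  g2 <- detect_groups(parse_reactions("A + B => 4*C"))
  expect_length(g2, 1)
  expect_equal(g2[[1]]$members, c("A", "B"))
  expect_equal(unname(g2[[1]]$coefficients), c(1L, 1L))
  # isolated places are never grouped
  iso <- parse_reactions("#!places A B L1 L2\nA => B")
  expect_length(detect_groups(iso), 0)
})

test_that("proportional detection groups scaled columns but merging refuses them", {
  net <- parse_reactions("3*A + 2*B => C")   # columns 3e and 2e: proportional
  expect_length(detect_groups(net), 0)
  gp <- detect_groups(net, proportional = TRUE)
  expect_length(gp, 1)
  expect_equal(sort(unname(gp[[1]]$coefficients)), c(2L, 3L))
  expect_equal(gp[[1]]$scale, 1L)
  expect_error(merge_net(net, gp), "not parallel")
})

test_that("merging collapses groups to representatives with the shared column", {
  big <- classic_net(10, 10)
  mapping <- merge_net(big, detect_groups(big))
  expect_equal(n_places(mapping$reduced_net), 10)
  expect_equal(n_transitions(mapping$reduced_net), 10)

  # no groups: the identity mapping
  id <- merge_net(enzymatic_net(), list())
  expect_identical(id$reduced_net, enzymatic_net())

  # Example net A + B => 4*C reduces to a single representative
  ab <- parse_reactions("A + B => 4*C")
  m <- merge_net(ab, detect_groups(ab))
  red <- m$reduced_net
  expect_equal(n_places(red), 2)
  expect_equal(red$post$t1, c(C = 4L))
  redb <- minimal_invariants(red, symmetry = FALSE)
  # single reduced solution: the representative takes the whole sum, D = 4
  expect_length(redb$vectors, 1)
  expect_equal(redb$vectors[[1]][[m$groups[[1]]$merged_id]], 4L)
})

test_that("paper-mode expansion reproduces the ordered compositions of 4", {
  ab <- parse_reactions("A + B => 4*C")
  m <- merge_net(ab, detect_groups(ab))
  red <- minimal_invariants(m$reduced_net, symmetry = FALSE)
  ex <- expand_basis(red$vectors, m, mode = "paper", member_bound = 8)
  keys <- vapply(ex, function(v) {
    a <- if ("A" %in% names(v)) v[["A"]] else 0L
    b <- if ("B" %in% names(v)) v[["B"]] else 0L
    paste(a, b)
  }, "")
  expect_setequal(keys, c("0 4", "1 3", "2 2"))
  # strict mode keeps only the two singleton supports
  st <- expand_basis(red$vectors, m, mode = "strict", member_bound = 8)
  expect_same_vectors(st, list(c(A = 4L, C = 1L), c(B = 4L, C = 1L)))
})

test_that("a merged value of 1 expands to unit choices (strict) or one representative (paper)", {
  net <- classic_net(3, 2)
  m <- merge_net(net, detect_groups(net))
  red <- minimal_invariants(m$reduced_net, symmetry = FALSE)
  # strict: every member choice, 3 per segment over 2 segments
  expect_length(expand_basis(red$vectors, m, mode = "strict", member_bound = 8), 9)
  # paper: one non-decreasing representative per group
  expect_length(expand_basis(red$vectors, m, mode = "paper", member_bound = 8), 1)
})

test_that("strict expansion of the reduced basis equals the direct basis", {
  for (seed in 1:60) {
    net <- random_parallel_net(seed)
    direct <- minimal_invariants(net, bound = 4, symmetry = FALSE)
    via_sym <- minimal_invariants(net, bound = 4, symmetry = TRUE)
    expect_same_vectors(via_sym$vectors, direct$vectors)
  }
  for (x in 1:3) for (y in 2:3) {
    net <- classic_net(x, y)
    expect_same_vectors(minimal_invariants(net)$vectors,
                        minimal_invariants(net, symmetry = FALSE)$vectors)
  }
})

test_that("merging never changes satisfiability", {
  for (seed in 1:25) {
    net <- random_parallel_net(seed)
    mapping <- merge_net(net, detect_groups(net))
    for (rel in c("eq", "le", "ge")) {
      a <- fd_next_solution(build_invariant_csp(net, rel, 4))
      b <- fd_next_solution(build_invariant_csp(mapping$reduced_net, rel,
                                                4 * n_places(net)))
      expect_equal(is.null(a), is.null(b))
    }
  }
})

test_that("the combinatorial expanded count matches actual strict enumeration", {
  for (seed in 1:40) {
    net <- random_parallel_net(seed)
    cc <- minimal_invariants(net, bound = 4, compressed = TRUE)
    full <- minimal_invariants(net, bound = 4, symmetry = FALSE)
    expect_equal(as.numeric(cc$count_expanded), length(full$vectors))
  }
  # no groups: the count is simply the basis size
  enz <- minimal_invariants(enzymatic_net())
  expect_equal(enz$count_expanded, "2")
})

test_that("the classic 10-10 ring is counted, not enumerated", {
  cc <- minimal_invariants(classic_net(10, 10), compressed = TRUE)
  expect_equal(cc$count_expanded, "10000000000")   # 10^10
  expect_length(cc$vectors, 1)
  expect_equal(n_places(cc$reduced_net), 10)
  expect_length(cc$groups, 10)
})

test_that("exact decimal arithmetic survives past double precision", {
  x <- "1"
  for (i in 1:30) x <- petrinv:::big_mul(x, "10")
  expect_equal(x, paste0("1", strrep("0", 30)))
  expect_equal(petrinv:::big_add("999999999999999999", "1"), "1000000000000000000")
  expect_equal(petrinv:::big_mul("123456789", "987654321"), "121932631112635269")
})
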