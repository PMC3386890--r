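test_that("the reaction dialect parses species, coefficients and arrows", {
  net <- parse_reactions("A + E => AE\nAE => A + E\nAE => B + E")
  expect_equal(net$places, c("A", "E", "AE", "B"))
  expect_length(net$transitions, 3)
  expect_equal(net$pre$t1, c(A = 1L, E = 1L))
  expect_equal(net$post$t1, c(AE = 1L))

  # reversible arrow splits into forward + backward transitions
  rev <- parse_reactions("bind: A + E <=> AE")
  expect_equal(rev$transitions, c("bind", "bind_rev"))
  expect_equal(rev$pre$bind_rev, rev$post$bind)
  expect_equal(rev$post$bind_rev, rev$pre$bind)

  # explicit coefficients, comments, blank lines, labels
  net2 <- parse_reactions("# a comment\n\nmk: A + B => 4*C  # trailing")
  expect_equal(net2$post$mk, c(C = 4L))
  expect_equal(net2$pre$mk, c(A = 1L, B = 1L))

  # source/sink reactions are legal; fully empty reactions are not
  src <- parse_reactions("=> A\nA =>")
  expect_equal(src$pre$t1, stats::setNames(integer(0), character(0)))
  expect_equal(src$post$t2, stats::setNames(integer(0), character(0)))
  expect_error(parse_reactions("=>"), "both sides")

  # empty input gives the empty net
  empty <- parse_reactions("")
  expect_equal(n_places(empty), 0)
  expect_equal(n_transitions(empty), 0)
})

test_that("parser rejects malformed input with a line number", {
  expect_error(parse_reactions("A => B\nA + => B"), "line 2")
  expect_error(parse_reactions("0*A => B"), "zero coefficient|not a positive")
  expect_error(parse_reactions("A -> B"), "line 1")
  expect_error(parse_reactions("x*A => B"), "not a positive integer")
})

test_that("incidence matrix is post minus pre", {
  enz <- enzymatic_net()
  I <- incidence(enz)
  expect_equal(I[1, ], c(A = -1, E = -1, AE = 1, B = 0))
  expect_equal(I[2, ], c(A = 1, E = 1, AE = -1, B = 0))
  expect_equal(I[3, ], c(A = 0, E = 1, AE = -1, B = 1))

  expect_equal(dim(incidence(parse_reactions(""))), c(0L, 0L))
  # a self-loop contributes nothing
  expect_equal(unname(incidence(parse_reactions("A => A"))), matrix(0, 1, 1))
})

test_that("incidence is linear over disjoint unions", {
  a <- parse_reactions("A => B")
  b <- parse_reactions("X + Y => 2*Z")
  u <- reaction_net(c(a$places, b$places),
                    c("t1", "u1"),
                    pre = list(t1 = a$pre$t1, u1 = b$pre$t1),
                    post = list(t1 = a$post$t1, u1 = b$post$t1))
  I <- incidence(u)
  expect_equal(I[1, a$places], incidence(a)[1, ])
  expect_equal(I[2, b$places], incidence(b)[1, ])
  expect_true(all(I[1, b$places] == 0))
  expect_true(all(I[2, a$places] == 0))
})

test_that("transpose swaps dimensions, transposes incidence, and is an involution", {
  enz <- enzymatic_net()
  tr <- transpose_net(enz)
  expect_equal(n_places(tr), 3)
  expect_equal(n_transitions(tr), 4)
  expect_equal(unname(incidence(tr)), unname(t(incidence(enz))))
  back <- transpose_net(tr)
  expect_equal(back$places, enz$places)
  expect_equal(back$transitions, enz$transitions)
  expect_equal(unname(incidence(back)), unname(incidence(enz)))

  for (seed in 1:5) {
    net <- random_net(4, 3, 2, 0.6, seed)
    expect_equal(unname(incidence(transpose_net(net))),
                 unname(t(incidence(net))))
  }
})

test_that("serialize/parse round trip preserves the net exactly", {
  nets <- c(list(enzymatic_net(), classic_net(2, 3), mapk_cascade()),
            lapply(1:10, function(s) random_net(5, 4, 3, 0.5, s)))
  # a net with an isolated place exercises the #!places pragma
  iso <- reaction_net(c("A", "B", "LONER"), "t1",
                      pre = list(t1 = c(A = 1)), post = list(t1 = c(B = 1)))
  nets <- c(nets, list(iso))
  for (net in nets) {
    back <- parse_reactions(write_reactions(net))
    expect_equal(back$places, net$places)
    expect_equal(back$transitions, net$transitions)
    expect_equal(back$pre, net$pre)
    expect_equal(back$post, net$post)
  }
})

test_that("net JSON dump lists all structure", {
  j <- jsonlite::fromJSON(net_to_json(enzymatic_net()))
  expect_equal(j$places, c("A", "E", "AE", "B"))
  expect_equal(j$pre$t1, list(A = 1L, E = 1L))
})

test_that("constructor validates weights and place references", {
  expect_error(reaction_net("A", "t", pre = list(t = c(B = 1))), "unknown place")
  expect_error(reaction_net("A", "t", pre = list(t = c(A = -1))), "natural")
  expect_error(reaction_net(c("A", "A"), character()), "duplicate")
})

sbml_fixture <- function(extra_product_attr = "", modifiers = "") {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="enzyme"><listOfSpecies>',
    '<species id="A"/><species id="E"/><species id="AE"/><species id="B"/><species id="M"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="bind" reversible="true"><listOfReactants>',
    '<speciesReference species="A"/><speciesReference species="E"/></listOfReactants>',
    '<listOfProducts><speciesReference species="AE"', extra_product_attr,
    '/></listOfProducts></reaction>',
    '<reaction id="cat" reversible="false">',
    '<listOfReactants><speciesReference species="AE"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B"/>',
    '<speciesReference species="E"/></listOfProducts>',
    modifiers,
    '</reaction></listOfReactions></model></sbml>')
}

test_that("SBML import matches the text parser on the same mechanism", {
  net <- read_sbml(sbml_fixture())
  txt <- parse_reactions("bind: A + E <=> AE\ncat: AE => B + E")
  expect_equal(net$transitions, txt$transitions)
  expect_equal(net$pre, txt$pre)
  expect_equal(net$post, txt$post)
  expect_equal(net$places, c(txt$places, "M"))  # unused species kept
})

test_that("SBML modifiers become read arcs invisible to the incidence matrix", {
  net <- read_sbml(sbml_fixture(
    modifiers = '<listOfModifiers><modifierSpeciesReference species="M"/></listOfModifiers>'))
  expect_equal(net$pre$cat[["M"]], 1L)
  expect_equal(net$post$cat[["M"]], 1L)
  expect_true(all(incidence(net)[, "M"] == 0))
})

test_that("fractional SBML stoichiometry is rejected by name, or rescaled on request", {
  doc <- sbml_fixture(extra_product_attr = ' stoichiometry="0.5"')
  expect_error(read_sbml(doc), "bind")
  scaled <- read_sbml(doc, scale_rationals = TRUE)
  expect_equal(scaled$pre$bind, c(A = 2L, E = 2L))
  expect_equal(scaled$post$bind, c(AE = 1L))
  # integral reactions in the same document are untouched
  expect_equal(scaled$pre$cat, c(AE = 1L))
})
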