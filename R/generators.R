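#' Benchmark net: the classic X-Y ring
#'
#' `y` transitions arranged in a cycle; between consecutive transitions
#' `t_j` and `t_(j+1)` lie `x` parallel places, each receiving one arc
#' from `t_j` and sending one arc to `t_(j+1)` — `x*y` places in all.
#' Every minimal semi-positive P-invariant picks exactly one of the `x`
#' parallel places per segment with weight 1, so there are `x^y` of them:
#' the standard exponential case for invariant enumeration, and the
#' reason the symmetry-compressed counting path exists.
#'
#' Places are named `P_<segment>_<copy>` so the symmetry groups are
#' visually evident.
#'
#' @param x parallel places per segment (>= 1).
#' @param y transitions in the ring (>= 2).
#' @return a [reaction_net()].
#' @examples
#' classic_net(2, 3)  # 6 places, 3 transitions, 8 minimal P-invariants
#' @export
classic_net <- function(x, y) {
  stopifnot(x >= 1, y >= 2)
  transitions <- paste0("t", seq_len(y))
  seg <- function(j) paste0("P_", j, "_", seq_len(x))
  places <- unlist(lapply(seq_len(y), seg))
  pre <- list()
  post <- list()
  for (j in seq_len(y)) {
    prev <- if (j == 1) y else j - 1
    pre[[transitions[j]]] <- stats::setNames(rep(1L, x), seg(prev))
    post[[transitions[j]]] <- stats::setNames(rep(1L, x), seg(j))
  }
  reaction_net(places, transitions, pre, post,
               source = sprintf("classic_%d_%d", x, y))
}

#' Benchmark net: the enzymatic reaction
#'
#' The textbook enzyme mechanism `A + E <=> AE => B + E`: substrate A
#' binds enzyme E reversibly into the complex AE, which releases product
#' B and frees the enzyme.  Four places (A, E, AE, B), three transitions.
#' Its two minimal semi-positive P-invariants are the enzyme moiety
#' `E + AE` and the substrate moiety `A + AE + B`; its minimal traps are
#' `{B}` and `{E, AE}`.
#'
#' @return a [reaction_net()].
#' @export
enzymatic_net <- function() {
  parse_reactions("A + E <=> AE\nAE => B + E", source = "enzymatic")
}

#' Benchmark net: dining philosophers
#'
#' The standard Petri-net encoding of Dijkstra's dining philosophers:
#' philosopher i has places `think_i` and `eat_i` and shares fork places
#' `fork_i`, `fork_(i+1)` with the neighbours; `take_i` consumes the
#' thinking state plus both forks and produces the eating state,
#' `release_i` the reverse.  Conservation laws: `think_i + eat_i` per
#' philosopher and `fork_i + eat_(i-1) + eat_i` per fork.  Used for
#' property testing only — the parameter-to-size correspondence with
#' published benchmark tables is approximate, so no exact counts are
#' asserted on it.
#'
#' @param n number of philosophers (>= 2).
#' @return a [reaction_net()].
#' @export
philosophers_net <- function(n) {
  stopifnot(n >= 2)
  places <- c(paste0("think_", 1:n), paste0("eat_", 1:n), paste0("fork_", 1:n))
  pre <- list(); post <- list()
  transitions <- character(0)
  for (i in 1:n) {
    nxt <- if (i == n) 1L else i + 1L
    take <- paste0("take_", i)
    rel <- paste0("release_", i)
    transitions <- c(transitions, take, rel)
    pre[[take]] <- stats::setNames(rep(1L, 3),
                                   c(paste0("think_", i), paste0("fork_", i),
                                     paste0("fork_", nxt)))
    post[[take]] <- stats::setNames(1L, paste0("eat_", i))
    pre[[rel]] <- stats::setNames(1L, paste0("eat_", i))
    post[[rel]] <- stats::setNames(rep(1L, 3),
                                   c(paste0("think_", i), paste0("fork_", i),
                                     paste0("fork_", nxt)))
  }
  reaction_net(places, transitions, pre, post,
               source = sprintf("philosophers_%d", n))
}

#' Benchmark net: circular trains
#'
#' `x` trains move around a ring of `y` track sections; a section holds
#' at most one train.  Train i at section j is place `T_i_j`; a free
#' section j is place `free_j`.  Transition `m_i_j` moves train i from
#' section j to section j+1 when the destination is free.  Conservation
#' laws: each train is somewhere (`sum_j T_i_j`), and each section is
#' free or occupied (`free_j + sum_i T_i_j`).  Property testing only, as
#' for [philosophers_net()].
#'
#' @param x number of trains (>= 1).
#' @param y number of track sections (>= 2).
#' @return a [reaction_net()].
#' @export
circular_trains_net <- function(x, y) {
  stopifnot(x >= 1, y >= 2)
  places <- c(paste0("free_", 1:y),
              unlist(lapply(1:x, function(i) paste0("T_", i, "_", 1:y))))
  pre <- list(); post <- list()
  transitions <- character(0)
  for (i in 1:x) {
    for (j in 1:y) {
      nxt <- if (j == y) 1L else j + 1L
      tr <- paste0("m_", i, "_", j)
      transitions <- c(transitions, tr)
      pre[[tr]] <- stats::setNames(rep(1L, 2),
                                   c(paste0("T_", i, "_", j), paste0("free_", nxt)))
      post[[tr]] <- stats::setNames(rep(1L, 2),
                                    c(paste0("T_", i, "_", nxt), paste0("free_", j)))
    }
  }
  reaction_net(places, transitions, pre, post,
               source = sprintf("trains_%d_%d", x, y))
}

#' Synthetic re-encoding of the two-site MAPK signalling cascade
#'
#' A reconstruction (from the published species list and the standard
#' mass-action mechanism) of the classic scaffold-free MAPK cascade with
#' two-site phosphorylation: RAF is activated by the kinase RAFK and
#' deactivated by the phosphatase RAFPH; active RAF~{p1} doubly
#' phosphorylates MEK (phosphatase MEKPH), and doubly phosphorylated
#' MEK~{p1p2} doubly phosphorylates MAPK (phosphatase MAPKPH).  Each
#' phosphorylation/dephosphorylation step is a reversible binding
#' followed by irreversible catalysis.  22 species; its 7 minimal
#' semi-positive P-invariants are the conserved moieties of the four
#' cascade levels and the three phosphatases, reducing the ODE system
#' from 22 to 15 free variables.
#'
#' This is a synthetic stand-in built from the mechanism's structure, not
#' an imported model file; kinetic parameters are absent by design.
#'
#' @return a [reaction_net()] with 22 places and 30 transitions.
#' @export
mapk_cascade <- function() {
  txt <- c(
    "RAF + RAFK <=> RAF-RAFK",
    "RAF-RAFK => RAF~{p1} + RAFK",
    "RAF~{p1} + RAFPH <=> RAFPH-RAF~{p1}",
    "RAFPH-RAF~{p1} => RAF + RAFPH",
    "MEK + RAF~{p1} <=> MEK-RAF~{p1}",
    "MEK-RAF~{p1} => MEK~{p1} + RAF~{p1}",
    "MEK~{p1} + RAF~{p1} <=> MEK~{p1}-RAF~{p1}",
    "MEK~{p1}-RAF~{p1} => MEK~{p1p2} + RAF~{p1}",
    "MEK~{p1} + MEKPH <=> MEKPH-MEK~{p1}",
    "MEKPH-MEK~{p1} => MEK + MEKPH",
    "MEK~{p1p2} + MEKPH <=> MEKPH-MEK~{p1p2}",
    "MEKPH-MEK~{p1p2} => MEK~{p1} + MEKPH",
    "MAPK + MEK~{p1p2} <=> MAPK-MEK~{p1p2}",
    "MAPK-MEK~{p1p2} => MAPK~{p1} + MEK~{p1p2}",
    "MAPK~{p1} + MEK~{p1p2} <=> MAPK~{p1}-MEK~{p1p2}",
    "MAPK~{p1}-MEK~{p1p2} => MAPK~{p1p2} + MEK~{p1p2}",
    "MAPK~{p1} + MAPKPH <=> MAPKPH-MAPK~{p1}",
    "MAPKPH-MAPK~{p1} => MAPK + MAPKPH",
    "MAPK~{p1p2} + MAPKPH <=> MAPKPH-MAPK~{p1p2}",
    "MAPKPH-MAPK~{p1p2} => MAPK~{p1} + MAPKPH")
  parse_reactions(txt, source = "mapk_cascade_synthetic")
}

#' Reproducible random reaction network
#'
#' Every (transition, place) pair gets a pre arc with probability
#' `density` and independently a post arc with probability `density`,
#' weights uniform on `1..max_weight`; a transition that ends up with no
#' arcs at all receives one random arc so that every transition touches
#' the net.  The same seed always yields the same net; the global RNG
#' state is left untouched.
#'
#' @param p number of places (>= 1).
#' @param t number of transitions (>= 1).
#' @param max_weight maximal arc weight (>= 1).
#' @param density arc probability in (0, 1].
#' @param seed integer seed fixing the net exactly.
#' @return a [reaction_net()].
#' @export
random_net <- function(p, t, max_weight = 3, density = 0.5, seed) {
  stopifnot(p >= 1, t >= 1, max_weight >= 1, density > 0, density <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  places <- paste0("p", seq_len(p))
  transitions <- paste0("t", seq_len(t))
  pre <- list(); post <- list()
  for (tr in transitions) {
    draw <- function() {
      on <- stats::runif(p) <= density
      w <- stats::setNames(sample.int(max_weight, p, replace = TRUE), places)
      w[on]
    }
    wpre <- draw()
    wpost <- draw()
    if (length(wpre) == 0 && length(wpost) == 0) {
      j <- sample.int(p, 1)
      w <- stats::setNames(sample.int(max_weight, 1), places[j])
      if (stats::runif(1) < 0.5) wpre <- w else wpost <- w
    }
    pre[[tr]] <- wpre
    post[[tr]] <- wpost
  }
  reaction_net(places, transitions, pre, post,
               source = sprintf("random_p%d_t%d_seed%d", p, t, seed))
}
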