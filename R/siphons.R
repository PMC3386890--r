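#' Boolean constraint problems for traps and siphons
#'
#' One 0/1 variable per place, telling whether the place belongs to the
#' set.  For a trap (a place set that, once marked, stays marked), every
#' transition consuming from the set must produce into it: per transition
#' the implication `(v over pre-places) => (v over post-places)`.  For a
#' siphon (once empty, stays empty) the implication is reversed.  A
#' non-emptiness constraint `sum > 0` is added so that the empty set is
#' not endlessly re-found.
#'
#' A transition with non-empty pre and empty post makes its pre-places
#' impossible trap members (implication with a false consequent) — that
#' is propagation, not an error; sources and sinks are legal.
#'
#' @param net a [reaction_net()].
#' @return an [fd_store()] over 0/1 variables named after the places.
#' @export
trap_csp <- function(net) place_set_csp(net, reverse = FALSE)

#' @rdname trap_csp
#' @export
siphon_csp <- function(net) place_set_csp(net, reverse = TRUE)

place_set_csp <- function(net, reverse) {
  store <- fd_store(net$places, lo = 0, hi = rep(1, n_places(net)))
  if (n_places(net) == 0) return(store)
  for (tr in net$transitions) {
    a <- names(net$pre[[tr]])
    b <- names(net$post[[tr]])
    if (reverse) { tmp <- a; a <- b; b <- tmp }
    if (length(a) == 0) next   # vacuous implication
    store <- fd_post(store, fd_bool_implication(a, b))
  }
  fd_post(store, fd_sum_positive(net$places))
}

#' Direct trap / siphon checkers
#'
#' Written straight from the definitions, independent of the constraint
#' encoding — the oracle used to validate enumeration output.
#'
#' @param net a [reaction_net()].
#' @param S a character vector of place names (the empty set is vacuously
#'   both a trap and a siphon).
#' @return `TRUE` or `FALSE`.
#' @export
is_trap <- function(net, S) {
  check_places(net, S)
  for (tr in net$transitions) {
    if (length(intersect(names(net$pre[[tr]]), S)) > 0 &&
        length(intersect(names(net$post[[tr]]), S)) == 0)
      return(FALSE)
  }
  TRUE
}

#' @rdname is_trap
#' @export
is_siphon <- function(net, S) {
  check_places(net, S)
  for (tr in net$transitions) {
    if (length(intersect(names(net$post[[tr]]), S)) > 0 &&
        length(intersect(names(net$pre[[tr]]), S)) == 0)
      return(FALSE)
  }
  TRUE
}

check_places <- function(net, S) {
  unknown <- setdiff(S, net$places)
  if (length(unknown)) stop("unknown place(s): ", paste(unknown, collapse = ", "))
}

#' Enumerate the minimal non-empty solutions of a boolean place-set CSP
#'
#' Repeats: find the lexicographically smallest remaining solution, add
#' it, post a support-exclusion constraint, until unsatisfiable.  Unlike
#' the invariant search there is no minimality filtering step: in the
#' boolean domain, low-to-high lexicographic labelling can only produce
#' inclusion-minimal sets (any proper sub-solution would be
#' lexicographically smaller and still feasible, so it would have been
#' found first).
#'
#' @param store a store built by [trap_csp()] or [siphon_csp()].
#' @param net the corresponding [reaction_net()] (fixes place order in
#'   the output).
#' @return a list of character vectors, each a minimal place set, sets in
#'   deterministic order (size, then place declaration order).
#' @export
minimal_sets <- function(store, net) {
  sets <- list()
  repeat {
    sol <- fd_next_solution(store)
    if (is.null(sol)) break
    supp <- names(sol)[sol > 0]
    sets[[length(sets) + 1L]] <- supp
    store <- fd_post(store, fd_zero_among(supp))
    if (!fd_consistent(store)) break
  }
  sort_sets(sets, net$places)
}

sort_sets <- function(sets, places) {
  if (length(sets) <= 1) return(sets)
  keys <- vapply(sets, function(s) {
    idx <- sort(match(s, places))
    sprintf("%04d|%s", length(s), paste(sprintf("%04d", idx), collapse = ","))
  }, "")
  sets[order(keys)]
}

#' Minimal traps / siphons of a reaction network
#'
#' High-level wrappers around [trap_csp()] / [siphon_csp()] and
#' [minimal_sets()], with the same parallel-place merging used for
#' invariants: interchangeable places are merged before enumeration and
#' each merged set member is expanded back to the individual places
#' (singleton substitutions, which preserves minimality).
#'
#' @param net a [reaction_net()].
#' @param symmetry merge parallel places before enumerating.
#' @return an object of class `place_set_family`: list with `sets`,
#'   `kind`, `places`.
#' @examples
#' minimal_traps(enzymatic_net())    # {B} and {E, AE}
#' minimal_siphons(enzymatic_net())  # {A, AE} and {E, AE}
#' @export
minimal_traps <- function(net, symmetry = TRUE) {
  place_set_family(net, "trap", symmetry)
}

#' @rdname minimal_traps
#' @export
minimal_siphons <- function(net, symmetry = TRUE) {
  place_set_family(net, "siphon", symmetry)
}

place_set_family <- function(net, kind, symmetry) {
  build <- if (kind == "trap") trap_csp else siphon_csp
  groups <- if (symmetry) detect_groups(net) else list()
  if (length(groups) == 0) {
    sets <- minimal_sets(build(net), net)
  } else {
    mapping <- merge_net(net, groups)
    red_sets <- minimal_sets(build(mapping$reduced_net), mapping$reduced_net)
    sets <- list()
    for (s in red_sets) {
      choices <- list(intersect(s, mapping$untouched))
      for (g in groups) {
        if (!(g$merged_id %in% s)) next
        choices <- unlist(lapply(choices, function(base)
          lapply(g$members, function(m) c(base, m))), recursive = FALSE)
      }
      sets <- c(sets, choices)
    }
    sets <- sort_sets(sets, net$places)
  }
  structure(list(sets = sets, kind = kind, places = net$places),
            class = "place_set_family")
}

#' @export
print.place_set_family <- function(x, ...) {
  cat(length(x$sets), " minimal ", x$kind, "s\n", sep = "")
  for (s in x$sets)
    cat("  {", paste(s, collapse = ", "), "}\n", sep = "")
  invisible(x)
}
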