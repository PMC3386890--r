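#' Build the constraint problem for invariant computation
#'
#' One finite-domain variable per place with domain `[0, bound]`; per
#' transition `i` one linear constraint `V.L_i (=|<=|>=) V.R_i`, where
#' `L_i`/`R_i` are the reactant/product stoichiometry vectors; plus the
#' non-triviality constraint `sum(V) > 0`.  With relation `"eq"` the
#' solutions are the semi-positive P-invariants within the bound; `"le"`
#' gives weighted pools that never decrease under firing, `"ge"` pools
#' that never increase.
#'
#' For T-invariants, build on [transpose_net()] output (the high-level
#' [minimal_invariants()] does this for you).
#'
#' @param net a [reaction_net()].
#' @param relation `"eq"`, `"le"` or `"ge"`.
#' @param bound upper domain bound, a scalar or per-place vector.
#' @return an [fd_store()] whose variables are `net$places` in
#'   declaration order.
#' @export
build_invariant_csp <- function(net, relation = c("eq", "le", "ge"), bound = 8) {
  relation <- match.arg(relation)
  store <- fd_store(net$places, lo = 0, hi = rep_len(bound, n_places(net)))
  if (n_places(net) == 0) return(store)
  pre <- pre_matrix(net)
  post <- post_matrix(net)
  for (i in seq_along(net$transitions)) {
    coef <- stats::setNames(pre[i, ] - post[i, ], net$places)  # V.L - V.R rel 0
    coef <- coef[coef != 0]
    if (length(coef) == 0) next           # self-loop row: always satisfied
    store <- fd_post(store, fd_linear(coef, relation, 0))
  }
  fd_post(store, fd_sum_positive(net$places))
}

#' Sufficient domain bound for complete invariant enumeration
#'
#' The product over transitions of the least common multiple of each
#' transition's non-zero stoichiometric coefficients.  Any minimal
#' semi-positive invariant has all components below this value, so running
#' [minimal_invariants()] with it guarantees completeness — at the price
#' of a bound that explodes quickly with net size, which is why the
#' default policy is a small fixed bound with an honest `complete` flag.
#'
#' @param net a [reaction_net()].
#' @return a number, at least 1.
#' @export
complete_bound <- function(net) {
  pre <- pre_matrix(net)
  post <- post_matrix(net)
  prod <- 1
  for (i in seq_along(net$transitions))
    prod <- prod * lcm_all(c(pre[i, ], post[i, ]))
  max(1, prod)
}

#' Normalize an invariant vector to gcd-normal form
#'
#' Minimal invariants are unique per support up to scaling; dividing by
#' the gcd of the non-zero weights picks the canonical representative.
#'
#' @param v a named non-negative integer vector with at least one positive
#'   entry.
#' @return the scaled vector, zero entries dropped.
#' @export
normalize_invariant <- function(v) {
  v <- v[v > 0]
  if (length(v) == 0) stop("cannot normalize the zero vector")
  g <- gcd_all(v)
  out <- as.integer(v / g)
  names(out) <- names(v)
  out
}

#' Does a weight vector satisfy the invariant relation on a net?
#'
#' Direct evaluation of `V.L_i rel V.R_i` for every transition, written
#' against the net itself rather than the constraint encoding — the
#' definitional soundness check for solver output.
#'
#' @param net a [reaction_net()].
#' @param v a named weight vector (absent places count 0).
#' @param relation `"eq"`, `"le"` or `"ge"`.
#' @return `TRUE` or `FALSE`.
#' @export
invariant_holds <- function(net, v, relation = c("eq", "le", "ge")) {
  relation <- match.arg(relation)
  w <- stats::setNames(numeric(n_places(net)), net$places)
  w[names(v)] <- v
  lhs <- as.numeric(pre_matrix(net) %*% w)
  rhs <- as.numeric(post_matrix(net) %*% w)
  switch(relation,
         eq = all(lhs == rhs),
         le = all(lhs <= rhs),
         ge = all(lhs >= rhs))
}

#' Minimal semi-positive invariants of a reaction network
#'
#' Branch-and-bound enumeration of all support-minimal semi-positive
#' P- or T-invariants with components within a domain bound.  The search
#' repeatedly asks the constraint store for its lexicographically smallest
#' remaining solution, gcd-normalizes it, adds it to the basis, drops any
#' earlier basis vector whose support strictly contains the new one, and
#' posts a support-exclusion constraint (at least one zero among the new
#' support) before continuing; it stops when the store becomes
#' unsatisfiable.
#'
#' Interchangeable ("parallel") places are detected syntactically first
#' and merged into one representative place each, so a basis with
#' exponentially many symmetric members is searched in the reduced space;
#' the result is then expanded back (or, with `compressed = TRUE`, left
#' reduced and only counted).
#'
#' @param net a [reaction_net()].
#' @param mode `"P"` (place invariants, conservation laws) or `"T"`
#'   (transition invariants, flux cycles; computed on the transposed net).
#' @param relation `"eq"` for invariants, `"le"` for non-decreasing pools,
#'   `"ge"` for non-increasing pools.
#' @param bound per-place domain bound.  The default 8 follows the
#'   observation that stoichiometric weights in curated biochemical models
#'   stay small; the returned basis carries `complete = FALSE` unless
#'   `bound >= complete_bound(net)`.
#' @param use_complete_bound replace `bound` by [complete_bound()] of the
#'   net (guarantees completeness, can be astronomically slow).
#' @param symmetry detect and merge parallel places before searching.
#' @param compressed return the reduced basis plus the combinatorial
#'   expanded count instead of enumerating the expansion.
#' @param expansion `"strict"` filters the expanded vectors to
#'   inclusion-minimal supports in gcd-normal form (the definition of a
#'   minimal invariant); `"paper"` emits every ordered composition of each
#'   merged value, which can include support-non-minimal vectors.
#' @return an object of class `invariant_basis`: a list with `vectors`
#'   (named weight vectors), `mode`, `relation`, `bound`, `complete`,
#'   `groups`, `compressed`, `count_expanded` (exact count as a decimal
#'   string) and, for compressed results, the `reduced_net` the basis
#'   lives on.
#' @examples
#' enz <- parse_reactions("A + E <=> AE\nAE => B + E")
#' minimal_invariants(enz)
#' @export
minimal_invariants <- function(net, mode = c("P", "T"),
                               relation = c("eq", "le", "ge"),
                               bound = 8, use_complete_bound = FALSE,
                               symmetry = TRUE, compressed = FALSE,
                               expansion = c("strict", "paper")) {
  mode <- match.arg(mode)
  relation <- match.arg(relation)
  expansion <- match.arg(expansion)
  work <- if (mode == "T") transpose_net(net) else net
  if (use_complete_bound) bound <- complete_bound(work)
  if (bound < 1) stop("bound must be >= 1")
  complete <- bound >= complete_bound(work)

  result <- function(vectors, groups, compressed_flag, count,
                     places = work$places, reduced_net = NULL) {
    structure(list(vectors = vectors, mode = mode, relation = relation,
                   bound = bound, complete = complete,
                   groups = groups, compressed = compressed_flag,
                   count_expanded = count,
                   places = places, reduced_net = reduced_net),
              class = "invariant_basis")
  }

  if (n_places(work) == 0)
    return(result(list(), list(), FALSE, "0"))

  groups <- if (symmetry) detect_groups(work) else list()
  if (length(groups) == 0) {
    basis <- solve_minimal_invariants(work, relation, rep(bound, n_places(work)))
    basis <- sort_basis(basis, work$places)
    return(result(basis, list(), FALSE, big_from_num(length(basis))))
  }

  mapping <- merge_net(work, groups)
  red <- mapping$reduced_net
  red_bound <- rep(bound, n_places(red))
  # a merged variable is the plain sum of its members, each capped at
  # `bound`, so its own cap is bound * group size
  for (g in mapping$groups)
    red_bound[match(g$merged_id, red$places)] <- bound * length(g$members)
  basis <- solve_minimal_invariants(red, relation, red_bound)
  basis <- sort_basis(basis, red$places)
  count <- count_expanded(basis, mapping, member_bound = bound)
  if (compressed)
    return(result(basis, mapping$groups, TRUE, count,
                  places = red$places, reduced_net = red))
  expanded <- expand_basis(basis, mapping, mode = expansion, member_bound = bound)
  expanded <- sort_basis(expanded, work$places)
  result(expanded, mapping$groups, FALSE, count)
}

# Core of Algorithm 1: enumerate support-minimal solutions of the
# invariant CSP over `net` with per-place bounds.
solve_minimal_invariants <- function(net, relation, bounds) {
  store <- build_invariant_csp(net, relation, bounds)
  basis <- list()
  repeat {
    sol <- fd_next_solution(store)
    if (is.null(sol)) break
    v <- normalize_invariant(sol)
    supp <- names(v)
    # drop earlier vectors with strictly larger support (they are not minimal)
    keep <- vapply(basis, function(b) {
      bs <- names(b)
      !(length(bs) > length(supp) && all(supp %in% bs))
    }, TRUE)
    basis <- basis[keep]
    # same support cannot reappear (its exclusion constraint forbids it),
    # but dedup defensively
    dup <- any(vapply(basis, function(b) identical(b, v), TRUE))
    if (!dup) basis[[length(basis) + 1L]] <- v
    store <- fd_post(store, fd_zero_among(supp))
    if (!fd_consistent(store)) break
  }
  basis
}

# Deterministic basis order: support size, then support position in place
# declaration order, then the weights themselves.  Entries within each
# vector are put in place declaration order too.
sort_basis <- function(basis, places) {
  basis <- lapply(basis, function(v) v[order(match(names(v), places))])
  if (length(basis) <= 1) return(basis)
  keys <- vapply(basis, function(v) {
    idx <- sort(match(names(v), places))
    w <- v[order(match(names(v), places))]
    sprintf("%04d|%s|%s", length(v),
            paste(sprintf("%04d", idx), collapse = ","),
            paste(sprintf("%06d", w), collapse = ","))
  }, "")
  basis[order(keys)]
}

#' @export
print.invariant_basis <- function(x, ...) {
  what <- switch(x$relation,
                 eq = paste0("minimal semi-positive ", x$mode, "-invariants"),
                 le = "minimal non-decreasing pools",
                 ge = "minimal non-increasing pools")
  cat(length(x$vectors),
      if (x$compressed) " reduced (symmetry-compressed) " else " ",
      what, "  [bound ", x$bound,
      if (x$complete) ", complete" else ", possibly incomplete", "]\n", sep = "")
  if (length(x$groups))
    cat("  ", length(x$groups), " parallel-place group(s) merged; expanded count = ",
        x$count_expanded, "\n", sep = "")
  for (v in x$vectors)
    cat("  ", format_side(v), "\n", sep = "")
  invisible(x)
}

#' Conservation-law report from a P-invariant basis
#'
#' Each equality P-invariant defines an algebraic conservation rule: the
#' weighted sum of its species concentrations is constant along any
#' trajectory of the corresponding ODE system, whatever the rate laws.
#' Independent rules reduce the number of free ODE variables by the rank
#' of the basis.
#'
#' @param net the analysed [reaction_net()].
#' @param basis an `invariant_basis` with `mode = "P"`, `relation = "eq"`.
#' @return an object of class `conservation_report` with fields `laws`
#'   (character), `n_species`, `n_laws`, `rank`, `free_variables`.
#' @export
conservation_report <- function(net, basis) {
  stopifnot(inherits(basis, "invariant_basis"))
  if (basis$mode != "P" || basis$relation != "eq")
    stop("conservation laws come from P-invariants with relation 'eq'")
  laws <- vapply(basis$vectors, function(v)
    paste0(paste(ifelse(v == 1L, paste0("[", names(v), "]"),
                        paste0(v, "*[", names(v), "]")),
                 collapse = " + "), " = constant"), "")
  rk <- if (length(basis$vectors) == 0) 0L else {
    m <- do.call(rbind, lapply(basis$vectors, function(v) {
      w <- stats::setNames(numeric(n_places(net)), net$places)
      w[names(v)] <- v
      w
    }))
    qr(m)$rank
  }
  structure(list(laws = laws, n_species = n_places(net),
                 n_laws = length(laws), rank = rk,
                 free_variables = n_places(net) - rk),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  if (x$n_laws == 0) {
    cat("no conservation laws; ", x$free_variables,
        " free ODE variables\n", sep = "")
    return(invisible(x))
  }
  for (l in x$laws) cat("  ", l, "\n", sep = "")
  cat(x$n_species, " species, ", x$n_laws, " conservation laws (rank ",
      x$rank, ") -> ", x$free_variables, " free ODE variables\n", sep = "")
  invisible(x)
}
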