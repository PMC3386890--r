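#' A finite-domain constraint store over bounded natural variables
#'
#' The store holds one integer interval domain `[lo, hi]` per variable plus
#' a set of constraints, and supports bounds-consistency propagation and
#' depth-first labelling that tries values from small to large.  Variables
#' are searched in declaration order, so solutions come out in ascending
#' lexicographic order — the property the minimal-siphon/trap enumeration
#' relies on to avoid any a posteriori minimality filtering.
#'
#' Constraint types:
#' \describe{
#'   \item{[fd_linear()]}{`sum(coef * x) (=|<=|>=) rhs` with integer
#'     coefficients.}
#'   \item{[fd_sum_positive()]}{the sum of the given variables is > 0
#'     (non-triviality of invariants).}
#'   \item{[fd_zero_among()]}{at least one of the given variables is 0
#'     (support-exclusion after a solution is found).}
#'   \item{[fd_bool_implication()]}{over 0/1 variables,
#'     `(x1 v x2 v ...) => (y1 v y2 v ...)`; compiled to linear form.}
#' }
#'
#' @param variables character vector of variable names, in the order the
#'   labelling will follow.
#' @param lo,hi domain bounds, scalars or vectors along `variables`.
#' @return an object of class `fd_store`.
#' @examples
#' s <- fd_store(c("x", "y"), lo = 0, hi = 4)
#' s <- fd_post(s, fd_linear(c(x = 1, y = 1), "eq", 4))
#' fd_next_solution(s)   # c(x = 0, y = 4)
#' @export
fd_store <- function(variables, lo = 0L, hi) {
  stopifnot(length(variables) >= 0, !anyDuplicated(variables))
  n <- length(variables)
  lo <- rep_len(as.numeric(lo), n)
  hi <- rep_len(as.numeric(hi), n)
  if (any(lo < 0) || any(lo > hi)) stop("domains must satisfy 0 <= lo <= hi")
  structure(
    list(vars = as.character(variables), lo = lo, hi = hi,
         lin = list(), zero_among = list(), posted = list(),
         failed = FALSE),
    class = "fd_store"
  )
}

#' Constraint constructors for [fd_store()]
#'
#' @param coeffs a named numeric vector of non-zero integer coefficients.
#' @param rel one of `"eq"`, `"le"`, `"ge"`.
#' @param rhs the right-hand side, an integer.
#' @return a constraint object for [fd_post()].
#' @export
fd_linear <- function(coeffs, rel = c("eq", "le", "ge"), rhs = 0) {
  rel <- match.arg(rel)
  coeffs <- coeffs[coeffs != 0]
  if (length(coeffs) == 0 || is.null(names(coeffs)))
    stop("fd_linear needs a non-empty named coefficient vector")
  structure(list(type = "linear", coeffs = coeffs, rel = rel, rhs = rhs),
            class = "fd_constraint")
}

#' @rdname fd_linear
#' @param variables variable names.
#' @export
fd_sum_positive <- function(variables) {
  if (length(variables) == 0) stop("fd_sum_positive needs at least one variable")
  structure(list(type = "sum_positive", variables = as.character(variables)),
            class = "fd_constraint")
}

#' @rdname fd_linear
#' @export
fd_zero_among <- function(variables) {
  if (length(variables) == 0) stop("fd_zero_among needs a non-empty set")
  structure(list(type = "zero_among", variables = as.character(variables)),
            class = "fd_constraint")
}

#' @rdname fd_linear
#' @param antecedent,consequent variable names forming the two
#'   disjunctions; an empty consequent forces every antecedent variable
#'   to 0.
#' @export
fd_bool_implication <- function(antecedent, consequent) {
  structure(list(type = "bool_implication",
                 antecedent = as.character(antecedent),
                 consequent = as.character(consequent)),
            class = "fd_constraint")
}

#' Post a constraint and propagate to fixpoint
#'
#' @param store an [fd_store()].
#' @param constraint a constraint built by [fd_linear()] and friends.
#' @return the updated store; `fd_consistent()` reports whether some
#'   domain emptied (inconsistency is a state, not an error).
#' @export
fd_post <- function(store, constraint) {
  stopifnot(inherits(store, "fd_store"), inherits(constraint, "fd_constraint"))
  vidx <- function(v) {
    i <- match(v, store$vars)
    if (anyNA(i)) stop("unknown variable(s): ",
                       paste(v[is.na(i)], collapse = ", "))
    i
  }
  store$posted <- c(store$posted, list(constraint))
  switch(constraint$type,
    linear = {
      store$lin <- c(store$lin, list(list(
        idx = vidx(names(constraint$coeffs)),
        coef = as.numeric(constraint$coeffs),
        rel = constraint$rel, rhs = as.numeric(constraint$rhs))))
    },
    sum_positive = {
      i <- vidx(constraint$variables)
      store$lin <- c(store$lin, list(list(
        idx = i, coef = rep(1, length(i)), rel = "ge", rhs = 1)))
    },
    zero_among = {
      store$zero_among <- c(store$zero_among, list(vidx(constraint$variables)))
    },
    bool_implication = {
      # over 0/1 variables, (v A) => (v C)  iff  for every a in A:
      # x_a <= sum(x_C); with C empty this pins every antecedent to 0
      ci <- vidx(constraint$consequent)
      for (a in constraint$antecedent) {
        ai <- vidx(a)
        idx <- c(ai, ci)
        coef <- c(1, rep(-1, length(ci)))
        keep <- !duplicated(idx)
        # a variable can appear on both sides; fold coefficients
        if (!all(keep)) {
          coef <- vapply(unique(idx), function(k) sum(coef[idx == k]), 0)
          idx <- unique(idx)
          nz <- coef != 0
          idx <- idx[nz]; coef <- coef[nz]
          if (length(idx) == 0) next  # tautology
        }
        store$lin <- c(store$lin, list(list(idx = idx, coef = coef,
                                            rel = "le", rhs = 0)))
      }
    },
    stop("unknown constraint type")
  )
  fd_propagate(store)
}

#' Run bounds-consistency propagation to fixpoint
#'
#' Linear constraints tighten each variable's interval against the extremal
#' values of the remaining terms.  A zero-among constraint fails when all
#' members are known non-zero and grounds the last member to 0 when it is
#' the only one left that can still be 0.  Propagation is idempotent at the
#' fixpoint.
#'
#' @param store an [fd_store()].
#' @return the store with tightened (only ever tightened) domains.
#' @export
fd_propagate <- function(store) {
  if (store$failed) return(store)
  res <- prop_run(store$lo, store$hi, store$lin, store$zero_among)
  store$lo <- res$lo
  store$hi <- res$hi
  store$failed <- res$failed
  store
}

prop_run <- function(lo, hi, lin, zero_among) {
  repeat {
    changed <- FALSE
    for (cn in lin) {
      idx <- cn$idx; coef <- cn$coef
      l <- lo[idx]; h <- hi[idx]
      tmin <- ifelse(coef > 0, coef * l, coef * h)
      tmax <- ifelse(coef > 0, coef * h, coef * l)
      smin <- sum(tmin); smax <- sum(tmax)
      if ((cn$rel == "eq" && (smin > cn$rhs || smax < cn$rhs)) ||
          (cn$rel == "le" && smin > cn$rhs) ||
          (cn$rel == "ge" && smax < cn$rhs))
        return(list(lo = lo, hi = hi, failed = TRUE))
      for (k in seq_along(idx)) {
        a <- coef[k]
        rest_min <- smin - tmin[k]
        rest_max <- smax - tmax[k]
        term_lb <- -Inf; term_ub <- Inf
        if (cn$rel != "ge") term_ub <- cn$rhs - rest_min  # eq or le
        if (cn$rel != "le") term_lb <- cn$rhs - rest_max  # eq or ge
        j <- idx[k]
        if (a > 0) {
          nlo <- if (is.finite(term_lb)) ceiling(term_lb / a) else lo[j]
          nhi <- if (is.finite(term_ub)) floor(term_ub / a) else hi[j]
        } else {
          nlo <- if (is.finite(term_ub)) ceiling(term_ub / a) else lo[j]
          nhi <- if (is.finite(term_lb)) floor(term_lb / a) else hi[j]
        }
        if (nlo > lo[j]) { lo[j] <- nlo; changed <- TRUE }
        if (nhi < hi[j]) { hi[j] <- nhi; changed <- TRUE }
        if (lo[j] > hi[j]) return(list(lo = lo, hi = hi, failed = TRUE))
        # keep the running sums coherent after a tightening
        if (changed) {
          nt_min <- if (a > 0) a * lo[j] else a * hi[j]
          nt_max <- if (a > 0) a * hi[j] else a * lo[j]
          smin <- smin - tmin[k] + nt_min
          smax <- smax - tmax[k] + nt_max
          tmin[k] <- nt_min; tmax[k] <- nt_max
        }
      }
    }
    for (s in zero_among) {
      if (any(hi[s] == 0)) next                 # already satisfied
      open <- s[lo[s] == 0]
      if (length(open) == 0)
        return(list(lo = lo, hi = hi, failed = TRUE))
      if (length(open) == 1) { hi[open] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  list(lo = lo, hi = hi, failed = FALSE)
}

#' Is the store still consistent?
#' @param store an [fd_store()].
#' @return `FALSE` once propagation has emptied a domain.
#' @export
fd_consistent <- function(store) !store$failed

#' Find the next solution of a constraint store
#'
#' Depth-first search labelling variables in declaration order, trying
#' values in increasing order from the domain minimum.  With `after =
#' NULL` this returns the lexicographically smallest solution; with
#' `after` set to a previous solution it returns the lexicographically
#' next one, so repeated calls enumerate all solutions in ascending
#' lexicographic order.
#'
#' @param store an [fd_store()].
#' @param after a previous solution (named or plain integer vector over
#'   all variables), or `NULL`.
#' @return a named integer vector, or `NULL` when no (further) solution
#'   exists.
#' @export
fd_next_solution <- function(store, after = NULL) {
  if (store$failed) return(NULL)
  n <- length(store$vars)
  if (!is.null(after)) {
    if (!is.null(names(after))) after <- after[store$vars]
    after <- as.numeric(after)
    stopifnot(length(after) == n)
  }
  lin <- store$lin
  za <- store$zero_among

  search <- function(lo, hi, d, boundary) {
    res <- prop_run(lo, hi, lin, za)
    if (res$failed) return(NULL)
    lo <- res$lo; hi <- res$hi
    while (d <= n && lo[d] == hi[d] && !boundary) d <- d + 1
    if (d > n) {
      if (boundary) return(NULL)  # equals `after` exactly: skip it
      return(stats::setNames(as.integer(lo), store$vars))
    }
    start <- lo[d]
    if (boundary) {
      if (after[d] > hi[d]) return(NULL)
      start <- max(start, after[d])
    }
    if (start > hi[d]) return(NULL)
    for (v in start:hi[d]) {
      nlo <- lo; nhi <- hi
      nlo[d] <- v; nhi[d] <- v
      sol <- search(nlo, nhi, d + 1, boundary && v == after[d])
      if (!is.null(sol)) return(sol)
    }
    NULL
  }
  if (n == 0) return(NULL)
  search(store$lo, store$hi, 1L, !is.null(after))
}

#' Enumerate all solutions of a store
#'
#' Repeatedly calls [fd_next_solution()]; solutions come out in ascending
#' lexicographic order.
#'
#' @param store an [fd_store()].
#' @param limit safety cap on the number of solutions.
#' @return a list of named integer vectors.
#' @export
fd_all_solutions <- function(store, limit = 100000L) {
  out <- list()
  sol <- fd_next_solution(store)
  while (!is.null(sol)) {
    out[[length(out) + 1L]] <- sol
    if (length(out) >= limit) stop("solution limit reached")
    sol <- fd_next_solution(store, after = sol)
  }
  out
}

#' Check an assignment against every posted constraint
#'
#' A direct evaluator, independent of the propagation and search code:
#' used as the soundness oracle for solver output.
#'
#' @param store an [fd_store()].
#' @param x a named (or declaration-ordered) integer vector over all
#'   variables.
#' @return `TRUE` iff `x` is within every domain and satisfies every
#'   posted constraint.
#' @export
fd_evaluate <- function(store, x) {
  if (!is.null(names(x))) x <- x[store$vars]
  x <- as.numeric(x)
  if (length(x) != length(store$vars)) stop("assignment length mismatch")
  names(x) <- store$vars
  if (any(x < store$lo_orig %||% 0) ) return(FALSE)
  for (cn in store$posted) {
    ok <- switch(cn$type,
      linear = {
        s <- sum(cn$coeffs * x[names(cn$coeffs)])
        switch(cn$rel, eq = s == cn$rhs, le = s <= cn$rhs, ge = s >= cn$rhs)
      },
      sum_positive = sum(x[cn$variables]) > 0,
      zero_among = any(x[cn$variables] == 0),
      bool_implication = !any(x[cn$antecedent] > 0) || any(x[cn$consequent] > 0)
    )
    if (!ok) return(FALSE)
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dump a constraint store as JSON (debugging aid)
#' @param store an [fd_store()].
#' @return a JSON string.
#' @export
fd_dump_json <- function(store) {
  jsonlite::toJSON(list(
    variables = store$vars, lo = store$lo, hi = store$hi,
    consistent = !store$failed,
    constraints = lapply(store$posted, unclass)
  ), auto_unbox = TRUE, pretty = TRUE)
}
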