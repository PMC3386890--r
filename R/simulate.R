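#' Token-game semantics: enabled transitions and firing
#'
#' A transition is enabled at a marking when every pre-place holds at
#' least the arc weight in tokens; firing removes the pre weights and
#' adds the post weights.  These are the dynamic counterparts of the
#' structural properties: an equality P-invariant keeps its weighted
#' token sum constant under any firing, a marked trap stays marked, an
#' empty siphon stays empty.
#'
#' @param net a [reaction_net()].
#' @param marking a named (or place-ordered) non-negative integer vector.
#' @return `enabled_transitions()`: the names of the enabled transitions;
#'   `fire()`: the successor marking.
#' @export
enabled_transitions <- function(net, marking) {
  m <- as_marking(net, marking)
  ok <- vapply(net$transitions, function(tr) {
    w <- net$pre[[tr]]
    length(w) == 0 || all(m[names(w)] >= w)
  }, TRUE)
  net$transitions[ok]
}

#' @rdname enabled_transitions
#' @param transition name of an enabled transition.
#' @export
fire <- function(net, marking, transition) {
  m <- as_marking(net, marking)
  w <- net$pre[[transition]]
  if (is.null(w)) stop("unknown transition '", transition, "'")
  if (length(w)) {
    if (any(m[names(w)] < w)) stop("transition '", transition, "' is not enabled")
    m[names(w)] <- m[names(w)] - w
  }
  v <- net$post[[transition]]
  if (length(v)) m[names(v)] <- m[names(v)] + v
  m
}

as_marking <- function(net, marking) {
  if (is.null(names(marking))) {
    stopifnot(length(marking) == n_places(net))
    return(stats::setNames(as.integer(marking), net$places))
  }
  m <- stats::setNames(integer(n_places(net)), net$places)
  unknown <- setdiff(names(marking), net$places)
  if (length(unknown)) stop("unknown place(s): ", paste(unknown, collapse = ", "))
  m[names(marking)] <- as.integer(marking)
  m
}

#' Simulate a random firing sequence
#'
#' From the given marking, repeatedly fires a uniformly chosen enabled
#' transition, stopping early in a deadlock.  Seed the RNG before calling
#' for reproducibility.
#'
#' @param net a [reaction_net()].
#' @param marking initial marking.
#' @param steps maximum number of firings.
#' @return an integer matrix of visited markings, one row per state
#'   (including the initial one), columns the places.
#' @export
simulate_firings <- function(net, marking, steps = 50) {
  m <- as_marking(net, marking)
  out <- matrix(m, nrow = 1, dimnames = list(NULL, net$places))
  for (i in seq_len(steps)) {
    en <- enabled_transitions(net, m)
    if (length(en) == 0) break
    m <- fire(net, m, if (length(en) == 1) en else sample(en, 1))
    out <- rbind(out, m)
  }
  out
}
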