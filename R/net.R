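#' Construct a reaction network (Petri net)
#'
#' A reaction network is stored as a Petri net: species are places,
#' reactions are transitions, and each transition carries two weighted
#' multisets of places — the reactants it consumes (`pre`) and the products
#' it produces (`post`).  All arc weights are positive integers; a place
#' absent from a multiset has weight 0.
#'
#' @param places character vector of place (species) names, in declaration
#'   order.  Order is significant: it fixes variable order in every
#'   constraint problem built from the net, and therefore the enumeration
#'   order of all results.
#' @param transitions character vector of transition (reaction) names.
#' @param pre,post named lists, one element per transition (in the same
#'   order), each a named integer vector of positive weights over a subset
#'   of `places`.  Zero-weight entries are dropped.
#' @param source free-text provenance label.
#' @param notes free-text notes.
#' @return an object of class `reaction_net`.
#' @examples
#' net <- reaction_net(
#'   places = c("A", "B"),
#'   transitions = "t1",
#'   pre = list(t1 = c(A = 1)),
#'   post = list(t1 = c(B = 2))
#' )
#' incidence(net)
#' @export
reaction_net <- function(places = character(), transitions = character(),
                         pre = NULL, post = NULL,
                         source = "", notes = "") {
  places <- as.character(places)
  transitions <- as.character(transitions)
  if (anyDuplicated(places)) stop("duplicate place names")
  if (anyDuplicated(transitions)) stop("duplicate transition names")
  pre <- normalize_arcs(pre, transitions, places, "pre")
  post <- normalize_arcs(post, transitions, places, "post")
  structure(
    list(places = places, transitions = transitions,
         pre = pre, post = post,
         source = source, notes = notes),
    class = "reaction_net"
  )
}

# Coerce one arc list to canonical form: one named integer vector of
# strictly positive weights per transition, unknown places rejected.
normalize_arcs <- function(arcs, transitions, places, what) {
  if (is.null(arcs)) arcs <- stats::setNames(vector("list", length(transitions)), transitions)
  out <- stats::setNames(vector("list", length(transitions)), transitions)
  for (tr in transitions) {
    w <- arcs[[tr]]
    if (is.null(w) || length(w) == 0) {
      out[[tr]] <- stats::setNames(integer(0), character(0))
      next
    }
    if (is.null(names(w)) || any(names(w) == ""))
      stop("unnamed ", what, " weights for transition '", tr, "'")
    if (any(w != floor(w)) || any(w < 0))
      stop("arc weights must be natural numbers (transition '", tr, "')")
    w <- w[w > 0]
    unknown <- setdiff(names(w), places)
    if (length(unknown))
      stop("unknown place(s) in ", what, " of '", tr, "': ",
           paste(unknown, collapse = ", "))
    if (anyDuplicated(names(w))) {
      w <- tapply(as.integer(w), names(w), sum)
      w <- stats::setNames(as.integer(w), names(w))
    }
    # keep deterministic order: by place declaration order
    w <- w[order(match(names(w), places))]
    storage.mode(w) <- "integer"
    out[[tr]] <- w
  }
  out
}

#' @export
print.reaction_net <- function(x, ...) {
  cat("Reaction network (Petri net): ",
      length(x$places), " places, ", length(x$transitions), " transitions\n",
      sep = "")
  if (nzchar(x$source)) cat("  source: ", x$source, "\n", sep = "")
  n <- length(x$transitions)
  show <- seq_len(min(n, 12L))
  for (i in show)
    cat("  ", format_reaction(x, x$transitions[i]), "\n", sep = "")
  if (n > 12L) cat("  ... (", n - 12L, " more)\n", sep = "")
  invisible(x)
}

format_side <- function(w) {
  if (length(w) == 0) return("_")
  paste(ifelse(w == 1L, names(w), paste0(w, "*", names(w))), collapse = " + ")
}

format_reaction <- function(net, tr) {
  paste0(tr, ": ", format_side(net$pre[[tr]]), " => ", format_side(net$post[[tr]]))
}

#' Number of places / transitions of a net
#' @param net a `reaction_net`.
#' @return an integer count.
#' @export
n_places <- function(net) length(net$places)

#' @rdname n_places
#' @export
n_transitions <- function(net) length(net$transitions)

# Dense t x p weight matrix for one arc list.
arc_matrix <- function(net, arcs) {
  m <- matrix(0L, nrow = length(net$transitions), ncol = length(net$places),
              dimnames = list(net$transitions, net$places))
  for (tr in net$transitions) {
    w <- arcs[[tr]]
    if (length(w)) m[tr, names(w)] <- w
  }
  m
}

#' Pre- and post-condition matrices of a net
#'
#' `pre_matrix()[i, j]` is the number of tokens transition `i` consumes from
#' place `j`; `post_matrix()` the number it produces.
#' @param net a `reaction_net`.
#' @return an integer transitions-by-places matrix with dimnames.
#' @export
pre_matrix <- function(net) arc_matrix(net, net$pre)

#' @rdname pre_matrix
#' @export
post_matrix <- function(net) arc_matrix(net, net$post)

#' Incidence matrix of a Petri net
#'
#' The entry for (transition i, place j) is the number of tokens of place j
#' produced by one firing of i minus the number consumed, i.e.
#' `post - pre`.  A vector `V` of place weights is a P-invariant exactly
#' when `incidence(net) %*% V == 0`.
#'
#' @param net a `reaction_net`.
#' @return an integer transitions-by-places matrix.
#' @export
incidence <- function(net) post_matrix(net) - pre_matrix(net)

#' Transpose a Petri net (place/transition dual)
#'
#' Swaps the roles of places and transitions so that T-invariant problems
#' become P-invariant problems on the transposed net: the incidence matrix
#' of the transposed net is the matrix transpose of the original's.
#' Transposing twice gives back the original net.
#'
#' @param net a `reaction_net`.
#' @return a `reaction_net` with `n_transitions(net)` places and
#'   `n_places(net)` transitions.
#' @export
transpose_net <- function(net) {
  pre <- pre_matrix(net)   # t x p
  post <- post_matrix(net)
  new_pre <- stats::setNames(vector("list", length(net$places)), net$places)
  new_post <- new_pre
  for (j in seq_along(net$places)) {
    pj <- net$places[j]
    wpre <- stats::setNames(pre[, j], net$transitions)
    wpost <- stats::setNames(post[, j], net$transitions)
    new_pre[[pj]] <- wpre[wpre > 0]
    new_post[[pj]] <- wpost[wpost > 0]
  }
  reaction_net(
    places = net$transitions, transitions = net$places,
    pre = new_pre, post = new_post,
    source = if (nzchar(net$source)) paste0("transpose(", net$source, ")") else "",
    notes = net$notes
  )
}

#' Serialize a net in the plain-text reaction dialect
#'
#' Writes one labelled reaction per line, `name: LHS => RHS`, with sides as
#' `+`-separated `k*Species` terms and an empty side left blank.  The
#' output parses back (with [parse_reactions()]) to an identical net.
#'
#' @param net a `reaction_net`.
#' @param path optional file path; if `NULL` the text is returned.
#' @return the serialized text, invisibly when written to a file.
#' @export
write_reactions <- function(net, path = NULL) {
  side <- function(w) {
    if (length(w) == 0) return("")
    paste(ifelse(w == 1L, names(w), paste0(w, "*", names(w))), collapse = " + ")
  }
  lines <- vapply(net$transitions, function(tr)
    paste0(tr, ": ", side(net$pre[[tr]]), " => ", side(net$post[[tr]])), "")
  # the "#!places" pragma pins the place list and its declaration order,
  # which first-occurrence parsing could not otherwise reconstruct
  # (isolated places, or construction order differing from use order)
  if (length(net$places))
    lines <- c(paste0("#!places ", paste(net$places, collapse = " ")), lines)
  text <- paste(lines, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}

#' Dump a net as JSON
#'
#' @param net a `reaction_net`.
#' @return a JSON string listing places, transitions and the pre/post arc
#'   weights of every transition.
#' @export
net_to_json <- function(net) {
  arcs <- function(a) lapply(a, function(w) as.list(w))
  jsonlite::toJSON(
    list(places = net$places, transitions = net$transitions,
         pre = arcs(net$pre), post = arcs(net$post)),
    auto_unbox = TRUE, pretty = TRUE
  )
}
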