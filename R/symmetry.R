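#' Detect equality classes of places (parallel-place symmetry)
#'
#' Places with identical arc patterns — every transition touches them
#' with the same pre and post weights — are interchangeable in every
#' invariant, siphon and trap.  They occur only in the context of their
#' sum, which can be replaced by a single representative variable before
#' solving; a basis with exponentially many symmetric members then
#' collapses to a few reduced vectors.
#'
#' With `proportional = TRUE`, detection generalizes to places whose arc
#' columns are proportional (member i's weights are `k_i` times a shared
#' per-transition base weight).  Such groups are reported for inspection
#' but are not merged by the computation paths: when the `k_i` differ,
#' the value of the merged sum constrains which members can realize it
#' (a divisibility condition), so support-minimality in the reduced
#' space no longer corresponds to support-minimality in the original —
#' only the equal-pattern ("parallel") case admits an exact
#' merge-then-expand round trip.
#'
#' Isolated places (all-zero columns) are never grouped; each keeps its
#' own trivial unit invariant.
#'
#' @param net a [reaction_net()].
#' @param proportional also group places whose columns are proportional
#'   rather than identical (reporting only, see above).
#' @return a list of merge groups, each a list with `members` (place
#'   names, declaration order), `coefficients` (named `k_i`, the gcd of
#'   each member's column), `merged_id` (fresh place name) and `scale`
#'   (`gcd(k_i)`).
#' @export
detect_groups <- function(net, proportional = FALSE) {
  p <- n_places(net)
  if (p < 2 || n_transitions(net) == 0) return(list())
  pre <- pre_matrix(net)
  post <- post_matrix(net)
  sig <- rbind(pre, post)               # 2t x p; column = full arc pattern
  keys <- character(p)
  kvec <- numeric(p)
  for (j in seq_len(p)) {
    col <- sig[, j]
    g <- gcd_all(col)
    if (g == 0) { keys[j] <- NA_character_; next }  # isolated place
    kvec[j] <- g
    keys[j] <- if (proportional) paste(col / g, collapse = ",")
               else paste(col, collapse = ",")
  }
  groups <- list()
  for (key in unique(keys[!is.na(keys)])) {
    members_idx <- which(!is.na(keys) & keys == key)
    if (length(members_idx) < 2) next
    members <- net$places[members_idx]
    k <- stats::setNames(as.integer(kvec[members_idx]), members)
    mid <- paste0("SUM_", members[1])
    while (mid %in% net$places) mid <- paste0(mid, "_")
    groups[[length(groups) + 1L]] <- list(
      members = members, coefficients = k, merged_id = mid,
      scale = as.integer(gcd_all(k)))
  }
  groups
}

#' Merge equality classes into a reduced net
#'
#' Each group's members are replaced by one representative place carrying
#' the members' common arc column; the representative variable stands for
#' the plain sum of the member variables.  Places outside any group are
#' copied verbatim; the reduced place count is `p - sum(|group| - 1)`.
#' Only parallel groups (identical member columns, as produced by
#' [detect_groups()] with its default settings) can be merged.
#'
#' @param net a [reaction_net()].
#' @param groups output of [detect_groups()] (or a subset; must be
#'   disjoint and valid for `net`).
#' @return a symmetry mapping: a list with `groups`, `reduced_net`,
#'   `untouched` (places copied verbatim) and `original_places`.
#' @export
merge_net <- function(net, groups) {
  all_members <- unlist(lapply(groups, `[[`, "members"))
  if (anyDuplicated(all_members)) stop("overlapping merge groups")
  if (length(setdiff(all_members, net$places)))
    stop("merge group references unknown places")
  if (length(groups) == 0) {
    return(list(groups = list(), reduced_net = net,
                untouched = net$places, original_places = net$places))
  }
  pre <- pre_matrix(net)
  post <- post_matrix(net)
  for (g in groups) {
    cols <- rbind(pre, post)[, g$members, drop = FALSE]
    if (any(cols != cols[, 1]))
      stop("group {", paste(g$members, collapse = ", "),
           "} is not parallel (member arc patterns differ); ",
           "only equal-pattern groups can be merged")
  }
  # reduced place list keeps declaration order, the representative sitting
  # at the position of the group's first member and carrying its column
  red_places <- character(0)
  col_of <- character(0)
  for (p in net$places) {
    gi <- which(vapply(groups, function(g) p %in% g$members, TRUE))
    if (length(gi) == 0) {
      red_places <- c(red_places, p)
      col_of <- c(col_of, p)
    } else if (groups[[gi]]$members[1] == p) {
      red_places <- c(red_places, groups[[gi]]$merged_id)
      col_of <- c(col_of, p)
    }
  }
  red_pre <- pre[, col_of, drop = FALSE]
  red_post <- post[, col_of, drop = FALSE]
  colnames(red_pre) <- colnames(red_post) <- red_places
  reduced <- net_from_matrices(red_places, net$transitions, red_pre, red_post,
                               source = net$source)
  list(groups = groups, reduced_net = reduced,
       untouched = setdiff(net$places, all_members),
       original_places = net$places)
}

net_from_matrices <- function(places, transitions, pre, post, source = "") {
  mk <- function(m) {
    out <- stats::setNames(vector("list", length(transitions)), transitions)
    for (i in seq_along(transitions)) {
      w <- stats::setNames(m[i, ], places)
      out[[transitions[i]]] <- w[w > 0]
    }
    out
  }
  reaction_net(places, transitions, mk(pre), mk(post), source = source)
}

# All solutions of sum(a_i) = d with 0 <= a_i <= cap, as a list of
# integer vectors of length g.
compositions_of <- function(g, d, cap = Inf) {
  if (d == 0) return(list(integer(g)))
  out <- list()
  rec <- function(i, rem, acc) {
    if (i > g) {
      if (rem == 0) out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    left_cap <- cap * (g - i)   # what the remaining members can absorb
    lo <- max(0, rem - left_cap)
    hi <- min(rem, cap)
    if (lo > hi) return(invisible())
    for (v in lo:hi) {
      acc[i] <- v
      rec(i + 1L, rem - v, acc)
    }
  }
  rec(1L, d, integer(g))
  out
}

# Support-minimal compositions of sum(a_i) = d with 0 <= a_i <= cap.
# When d fits one member the minimal ones are exactly the g singletons;
# otherwise (d > cap) every composition uses the fewest members possible
# and minimality must be filtered explicitly.
minimal_compositions <- function(g, d, cap = Inf) {
  if (d == 0) return(list(integer(g)))
  if (d <= cap) {
    return(lapply(seq_len(g), function(i) {
      a <- integer(g); a[i] <- as.integer(d); a
    }))
  }
  sols <- compositions_of(g, d, cap)
  supports <- lapply(sols, function(a) which(a > 0))
  keep <- rep(TRUE, length(sols))
  for (i in seq_along(sols)) {
    for (j in seq_along(sols)) {
      if (i != j && keep[i] &&
          length(supports[[j]]) < length(supports[[i]]) &&
          all(supports[[j]] %in% supports[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sols[keep]
}

#' Expand a reduced-net basis back to the original places
#'
#' Each basis vector with value `d` on a merged place yields, per group,
#' the distributions of `d` over the group's members (solutions of
#' `sum(a_i) = d` with each member capped at `member_bound`); the cross
#' product across groups is combined with the untouched weights.
#'
#' `mode = "strict"` keeps only support-minimal distributions per group,
#' filters the full expanded set to inclusion-minimal supports in
#' gcd-normal form, and keeps one canonical (lexicographically least)
#' vector per support — the definitional contract for a minimal
#' semi-positive invariant basis.  `mode = "paper"` emits every
#' distribution whose member values are non-decreasing along the group's
#' declaration order (the conventional symmetry-breaking order
#' `A1 <= A2 <= ...`), which also includes support-non-minimal vectors
#' when `d > 1`.
#'
#' @param basis a list of named weight vectors over the reduced net's
#'   places (e.g. `minimal_invariants(..., compressed = TRUE)$vectors`).
#' @param mapping the symmetry mapping from [merge_net()].
#' @param mode `"strict"` or `"paper"`.
#' @param member_bound cap on expanded member weights.
#' @return a list of named weight vectors over the original places.
#' @export
expand_basis <- function(basis, mapping, mode = c("strict", "paper"),
                         member_bound = Inf) {
  mode <- match.arg(mode)
  groups <- mapping$groups
  merged_ids <- vapply(groups, `[[`, "", "merged_id")
  out <- list()
  for (v in basis) {
    parts <- list(v[setdiff(names(v), merged_ids)])
    for (g in groups) {
      d <- if (g$merged_id %in% names(v)) v[[g$merged_id]] else 0L
      comps <- if (mode == "strict")
        minimal_compositions(length(g$members), d, member_bound)
      else {
        all_c <- compositions_of(length(g$members), d, member_bound)
        Filter(function(a) all(diff(a) >= 0), all_c)
      }
      if (length(comps) == 0) { parts <- list(); break }
      parts <- unlist(lapply(parts, function(base) {
        lapply(comps, function(a) {
          w <- stats::setNames(as.integer(a), g$members)
          c(base, w[w > 0])
        })
      }), recursive = FALSE)
    }
    out <- c(out, parts)
  }
  out <- Filter(function(v) length(v) > 0, out)
  if (mode == "strict") {
    out <- lapply(out, normalize_invariant)
    out <- minimal_support_filter(out)
    out <- canonical_per_support(out, mapping$original_places)
  }
  out
}

# Keep vectors whose support is inclusion-minimal within the list.
minimal_support_filter <- function(vectors) {
  supports <- lapply(vectors, names)
  keep <- rep(TRUE, length(vectors))
  for (i in seq_along(vectors)) {
    for (j in seq_along(vectors)) {
      if (i == j || !keep[i]) next
      si <- supports[[i]]; sj <- supports[[j]]
      if (length(sj) < length(si) && all(sj %in% si)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  vectors[keep]
}

# One vector per support: the lexicographically least (by weights in
# place declaration order) — the same representative the search itself
# would find first.
canonical_per_support <- function(vectors, places) {
  if (length(vectors) <= 1) return(vectors)
  full <- lapply(vectors, function(v) {
    w <- stats::setNames(integer(length(places)), places)
    w[names(v)] <- v
    w
  })
  skey <- vapply(vectors, function(v)
    paste(sort(match(names(v), places)), collapse = ","), "")
  keep <- logical(length(vectors))
  for (s in unique(skey)) {
    idx <- which(skey == s)
    best <- idx[1]
    for (i in idx[-1]) {
      a <- full[[i]]; b <- full[[best]]
      dpos <- which(a != b)
      if (length(dpos) && a[dpos[1]] < b[dpos[1]]) best <- i
    }
    keep[best] <- TRUE
  }
  vectors[keep]
}

#' Count the strict expansion of a reduced basis without enumerating it
#'
#' The number of support-minimal expanded vectors is combinatorial: per
#' basis vector, the product over merge groups of the number of minimal
#' distributions of the merged value; summed over the basis.  Computed
#' with exact decimal arithmetic, so counts like 10^10 are returned
#' exactly.
#'
#' @param basis a list of reduced-net weight vectors.
#' @param mapping the symmetry mapping from [merge_net()].
#' @param member_bound cap on expanded member weights.
#' @return the count as a decimal string.
#' @export
count_expanded <- function(basis, mapping, member_bound = Inf) {
  groups <- mapping$groups
  total <- "0"
  for (v in basis) {
    term <- "1"
    for (g in groups) {
      d <- if (g$merged_id %in% names(v)) v[[g$merged_id]] else 0L
      # several weightings can share one support (d > bound forces multi-
      # member splits); the basis keeps one canonical vector per support,
      # so distinct supports are what gets counted
      nc <- if (d == 0) 1L
      else if (d <= member_bound) length(g$members)
      else length(unique(lapply(
        minimal_compositions(length(g$members), d, member_bound),
        function(a) which(a > 0))))
      term <- big_mul(term, big_from_num(nc))
    }
    total <- big_add(total, term)
  }
  total
}
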