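# Independent brute-force oracles and fixture builders shared by the
# suite.  The oracles enumerate exhaustively and never touch the
# constraint engine, so they can referee its output.

inv_key <- function(v) {
  v <- v[order(names(v))]
  paste(names(v), v, sep = "=", collapse = ",")
}
set_key <- function(s) paste(sort(s), collapse = ",")

lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

gcd_pair <- function(a, b) { while (b != 0) { t <- a %% b; a <- b; b <- t }; a }

# All gcd-normalized canonical minimal-support solutions of the invariant
# system within the bound: full grid enumeration, inclusion-minimal
# supports, lexicographically least representative per support.
brute_invariants <- function(net, relation = "eq", bound = 4) {
  p <- n_places(net)
  grid <- as.matrix(expand.grid(rep(list(0:bound), p))[, p:1, drop = FALSE])
  colnames(grid) <- net$places
  D <- pre_matrix(net) - post_matrix(net)   # V.L - V.R per transition
  lhs <- grid %*% t(D)
  ok <- switch(relation,
               eq = rowSums(lhs != 0) == 0,
               le = rowSums(lhs > 0) == 0,
               ge = rowSums(lhs < 0) == 0)
  ok <- ok & rowSums(grid) > 0
  sols <- grid[ok, , drop = FALSE]
  if (nrow(sols) == 0) return(list())
  supp <- apply(sols, 1, function(v) paste(which(v > 0), collapse = ","))
  usupp <- unique(supp)
  sets <- lapply(usupp, function(s) as.integer(strsplit(s, ",")[[1]]))
  minimal <- vapply(seq_along(sets), function(i)
    !any(vapply(seq_along(sets), function(j)
      i != j && length(sets[[j]]) < length(sets[[i]]) &&
        all(sets[[j]] %in% sets[[i]]), TRUE)), TRUE)
  out <- list()
  for (s in usupp[minimal]) {
    cand <- sols[supp == s, , drop = FALSE]
    best <- cand[1, ]
    if (nrow(cand) > 1)
      for (r in 2:nrow(cand)) if (lex_less(cand[r, ], best)) best <- cand[r, ]
    v <- best[best > 0]
    g <- Reduce(gcd_pair, v)
    out[[length(out) + 1L]] <- stats::setNames(as.integer(v / g), names(v))
  }
  out
}

# All inclusion-minimal non-empty traps/siphons by subset enumeration
# over the definitional checkers.
brute_place_sets <- function(net, kind = c("trap", "siphon")) {
  kind <- match.arg(kind)
  p <- n_places(net)
  stopifnot(p <= 16)
  chk <- if (kind == "trap") is_trap else is_siphon
  subs <- list()
  for (m in 1:(2^p - 1)) {
    S <- net$places[bitwAnd(m, 2^(0:(p - 1))) > 0]
    if (chk(net, S)) subs[[length(subs) + 1L]] <- S
  }
  minimal <- vapply(seq_along(subs), function(i)
    !any(vapply(seq_along(subs), function(j)
      i != j && length(subs[[j]]) < length(subs[[i]]) &&
        all(subs[[j]] %in% subs[[i]]), TRUE)), TRUE)
  subs[minimal]
}

# All solutions of an fd store by raw grid enumeration against the
# direct constraint evaluator (completeness oracle for the search).
brute_fd_solutions <- function(store) {
  n <- length(store$vars)
  grid <- as.matrix(expand.grid(stats::setNames(
    lapply(seq_len(n), function(i) store$lo[i]:store$hi[i]), store$vars)))
  keep <- apply(grid, 1, function(x) fd_evaluate(store, x))
  lapply(which(keep), function(r) stats::setNames(as.integer(grid[r, ]), store$vars))
}

# A random net with a few genuinely parallel places appended, so
# symmetry merging actually triggers.  Fully determined by `seed`; the
# global RNG state is restored afterwards.
random_parallel_net <- function(seed, max_base_places = 5) {
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed * 7919 + 1)
  p <- sample(2:max_base_places, 1)
  t <- sample(2:5, 1)
  ncopy <- sample(1:3, 1)
  origin <- sample(p, ncopy, replace = TRUE)
  base <- random_net(p = p, t = t, max_weight = 2, density = 0.6, seed = seed)
  pre <- pre_matrix(base)
  post <- post_matrix(base)
  for (i in seq_len(ncopy)) {
    j <- origin[i]
    nm <- paste0(colnames(pre)[j], "_c", i)
    pre <- cbind(pre, pre[, j])
    post <- cbind(post, post[, j])
    colnames(pre)[ncol(pre)] <- colnames(post)[ncol(post)] <- nm
  }
  petrinv:::net_from_matrices(colnames(pre), base$transitions, pre, post,
                              source = paste0("parallel_seed", seed))
}

expect_same_vectors <- function(a, b) {
  expect_setequal(vapply(a, inv_key, ""), vapply(b, inv_key, ""))
}

expect_same_sets <- function(a, b) {
  expect_setequal(vapply(a, set_key, ""), vapply(b, set_key, ""))
}
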