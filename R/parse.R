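#' Parse a plain-text reaction system into a Petri net
#'
#' The dialect is one reaction per line:
#' \preformatted{
#'   # a comment
#'   complexation: A + E => A-E
#'   A-E => A + E
#'   binding: 2*X + Y <=> Z        # reversible: split into two transitions
#' }
#' Sides are `+`-separated terms, each `k*Species` or bare `Species` with
#' `k` a positive decimal integer.  Species names match
#' `[A-Za-z0-9_~{}-]+`.  A reversible arrow `<=>` produces two transitions,
#' forward then backward (named `r` and `r_rev`).  An empty side is legal
#' when the other side is not (source/sink reactions).  `#` starts a
#' comment; blank lines are ignored; an optional `name:` prefix labels the
#' transition; a `#!places A B C` pragma pins the full place list (used to
#' round-trip nets with isolated places).
#'
#' Species become places in order of first occurrence.
#'
#' @param text the reaction source, as a single string or a character
#'   vector of lines.
#' @param source provenance label stored on the net.
#' @return a [reaction_net()].
#' @examples
#' enz <- parse_reactions("A + E <=> AE\nAE => B + E")
#' enz$transitions
#' @export
parse_reactions <- function(text, source = "reactions") {
  if (length(text) == 1 && grepl("\n", text)) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  species_rx <- "^[A-Za-z0-9_~{}-]+$"
  places <- character()
  declared <- character()
  transitions <- character()
  pre <- list()
  post <- list()
  auto <- 0L

  see_species <- function(s) {
    if (!(s %in% places)) places <<- c(places, s)
  }

  parse_side <- function(side, lineno) {
    side <- trimws(side)
    if (side == "") return(stats::setNames(integer(0), character(0)))
    # strsplit drops trailing empty fields, so catch stray "+" up front
    if (grepl("^\\+|\\+\\s*(\\+|$)", side))
      stop("line ", lineno, ": empty term (stray '+')")
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    w <- integer(0)
    for (term in terms) {
      if (term == "")
        stop("line ", lineno, ": empty term (stray '+')")
      parts <- strsplit(term, "*", fixed = TRUE)[[1]]
      if (length(parts) == 1) {
        k <- 1L; sp <- trimws(parts[1])
      } else if (length(parts) == 2) {
        ktxt <- trimws(parts[1]); sp <- trimws(parts[2])
        if (!grepl("^[0-9]+$", ktxt))
          stop("line ", lineno, ": coefficient '", ktxt, "' is not a positive integer")
        k <- as.integer(ktxt)
        if (k <= 0) stop("line ", lineno, ": zero coefficient for '", sp, "'")
      } else stop("line ", lineno, ": malformed term '", term, "'")
      if (!grepl(species_rx, sp))
        stop("line ", lineno, ": invalid species name '", sp, "'")
      see_species(sp)
      w[sp] <- (if (sp %in% names(w)) w[[sp]] else 0L) + k
    }
    w
  }

  add_transition <- function(name, lhs, rhs) {
    if (name %in% transitions)
      stop("duplicate transition name '", name, "'")
    transitions <<- c(transitions, name)
    pre[[name]] <<- lhs
    post[[name]] <<- rhs
  }

  for (i in seq_along(text)) {
    line <- text[i]
    if (grepl("^\\s*#!places\\b", line)) {
      declared <- strsplit(trimws(sub("^\\s*#!places", "", line)), "\\s+")[[1]]
      next
    }
    line <- sub("#.*$", "", line)
    line <- trimws(line)
    if (line == "") next
    name <- NULL
    m <- regmatches(line, regexec("^([A-Za-z0-9_~{}-]+)\\s*:\\s*(.*)$", line))[[1]]
    if (length(m)) {
      name <- m[2]
      line <- m[3]
    }
    reversible <- grepl("<=>", line, fixed = TRUE)
    arrow <- if (reversible) "<=>" else "=>"
    halves <- strsplit(line, arrow, fixed = TRUE)[[1]]
    if (!grepl(arrow, line, fixed = TRUE) || length(halves) > 2)
      stop("line ", i, ": expected exactly one '=>' or '<=>'")
    lhs_txt <- halves[1]
    rhs_txt <- if (length(halves) == 2) halves[2] else ""
    if (grepl("=>", lhs_txt, fixed = TRUE) || grepl("=>", rhs_txt, fixed = TRUE))
      stop("line ", i, ": expected exactly one '=>' or '<=>'")
    lhs <- parse_side(lhs_txt, i)
    rhs <- parse_side(rhs_txt, i)
    if (length(lhs) == 0 && length(rhs) == 0)
      stop("line ", i, ": both sides are empty")
    if (is.null(name)) {
      auto <- auto + 1L
      name <- paste0("t", auto)
      while (name %in% transitions) {
        auto <- auto + 1L
        name <- paste0("t", auto)
      }
    }
    add_transition(name, lhs, rhs)
    if (reversible) add_transition(paste0(name, "_rev"), rhs, lhs)
  }

  if (length(declared)) {
    extra <- setdiff(places, declared)
    if (length(extra))
      stop("#!places pragma omits species used in reactions: ",
           paste(extra, collapse = ", "))
    places <- declared
  }
  reaction_net(places, transitions, pre, post, source = source)
}

#' Read a reaction file
#'
#' @param path path to a file in the reaction dialect of
#'   [parse_reactions()].
#' @return a [reaction_net()].
#' @export
read_reactions <- function(path) {
  parse_reactions(readLines(path, warn = FALSE), source = basename(path))
}
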