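#' Read an SBML document as a Petri net
#'
#' Supports SBML Level 2/3 core read-only: `listOfSpecies`,
#' `listOfReactions` with reactants, products and modifiers, per-reference
#' `stoichiometry` (default 1) and the `reversible` flag (default `true`
#' in Level 2; Level 3 documents must state it, and an absent flag is
#' also treated as reversible there).
#'
#' Species become places — including boundary-condition species, which are
#' ordinary places here.  Each reaction becomes one transition, or two
#' (forward then `_rev`) when reversible.  Modifiers become read arcs:
#' weight 1 in both pre and post of their transition, so they contribute
#' nothing to the incidence matrix (and hence to invariants) but do count
#' for siphon/trap pre/post-set logic.
#'
#' Stoichiometries must be positive integers.  With
#' `scale_rationals = TRUE`, a reaction whose stoichiometries are decimal
#' fractions (e.g. `0.5`) is rescaled by the least common multiple of the
#' denominators; otherwise such a reaction is rejected by name.
#'
#' @param x an SBML document: a file path, a literal XML string, or an
#'   `xml2` document.
#' @param scale_rationals scale fractional stoichiometries to integers
#'   instead of rejecting them.
#' @return a [reaction_net()].
#' @export
read_sbml <- function(x, scale_rationals = FALSE) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("no <model> element in SBML document")

  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  places <- xml2::xml_attr(sp_nodes, "id")
  if (any(is.na(places))) stop("species without id attribute")

  transitions <- character()
  pre <- list()
  post <- list()

  rx_nodes <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  for (rx in rx_nodes) {
    rid <- xml2::xml_attr(rx, "id")
    if (is.na(rid)) rid <- paste0("r", length(transitions) + 1L)
    rev_attr <- xml2::xml_attr(rx, "reversible")
    reversible <- is.na(rev_attr) || identical(rev_attr, "true") || identical(rev_attr, "1")

    refs <- function(kind) {
      nodes <- xml2::xml_find_all(rx, paste0("./", kind, "/speciesReference"))
      ids <- xml2::xml_attr(nodes, "species")
      st <- xml2::xml_attr(nodes, "stoichiometry")
      st[is.na(st)] <- "1"
      list(species = ids, stoich = st)
    }
    reac <- refs("listOfReactants")
    prod <- refs("listOfProducts")
    mods <- xml2::xml_attr(
      xml2::xml_find_all(rx, "./listOfModifiers/modifierSpeciesReference"),
      "species")

    st_all <- sbml_stoich(c(reac$stoich, prod$stoich), rid, scale_rationals)
    nr <- length(reac$species)
    wre <- collapse_weights(reac$species, st_all[seq_len(nr)])
    wpr <- collapse_weights(prod$species, st_all[seq_len(length(prod$species)) + nr])
    for (m in mods) {
      wre[m] <- (if (m %in% names(wre)) wre[[m]] else 0L) + 1L
      wpr[m] <- (if (m %in% names(wpr)) wpr[[m]] else 0L) + 1L
    }
    unknown <- setdiff(c(names(wre), names(wpr)), places)
    if (length(unknown))
      stop("reaction '", rid, "' references unknown species: ",
           paste(unknown, collapse = ", "))

    transitions <- c(transitions, rid)
    pre[[rid]] <- wre
    post[[rid]] <- wpr
    if (reversible) {
      rrev <- paste0(rid, "_rev")
      transitions <- c(transitions, rrev)
      pre[[rrev]] <- wpr
      post[[rrev]] <- wre
    }
  }
  src <- xml2::xml_attr(model, "id")
  reaction_net(places, transitions, pre, post,
               source = if (is.na(src)) "sbml" else src)
}

# Turn SBML stoichiometry strings for one reaction into positive integers,
# optionally rescaling the whole reaction by the lcm of decimal denominators.
sbml_stoich <- function(st, rid, scale_rationals) {
  if (length(st) == 0) return(integer(0))
  num <- suppressWarnings(as.numeric(st))
  if (any(is.na(num)) || any(num <= 0))
    stop("reaction '", rid, "' has a non-positive or unreadable stoichiometry")
  frac <- function(s) {
    # decimal string -> c(numerator, denominator), exactly
    if (grepl("^[0-9]+$", s)) return(c(as.numeric(s), 1))
    m <- regmatches(s, regexec("^([0-9]*)\\.([0-9]+)$", s))[[1]]
    if (!length(m)) return(NULL)
    den <- 10^nchar(m[3])
    num <- (if (m[2] == "") 0 else as.numeric(m[2])) * den + as.numeric(m[3])
    g <- gcd2(num, den)
    c(num / g, den / g)
  }
  fr <- lapply(st, frac)
  if (any(vapply(fr, is.null, TRUE)))
    stop("reaction '", rid, "' has a non-integer stoichiometry")
  dens <- vapply(fr, `[`, 0, 2)
  if (all(dens == 1))
    return(as.integer(vapply(fr, `[`, 0, 1)))
  if (!scale_rationals)
    stop("reaction '", rid, "' has non-integer stoichiometry ",
         "(set scale_rationals = TRUE to rescale)")
  scale <- Reduce(lcm2, dens)
  as.integer(vapply(fr, function(f) f[1] * (scale / f[2]), 0))
}

collapse_weights <- function(species, w) {
  out <- integer(0)
  for (i in seq_along(species)) {
    s <- species[i]
    out[s] <- (if (s %in% names(out)) out[[s]] else 0L) + as.integer(w[i])
  }
  out
}

gcd2 <- function(a, b) {
  while (b != 0) { tmp <- a %% b; a <- b; b <- tmp }
  abs(a)
}

lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  abs(a / gcd2(a, b) * b)
}

#' Greatest common divisor / least common multiple of a vector
#' @param x a numeric vector of non-negative integers.
#' @return a single number.
#' @keywords internal
gcd_all <- function(x) {
  x <- x[x != 0]
  if (length(x) == 0) return(0)
  Reduce(gcd2, x)
}

#' @rdname gcd_all
#' @keywords internal
lcm_all <- function(x) {
  x <- x[x != 0]
  if (length(x) == 0) return(1)
  Reduce(lcm2, x)
}
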