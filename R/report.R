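#' Run one analysis task from a configuration
#'
#' The programmatic core of the command-line tool.  A configuration names
#' one task and its options; the function loads the input, dispatches,
#' and returns the result object together with its serialized report and
#' a provenance log.  Identical inputs and configuration produce
#' byte-identical serialized output (no timestamps or unordered
#' collections leak into reports; timing never enters machine-readable
#' output).
#'
#' @param config a list (or JSON file path) with fields:
#'   \describe{
#'     \item{task}{one of `pinv`, `tinv`, `growinv` (relation `le`),
#'       `shrinkinv` (relation `ge`), `traps`, `siphons`, `generate`.}
#'     \item{input}{path to the input net (except for `generate`).}
#'     \item{format}{`"reactions"` (default) or `"sbml"`.}
#'     \item{bound}{domain bound, default 8.}
#'     \item{complete_bound}{logical: use [complete_bound()] instead.}
#'     \item{symmetry}{logical, default `TRUE`.}
#'     \item{compressed}{logical: report the reduced basis plus the
#'       expanded count instead of enumerating.}
#'     \item{expansion}{`"strict"` (default) or `"paper"`.}
#'     \item{output_format}{`"text"`, `"json"` or `"tsv"`.}
#'     \item{scale_rationals}{SBML option, see [read_sbml()].}
#'     \item{family, x, y, n, p, t, max_weight, density, seed, out}{
#'       options of the `generate` task (see [classic_net()],
#'       [random_net()] and friends).}
#'   }
#' @return a list of class `petrinv_report`: `result` (the computed
#'   object), `output` (character vector of report lines), `log`
#'   (character vector of provenance lines).
#' @export
run_task <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(list(
    format = "reactions", bound = 8, complete_bound = FALSE,
    symmetry = TRUE, compressed = FALSE, expansion = "strict",
    output_format = "text", scale_rationals = FALSE), config)
  if (is.null(cfg$task)) stop("config must name exactly one task")
  known <- c("pinv", "tinv", "growinv", "shrinkinv", "traps", "siphons",
             "generate")
  if (!cfg$task %in% known) stop("unknown task '", cfg$task, "'")
  if (cfg$bound < 1) stop("bound must be >= 1")

  if (cfg$task == "generate") return(run_generate(cfg))

  if (is.null(cfg$input)) stop("task '", cfg$task, "' needs an input file")
  net <- switch(cfg$format,
    reactions = read_reactions(cfg$input),
    sbml = read_sbml(cfg$input, scale_rationals = isTRUE(cfg$scale_rationals)),
    stop("unknown input format '", cfg$format, "'"))
  log <- sprintf("net: %d places, %d transitions (%s)",
                 n_places(net), n_transitions(net), cfg$format)

  inv_task <- c(pinv = "eq", tinv = "eq", growinv = "le", shrinkinv = "ge")
  if (cfg$task %in% names(inv_task)) {
    basis <- minimal_invariants(
      net, mode = if (cfg$task == "tinv") "T" else "P",
      relation = inv_task[[cfg$task]],
      bound = cfg$bound, use_complete_bound = isTRUE(cfg$complete_bound),
      symmetry = isTRUE(cfg$symmetry), compressed = isTRUE(cfg$compressed),
      expansion = cfg$expansion)
    log <- c(log,
             sprintf("symmetry groups: %d", length(basis$groups)),
             sprintf("bound: %d (complete: %s)", basis$bound,
                     tolower(basis$complete)),
             sprintf("basis size: %d; expanded count: %s",
                     length(basis$vectors), basis$count_expanded))
    return(report(basis, basis_output(basis, cfg$output_format), log))
  }
  if (cfg$task %in% c("traps", "siphons")) {
    fam <- if (cfg$task == "traps") minimal_traps(net, isTRUE(cfg$symmetry))
           else minimal_siphons(net, isTRUE(cfg$symmetry))
    log <- c(log, sprintf("%s found: %d", cfg$task, length(fam$sets)))
    return(report(fam, sets_output(fam, cfg$output_format), log))
  }
  stop("unknown task '", cfg$task, "'")
}

report <- function(result, output, log) {
  structure(list(result = result, output = output, log = log),
            class = "petrinv_report")
}

#' @export
print.petrinv_report <- function(x, ...) {
  cat(x$output, sep = "\n")
  invisible(x)
}

run_generate <- function(cfg) {
  fam <- cfg$family
  if (is.null(fam)) stop("generate needs a family")
  net <- switch(fam,
    classic = classic_net(cfg$x, cfg$y),
    enzymatic = enzymatic_net(),
    philosophers = philosophers_net(cfg$n),
    trains = circular_trains_net(cfg$x, cfg$y),
    mapk = mapk_cascade(),
    random = random_net(cfg$p, cfg$t, cfg$max_weight %||% 3,
                        cfg$density %||% 0.5, cfg$seed),
    stop("unknown family '", fam, "'"))
  text <- write_reactions(net)
  if (!is.null(cfg$out)) writeLines(text, cfg$out)
  report(net, strsplit(text, "\n")[[1]],
         sprintf("generated %s: %d places, %d transitions",
                 fam, n_places(net), n_transitions(net)))
}

basis_output <- function(basis, format) {
  switch(format,
    text = utils::capture.output(print(basis)),
    json = basis_json(basis),
    tsv = {
      header <- "support_size\tweights"
      rows <- vapply(basis$vectors, function(v)
        paste0(length(v), "\t",
               paste(names(v), v, sep = "=", collapse = ",")), "")
      c(header, rows)
    },
    stop("unknown output format '", format, "'"))
}

basis_json <- function(basis) {
  inv <- lapply(basis$vectors, function(v)
    list(weights = as.list(v), support_size = length(v)))
  strsplit(as.character(jsonlite::toJSON(list(
    mode = basis$mode, relation = basis$relation,
    bound = basis$bound, complete = basis$complete,
    compressed = basis$compressed,
    groups = lapply(basis$groups, function(g)
      list(merged_id = g$merged_id, members = g$members,
           coefficients = as.list(g$coefficients))),
    invariants = inv,
    count_expanded = basis$count_expanded
  ), auto_unbox = TRUE, pretty = TRUE)), "\n")[[1]]
}

sets_output <- function(fam, format) {
  switch(format,
    text = utils::capture.output(print(fam)),
    json = strsplit(as.character(jsonlite::toJSON(list(
      kind = fam$kind,
      sets = lapply(fam$sets, function(s) s[order(match(s, fam$places))]),
      count = length(fam$sets)
    ), auto_unbox = TRUE, pretty = TRUE)), "\n")[[1]],
    tsv = {
      c("size\tmembers",
        vapply(fam$sets, function(s)
          paste0(length(s), "\t", paste(s, collapse = ",")), ""))
    },
    stop("unknown output format '", format, "'"))
}
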