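# Human-readable JSON serialization of structures and fitted networks.
# Schema: {version, nodes, edges[, cpds, fit_metadata]}. Parameters
# round-trip losslessly (17 significant digits uniquely identify a double).

SCHEMA_VERSION <- "1.0"

structure_to_list <- function(s) {
  list(
    nodes = lapply(unname(s$nodes), function(nd) {
      out <- list(name = nd$name, kind = nd$kind)
      if (!is.null(nd$states)) out$states <- as.list(nd$states)
      out
    }),
    edges = if (nrow(s$edges)) {
      lapply(seq_len(nrow(s$edges)),
             function(i) list(from = s$edges$from[i], to = s$edges$to[i]))
    } else list()
  )
}

structure_from_list <- function(x) {
  nodes <- lapply(x$nodes, function(nd) {
    if (is.null(nd$name) || is.null(nd$kind)) stopf("node entry lacks name/kind")
    if (nd$kind == "discrete") discrete_node(nd$name, unlist(nd$states))
    else gaussian_node(nd$name)
  })
  edges <- if (length(x$edges)) {
    data.frame(from = vapply(x$edges, `[[`, character(1), "from"),
               to = vapply(x$edges, `[[`, character(1), "to"),
               stringsAsFactors = FALSE)
  } else NULL
  bn_structure(nodes, edges)
}

#' Save / load a network structure as JSON
#'
#' @param structure A `bn_structure`.
#' @param path File path.
#' @return `save_structure` returns `path` invisibly; `load_structure`
#'   returns the validated `bn_structure`.
#' @export
save_structure <- function(structure, path) {
  stopifnot(inherits(structure, "bn_structure"))
  obj <- c(list(version = SCHEMA_VERSION), structure_to_list(structure))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_structure
#' @export
load_structure <- function(path) {
  x <- jsonlite::read_json(path)
  check_version(x, path)
  structure_from_list(x)
}

check_version <- function(x, path) {
  if (is.null(x$version)) stopf("%s: missing format-version field", path)
  if (!identical(x$version, SCHEMA_VERSION))
    stopf("%s: unsupported format version '%s' (expected %s)",
          path, x$version, SCHEMA_VERSION)
}

#' Save / load a fitted network as JSON
#'
#' Lossless round trip of structure plus all CPD parameters and fit
#' metadata; the file carries a format-version field and loading validates
#' the schema, naming any offending node.
#'
#' @param fit A `bn_fit`.
#' @param path File path.
#' @return `save_network` returns `path` invisibly; `load_network` the
#'   reconstructed `bn_fit`.
#' @export
save_network <- function(fit, path) {
  stopifnot(inherits(fit, "bn_fit"))
  cpds <- lapply(fit$cpds, function(cpd) {
    if (inherits(cpd, "discrete_cpd")) {
      list(type = "discrete", states = as.list(cpd$states),
           parents = as.list(cpd$parents),
           parent_states = lapply(cpd$parent_states, as.list),
           prob = apply(cpd$prob, 2L, as.list, simplify = FALSE),
           counts = as.list(cpd$counts), fallback = as.list(cpd$fallback))
    } else {
      list(type = "clg", dparents = as.list(cpd$dparents),
           dparent_states = lapply(cpd$dparent_states, as.list),
           cparents = as.list(cpd$cparents),
           params = lapply(cpd$params, function(p)
             list(beta0 = p$beta0, beta = as.list(p$beta), sigma2 = p$sigma2,
                  n = p$n %||% NA, fallback = isTRUE(p$fallback))))
    }
  })
  obj <- c(list(version = SCHEMA_VERSION), structure_to_list(fit$structure),
           list(cpds = cpds, fit_metadata = fit$metadata))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  x <- jsonlite::read_json(path)
  check_version(x, path)
  s <- structure_from_list(x)
  cpds <- list()
  for (v in names(s$nodes)) {
    c_x <- x$cpds[[v]]
    if (is.null(c_x)) stopf("%s: missing CPD for node %s", path, v)
    if (identical(c_x$type, "discrete")) {
      states <- unlist(c_x$states)
      pstates <- lapply(c_x$parent_states, unlist)
      prob <- matrix(unlist(lapply(c_x$prob, unlist)),
                     nrow = length(states))
      cpds[[v]] <- discrete_cpd(v, states, unlist(c_x$parents) %||% character(0),
                                pstates, prob,
                                counts = unlist(c_x$counts),
                                fallback = unlist(c_x$fallback))
    } else if (identical(c_x$type, "clg")) {
      params <- lapply(c_x$params, function(p)
        list(beta0 = p$beta0, beta = unlist(p$beta) %||% numeric(0),
             sigma2 = p$sigma2, n = p$n, fallback = isTRUE(p$fallback)))
      cpds[[v]] <- clg_cpd(v, unlist(c_x$dparents) %||% character(0),
                           lapply(c_x$dparent_states, unlist),
                           unlist(c_x$cparents) %||% character(0), params)
    } else stopf("%s: CPD for node %s has unknown type", path, v)
  }
  meta <- x$fit_metadata %||% list()
  bn_fit(s, cpds, metadata = meta)
}
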