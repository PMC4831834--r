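# Typed DAG for conditional linear Gaussian (CLG) networks. Discrete nodes
# carry a state list; Gaussian nodes are scalar. Admissibility: a Gaussian
# node may never be a parent of a discrete node, so that exact inference
# stays closed-form.

#' Declare a discrete or Gaussian node
#'
#' @param name Node name.
#' @param states Ordered character vector of at least two state labels.
#' @return A `node_spec` list with fields `name`, `kind` and (discrete
#'   only) `states`.
#' @export
discrete_node <- function(name, states) {
  if (!is_string(name)) stopf("node name must be a single string")
  if (!is.character(states) || length(states) < 2L || anyDuplicated(states))
    stopf("discrete node %s needs >= 2 distinct states", name)
  structure(list(name = name, kind = "discrete", states = states),
            class = "node_spec")
}

#' @rdname discrete_node
#' @export
gaussian_node <- function(name) {
  if (!is_string(name)) stopf("node name must be a single string")
  structure(list(name = name, kind = "gaussian", states = NULL),
            class = "node_spec")
}

#' Node set for a patient feature table
#'
#' Builds the standard typed node list for grading networks: `grade`
#' (discrete, high/low), `T1WC` (discrete, negative/slight/apparent) and
#' one Gaussian node per continuous feature.
#'
#' @param features Character vector of continuous feature names.
#' @param include_t1wc Include the T1WC node (default TRUE).
#' @return Named list of `node_spec` objects.
#' @export
cohort_nodes <- function(features, include_t1wc = TRUE) {
  nodes <- list(discrete_node("grade", grade_states()))
  if (include_t1wc) nodes <- c(nodes, list(discrete_node("T1WC", t1wc_states())))
  nodes <- c(nodes, lapply(features, gaussian_node))
  stats::setNames(nodes, vapply(nodes, `[[`, character(1), "name"))
}

#' Construct a validated network structure
#'
#' A directed acyclic graph over typed nodes with the CLG admissibility
#' constraint: no Gaussian node is a parent of a discrete node.
#'
#' @param nodes List of node specs from [discrete_node()] / [gaussian_node()].
#' @param edges A two-column matrix or data.frame of directed edges
#'   (`from`, `to`), or `NULL` for an empty edge set.
#' @return An object of class `bn_structure` with fields `nodes` (named
#'   list) and `edges` (data.frame with columns `from`, `to`).
#' @export
bn_structure <- function(nodes, edges = NULL) {
  if (inherits(nodes, "node_spec")) nodes <- list(nodes)
  if (!all(vapply(nodes, inherits, logical(1), "node_spec")))
    stopf("nodes must be node_spec objects")
  nm <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stopf("duplicate node names: %s", nm[duplicated(nm)][1L])
  nodes <- stats::setNames(nodes, nm)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges) <- c("from", "to")
    edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  }
  obj <- structure(list(nodes = nodes, edges = edges), class = "bn_structure")
  validate_structure(obj)
  obj
}

validate_structure <- function(s) {
  nm <- names(s$nodes)
  for (col in c("from", "to")) {
    unknown <- setdiff(s$edges[[col]], nm)
    if (length(unknown)) stopf("edge endpoint not a declared node: %s", unknown[1L])
  }
  if (any(s$edges$from == s$edges$to)) stopf("self-loop edge")
  if (anyDuplicated(paste(s$edges$from, s$edges$to))) stopf("duplicate edge")
  kind <- vapply(s$nodes, `[[`, character(1), "kind")
  bad <- kind[s$edges$from] == "gaussian" & kind[s$edges$to] == "discrete"
  if (any(bad))
    stopf("CLG admissibility violated: gaussian node %s is a parent of discrete node %s",
          s$edges$from[bad][1L], s$edges$to[bad][1L])
  topo_sort(s)  # errors on cycles
  invisible(s)
}

#' Parents of a node
#' @param structure A `bn_structure`.
#' @param node Node name.
#' @return Character vector of parent names (in edge order).
#' @export
parents_of <- function(structure, node) {
  structure$edges$from[structure$edges$to == node]
}

#' Topological order of a structure
#' @param structure A `bn_structure`.
#' @return Character vector of node names, parents before children.
#' @export
topo_sort <- function(structure) {
  nm <- names(structure$nodes)
  indeg <- stats::setNames(integer(length(nm)), nm)
  for (to in structure$edges$to) indeg[to] <- indeg[to] + 1L
  out <- character(0)
  avail <- nm[indeg == 0L]
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    out <- c(out, v)
    ch <- structure$edges$to[structure$edges$from == v]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- c(avail, w)
    }
  }
  if (length(out) != length(nm)) stopf("structure contains a cycle")
  out
}

node_kinds <- function(structure) {
  vapply(structure$nodes, `[[`, character(1), "kind")
}

#' Merge two network structures
#'
#' Union of nodes and edges; shared nodes must agree in kind and states.
#' Used to compose a network learned on one modality-complete subset with
#' one learned on another, sharing the grade (and possibly T1WC) node.
#' The merged structure is re-validated (acyclicity, admissibility).
#'
#' @param a,b `bn_structure` objects.
#' @return A `bn_structure`.
#' @export
merge_structures <- function(a, b) {
  stopifnot(inherits(a, "bn_structure"), inherits(b, "bn_structure"))
  nodes <- a$nodes
  for (nd in b$nodes) {
    if (nd$name %in% names(nodes)) {
      old <- nodes[[nd$name]]
      if (old$kind != nd$kind || !identical(old$states, nd$states))
        stopf("shared node %s has conflicting definitions", nd$name)
    } else nodes[[nd$name]] <- nd
  }
  edges <- unique(rbind(a$edges, b$edges))
  bn_structure(unname(nodes), edges)
}

#' @export
print.bn_structure <- function(x, ...) {
  kind <- node_kinds(x)
  cat(sprintf("CLG network structure: %d nodes (%d discrete, %d gaussian), %d edges\n",
              length(x$nodes), sum(kind == "discrete"), sum(kind == "gaussian"),
              nrow(x$edges)))
  for (v in names(x$nodes)) {
    p <- parents_of(x, v)
    cat(sprintf("  %s [%s]%s\n", v, kind[v],
                if (length(p)) paste0(" <- ", paste(p, collapse = ", ")) else ""))
  }
  invisible(x)
}
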