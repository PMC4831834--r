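# K2 greedy structure search over a fixed node ordering, scored by BIC
# over the CLG likelihood (decomposable: the network score is the sum of
# per-family scores, each computed on the rows complete for that family).
# An exhaustive search over all order-consistent DAGs is provided as an
# exact reference for small node sets.

#' BIC score of one family
#'
#' Available-case maximum log-likelihood of `child` given `parents`, minus
#' `0.5 * k * log(n)` where `k` is the number of free parameters and `n`
#' the family's case count. Discrete children contribute multinomial
#' log-likelihoods per parent configuration (`k = q * (r - 1)`); Gaussian
#' children contribute per-configuration regression log-likelihoods with
#' MLE variance (`k = q_disc * (|continuous parents| + 2)`). Families that
#' cannot be fitted (too few cases in some configuration, or a Gaussian
#' parent of a discrete child) score `-Inf`.
#'
#' @param child Child node name.
#' @param parents Character vector of parent names.
#' @param table Data table.
#' @param nodes Named list of node specs (see [cohort_nodes()]).
#' @param var_floor Variance floor for Gaussian fits.
#' @return A single number (possibly `-Inf`).
#' @export
score_family <- function(child, parents, table, nodes, var_floor = 1e-6) {
  kind <- vapply(nodes, `[[`, character(1), "kind")
  if (!child %in% names(nodes)) stopf("unknown node %s", child)
  cols <- c(child, parents)
  ok <- stats::complete.cases(table[cols])
  sub <- table[ok, cols, drop = FALSE]
  n <- nrow(sub)
  if (n == 0L) return(-Inf)
  if (kind[child] == "discrete") {
    if (any(kind[parents] == "gaussian")) return(-Inf)
    r <- length(nodes[[child]]$states)
    grid <- config_grid(stats::setNames(
      lapply(parents, function(p) nodes[[p]]$states), parents))
    q <- max(1L, nrow(grid))
    ll <- 0
    for (j in seq_len(q)) {
      sel <- rep(TRUE, n)
      for (p in parents) sel <- sel & sub[[p]] == grid[j, p]
      if (!any(sel)) next
      cnt <- table(factor(sub[[child]][sel], levels = nodes[[child]]$states))
      cnt <- cnt[cnt > 0]
      ll <- ll + sum(cnt * log(cnt / sum(cnt)))
    }
    k <- q * (r - 1)
  } else {
    dpa <- parents[kind[parents] == "discrete"]
    cpa <- parents[kind[parents] == "gaussian"]
    grid <- config_grid(stats::setNames(
      lapply(dpa, function(p) nodes[[p]]$states), dpa))
    q <- max(1L, nrow(grid))
    need <- length(cpa) + 2L
    Xall <- as.matrix(sub[cpa])
    ll <- 0
    for (j in seq_len(q)) {
      sel <- rep(TRUE, n)
      for (p in dpa) sel <- sel & sub[[p]] == grid[j, p]
      nj <- sum(sel)
      if (nj == 0L) next
      if (nj < need) return(-Inf)
      f <- ls_fit(sub[[child]][sel], Xall[sel, , drop = FALSE], var_floor)
      ll <- ll - nj / 2 * (log(2 * pi * f$sigma2) + 1)
    }
    k <- q * (length(cpa) + 2)
  }
  ll - 0.5 * k * log(n)
}

#' Total decomposable score of a structure
#'
#' Sum of [score_family()] over all nodes, using each node's parent set in
#' `structure`.
#'
#' @param structure A `bn_structure`.
#' @param table Data table.
#' @param var_floor Variance floor for Gaussian fits.
#' @return A single number.
#' @export
network_score <- function(structure, table, var_floor = 1e-6) {
  sum(vapply(names(structure$nodes), function(v)
    score_family(v, parents_of(structure, v), table, structure$nodes, var_floor),
    numeric(1)))
}

admissible_candidates <- function(child, preds, nodes, forbid_edges) {
  kind <- vapply(nodes, `[[`, character(1), "kind")
  cands <- preds
  if (kind[child] == "discrete") cands <- cands[kind[cands] == "discrete"]
  if (!is.null(forbid_edges) && nrow(forbid_edges))
    cands <- cands[!cands %in% forbid_edges$from[forbid_edges$to == child]]
  cands
}

#' K2 greedy structure learning
#'
#' Greedy parent selection per node under a fixed node ordering: each node
#' starts with no parents, and the single candidate parent (a predecessor
#' in the ordering, CLG-admissible, not forbidden) whose addition most
#' increases the family score is added repeatedly until no addition
#' increases the score or `max_parents` is reached. Score ties between
#' candidates are broken toward the earlier position in the ordering, so
#' the result is deterministic given the table and configuration.
#'
#' @param table Data table.
#' @param nodes Named list of node specs covering `node_order`.
#' @param node_order Character permutation of the node names; candidate
#'   parents of a node are its predecessors.
#' @param max_parents Maximum number of parents per node (default 3).
#' @param forbid_edges Optional data.frame (`from`, `to`) of disallowed edges.
#' @param var_floor Variance floor for Gaussian fits.
#' @return A `bn_structure`.
#' @export
k2_search <- function(table, nodes, node_order = names(nodes), max_parents = 3L,
                      forbid_edges = NULL, var_floor = 1e-6) {
  if (!setequal(node_order, names(nodes)) || anyDuplicated(node_order))
    stopf("node_order must be a permutation of the node names")
  if (max_parents < 0L) stopf("max_parents must be >= 0")
  edges <- NULL
  for (i in seq_along(node_order)) {
    child <- node_order[i]
    preds <- node_order[seq_len(i - 1L)]
    cands <- admissible_candidates(child, preds, nodes, forbid_edges)
    parents <- character(0)
    cur <- score_family(child, parents, table, nodes, var_floor)
    while (length(parents) < max_parents && length(cands)) {
      trial <- vapply(cands, function(p)
        score_family(child, c(parents, p), table, nodes, var_floor), numeric(1))
      best <- which.max(trial)  # first maximum: earlier order position wins ties
      if (trial[best] > cur) {
        parents <- c(parents, cands[best])
        cur <- trial[best]
        cands <- cands[-best]
      } else break
    }
    if (length(parents))
      edges <- rbind(edges, data.frame(from = parents, to = child,
                                       stringsAsFactors = FALSE))
  }
  bn_structure(unname(nodes[node_order]), edges)
}

#' Exact best order-consistent DAG (small node sets)
#'
#' Enumerates, independently for each node (the score is decomposable),
#' every admissible subset of its predecessors up to `max_parents` and
#' keeps the subset with the highest family score; ties prefer fewer
#' parents, then the earlier enumeration. Refused above 5 nodes.
#'
#' @inheritParams k2_search
#' @return A `bn_structure` whose total [network_score()] is the exact
#'   maximum over all order-consistent, admissible DAGs.
#' @export
exhaustive_best_dag <- function(table, nodes, node_order = names(nodes),
                                max_parents = 3L, var_floor = 1e-6) {
  if (length(node_order) > 5L)
    stopf("exhaustive search refused for more than 5 nodes")
  if (!setequal(node_order, names(nodes)))
    stopf("node_order must be a permutation of the node names")
  edges <- NULL
  for (i in seq_along(node_order)) {
    child <- node_order[i]
    cands <- admissible_candidates(child, node_order[seq_len(i - 1L)],
                                   nodes, NULL)
    best_sc <- score_family(child, character(0), table, nodes, var_floor)
    best_set <- character(0)
    for (sz in seq_len(min(max_parents, length(cands)))) {
      for (cmb in utils::combn(cands, sz, simplify = FALSE)) {
        sc <- score_family(child, cmb, table, nodes, var_floor)
        if (sc > best_sc) { best_sc <- sc; best_set <- cmb }
      }
    }
    if (length(best_set))
      edges <- rbind(edges, data.frame(from = best_set, to = child,
                                       stringsAsFactors = FALSE))
  }
  bn_structure(unname(nodes[node_order]), edges)
}
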