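# Maximum-likelihood parameter estimation for CLG networks. Discrete nodes
# get multinomial CPTs (relative frequencies, optional add-k smoothing);
# each Gaussian node gets, per configuration of its discrete parents, a
# least-squares regression on its continuous parents with MLE residual
# variance (n denominator). Families are fitted on available-case rows.

config_grid <- function(parent_states) {
  if (length(parent_states) == 0L)
    return(data.frame(row.names = "1")[1L, 0L, drop = FALSE])
  expand.grid(parent_states, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

config_key <- function(values) {
  if (length(values) == 0L) return("(root)")
  paste(unlist(values), collapse = "|")
}

#' Multinomial CPT for a discrete node
#'
#' @param node Child node name.
#' @param states Child state labels.
#' @param parents Discrete parent names (possibly none).
#' @param parent_states Named list of parent state labels, in `parents` order.
#' @param prob Matrix with one row per child state and one column per
#'   parent configuration (configurations enumerated by `expand.grid` over
#'   `parent_states`, first parent varying fastest); every column must sum
#'   to 1.
#' @param counts Optional per-configuration case counts (metadata).
#' @param fallback Optional logical per configuration: TRUE where the fit
#'   fell back to the child's marginal because the configuration had no data.
#' @return An object of class `discrete_cpd`.
#' @export
discrete_cpd <- function(node, states, parents = character(0),
                         parent_states = list(), prob,
                         counts = NULL, fallback = NULL) {
  grid <- config_grid(parent_states)
  q <- max(1L, nrow(grid))
  prob <- matrix(as.numeric(prob), nrow = length(states), ncol = q)
  if (any(prob < -1e-12)) stopf("CPT for %s has negative entries", node)
  bad <- abs(colSums(prob) - 1) > 1e-10
  if (any(bad)) stopf("CPT column for %s does not sum to 1", node)
  keys <- if (length(parent_states)) apply(grid, 1L, config_key) else "(root)"
  colnames(prob) <- keys
  rownames(prob) <- states
  structure(list(node = node, states = states, parents = parents,
                 parent_states = parent_states, prob = prob,
                 counts = counts %||% rep(NA_integer_, q),
                 fallback = fallback %||% rep(FALSE, q)),
            class = "discrete_cpd")
}

#' Conditional linear Gaussian CPD
#'
#' Per configuration of the discrete parents, the child is Gaussian with
#' mean `beta0 + sum(beta * continuous parents)` and variance `sigma2`.
#'
#' @param node Child node name.
#' @param dparents,dparent_states Discrete parent names and their state
#'   labels (named list in `dparents` order).
#' @param cparents Continuous parent names.
#' @param params Named list keyed by configuration (see [discrete_cpd()]
#'   for the enumeration); each element a list with `beta0`, `beta`
#'   (numeric, `cparents` order), `sigma2` (> 0), and optionally `n`,
#'   `fallback`.
#' @return An object of class `clg_cpd`.
#' @export
clg_cpd <- function(node, dparents = character(0), dparent_states = list(),
                    cparents = character(0), params) {
  grid <- config_grid(dparent_states)
  keys <- if (length(dparent_states)) apply(grid, 1L, config_key) else "(root)"
  if (!setequal(names(params), keys))
    stopf("CLG CPD for %s: params must cover configurations %s",
          node, paste(keys, collapse = "; "))
  for (k in keys) {
    p <- params[[k]]
    if (length(p$beta) != length(cparents))
      stopf("CLG CPD for %s, config %s: beta length != number of continuous parents",
            node, k)
    if (!is.finite(p$sigma2) || p$sigma2 <= 0)
      stopf("CLG CPD for %s, config %s: sigma2 must be positive", node, k)
    params[[k]]$beta <- stats::setNames(as.numeric(p$beta), cparents)
  }
  structure(list(node = node, dparents = dparents,
                 dparent_states = dparent_states, cparents = cparents,
                 params = params[keys]),
            class = "clg_cpd")
}

#' Assemble a fitted network from structure and CPDs
#'
#' Mostly used internally by [fit_mle()] and by tests constructing known
#' networks; validates that there is exactly one CPD per node and that CPD
#' parent sets match the structure.
#'
#' @param structure A `bn_structure`.
#' @param cpds Named list of [discrete_cpd()] / [clg_cpd()] objects.
#' @param metadata Free-form fit metadata (per-family case counts etc.).
#' @return An object of class `bn_fit`.
#' @export
bn_fit <- function(structure, cpds, metadata = list()) {
  stopifnot(inherits(structure, "bn_structure"))
  if (!setequal(names(cpds), names(structure$nodes)))
    stopf("need exactly one CPD per node")
  kind <- node_kinds(structure)
  for (v in names(structure$nodes)) {
    cpd <- cpds[[v]]
    pa <- parents_of(structure, v)
    if (kind[v] == "discrete") {
      if (!inherits(cpd, "discrete_cpd")) stopf("node %s needs a discrete_cpd", v)
      if (!setequal(cpd$parents, pa)) stopf("CPD parents mismatch for %s", v)
    } else {
      if (!inherits(cpd, "clg_cpd")) stopf("node %s needs a clg_cpd", v)
      if (!setequal(c(cpd$dparents, cpd$cparents), pa))
        stopf("CPD parents mismatch for %s", v)
    }
  }
  structure(list(structure = structure, cpds = cpds[names(structure$nodes)],
                 metadata = metadata),
            class = "bn_fit")
}

# Least-squares fit of y on X columns (with intercept); returns beta0,
# beta, MLE sigma2 (floored) and n.
ls_fit <- function(y, X, var_floor) {
  n <- length(y)
  Xd <- cbind(`(Intercept)` = 1, X)
  coefs <- qr.coef(qr(Xd), y)
  coefs[is.na(coefs)] <- 0  # collinear columns: pin redundant coefficients at 0
  resid <- y - as.vector(Xd %*% coefs)
  list(beta0 = unname(coefs[1L]), beta = unname(coefs[-1L]),
       sigma2 = max(mean(resid^2), var_floor), n = n)
}

#' Fit network parameters by maximum likelihood
#'
#' Fits every node's CPD on the rows where the node and all of its parents
#' are observed (available-case analysis per family, so that each part of
#' a two-part network is learned from its modality-complete subset).
#' Discrete CPTs are (optionally add-k smoothed) relative frequencies per
#' parent configuration; a configuration with zero cases falls back to the
#' child's marginal distribution, recorded in the metadata. Gaussian nodes
#' get per-configuration least-squares regressions with MLE residual
#' variance (divide by n), floored at `var_floor`; a configuration with
#' fewer cases than coefficients + 1 falls back to the pooled
#' (configuration-marginal) fit.
#'
#' @param structure A `bn_structure`.
#' @param table A patient feature table.
#' @param smooth Add-k smoothing constant for discrete CPTs (default 0).
#' @param var_floor Lower bound for residual variances (default 1e-6,
#'   squared feature units).
#' @return A `bn_fit`; `metadata$families` records each family's case
#'   count and any fallback configurations.
#' @examples
#' tab <- generate_cohort(default_cohort_spec())
#' s <- bn_structure(cohort_nodes("nrCBV"),
#'                   data.frame(from = "grade", to = "nrCBV"))
#' fit <- fit_mle(s, tab)
#' fit$cpds$grade$prob  # 30/56, 26/56
#' @export
fit_mle <- function(structure, table, smooth = 0, var_floor = 1e-6) {
  stopifnot(inherits(structure, "bn_structure"))
  kind <- node_kinds(structure)
  for (v in names(structure$nodes))
    if (!v %in% names(table)) stopf("table lacks column for node %s", v)
  cpds <- list()
  fam_meta <- list()
  for (v in topo_sort(structure)) {
    pa <- parents_of(structure, v)
    if (kind[v] == "discrete") {
      nd <- structure$nodes[[v]]
      if (any(kind[pa] == "gaussian")) stopf("discrete node %s has gaussian parent", v)
      cols <- c(v, pa)
      ok <- stats::complete.cases(table[cols])
      sub <- table[ok, cols, drop = FALSE]
      if (nrow(sub) == 0L) stopf("family of %s has no fully observed rows", v)
      pstates <- stats::setNames(
        lapply(pa, function(p) structure$nodes[[p]]$states), pa)
      grid <- config_grid(pstates)
      q <- max(1L, nrow(grid))
      marg <- vapply(nd$states, function(s) sum(sub[[v]] == s), numeric(1))
      marg <- (marg + smooth) / sum(marg + smooth)
      prob <- matrix(NA_real_, length(nd$states), q)
      counts <- integer(q); fb <- logical(q)
      for (j in seq_len(q)) {
        sel <- rep(TRUE, nrow(sub))
        for (p in pa) sel <- sel & sub[[p]] == grid[j, p]
        counts[j] <- sum(sel)
        if (counts[j] == 0L && smooth == 0) {
          prob[, j] <- marg; fb[j] <- TRUE
        } else {
          cnt <- vapply(nd$states, function(s) sum(sub[[v]][sel] == s), numeric(1))
          prob[, j] <- (cnt + smooth) / sum(cnt + smooth)
        }
      }
      cpds[[v]] <- discrete_cpd(v, nd$states, pa, pstates, prob, counts, fb)
      fam_meta[[v]] <- list(n = nrow(sub), fallback_configs = sum(fb))
    } else {
      dpa <- pa[kind[pa] == "discrete"]
      cpa <- pa[kind[pa] == "gaussian"]
      cols <- c(v, pa)
      ok <- stats::complete.cases(table[cols])
      sub <- table[ok, cols, drop = FALSE]
      need <- length(cpa) + 2L  # intercept + slopes + one extra case
      if (nrow(sub) < need)
        stopf("family of %s has %d fully observed rows; at least %d required",
              v, nrow(sub), need)
      pstates <- stats::setNames(
        lapply(dpa, function(p) structure$nodes[[p]]$states), dpa)
      grid <- config_grid(pstates)
      q <- max(1L, nrow(grid))
      keys <- if (length(dpa)) apply(grid, 1L, config_key) else "(root)"
      Xall <- as.matrix(sub[cpa])
      pooled <- ls_fit(sub[[v]], Xall, var_floor)
      params <- list(); nfb <- 0L
      for (j in seq_len(q)) {
        sel <- rep(TRUE, nrow(sub))
        for (p in dpa) sel <- sel & sub[[p]] == grid[j, p]
        if (sum(sel) < need) {
          par <- pooled; par$fallback <- TRUE; nfb <- nfb + 1L
        } else {
          par <- ls_fit(sub[[v]][sel], Xall[sel, , drop = FALSE], var_floor)
          par$fallback <- FALSE
        }
        params[[keys[j]]] <- par
      }
      cpds[[v]] <- clg_cpd(v, dpa, pstates, cpa, params)
      fam_meta[[v]] <- list(n = nrow(sub), fallback_configs = nfb)
    }
  }
  bn_fit(structure, cpds, metadata = list(families = fam_meta))
}

#' @export
print.bn_fit <- function(x, ...) {
  cat("Fitted CLG network\n")
  print(x$structure)
  ns <- vapply(x$metadata$families, function(f) f$n, numeric(1))
  cat(sprintf("family case counts: %s\n",
              paste(sprintf("%s=%d", names(ns), ns), collapse = ", ")))
  invisible(x)
}
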