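# Independent oracles used across the suite. These deliberately avoid the
# package's inference path: the grid oracle works node-wise on conditional
# densities, never compiling a joint Gaussian; the pair-count AUC counts
# concordant pairs directly; the permutation oracle enumerates group
# assignments.

# ---- forward sampling from a fitted CLG network ----------------------------

forward_sample <- function(fit, n) {
  ord <- topo_sort(fit$structure)
  kind <- vapply(fit$structure$nodes, `[[`, character(1), "kind")
  out <- as.data.frame(matrix(NA, n, length(ord)),
                       stringsAsFactors = FALSE)
  names(out) <- ord
  for (v in ord) {
    cpd <- fit$cpds[[v]]
    if (kind[v] == "discrete") {
      col <- character(n)
      if (length(cpd$parents) == 0L) {
        col <- sample(cpd$states, n, replace = TRUE, prob = cpd$prob[, 1L])
      } else {
        keys <- apply(as.matrix(out[cpd$parents]), 1L,
                      function(r) paste(r, collapse = "|"))
        for (k in unique(keys)) {
          sel <- keys == k
          col[sel] <- sample(cpd$states, sum(sel), replace = TRUE,
                             prob = cpd$prob[, k])
        }
      }
      out[[v]] <- col
    } else {
      mu <- numeric(n)
      s2 <- numeric(n)
      keys <- if (length(cpd$dparents))
        apply(as.matrix(out[cpd$dparents]), 1L,
              function(r) paste(r, collapse = "|")) else rep("(root)", n)
      for (k in unique(keys)) {
        sel <- keys == k
        p <- cpd$params[[k]]
        m <- rep(p$beta0, sum(sel))
        if (length(cpd$cparents))
          m <- m + as.matrix(out[sel, cpd$cparents, drop = FALSE]) %*% p$beta
        mu[sel] <- m
        s2[sel] <- p$sigma2
      }
      out[[v]] <- stats::rnorm(n, mu, sqrt(s2))
    }
  }
  out
}

# ---- fine-grid posterior oracle --------------------------------------------

g_descendants <- function(structure, v) {
  out <- character(0)
  frontier <- v
  while (length(frontier)) {
    ch <- structure$edges$to[structure$edges$from %in% frontier]
    ch <- setdiff(ch, out)
    out <- c(out, ch)
    frontier <- ch
  }
  out
}

# Upper bound on the prior SD of a gaussian node for a given discrete
# config (triangle inequality through its continuous ancestry).
prior_sd_bound <- function(fit, v, config, memo = new.env()) {
  if (!is.null(memo[[v]])) return(memo[[v]])
  cpd <- fit$cpds[[v]]
  key <- paste(unlist(config[cpd$dparents]), collapse = "|")
  if (key == "") key <- "(root)"
  p <- cpd$params[[key]]
  s <- sqrt(p$sigma2)
  for (j in seq_along(cpd$cparents))
    s <- s + abs(p$beta[j]) * prior_sd_bound(fit, cpd$cparents[j], config, memo)
  memo[[v]] <- s
  s
}

prior_mean <- function(fit, v, config, evidence) {
  if (!is.null(evidence[[v]])) return(evidence[[v]])
  cpd <- fit$cpds[[v]]
  key <- paste(unlist(config[cpd$dparents]), collapse = "|")
  if (key == "") key <- "(root)"
  p <- cpd$params[[key]]
  m <- p$beta0
  for (j in seq_along(cpd$cparents))
    m <- m + p$beta[j] * prior_mean(fit, cpd$cparents[j], config, evidence)
  m
}

# Brute-force posterior over the grade node: enumerate discrete configs,
# prune barren unobserved gaussians (their conditional densities integrate
# to one), and integrate the single remaining unobserved gaussian (if any)
# on a fine grid of width step_frac * sd over +/- range_sd * sd.
grid_posterior <- function(fit, evidence, grade_node = "grade",
                           step_frac = 1e-3, range_sd = 8) {
  s <- fit$structure
  kind <- vapply(s$nodes, `[[`, character(1), "kind")
  ord <- topo_sort(s)
  dn <- ord[kind[ord] == "discrete"]
  gn <- ord[kind[ord] == "gaussian"]
  gobs <- intersect(gn, names(evidence))
  gun <- setdiff(gn, gobs)
  nonbarren <- gun[vapply(gun, function(v)
    length(intersect(g_descendants(s, v), gobs)) > 0L, logical(1))]
  if (length(nonbarren) > 1L)
    stop("grid oracle supports at most one marginalized non-barren gaussian")
  dobs <- intersect(dn, names(evidence))
  dun <- setdiff(dn, dobs)
  stopifnot(grade_node %in% dun)
  grids <- lapply(dun, function(v) s$nodes[[v]]$states)
  names(grids) <- dun
  cfgs <- expand.grid(grids, stringsAsFactors = FALSE)

  cond_logd <- function(v, value, vals, config) {
    cpd <- fit$cpds[[v]]
    key <- paste(unlist(config[cpd$dparents]), collapse = "|")
    if (key == "") key <- "(root)"
    p <- cpd$params[[key]]
    m <- p$beta0
    for (j in seq_along(cpd$cparents))
      m <- m + p$beta[j] * vals[[cpd$cparents[j]]]
    stats::dnorm(value, m, sqrt(p$sigma2), log = TRUE)
  }

  logw <- numeric(nrow(cfgs))
  for (r in seq_len(nrow(cfgs))) {
    config <- c(as.list(cfgs[r, , drop = FALSE]), evidence[dobs])
    lw <- 0
    for (v in dn) {
      cpd <- fit$cpds[[v]]
      key <- paste(unlist(config[cpd$parents]), collapse = "|")
      if (key == "") key <- "(root)"
      lw <- lw + log(cpd$prob[config[[v]], key])
    }
    if (length(nonbarren) == 0L) {
      vals <- evidence
      for (v in gobs) lw <- lw + cond_logd(v, evidence[[v]], vals, config)
    } else {
      u <- nonbarren
      sdb <- prior_sd_bound(fit, u, config)
      mu0 <- prior_mean(fit, u, config, evidence)
      step <- step_frac * sdb
      x <- seq(mu0 - range_sd * sdb, mu0 + range_sd * sdb, by = step)
      ll <- rep(0, length(x))
      vals <- c(evidence, stats::setNames(list(x), u))
      for (v in c(u, gobs)) {
        value <- if (v == u) x else evidence[[v]]
        ll <- ll + cond_logd(v, value, vals, config)
      }
      m <- max(ll)
      lw <- lw + m + log(sum(exp(ll - m))) + log(step)
    }
    logw[r] <- lw
  }
  states <- s$nodes[[grade_node]]$states
  lp <- vapply(states, function(st) {
    sel <- cfgs[[grade_node]] == st
    m <- max(logw[sel])
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(logw[sel] - m)))
  }, numeric(1))
  tot <- max(lp) + log(sum(exp(lp - max(lp))))
  stats::setNames(exp(lp - tot), states)
}

# ---- random CLG networks and evidence --------------------------------------

rand_clg_fit <- function(n_gauss = 3L, second_discrete = FALSE,
                         edge_prob = 0.5, max_cparents = 2L) {
  nodes <- list(discrete_node("grade", c("high", "low")))
  if (second_discrete) nodes <- c(nodes, list(discrete_node("D", c("a", "b", "c"))))
  gnames <- paste0("g", seq_len(n_gauss))
  nodes <- c(nodes, lapply(gnames, gaussian_node))
  nm <- vapply(nodes, `[[`, character(1), "name")
  names(nodes) <- nm
  kind <- vapply(nodes, `[[`, character(1), "kind")
  edges <- NULL
  for (i in seq_along(nm)[-1L]) {
    child <- nm[i]
    preds <- nm[seq_len(i - 1L)]
    cands <- if (kind[child] == "discrete") preds[kind[preds] == "discrete"] else preds
    pick <- cands[stats::runif(length(cands)) < edge_prob]
    cpick <- pick[kind[pick] == "gaussian"]
    if (length(cpick) > max_cparents)
      pick <- c(pick[kind[pick] == "discrete"], sample(cpick, max_cparents))
    if (length(pick))
      edges <- rbind(edges, data.frame(from = pick, to = child,
                                       stringsAsFactors = FALSE))
  }
  s <- bn_structure(nodes, edges)
  cpds <- list()
  for (v in nm) {
    pa <- parents_of(s, v)
    if (kind[v] == "discrete") {
      ps <- stats::setNames(lapply(pa, function(p) nodes[[p]]$states), pa)
      q <- max(1L, prod(vapply(ps, length, integer(1))))
      r <- length(nodes[[v]]$states)
      prob <- matrix(stats::runif(r * q, 0.15, 1), r, q)
      prob <- sweep(prob, 2L, colSums(prob), "/")
      cpds[[v]] <- discrete_cpd(v, nodes[[v]]$states, pa, ps, prob)
    } else {
      dpa <- pa[kind[pa] == "discrete"]
      cpa <- pa[kind[pa] == "gaussian"]
      ps <- stats::setNames(lapply(dpa, function(p) nodes[[p]]$states), dpa)
      grid <- expand.grid(ps, stringsAsFactors = FALSE)
      keys <- if (length(dpa)) apply(grid, 1L, paste, collapse = "|") else "(root)"
      params <- lapply(keys, function(k)
        list(beta0 = stats::runif(1, -2, 2),
             beta = stats::runif(length(cpa), -1.5, 1.5),
             sigma2 = stats::runif(1, 0.3, 2)))
      names(params) <- keys
      cpds[[v]] <- clg_cpd(v, dpa, ps, cpa, params)
    }
  }
  bn_fit(s, cpds)
}

# Random partial evidence drawn from one forward sample; grade is never
# observed, and all but one non-barren unobserved gaussian are promoted to
# observed so the grid oracle stays one-dimensional.
rand_evidence <- function(fit, p_gauss = 0.6, p_disc = 0.5) {
  s <- fit$structure
  kind <- vapply(s$nodes, `[[`, character(1), "kind")
  draw <- forward_sample(fit, 1L)
  ev <- list()
  for (v in names(s$nodes)) {
    if (v == "grade") next
    p <- if (kind[v] == "discrete") p_disc else p_gauss
    if (stats::runif(1) < p)
      ev[[v]] <- if (kind[v] == "discrete") draw[[v]][1L] else draw[[v]][1L]
  }
  gn <- names(kind)[kind == "gaussian"]
  repeat {
    gun <- setdiff(gn, names(ev))
    nb <- gun[vapply(gun, function(v)
      length(intersect(g_descendants(s, v), intersect(gn, names(ev)))) > 0L,
      logical(1))]
    if (length(nb) <= 1L) break
    ev[[nb[length(nb)]]] <- draw[[nb[length(nb)]]][1L]
  }
  ev
}

# ---- rank-test oracles ------------------------------------------------------

# Tie-corrected H computed from first principles (explicit correction loop).
brute_kw_h <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled)
  r <- rank(pooled)
  R1 <- sum(r[seq_along(x)]); R2 <- sum(r[-seq_along(x)])
  H <- 12 / (N * (N + 1)) * (R1^2 / length(x) + R2^2 / length(y)) - 3 * (N + 1)
  corr <- 0
  for (u in unique(pooled)) {
    t <- sum(pooled == u)
    corr <- corr + (t^3 - t)
  }
  C <- 1 - corr / (N^3 - N)
  if (C <= 0) 0 else H / C
}

# Exact permutation distribution of H over all group assignments; returns
# the standard and mid-p values for the observed split.
perm_kw_p <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled)
  idx <- utils::combn(N, length(x))
  h_obs <- kruskal_wallis(x, y)$H
  hs <- apply(idx, 2L, function(ii)
    kruskal_wallis(pooled[ii], pooled[-ii])$H)
  eq <- abs(hs - h_obs) <= 1e-9
  gt <- hs > h_obs + 1e-9
  list(p = mean(gt | eq), mid_p = mean(gt) + 0.5 * mean(eq))
}

# ---- AUC oracle -------------------------------------------------------------

pair_count_auc <- function(scores, labels, positive = "high") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}
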