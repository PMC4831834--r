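# End-to-end grading procedure: screening -> two-part K2 structure
# learning on modality-complete subsets -> merge -> leave-one-out
# evaluation under configurable observation patterns -> accuracy / ROC /
# AUC reporting.

modality_nodes <- function(pattern, node_names) {
  out <- character(0)
  for (m in pattern) {
    out <- c(out, switch(m,
      T1WC = intersect("T1WC", node_names),
      perfusion = intersect(perfusion_features(), node_names),
      MRSI = intersect(mrsi_features(), node_names),
      {
        if (!m %in% node_names) stopf("unknown modality or node in pattern: %s", m)
        m
      }))
  }
  unique(out)
}

#' ROC curve and trapezoidal AUC
#'
#' Threshold sweep over the unique scores (descending), producing the ROC
#' staircase from (0, 0) to (1, 1). Tied scores share one threshold and
#' yield a diagonal segment, so the trapezoidal AUC equals the
#' Mann-Whitney concordant-pair statistic with ties counted one half.
#'
#' @param scores Numeric scores (higher means more likely positive).
#' @param labels Vector of class labels.
#' @param positive The label treated as positive (default `"high"`).
#' @return List with `points` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "high") {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stopf("roc_auc requires at least one positive and one negative label")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), numeric(1))
  pts <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Leave-one-out evaluation of a grading network
#'
#' For each evaluated case, the network parameters are refitted by
#' [fit_mle()] on all other rows (the structure is held fixed across
#' folds) and the case's grade is predicted from the evidence named by
#' `pattern`. The evaluated cases are the rows complete for the `require`
#' modalities (default: the pattern itself), reproducing per-pattern
#' denominators such as 56 / 51 / 26 when requiring the enhancement,
#' perfusion or MRSI modality respectively; pattern features beyond
#' `require` contribute evidence where observed.
#'
#' @param table Patient feature table.
#' @param structure A `bn_structure` containing the grade node.
#' @param pattern Character vector of modalities (`"T1WC"`, `"perfusion"`,
#'   `"MRSI"`) and/or explicit node names used as evidence.
#' @param require Modalities/nodes that must be fully observed for a case
#'   to enter the denominator; defaults to `pattern`.
#' @param grade_node Class node name.
#' @param smooth,var_floor Passed to [fit_mle()].
#' @return An `evaluation_report`: list with `cases` (per-case data.frame
#'   with true grade, prediction, posterior P(high)), `n`, `accuracy`,
#'   `n_wrong`, `auc`, `roc` points, `pattern` and `excluded_folds` (folds
#'   whose training data could not fit some family).
#' @export
loocv_evaluate <- function(table, structure, pattern, require = pattern,
                           grade_node = "grade", smooth = 0, var_floor = 1e-6) {
  validate_patient_table(table)
  stopifnot(inherits(structure, "bn_structure"))
  node_names <- names(structure$nodes)
  ev_nodes <- setdiff(modality_nodes(pattern, node_names), grade_node)
  req_nodes <- setdiff(modality_nodes(require, node_names), grade_node)
  if (length(ev_nodes) == 0L) stopf("pattern selects no evidence nodes")
  eval_idx <- which(stats::complete.cases(table[req_nodes]))
  cases <- data.frame(patient_id = character(0), true = character(0),
                      predicted = character(0), p_high = numeric(0),
                      stringsAsFactors = FALSE)
  excluded <- character(0)
  for (i in eval_idx) {
    fit_i <- tryCatch(
      fit_mle(structure, table[-i, , drop = FALSE], smooth, var_floor),
      error = function(e) e)
    if (inherits(fit_i, "error")) {
      excluded <- c(excluded, sprintf("%s: %s", table$patient_id[i],
                                      conditionMessage(fit_i)))
      next
    }
    row <- as.list(table[i, ev_nodes, drop = FALSE])
    ev <- row[!vapply(row, function(x) is.na(x[[1L]]), logical(1))]
    pred <- predict_grade(fit_i, ev, grade_node)
    cases <- rbind(cases, data.frame(
      patient_id = table$patient_id[i], true = table$grade[i],
      predicted = pred$grade, p_high = pred$p_high,
      stringsAsFactors = FALSE))
  }
  n <- nrow(cases)
  n_wrong <- sum(cases$predicted != cases$true)
  roc <- if (n && length(unique(cases$true)) == 2L)
    roc_auc(cases$p_high, cases$true) else NULL
  structure(list(cases = cases, n = n,
                 accuracy = if (n) (n - n_wrong) / n else NA_real_,
                 n_wrong = n_wrong,
                 auc = if (is.null(roc)) NA_real_ else roc$auc,
                 roc = roc$points, pattern = pattern, require = require,
                 excluded_folds = excluded),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("LOOCV evaluation | evidence: %s | n = %d\n",
              paste(x$pattern, collapse = " + "), x$n))
  cat(sprintf("  accuracy %.4f (%d wrong), AUC %s\n", x$accuracy, x$n_wrong,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  if (length(x$excluded_folds))
    cat(sprintf("  %d folds excluded (unfittable)\n", length(x$excluded_folds)))
  invisible(x)
}

#' Build the two-part grading network
#'
#' Implements the composition strategy for cohorts where few patients have
#' every modality: screen the continuous features with [screen_features()],
#' learn one sub-network over grade, T1WC and the retained perfusion
#' features on the perfusion-complete rows, learn a second over grade and
#' the retained MRSI features on the MRSI-complete rows (each with
#' [k2_search()] under a grade-first ordering, features ordered by
#' ascending screening p-value), and merge the two parts on the shared
#' grade node. Grade-first orderings guarantee the merge is acyclic.
#'
#' @param table Patient feature table.
#' @param alpha Screening level (default 0.05).
#' @param max_parents Per-node parent cap for K2 (default 3).
#' @param var_floor Variance floor for Gaussian fits.
#' @return A `grading_network` list: `structure` (merged), `part_a`,
#'   `part_b` (either may be `NULL` when its feature set screens out),
#'   `screening` (the [screen_features()] table), `n_part_a`, `n_part_b`
#'   (rows used to learn each part).
#' @export
build_two_part_network <- function(table, alpha = 0.05, max_parents = 3L,
                                   var_floor = 1e-6) {
  validate_patient_table(table)
  scr <- screen_features(table, alpha)
  keep <- scr$feature[scr$retained]
  pv <- stats::setNames(scr$p_value, scr$feature)
  pf <- intersect(perfusion_features(), keep)
  mf <- intersect(mrsi_features(), keep)
  pf <- pf[order(pv[pf])]
  mf <- mf[order(pv[mf])]

  order_a <- c("grade", "T1WC", pf)
  nodes_a <- cohort_nodes(pf)
  rows_a <- table[stats::complete.cases(table[order_a]), , drop = FALSE]
  part_a <- k2_search(rows_a, nodes_a, order_a, max_parents,
                      var_floor = var_floor)

  part_b <- NULL; rows_b <- NULL
  if (length(mf)) {
    order_b <- c("grade", mf)
    nodes_b <- cohort_nodes(mf, include_t1wc = FALSE)
    rows_b <- table[stats::complete.cases(table[order_b]), , drop = FALSE]
    part_b <- k2_search(rows_b, nodes_b, order_b, max_parents,
                        var_floor = var_floor)
  }
  merged <- if (is.null(part_b)) part_a else merge_structures(part_a, part_b)
  structure(list(structure = merged, part_a = part_a, part_b = part_b,
                 screening = scr, n_part_a = nrow(rows_a),
                 n_part_b = if (is.null(rows_b)) 0L else nrow(rows_b)),
            class = "grading_network")
}

#' @export
print.grading_network <- function(x, ...) {
  cat(sprintf("Two-part grading network (part A: %d rows, part B: %d rows)\n",
              x$n_part_a, x$n_part_b))
  print(x$structure)
  invisible(x)
}

#' Accuracy sweep over feature subsets
#'
#' For each candidate feature subset, learns a network by [k2_search()]
#' over grade (plus T1WC when the subset names it) and the subset's
#' features on the rows complete for them, evaluates it by
#' [loocv_evaluate()] with the subset as both evidence and denominator
#' requirement, and tabulates accuracy, wrong-prediction count and AUC,
#' ranked by accuracy. With `subsets = NULL` every nonempty subset of
#' `candidates` is evaluated.
#'
#' @param table Patient feature table.
#' @param candidates Character vector of candidate evidence nodes
#'   (continuous features and/or `"T1WC"`).
#' @param subsets Optional list of character vectors to restrict the sweep.
#' @param max_parents,smooth,var_floor Passed through.
#' @return A data.frame with columns `features`, `n`, `accuracy`,
#'   `n_wrong`, `auc`, sorted by decreasing accuracy.
#' @export
feature_subset_sweep <- function(table, candidates, subsets = NULL,
                                 max_parents = 3L, smooth = 0,
                                 var_floor = 1e-6) {
  if (length(candidates) == 0L) stopf("candidate feature list is empty")
  if (is.null(subsets)) {
    subsets <- unlist(lapply(seq_along(candidates), function(k)
      utils::combn(candidates, k, simplify = FALSE)), recursive = FALSE)
  }
  rows <- lapply(subsets, function(sub) {
    feats <- setdiff(sub, "T1WC")
    nodes <- cohort_nodes(feats, include_t1wc = "T1WC" %in% sub)
    ord <- intersect(c("grade", "T1WC", feats), names(nodes))
    complete <- table[stats::complete.cases(table[setdiff(ord, "grade")]), ,
                      drop = FALSE]
    s <- k2_search(complete, nodes, ord, max_parents, var_floor = var_floor)
    rep_ <- loocv_evaluate(complete, s, pattern = sub, require = sub,
                           smooth = smooth, var_floor = var_floor)
    data.frame(features = paste(sub, collapse = " "), n = rep_$n,
               accuracy = rep_$accuracy, n_wrong = rep_$n_wrong,
               auc = rep_$auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$accuracy, out$features), , drop = FALSE]
}
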