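# K2 greedy structure search and its BIC family score.

disc2 <- function(name) discrete_node(name, c("0", "1"))

rand_k2_table <- function(n, p_edge = 0.6) {
  # 4 discrete binary nodes with random chain-ish dependence
  A <- sample(c("0", "1"), n, replace = TRUE)
  B <- ifelse(runif(n) < ifelse(A == "1", 0.8, 0.2), "1", "0")
  C <- ifelse(runif(n) < ifelse(B == "1", 0.75, 0.25), "1", "0")
  D <- sample(c("0", "1"), n, replace = TRUE, prob = c(0.6, 0.4))
  data.frame(A = A, B = B, C = C, D = D, stringsAsFactors = FALSE)
}

test_that("the BIC family score is decomposable and column-order invariant", {
  set.seed(1)
  n <- 500
  tab <- rand_k2_table(n)
  nodes <- setNames(lapply(c("A", "B", "C", "D"), disc2), c("A", "B", "C", "D"))
  sc1 <- score_family("C", "B", tab, nodes)
  sc2 <- score_family("C", "B", tab[, c("D", "C", "B", "A")], nodes)
  expect_identical(sc1, sc2)
  # network score is the sum of family scores
  s <- bn_structure(unname(nodes), data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_equal(network_score(s, tab),
               score_family("A", character(0), tab, nodes) +
                 score_family("B", "A", tab, nodes) +
                 score_family("C", "B", tab, nodes) +
                 score_family("D", character(0), tab, nodes),
               tolerance = 1e-12)
})

test_that("a perfectly dependent parent increases the score; noise parents do not", {
  set.seed(2)
  n <- 200
  A <- sample(c("0", "1"), n, replace = TRUE)
  tab <- data.frame(A = A, B = A, stringsAsFactors = FALSE)  # B copies A
  nodes <- list(A = disc2("A"), B = disc2("B"))
  expect_gt(score_family("B", "A", tab, nodes),
            score_family("B", character(0), tab, nodes))
  # independent columns: BIC penalty dominates in most draws
  wins <- 0L
  for (i in 1:20) {
    tab2 <- data.frame(A = sample(c("0", "1"), 1000, replace = TRUE),
                       B = sample(c("0", "1"), 1000, replace = TRUE),
                       stringsAsFactors = FALSE)
    wins <- wins + (score_family("B", character(0), tab2, nodes) >
                      score_family("B", "A", tab2, nodes))
  }
  expect_gte(wins, 19L)
})

test_that("k2_search respects ordering, admissibility and max_parents", {
  set.seed(3)
  tab <- generate_cohort(default_cohort_spec(12L))
  feats <- c("nrCBV", "nMTT", "nrCBF")
  nodes <- cohort_nodes(feats)
  ord <- c("grade", "T1WC", feats)
  rows <- tab[complete.cases(tab[ord]), ]
  s <- k2_search(rows, nodes, ord, max_parents = 2L)
  pos <- setNames(seq_along(ord), ord)
  kind <- sapply(nodes, `[[`, "kind")
  for (i in seq_len(nrow(s$edges))) {
    expect_lt(pos[s$edges$from[i]], pos[s$edges$to[i]])
    expect_false(kind[s$edges$from[i]] == "gaussian" &&
                   kind[s$edges$to[i]] == "discrete")
  }
  expect_true(all(table(s$edges$to) <= 2))
  # determinism
  expect_identical(k2_search(rows, nodes, ord, max_parents = 2L)$edges, s$edges)
  # forbidden edges are honored
  s2 <- k2_search(rows, nodes, ord, max_parents = 2L,
                  forbid_edges = data.frame(from = "grade", to = "nrCBV"))
  expect_false(any(s2$edges$from == "grade" & s2$edges$to == "nrCBV"))
  # single node: empty structure
  s1 <- k2_search(rows, nodes["grade"], "grade")
  expect_equal(nrow(s1$edges), 0L)
})

test_that("k2 recovers a strong discrete chain from its generator", {
  hits <- 0L
  set.seed(4)
  for (i in 1:40) {
    A <- sample(c("0", "1"), 500, replace = TRUE)
    B <- ifelse(runif(500) < ifelse(A == "1", 0.9, 0.1), "1", "0")
    C <- ifelse(runif(500) < ifelse(B == "1", 0.9, 0.1), "1", "0")
    tab <- data.frame(A = A, B = B, C = C, stringsAsFactors = FALSE)
    nodes <- list(A = disc2("A"), B = disc2("B"), C = disc2("C"))
    s <- k2_search(tab, nodes, c("A", "B", "C"), max_parents = 2L)
    ed <- paste(s$edges$from, s$edges$to)
    hits <- hits + setequal(ed, c("A B", "B C"))
  }
  expect_gte(hits, 38L)
})

test_that("k2 never beats the exhaustive order-consistent optimum", {
  set.seed(5)
  equal_cases <- 0L
  for (i in 1:30) {
    tab <- rand_k2_table(300)
    nodes <- setNames(lapply(names(tab), disc2), names(tab))
    ord <- names(tab)
    sk <- k2_search(tab, nodes, ord, max_parents = 3L)
    se <- exhaustive_best_dag(tab, nodes, ord, max_parents = 3L)
    sc_k <- network_score(sk, tab)
    sc_e <- network_score(se, tab)
    expect_lte(sc_k, sc_e + 1e-9)
    equal_cases <- equal_cases + (abs(sc_k - sc_e) < 1e-9)
  }
  expect_gte(equal_cases, 24L)
  expect_error(exhaustive_best_dag(generate_cohort(default_cohort_spec()),
                                   cohort_nodes(perfusion_features())),
               "more than 5 nodes")
})

test_that("hybrid scoring lets k2 link grade to informative gaussian features", {
  set.seed(6)
  spec <- default_cohort_spec(20L)
  big <- cohort_spec(300, 260, 560, 560, 560, 20L,
                     unname(spec$features), spec$enhancement)
  tab <- generate_cohort(big)
  nodes <- cohort_nodes("nrCBV")
  s <- k2_search(tab, nodes, c("grade", "T1WC", "nrCBV"), max_parents = 2L)
  expect_true(any(s$edges$from == "grade" & s$edges$to == "nrCBV"))
  expect_true(any(s$edges$from == "grade" & s$edges$to == "T1WC"))
})
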