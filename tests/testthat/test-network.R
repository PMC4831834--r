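# CLG network core: structure validation, MLE fitting, joint-Gaussian
# compilation, exact posterior inference, likelihood, serialization.

toy_symmetric_fit <- function(mu = 1, sd = 1, p_high = 0.5) {
  s <- bn_structure(list(discrete_node("grade", c("high", "low")),
                         gaussian_node("X")),
                    data.frame(from = "grade", to = "X"))
  bn_fit(s, list(
    grade = discrete_cpd("grade", c("high", "low"), prob = c(p_high, 1 - p_high)),
    X = clg_cpd("X", "grade", list(grade = c("high", "low")), character(0),
                list(`high` = list(beta0 = mu, beta = numeric(0), sigma2 = sd^2),
                     `low` = list(beta0 = -mu, beta = numeric(0), sigma2 = sd^2)))))
}

test_that("structure validation enforces the CLG constraints", {
  nodes <- list(discrete_node("grade", c("high", "low")),
                gaussian_node("X"), gaussian_node("Y"))
  expect_error(bn_structure(nodes, data.frame(from = "X", to = "grade")),
               "admissibility")
  expect_error(bn_structure(nodes, data.frame(from = c("X", "Y"),
                                              to = c("Y", "X"))), "cycle")
  expect_error(bn_structure(nodes, data.frame(from = "Z", to = "X")),
               "not a declared node")
  expect_error(discrete_node("g", "one_state"), "2 distinct states")
  s <- bn_structure(nodes, data.frame(from = c("grade", "X"), to = c("X", "Y")))
  expect_equal(topo_sort(s), c("grade", "X", "Y"))
  expect_equal(parents_of(s, "Y"), "X")
})

test_that("fit_mle recovers closed-form estimates on small tables", {
  tab <- generate_cohort(default_cohort_spec())
  s <- bn_structure(cohort_nodes(character(0)),
                    data.frame(from = "grade", to = "T1WC"))
  fit <- fit_mle(s, tab)
  expect_equal(unname(fit$cpds$grade$prob["high", 1]), 30 / 56, tolerance = 1e-12)
  # two-point gaussian: mean 2, MLE (n-denominator) variance 1
  toy <- data.frame(patient_id = c("a", "b"), grade = c("high", "low"),
                    T1WC = c("apparent", "negative"), X = c(1, 3),
                    stringsAsFactors = FALSE)
  s2 <- bn_structure(list(discrete_node("grade", c("high", "low")),
                          gaussian_node("X")))
  f2 <- fit_mle(s2, toy)
  expect_equal(f2$cpds$X$params$`(root)`$beta0, 2)
  expect_equal(f2$cpds$X$params$`(root)`$sigma2, 1)
})

test_that("CLG regression fitting matches an independent normal-equations solve", {
  set.seed(42)
  n <- 200
  x <- rnorm(n, 0, 2)
  y <- 1.5 + 0.8 * x + rnorm(n, 0, 0.5)
  tab <- data.frame(patient_id = as.character(seq_len(n)),
                    grade = rep(c("high", "low"), n / 2),
                    T1WC = rep("apparent", n), X = x, Y = y,
                    stringsAsFactors = FALSE)
  s <- bn_structure(list(discrete_node("grade", c("high", "low")),
                         gaussian_node("X"), gaussian_node("Y")),
                    data.frame(from = "X", to = "Y"))
  fit <- fit_mle(s, tab)
  Xd <- cbind(1, x)
  beta_ref <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  p <- fit$cpds$Y$params$`(root)`
  expect_equal(p$beta0, beta_ref[1], tolerance = 1e-8)
  expect_equal(unname(p$beta), beta_ref[2], tolerance = 1e-8)
  expect_equal(p$sigma2, mean((y - Xd %*% beta_ref)^2), tolerance = 1e-8)
})

test_that("zero-count parent configurations fall back to the marginal", {
  tab <- data.frame(patient_id = as.character(1:6),
                    grade = c(rep("high", 4), rep("low", 2)),
                    T1WC = c("apparent", "apparent", "slight", "apparent",
                             "negative", "negative"),
                    stringsAsFactors = FALSE)
  s <- bn_structure(cohort_nodes(character(0)),
                    data.frame(from = "grade", to = "T1WC"))
  fit <- fit_mle(s, tab)
  # no "slight"/"apparent" among low rows is fine; full fallback only when a
  # grade state has zero rows:
  tab2 <- tab; tab2$grade <- "high"
  s2 <- bn_structure(cohort_nodes(character(0)),
                     data.frame(from = "grade", to = "T1WC"))
  fit2 <- fit_mle(s2, tab2)
  expect_true(any(fit2$cpds$T1WC$fallback))
  marg <- fit2$cpds$T1WC$prob[, "low"]
  expect_equal(unname(marg),
               as.numeric(table(factor(tab2$T1WC, t1wc_states()))) / 6)
  expect_equal(fit2$metadata$families$T1WC$fallback_configs, 1)
})

test_that("joint gaussian compilation matches hand computation and sampling", {
  # chain X -> Y with Y = 2X + 1, Var(X) = 1, residual 0.5
  s <- bn_structure(list(discrete_node("grade", c("high", "low")),
                         gaussian_node("X"), gaussian_node("Y")),
                    data.frame(from = "X", to = "Y"))
  fit <- bn_fit(s, list(
    grade = discrete_cpd("grade", c("high", "low"), prob = c(0.5, 0.5)),
    X = clg_cpd("X", params = list(`(root)` = list(beta0 = 0, beta = numeric(0),
                                                   sigma2 = 1))),
    Y = clg_cpd("Y", cparents = "X",
                params = list(`(root)` = list(beta0 = 1, beta = 2, sigma2 = 0.5)))))
  jg <- joint_gaussian_for_config(fit, list(grade = "high"))
  expect_equal(unname(jg$mean), c(0, 1))
  expect_equal(jg$cov["Y", "Y"], 4.5)
  expect_equal(jg$cov["X", "Y"], 2)
  # single root gaussian: its own mean and variance
  expect_equal(jg$cov["X", "X"], 1)

  set.seed(7)
  rf <- rand_clg_fit(n_gauss = 3, second_discrete = TRUE)
  draws <- forward_sample(rf, 2e5)
  kind <- vapply(rf$structure$nodes, `[[`, character(1), "kind")
  gn <- names(kind)[kind == "gaussian"]
  cfg <- list(grade = "high", D = "b")
  sel <- draws$grade == "high" & draws$D == "b"
  jg2 <- joint_gaussian_for_config(rf, cfg)
  emp_mu <- colMeans(draws[sel, gn])
  emp_cov <- stats::cov(draws[sel, gn])
  expect_equal(unname(jg2$mean[gn]), unname(emp_mu), tolerance = 0.05)
  expect_equal(unname(jg2$cov[gn, gn]), unname(emp_cov), tolerance = 0.1)
  expect_true(isSymmetric(jg2$cov, tol = 1e-8))
  expect_true(all(eigen(jg2$cov, only.values = TRUE)$values > -1e-8))
})

test_that("posterior behaves correctly in closed-form cases", {
  fit <- toy_symmetric_fit()
  # empty evidence returns the fitted marginal
  expect_equal(unname(posterior_grade(fit)$prob), c(0.5, 0.5))
  # symmetric likelihoods at x = 0
  expect_equal(unname(posterior_grade(fit, list(X = 0))$prob), c(0.5, 0.5),
               tolerance = 1e-12)
  # closed-form Bayes rule at arbitrary x
  for (x in c(-2.3, 0.1, 1.7)) {
    lh <- dnorm(x, 1, 1); ll <- dnorm(x, -1, 1)
    expect_equal(unname(posterior_grade(fit, list(X = x))$prob["high"]),
                 lh / (lh + ll), tolerance = 1e-12)
  }
  # monotone in the evidence value
  ps <- sapply(seq(-3, 3, 0.5), function(x)
    posterior_grade(fit, list(X = x))$prob["high"])
  expect_true(all(diff(ps) > 0))
  expect_error(posterior_grade(fit, list(grade = "high")), "grade")
})

test_that("prediction uses argmax with the documented high-grade tie rule", {
  fit <- toy_symmetric_fit()
  expect_equal(predict_grade(fit, list(X = 2))$grade, "high")
  expect_equal(predict_grade(fit, list(X = -2))$grade, "low")
  expect_equal(predict_grade(fit, list(X = 0.1))$grade, "high")
  expect_equal(predict_grade(fit, list(X = 0))$grade, "high")  # exact tie
})

test_that("posterior matches the fine-grid oracle on randomized networks", {
  set.seed(314)
  for (i in 1:25) {
    fit <- rand_clg_fit(n_gauss = sample(1:3, 1),
                        second_discrete = runif(1) < 0.5)
    ev <- rand_evidence(fit)
    post <- posterior_grade(fit, ev)$prob
    oracle <- grid_posterior(fit, ev)
    expect_lt(0.5 * sum(abs(post - oracle[names(post)])), 1e-3)
    expect_equal(sum(post), 1, tolerance = 1e-10)
  }
})

test_that("pruning barren unobserved nodes leaves the posterior unchanged", {
  set.seed(99)
  fit <- rand_clg_fit(n_gauss = 2)
  # add a barren leaf: child of g1, never observed
  s2 <- bn_structure(c(unname(fit$structure$nodes), list(gaussian_node("leaf"))),
                     rbind(fit$structure$edges,
                           data.frame(from = "g1", to = "leaf")))
  cpds2 <- c(fit$cpds, list(
    leaf = clg_cpd("leaf", cparents = "g1",
                   params = list(`(root)` = list(beta0 = 0.3, beta = 1.1,
                                                 sigma2 = 0.7)))))
  fit2 <- bn_fit(s2, cpds2)
  ev <- list(g1 = 0.4, g2 = -1.2)
  expect_equal(posterior_grade(fit2, ev)$prob, posterior_grade(fit, ev)$prob,
               tolerance = 1e-12)
  expect_equal(posterior_grade(fit2, ev)$log_evidence,
               posterior_grade(fit, ev)$log_evidence, tolerance = 1e-12)
})

test_that("log_likelihood sums local terms on complete data and ignores barren nodes", {
  set.seed(5)
  fit <- toy_symmetric_fit(mu = 0.8, sd = 1.2, p_high = 0.6)
  tab <- forward_sample(fit, 50)
  tab$patient_id <- as.character(1:50)
  ll <- log_likelihood(fit, tab)
  # factorization identity: sum of local log-CPD terms
  manual <- sum(log(ifelse(tab$grade == "high", 0.6, 0.4))) +
    sum(dnorm(tab$X, ifelse(tab$grade == "high", 0.8, -0.8), 1.2, log = TRUE))
  expect_equal(ll, manual, tolerance = 1e-10)
  expect_equal(log_likelihood(fit, tab[0, ]), 0)
  # marginalization: dropping the observed column marginalizes it
  tab2 <- tab; tab2$X <- NA_real_
  expect_equal(log_likelihood(fit, tab2),
               sum(log(ifelse(tab$grade == "high", 0.6, 0.4))), tolerance = 1e-10)
})

test_that("fitted networks survive a JSON round trip bit-for-bit", {
  tab <- generate_cohort(default_cohort_spec(8L))
  gn <- build_two_part_network(tab)
  fit <- fit_mle(gn$structure, tab)
  path <- withr::local_tempfile(fileext = ".json")
  save_network(fit, path)
  back <- load_network(path)
  expect_identical(names(back$cpds), names(fit$cpds))
  for (v in names(fit$cpds)) {
    a <- fit$cpds[[v]]; b <- back$cpds[[v]]
    if (inherits(a, "discrete_cpd")) {
      expect_identical(b$prob, a$prob)
    } else {
      for (k in names(a$params)) {
        expect_identical(b$params[[k]]$beta0, a$params[[k]]$beta0)
        expect_identical(b$params[[k]]$beta, a$params[[k]]$beta)
        expect_identical(b$params[[k]]$sigma2, a$params[[k]]$sigma2)
      }
    }
  }
  # structures round trip too
  sp <- withr::local_tempfile(fileext = ".json")
  save_structure(gn$structure, sp)
  s2 <- load_structure(sp)
  expect_identical(s2$edges, gn$structure$edges)

  # schema violations are named
  x <- jsonlite::read_json(path)
  x$cpds$grade <- NULL
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(x, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_network(bad), "missing CPD for node grade")
  x2 <- jsonlite::read_json(path)
  x2$version <- "99"
  jsonlite::write_json(x2, bad, auto_unbox = TRUE, digits = NA)
  expect_error(load_network(bad), "unsupported format version")
})
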