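test_that("degenerate zero-rate likelihoods are exact", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(mk_loglik(t2, c(A = 1, B = 1), 0, 0), log(0.5))
  ll <- mk_loglik(t2, c(A = 0, B = 1), 0, 0)
  expect_true(is.infinite(ll) && ll < 0)
  expect_true(attr(ll, "impossible"))
  expect_error(mk_loglik(t2, c(A = 0, B = 1), -1, 1), "negative rate")
})

test_that("pruning equals brute-force enumeration on small random trees", {
  set.seed(401)
  for (i in 1:30) {
    n <- sample(3:5, 1)
    tr <- ape::rtree(n)
    s <- sample(0:1, n, replace = TRUE)
    q01 <- stats::runif(1, 0.05, 3)
    q10 <- stats::runif(1, 0.05, 3)
    expect_equal(mk_loglik(tr, stats::setNames(s, tr$tip.label), q01, q10),
                 brute_force_loglik(tr, s, q01, q10), tolerance = 1e-10)
  }
})

test_that("pruning agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(n_tips = 16, clades = NULL, seed = 5)
  s <- simulate_mk_trait(tr, 1, 1, seed = 9)
  fit <- fit_mk(tr, s, "ER")
  pf <- phytools::fitMk(tr, stats::setNames(factor(s), names(s)),
                        model = "ER", pi = c(0.5, 0.5))
  expect_equal(fit$logL, pf$logLik, tolerance = 1e-4)
  expect_equal(mk_loglik(tr, s, pf$rates[1], pf$rates[1]), pf$logLik,
               tolerance = 1e-6)
})

test_that("ML recovery: ER rates within a factor of 2 on a large tree", {
  # simulation-recovery at q = 1 on a deep synthetic tree; total tree length
  # gives dozens of expected changes, so the rate is well identified
  tr <- simulate_tree(n_tips = 300, clades = NULL, root_depth = 5, seed = 21)
  ok <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    s <- simulate_mk_trait(tr, 1, 1, seed = 500 + i)
    if (sum(s) %in% c(0L, length(s))) next
    fit <- fit_mk(tr, s, "ER")
    if (fit$q01 > 0.5 && fit$q01 < 2) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("ARD never fits worse than ER and boundary traits warn", {
  tr <- simulate_tree(n_tips = 16, clades = NULL, seed = 5)
  for (i in 1:5) {
    s <- simulate_mk_trait(tr, 1.5, 0.7, seed = 600 + i)
    if (sum(s) %in% c(0L, length(s))) next
    er <- fit_mk(tr, s, "ER")
    ard <- fit_mk(tr, s, "ARD")
    expect_gte(ard$logL, er$logL - 1e-4)
  }
  const <- stats::setNames(rep(1L, 16), tr$tip.label)
  expect_warning(fit <- fit_mk(tr, const, "ER"), "constant")
  expect_lt(fit$q01, 1e-6)  # rates driven to the lower bound
})

test_that("the LRT uses the chi-square(1) critical value", {
  fake <- function(model, logL) {
    structure(list(model = model, q01 = 1, q10 = 1, logL = logL, k = 1,
                   convergence = 0, n_tips = 10, n_present = 5),
              class = "mk_fit")
  }
  # identical likelihoods: keep ER
  expect_identical(select_model_lrt(fake("ER", -10), fake("ARD", -10))$model,
                   "ER")
  # 2 * delta = 10 > 3.841: choose ARD
  sel <- select_model_lrt(fake("ER", -15), fake("ARD", -10))
  expect_identical(sel$model, "ARD")
  expect_equal(sel$statistic, 10)
  # 2 * delta = 3 < 3.841: keep ER
  expect_identical(select_model_lrt(fake("ER", -11.5),
                                    fake("ARD", -10))$model, "ER")
  expect_error(select_model_lrt(fake("ER", -9), fake("ARD", -10)),
               "beyond tolerance")
})

test_that("tidy and glance expose rates and fit summaries", {
  tr <- simulate_tree(n_tips = 16, clades = NULL, seed = 5)
  s <- simulate_mk_trait(tr, 1, 1, seed = 9)
  fit <- fit_mk(tr, s, "ARD")
  td <- tidy(fit)
  expect_identical(td$term, c("q01", "q10"))
  expect_identical(glance(fit)$model, "ARD")
})
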