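test_that("maps are consistent with tip data and the parsimony bound", {
  tr <- simulate_tree(n_tips = 16, clades = NULL, seed = 5)
  s <- simulate_mk_trait(tr, 1, 1, seed = 9)
  maps <- sample_stochastic_maps(tr, s, "ER", n_sim = 200, seed = 3)
  expect_identical(length(maps$changes), 200L)
  expect_true(all(maps$changes >= fitch_score(tr, s)))
  # tip rows of the node-frequency table are the observed states
  ntip <- ape::Ntip(maps$tree)
  expect_equal(maps$node_freq[seq_len(ntip), 2],
               unname(s[maps$tree$tip.label]))
  # node frequencies are proper probabilities
  expect_true(all(abs(rowSums(maps$node_freq) - 1) < 1e-12))
})

test_that("segment durations on each branch sum to the branch length", {
  tr <- simulate_tree(n_tips = 8, clades = NULL, seed = 6)
  s <- simulate_mk_trait(tr, 2, 2, seed = 10)
  # this draw happens to be a singleton; the boundary-rate warning is fine
  maps <- suppressWarnings(
    sample_stochastic_maps(tr, s, "ER", n_sim = 20, seed = 4))
  for (m in 1:5) {
    hist <- maps$histories[[m]]
    for (k in seq_along(hist)) {
      expect_equal(sum(hist[[k]]$times), maps$tree$edge.length[k],
                   tolerance = 1e-9)
      expect_identical(length(hist[[k]]$states), length(hist[[k]]$times))
    }
  }
})

test_that("near-zero rates give the parsimony history for a singleton", {
  tr <- simulate_tree(n_tips = 10, clades = NULL, seed = 7)
  s <- stats::setNames(c(1L, rep(0L, 9)), tr$tip.label)
  fit <- structure(list(model = "ER", q01 = 1e-6, q10 = 1e-6, logL = NA,
                        k = 1, convergence = 0, n_tips = 10, n_present = 1),
                   class = "mk_fit")
  maps <- sample_stochastic_maps(tr, s, fit, n_sim = 50, seed = 8)
  expect_true(all(maps$changes == 1L))
})

test_that("node-state frequencies converge to analytic marginals", {
  tr <- simulate_tree(n_tips = 16, clades = NULL, seed = 5)
  s <- simulate_mk_trait(tr, 1, 1, seed = 9)
  fit <- fit_mk(tr, s, "ER")
  n_sim <- 500
  maps <- sample_stochastic_maps(tr, s, fit, n_sim = n_sim, seed = 11)
  marg <- mk_marginals(tr, s, fit$q01, fit$q10)
  ntip <- ape::Ntip(tr)
  nodes <- (ntip + 1L):(ntip + tr$Nnode)
  for (nd in nodes) {
    p <- marg[nd, 2]
    # 3 Monte-Carlo SE on the count scale, floored at 4 counts where the
    # normal approximation breaks down near p = 0 or 1
    bound <- max(3 * sqrt(n_sim * p * (1 - p)), 4)
    expect_lt(abs(n_sim * maps$node_freq[nd, 2] - n_sim * p), bound)
  }
})

test_that("rate uncertainty widens but does not bias the map ensemble", {
  tr <- simulate_tree(n_tips = 16, clades = NULL, seed = 5)
  s <- simulate_mk_trait(tr, 1, 1, seed = 9)
  maps <- sample_stochastic_maps(tr, s, "ER", n_sim = 60,
                                 rate_uncertainty = TRUE, seed = 13)
  expect_identical(nrow(maps$rates), 60L)
  expect_gt(stats::sd(maps$rates[, 1]), 0)  # rates actually vary
  expect_true(all(maps$changes >= fitch_score(tr, s)))
})

test_that("summaries report expected changes and clade MRCA probabilities", {
  tr <- simulate_tree(seed = 42)
  cm <- sim_clade_map(tr)
  # trait fixed present in one clade, absent elsewhere
  s <- stats::setNames(as.integer(cm$clade == "entomophagus"), cm$species)
  fit <- structure(list(model = "ER", q01 = 0.05, q10 = 0.05, logL = NA,
                        k = 1, convergence = 0, n_tips = 32,
                        n_present = sum(s)),
                   class = "mk_fit")
  maps <- sample_stochastic_maps(tr, s, fit, n_sim = 300, seed = 14)
  summ <- summarize_maps(maps, clades = cm)
  expect_equal(summ$expected_changes, mean(maps$changes))
  p_ento <- summ$mrca_presence$p_present[
    summ$mrca_presence$clade == "entomophagus"]
  expect_gt(p_ento, 0.95)
  expect_error(summarize_maps(maps, clades = data.frame(
    species = "x", clade = "nope")), "unknown clade|fewer than 2")
  # simple mean example
  fake <- maps; fake$changes <- c(2, 3, 4)
  expect_equal(summarize_maps(fake)$expected_changes, 3)
})

test_that("constant traits are rejected and seeds reproduce maps", {
  tr <- simulate_tree(n_tips = 8, clades = NULL, seed = 6)
  expect_error(
    sample_stochastic_maps(tr, stats::setNames(rep(1L, 8), tr$tip.label)),
    "constant"
  )
  s <- simulate_mk_trait(tr, 2, 1, seed = 10)
  m1 <- suppressWarnings(
    sample_stochastic_maps(tr, s, "ER", n_sim = 30, seed = 99))
  m2 <- suppressWarnings(
    sample_stochastic_maps(tr, s, "ER", n_sim = 30, seed = 99))
  expect_identical(m1$changes, m2$changes)
  expect_identical(m1$node_freq, m2$node_freq)
})
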