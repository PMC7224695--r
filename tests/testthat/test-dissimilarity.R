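test_that("Bray-Curtis matches hand computation and bounds", {
  m <- rbind(a = c(60, 40), b = c(40, 60))
  expect_equal(bray_curtis_matrix(m)["a", "b"], 0.2)  # (20+20)/200
  ident <- rbind(x = c(30, 70), y = c(30, 70))
  expect_equal(bray_curtis_matrix(ident)["x", "y"], 0)
  disjoint <- rbind(x = c(100, 0), y = c(0, 100))
  expect_equal(bray_curtis_matrix(disjoint)["x", "y"], 1)
  expect_error(bray_curtis_matrix(rbind(x = c(0, 0), y = c(1, 1))),
               "all-zero")
})

test_that("Bray-Curtis agrees with vegan on random compositions", {
  set.seed(31)
  m <- matrix(stats::runif(60), 6, 10,
              dimnames = list(paste0("s", 1:6), NULL))
  m <- 100 * m / rowSums(m)
  expect_equal(bray_curtis_matrix(m),
               as.matrix(vegan::vegdist(m, method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the Mantel test is exact on identical matrices", {
  set.seed(5)
  m <- as.matrix(stats::dist(matrix(stats::rnorm(30), 10)))
  mt <- mantel_test(m, m, n_perm = 999, seed = 1)
  expect_equal(mt$rho, 1)
  expect_equal(mt$p_value, 1 / 1000)
})

test_that("Spearman rho is invariant to monotone transforms", {
  set.seed(6)
  m1 <- as.matrix(stats::dist(matrix(stats::rnorm(30), 10)))
  m2 <- as.matrix(stats::dist(matrix(stats::rnorm(30), 10)))
  r0 <- mantel_test(m1, m2, n_perm = 99, seed = 2)$rho
  r1 <- mantel_test(m1^3, m2, n_perm = 99, seed = 2)$rho
  r2 <- mantel_test(m1, sqrt(m2), n_perm = 99, seed = 2)$rho
  expect_equal(r0, r1)
  expect_equal(r0, r2)
})

test_that("Mantel statistics agree with vegan's spearman mantel", {
  set.seed(7)
  m1 <- as.matrix(stats::dist(matrix(stats::rnorm(36), 12)))
  m2 <- as.matrix(stats::dist(matrix(stats::rnorm(36), 12)))
  ours <- mantel_test(m1, m2, n_perm = 999, seed = 3)
  ref <- vegan::mantel(m1, m2, method = "spearman", permutations = 999)
  expect_equal(ours$rho, unname(ref$statistic), tolerance = 1e-12)
  expect_error(mantel_test(m1, m2[1:10, 1:10]), "size mismatch")
})

test_that("NMDS embeds collinear configurations with near-zero stress", {
  d <- stats::dist(cbind(c(0, 1, 2, 3.5), 0))
  fit <- nmds_ordination(d, k = 2, n_restarts = 10, seed = 4)
  expect_lt(fit$stress, 0.01)
  expect_identical(nrow(fit$points), 4L)
  expect_identical(names(fit$points), c("species", "NMDS1", "NMDS2"))
})

test_that("NMDS is reproducible given a seed and rejects degenerate input", {
  set.seed(8)
  m <- as.matrix(stats::dist(matrix(stats::rnorm(40), 10)))
  f1 <- nmds_ordination(m, seed = 5)
  f2 <- nmds_ordination(m, seed = 5)
  expect_identical(f1$stress, f2$stress)
  expect_identical(f1$points, f2$points)
  deg <- matrix(1, 5, 5); diag(deg) <- 0
  expect_error(nmds_ordination(deg, seed = 1), "degenerate")
  expect_error(nmds_ordination(stats::dist(cbind(0:2)), k = 3), "more than k")
})

test_that("clade-structured profiles ordinate with clade separation", {
  tr <- simulate_tree(seed = 17)
  prof <- simulate_profiles(tr, n_compounds = 30, signal_strength = 0.95,
                            concentration = 3, seed = 18)
  bc <- bray_curtis_matrix(prof)
  fit <- nmds_ordination(bc, k = 2, n_restarts = 10, seed = 19)
  pts <- fit$points
  cm <- sim_clade_map(tr)
  pts <- dplyr::left_join(pts, cm, by = "species")
  xy <- as.matrix(pts[, c("NMDS1", "NMDS2")])
  dd <- as.matrix(stats::dist(xy))
  same <- outer(pts$clade, pts$clade, "==")
  diag(same) <- NA
  expect_lt(mean(dd[same & !is.na(same)]), mean(dd[!same & !is.na(same)]))
})
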