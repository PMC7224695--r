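# Fritz-Purvis D: phylogenetic signal for a binary trait. The observed sum
# of sister-clade differences is scaled between its expectations under
# non-phylogenetic randomness (tip-label shuffles; D = 1) and under
# Brownian-threshold evolution (D = 0). Implemented matrix-wise so the
# thousands of null replicates per trait share one postorder pass.

# Sum of sister-clade differences for each column of a tips x m matrix:
# nodal values are computed tip-to-root by averaging daughter values, and
# each internal node contributes |difference of its daughters' values|.
.d_sums <- function(tree, X) {
  X <- as.matrix(X)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  V <- matrix(0, nn, ncol(X))
  V[seq_len(ntip), ] <- X
  tr <- ape::reorder.phylo(tree, "postorder")
  d <- numeric(ncol(X))
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  # valid postorder over internal nodes: last appearance as a parent in the
  # postorder edge list comes after the node's whole subtree
  ord <- unique(tr$edge[, 1], fromLast = TRUE)
  for (node in ord) {
    ch <- kids[[as.character(node)]]
    vals <- V[ch, , drop = FALSE]
    V[node, ] <- colMeans(vals)
    d <- d + colSums(abs(sweep(vals, 2, V[node, ], "-"))) *
      (2 / length(ch))  # |a-b| for bifurcations; generalized mean deviation
  }
  d
}

# Brownian tip values: columns are independent simulations.
.brownian_tips <- function(tree, m) {
  C <- ape::vcv.phylo(tree)
  U <- chol(C)
  Z <- matrix(stats::rnorm(nrow(C) * m), nrow(C), m)
  X <- crossprod(U, Z)
  rownames(X) <- rownames(C)
  X[tree$tip.label, , drop = FALSE]
}

# Threshold continuous tip values at the rank matching a target count of 1s.
.rank_threshold <- function(X, k) {
  apply(X, 2, function(col) {
    out <- integer(length(col))
    out[order(col, decreasing = TRUE)[seq_len(k)]] <- 1L
    out
  })
}

#' Fritz-Purvis D statistic with permutation tests
#'
#' Estimates phylogenetic signal in a binary trait as
#' `D = (d_obs - mean(d_brownian)) / (mean(d_random) - mean(d_brownian))`,
#' where `d` is the sum over internal nodes of the absolute difference
#' between daughter nodal values (nodal values computed tip-to-root by
#' averaging daughters), `d_random` comes from tip-label shuffles and
#' `d_brownian` from Brownian simulations thresholded at the observed
#' prevalence. `D` is about 1 for phylogenetically random traits and about
#' 0 under Brownian-threshold evolution; `D < 0` indicates stronger
#' conservation than Brownian, `D > 1` overdispersion.
#'
#' One-sided permutation p-values for the hypotheses D = 1 (against the
#' shuffle null) and D = 0 (against the Brownian null) are converted to
#' two-sided values as `2 * min(p_low, p_high)`, capped at 1.
#'
#' D is undefined for constant traits and for singletons (a single species
#' differing from all others); these raise an error.
#'
#' @inheritParams mk_loglik
#' @param n_perm Number of tip-label shuffles (default 10000).
#' @param n_brownian Number of Brownian-threshold simulations (default
#'   10000).
#' @param seed Optional integer seed.
#' @return A `d_result`: `D`, `d_obs`, `mean_d_random`, `mean_d_brownian`,
#'   `p_d1`, `p_d0` (two-sided), `n_perm`, `n_brownian`, `prevalence`.
#' @export
estimate_D <- function(tree, states, n_perm = 10000, n_brownian = 10000,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- .states_vector(tree, states)
  n <- length(s); k <- sum(s)
  if (k %in% c(0L, n)) {
    stop("D cannot be estimated and tested for constant traits",
         call. = FALSE)
  }
  if (k %in% c(1L, n - 1L)) {
    stop("D cannot be estimated and tested for traits where a single ",
         "species differs from all others", call. = FALSE)
  }

  d_obs <- .d_sums(tree, matrix(s, ncol = 1))

  perm <- replicate(n_perm, sample(s))
  d_rand <- .d_sums(tree, perm)

  bm <- .brownian_tips(tree, n_brownian)
  d_brown <- .d_sums(tree, .rank_threshold(bm, k))

  mr <- mean(d_rand); mb <- mean(d_brown)
  D <- (d_obs - mb) / (mr - mb)

  # one-sided tails, then two-sided conversion
  p_low_rand <- (1 + sum(d_rand <= d_obs)) / (n_perm + 1)
  p_high_rand <- (1 + sum(d_rand >= d_obs)) / (n_perm + 1)
  p_d1 <- min(1, 2 * min(p_low_rand, p_high_rand))
  p_low_bm <- (1 + sum(d_brown <= d_obs)) / (n_brownian + 1)
  p_high_bm <- (1 + sum(d_brown >= d_obs)) / (n_brownian + 1)
  p_d0 <- min(1, 2 * min(p_low_bm, p_high_bm))

  structure(
    list(D = unname(D), d_obs = unname(d_obs),
         mean_d_random = mr, mean_d_brownian = mb,
         p_d1 = p_d1, p_d0 = p_d0,
         n_perm = n_perm, n_brownian = n_brownian,
         prevalence = k / n, n_tips = n,
         d_random = as.numeric(d_rand), d_brownian = as.numeric(d_brown)),
    class = "d_result"
  )
}

#' @export
print.d_result <- function(x, ...) {
  cat("<d_result> D = ", round(x$D, 4),
      "  P(D=0) = ", signif(x$p_d0, 3),
      "  P(D=1) = ", signif(x$p_d1, 3),
      "  (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up FDR control at level `q` (default 10%).
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param q FDR level.
#' @return Logical vector: TRUE where the hypothesis is rejected.
#' @export
bh_fdr <- function(pvalues, q = 0.10) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH") <= q
}
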