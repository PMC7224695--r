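# Stochastic character mapping for a binary trait: sample internal-node
# states from the conditional likelihoods root-down, then fill in each
# branch's state history conditioned on its endpoint states (rejection
# sampling with a uniformization fallback). Optionally integrates over rate
# uncertainty by drawing Q per map from a Metropolis MCMC posterior sample.

# Sample a CTMC path on one branch conditional on endpoints, by rejection.
# Returns list(states, times): segment states in order and their durations
# (summing to t), plus the number of state changes.
.branch_history_rejection <- function(a, b, q01, q10, t, max_tries = 500L) {
  rates <- c(q01, q10)  # leaving rate of state 0 is q01, of state 1 is q10
  for (try in seq_len(max_tries)) {
    s <- a; tt <- 0; states <- a; times <- numeric(0)
    repeat {
      r <- rates[s + 1L]
      w <- if (r > 0) stats::rexp(1, r) else Inf
      if (tt + w >= t) { times <- c(times, t - tt); break }
      tt <- tt + w
      times <- c(times, w)
      s <- 1L - s
      states <- c(states, s)
    }
    if (s == b) return(list(states = states, times = times))
  }
  NULL
}

# Uniformization fallback: exact conditional path via the uniformized chain.
.branch_history_uniformization <- function(a, b, q01, q10, t) {
  mu <- max(q01, q10) * 1.05 + 1e-12
  R <- diag(2) + matrix(c(-q01, q01, q10, -q10), 2, byrow = TRUE) / mu
  Pt <- mk_pmat(q01, q10, t)[a + 1L, b + 1L]
  if (Pt <= 0) stop("impossible endpoint pair in uniformization",
                    call. = FALSE)
  # P(N = n | a, b, t) ~ dpois(n, mu t) R^n[a,b] / Pt; sample by inversion
  # over a truncated support.
  nmax <- max(20L, stats::qpois(1 - 1e-10, mu * t) + 5L)
  Rn <- diag(2); probs <- numeric(nmax + 1L)
  for (n in 0:nmax) {
    probs[n + 1L] <- stats::dpois(n, mu * t) * Rn[a + 1L, b + 1L]
    Rn <- Rn %*% R
  }
  probs <- probs / sum(probs)
  N <- sample.int(nmax + 1L, 1L, prob = probs) - 1L
  if (N == 0L) return(list(states = a, times = t))
  # virtual jump chain bridge: sample states at the N jump points
  jumps <- sort(stats::runif(N, 0, t))
  chain <- integer(N + 1L); chain[1] <- a
  # backward probabilities R^(N-k)[., b]
  Rpow <- vector("list", N + 1L); Rpow[[1]] <- diag(2)
  for (k in seq_len(N)) Rpow[[k + 1L]] <- Rpow[[k]] %*% R
  for (k in seq_len(N)) {
    prev <- chain[k]
    w <- R[prev + 1L, ] * Rpow[[N - k + 1L]][, b + 1L]
    chain[k + 1L] <- sample.int(2L, 1L, prob = w) - 1L
  }
  # collapse virtual self-transitions
  bounds <- c(0, jumps, t)
  keep <- c(TRUE, diff(chain) != 0)
  states <- chain[keep]
  seg_start <- bounds[-length(bounds)][keep]
  times <- diff(c(seg_start, t))
  list(states = states, times = times)
}

.branch_history <- function(a, b, q01, q10, t) {
  h <- .branch_history_rejection(a, b, q01, q10, t)
  if (is.null(h)) h <- .branch_history_uniformization(a, b, q01, q10, t)
  h
}

# Metropolis sampler on log-rates with gamma priors; returns a matrix of
# (q01, q10) draws, one per requested map.
.mk_rate_mcmc <- function(tree, s, model, fit, n_sim,
                          burnin = 1000L, thin = 10L, prop_sd = 0.5) {
  npar <- if (model == "ER") 1L else 2L
  # gamma prior centered on the ML prefit (shape 2 => mild regularization)
  prior_rate <- 2 / max(c(fit$q01, fit$q10), 1e-6)
  logpost <- function(lp) {
    q <- exp(lp)
    ll <- if (model == "ER") mk_loglik(tree, s, q[1], q[1]) else
      mk_loglik(tree, s, q[1], q[2])
    if (!is.finite(ll)) return(-Inf)
    ll + sum(stats::dgamma(q, shape = 2, rate = prior_rate, log = TRUE)) +
      sum(lp)  # Jacobian of the log transform
  }
  cur <- log(pmax(c(fit$q01, fit$q10)[seq_len(npar)], 1e-8))
  cur_lp <- logpost(cur)
  out <- matrix(NA_real_, n_sim, 2)
  n_iter <- burnin + thin * n_sim
  j <- 0L
  for (i in seq_len(n_iter)) {
    prop <- cur + stats::rnorm(npar, 0, prop_sd)
    prop_lp <- logpost(prop)
    if (is.finite(prop_lp) && log(stats::runif(1)) < prop_lp - cur_lp) {
      cur <- prop; cur_lp <- prop_lp
    }
    if (i > burnin && (i - burnin) %% thin == 0L) {
      j <- j + 1L
      q <- exp(cur)
      out[j, ] <- if (model == "ER") c(q[1], q[1]) else q
    }
  }
  out
}

#' Sample stochastic character maps
#'
#' Draws full character histories consistent with the tip data: internal-node
#' states are sampled from their conditional distributions root-down (equal
#' root prior), then each branch history is simulated conditional on its
#' endpoint states. With `rate_uncertainty = TRUE`, each map uses a Q drawn
#' from a Metropolis MCMC posterior over the rates (gamma prior centered on
#' the ML fit, 1000 burn-in, thinned); otherwise all maps use the ML rates.
#'
#' @inheritParams mk_loglik
#' @param model `"ER"` or `"ARD"`, or an `mk_fit` object.
#' @param n_sim Number of maps (default 100).
#' @param rate_uncertainty Draw rates from an MCMC posterior per map.
#' @param seed Optional integer seed for reproducibility.
#' @return A `simmap_set`: `changes` (per-map change counts), `node_freq`
#'   (nodes x 2 matrix of state frequencies over maps, rows summing to 1),
#'   `histories` (per map, per edge segment lists), `rates` (per-map Q),
#'   plus the `tree`.
#' @export
sample_stochastic_maps <- function(tree, states, model = "ER", n_sim = 100,
                                   rate_uncertainty = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- .states_vector(tree, states)
  n1 <- sum(s)
  if (n1 %in% c(0L, length(s))) {
    stop("trait is constant; stochastic mapping is undefined", call. = FALSE)
  }
  fit <- if (inherits(model, "mk_fit")) model else fit_mk(tree, s, model)
  model_name <- fit$model

  rates <- if (rate_uncertainty) {
    .mk_rate_mcmc(tree, s, model_name, fit, n_sim)
  } else {
    matrix(rep(c(fit$q01, fit$q10), each = n_sim), n_sim, 2)
  }

  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  tr <- ape::reorder.phylo(tree, "postorder")
  pre_edges <- rev(seq_len(nrow(tr$edge)))  # preorder traversal of edges

  node_counts <- matrix(0, nn, 2)
  changes <- integer(n_sim)
  histories <- vector("list", n_sim)

  for (m in seq_len(n_sim)) {
    q01 <- rates[m, 1]; q10 <- rates[m, 2]
    L <- .mk_partials(tree, s, q01, q10)
    node_state <- integer(nn)
    node_state[seq_len(ntip)] <- s
    w <- 0.5 * L[root, ]
    if (sum(w) <= 0) stop("tip data impossible under the sampled rates",
                          call. = FALSE)
    node_state[root] <- sample.int(2L, 1L, prob = w) - 1L
    hist_m <- vector("list", nrow(tr$edge))
    nchanges <- 0L
    for (k in pre_edges) {
      par <- tr$edge[k, 1]; chi <- tr$edge[k, 2]
      t <- tr$edge.length[k]
      P <- mk_pmat(q01, q10, t)
      if (chi > ntip) {
        w <- P[node_state[par] + 1L, ] * L[chi, ]
        node_state[chi] <- sample.int(2L, 1L, prob = w) - 1L
      }
      h <- .branch_history(node_state[par], node_state[chi], q01, q10, t)
      hist_m[[k]] <- h
      nchanges <- nchanges + length(h$states) - 1L
    }
    changes[m] <- nchanges
    histories[[m]] <- hist_m
    node_counts[cbind(seq_len(nn), node_state + 1L)] <-
      node_counts[cbind(seq_len(nn), node_state + 1L)] + 1
  }

  structure(
    list(tree = tr, changes = changes,
         node_freq = node_counts / n_sim,
         histories = histories, rates = rates,
         model = model_name, n_sim = n_sim),
    class = "simmap_set"
  )
}

#' @export
print.simmap_set <- function(x, ...) {
  cat("<simmap_set> ", x$n_sim, " maps (", x$model,
      "), expected changes = ", round(mean(x$changes), 2), "\n", sep = "")
  invisible(x)
}

#' Summarize a set of stochastic maps
#'
#' Mean change count over maps and, when a clade map is supplied, the
#' probability that each named clade's MRCA carried the trait.
#'
#' @param maps A `simmap_set`.
#' @param clades Optional tibble with columns `species`, `clade`.
#' @return A list: `expected_changes`, `node_probabilities` (tibble of node,
#'   p_absent, p_present), and (with clades) `mrca_presence` (tibble of
#'   clade, node, p_present).
#' @export
summarize_maps <- function(maps, clades = NULL) {
  stopifnot(inherits(maps, "simmap_set"))
  tree <- maps$tree
  ntip <- ape::Ntip(tree)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  node_probs <- tibble::tibble(
    node = nodes,
    p_absent = maps$node_freq[nodes, 1],
    p_present = maps$node_freq[nodes, 2]
  )
  out <- list(expected_changes = mean(maps$changes),
              node_probabilities = node_probs)
  if (!is.null(clades)) {
    cl <- unique(clades$clade)
    out$mrca_presence <- purrr::map_dfr(cl, function(x) {
      node <- clade_mrca(tree, clades, x)
      tibble::tibble(clade = x, node = node,
                     p_present = maps$node_freq[node, 2])
    })
  }
  out
}

#' Fitch parsimony score of a binary trait
#'
#' Minimum number of state changes needed on the tree; every stochastic map
#' must contain at least this many changes.
#'
#' @inheritParams mk_loglik
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, states) {
  s <- .states_vector(tree, states)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- s[i]
  tr <- ape::reorder.phylo(tree, "postorder")
  score <- 0L
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; chi <- tr$edge[k, 2]
    if (is.null(sets[[par]])) {
      sets[[par]] <- sets[[chi]]
    } else {
      inter <- intersect(sets[[par]], sets[[chi]])
      if (length(inter)) {
        sets[[par]] <- inter
      } else {
        sets[[par]] <- union(sets[[par]], sets[[chi]])
        score <- score + 1L
      }
    }
  }
  score
}
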