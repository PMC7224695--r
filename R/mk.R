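# Two-state Mk model machinery: closed-form transition probabilities,
# Felsenstein pruning log-likelihood with an equal (1/2, 1/2) root prior,
# maximum-likelihood fitting of the equal-rates (ER) and all-rates-differ
# (ARD) parameterizations, and likelihood-ratio model selection.

#' Two-state transition probability matrix
#'
#' For rates `q01` (0 -> 1) and `q10` (1 -> 0) over time `t`:
#' `P(t) = pi + (I - pi) * exp(-(q01 + q10) t)` row-wise, where `pi` is the
#' stationary distribution. `q01 = q10 = 0` gives the identity.
#'
#' @param q01,q10 Non-negative rates per unit branch length.
#' @param t Non-negative time (branch length).
#' @return A 2x2 matrix, rows = starting state (0, 1).
#' @export
mk_pmat <- function(q01, q10, t) {
  if (q01 < 0 || q10 < 0) stop("negative rate", call. = FALSE)
  q <- q01 + q10
  if (q == 0) return(diag(2))
  e <- exp(-q * t)
  p0 <- q10 / q  # stationary probability of state 0
  p1 <- q01 / q
  matrix(c(p0 + p1 * e, p1 - p1 * e,
           p0 - p0 * e, p1 + p0 * e),
         nrow = 2, byrow = TRUE)
}

.states_vector <- function(tree, states) {
  if (is.null(names(states))) {
    stopifnot(length(states) == ape::Ntip(tree))
    names(states) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) {
    stop("states missing for tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  s <- as.integer(states[tree$tip.label])
  if (!all(s %in% c(0L, 1L))) stop("states must be 0/1", call. = FALSE)
  s
}

# Postorder partial likelihoods for all nodes. Returns an (Ntip+Nnode) x 2
# matrix of conditional likelihoods of the data below each node.
.mk_partials <- function(tree, tipstates, q01, q10) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  L <- matrix(1, nn, 2)
  L[cbind(seq_len(ntip), 2L - tipstates)] <- 0  # tip state s -> column s+1
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; chi <- tr$edge[k, 2]
    P <- mk_pmat(q01, q10, tr$edge.length[k])
    L[par, ] <- L[par, ] * as.vector(P %*% L[chi, ])
  }
  L
}

#' Pruning log-likelihood of a binary trait under the Mk model
#'
#' Felsenstein pruning over the closed-form two-state transition
#' probabilities, with an equal (1/2, 1/2) prior on the root state.
#' Data impossible under the rates (e.g. differing tips with both rates
#' zero) give `-Inf` with attribute `impossible = TRUE`.
#'
#' @param tree An ape `phylo` with branch lengths.
#' @param states Named 0/1 vector over the tips (or unnamed in tip order).
#' @param q01,q10 Non-negative transition rates.
#' @param root_prior Root state prior (default equal).
#' @return The log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, states, q01, q10, root_prior = c(0.5, 0.5)) {
  if (q01 < 0 || q10 < 0) stop("negative rate", call. = FALSE)
  s <- .states_vector(tree, states)
  L <- .mk_partials(tree, s, q01, q10)
  root <- ape::Ntip(tree) + 1L
  lik <- sum(root_prior * L[root, ])
  if (lik <= 0) return(structure(-Inf, impossible = TRUE))
  log(lik)
}

#' Marginal ancestral state probabilities under the Mk model
#'
#' Exact per-node marginals from the two-pass (down/up) algorithm: the
#' down-pass computes the conditional likelihood of the data below each
#' node, the up-pass the likelihood of everything above it; their product,
#' with the equal root prior, normalizes to the marginal posterior.
#' Stochastic-map node-state frequencies converge to these values.
#'
#' @inheritParams mk_loglik
#' @return An (Ntip + Nnode) x 2 matrix of marginal probabilities (tip rows
#'   are their observed states).
#' @export
mk_marginals <- function(tree, states, q01, q10, root_prior = c(0.5, 0.5)) {
  s <- .states_vector(tree, states)
  L <- .mk_partials(tree, s, q01, q10)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  tr <- ape::reorder.phylo(tree, "postorder")
  # "above" partials A: A[root, ] = prior; children in preorder
  A <- matrix(0, nn, 2)
  A[root, ] <- root_prior
  # per-edge child messages M_k(i) = sum_j P_ij(t_k) L[child_k, j]
  msg <- matrix(0, nrow(tr$edge), 2)
  for (k in seq_len(nrow(tr$edge))) {
    P <- mk_pmat(q01, q10, tr$edge.length[k])
    msg[k, ] <- as.vector(P %*% L[tr$edge[k, 2], ])
  }
  for (k in rev(seq_len(nrow(tr$edge)))) {  # preorder
    par <- tr$edge[k, 1]; chi <- tr$edge[k, 2]
    P <- mk_pmat(q01, q10, tr$edge.length[k])
    sib <- which(tr$edge[, 1] == par)
    sib <- sib[sib != k]
    g <- A[par, ]
    for (kk in sib) g <- g * msg[kk, ]
    A[chi, ] <- as.vector(g %*% P)
  }
  post <- A * L
  post / rowSums(post)
}

#' Fit a two-state Mk model by maximum likelihood
#'
#' Bounded optimization on the log-rate scale with multiple starts; the ER
#' model has one rate (`q01 = q10`), ARD two. Constant or singleton traits
#' are fit with a warning (estimates sit at the optimizer boundary and carry
#' little information).
#'
#' @inheritParams mk_loglik
#' @param model `"ER"` or `"ARD"`.
#' @param bounds Rate bounds (default `c(1e-9, 1e3)` per unit branch length).
#' @return An object of class `mk_fit`: fields `model`, `q01`, `q10`,
#'   `logL`, `k` (number of free rates), `convergence`.
#' @export
fit_mk <- function(tree, states, model = c("ER", "ARD"),
                   bounds = c(1e-9, 1e3)) {
  model <- match.arg(model)
  s <- .states_vector(tree, states)
  n1 <- sum(s)
  if (n1 %in% c(0L, length(s), 1L, length(s) - 1L)) {
    warning("trait is ", if (n1 %in% c(0L, length(s))) "constant"
            else "a singleton",
            "; rate estimates will sit near the boundary", call. = FALSE)
  }
  lb <- log(bounds[1]); ub <- log(bounds[2])
  # parsimony-informed central start: changes per unit tree length
  start0 <- log(max(min(n1, length(s) - n1), 0.5) / sum(tree$edge.length))
  start0 <- min(max(start0, lb + 1), ub - 1)
  starts <- unique(pmin(pmax(c(start0, start0 - 3, start0 + 3, 0), lb), ub))

  nll <- if (model == "ER") {
    function(p) -mk_loglik(tree, s, exp(p[1]), exp(p[1]))
  } else {
    function(p) -mk_loglik(tree, s, exp(p[1]), exp(p[2]))
  }
  npar <- if (model == "ER") 1L else 2L
  best <- NULL
  for (st in starts) {
    par0 <- rep(st, npar)
    fit <- tryCatch(
      stats::optim(par0, nll, method = "L-BFGS-B",
                   lower = rep(lb, npar), upper = rep(ub, npar)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("Mk optimization failed", call. = FALSE)
  q <- exp(best$par)
  structure(
    list(model = model,
         q01 = q[1], q10 = if (model == "ER") q[1] else q[2],
         logL = -best$value, k = npar, convergence = best$convergence,
         n_tips = length(s), n_present = n1),
    class = "mk_fit"
  )
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("<mk_fit> ", x$model, "  q01 = ", signif(x$q01, 4),
      "  q10 = ", signif(x$q10, 4), "  logL = ", round(x$logL, 4), "\n",
      sep = "")
  invisible(x)
}

#' Likelihood-ratio model selection between ER and ARD
#'
#' ER is nested in ARD; rejects ER when `2 * (logL_ARD - logL_ER)` exceeds
#' the chi-square(1) critical value at `alpha`.
#'
#' @param er,ard `mk_fit` objects for the same tree and trait.
#' @param alpha Test level (default 0.05).
#' @param tol Tolerance for the nestedness check (`logL_ARD` may fall below
#'   `logL_ER` by at most `tol` through optimizer noise).
#' @return A list: `model` (`"ER"` or `"ARD"`), `statistic`, `df`,
#'   `p_value`, and the chosen `fit`.
#' @export
select_model_lrt <- function(er, ard, alpha = 0.05, tol = 1e-3) {
  stopifnot(inherits(er, "mk_fit"), inherits(ard, "mk_fit"),
            er$model == "ER", ard$model == "ARD")
  delta <- ard$logL - er$logL
  if (delta < -tol) {
    stop("logL_ARD < logL_ER beyond tolerance (", signif(delta, 3),
         "); ARD optimization has not converged", call. = FALSE)
  }
  stat <- max(2 * delta, 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  chosen <- if (p < alpha) "ARD" else "ER"
  list(model = chosen, statistic = stat, df = 1L, p_value = p,
       fit = if (chosen == "ARD") ard else er)
}
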