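# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an Mk model fit
#'
#' @param x An `mk_fit`.
#' @param ... Unused.
#' @return One row per rate: `term`, `estimate`.
#' @export
tidy.mk_fit <- function(x, ...) {
  tibble::tibble(term = c("q01", "q10"), estimate = c(x$q01, x$q10))
}

#' @rdname tidy.mk_fit
#' @return For `glance`: one row with `model`, `logL`, `k`, `n_tips`,
#'   `n_present`, `convergence`.
#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logL = x$logL, k = x$k,
                 n_tips = x$n_tips, n_present = x$n_present,
                 convergence = x$convergence)
}

#' Tidy a D-statistic result
#'
#' @param x A `d_result`.
#' @param ... Unused.
#' @return One row: `D`, `d_obs`, `mean_d_random`, `mean_d_brownian`,
#'   `p_d0`, `p_d1`, `prevalence`, `n_perm`, `n_brownian`.
#' @export
tidy.d_result <- function(x, ...) {
  tibble::tibble(D = x$D, d_obs = x$d_obs,
                 mean_d_random = x$mean_d_random,
                 mean_d_brownian = x$mean_d_brownian,
                 p_d0 = x$p_d0, p_d1 = x$p_d1,
                 prevalence = x$prevalence,
                 n_perm = x$n_perm, n_brownian = x$n_brownian)
}

#' Tidy a stochastic-map set
#'
#' @param x A `simmap_set`.
#' @param ... Unused.
#' @return One row per map: `map`, `changes`, `q01`, `q10`.
#' @export
tidy.simmap_set <- function(x, ...) {
  tibble::tibble(map = seq_along(x$changes), changes = x$changes,
                 q01 = x$rates[, 1], q10 = x$rates[, 2])
}

#' @rdname tidy.simmap_set
#' @return For `glance`: one row with `n_sim`, `model`, `expected_changes`.
#' @export
glance.simmap_set <- function(x, ...) {
  tibble::tibble(n_sim = x$n_sim, model = x$model,
                 expected_changes = mean(x$changes))
}

#' Tidy a Mantel test result
#'
#' @param x A `mantel_result`.
#' @param ... Unused.
#' @return One row: `rho`, `p_value`, `n_perm`, `n`.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p_value,
                 n_perm = x$n_perm, n = x$n)
}

#' Tidy an NMDS ordination
#'
#' @param x An `nmds_result`.
#' @param ... Unused.
#' @return The site scores: `species`, `NMDS1`, ..., one row per object.
#' @export
tidy.nmds_result <- function(x, ...) x$points

#' @rdname tidy.nmds_result
#' @return For `glance`: one row with `stress`, `n_restarts`, `converged`.
#' @export
glance.nmds_result <- function(x, ...) {
  tibble::tibble(stress = x$stress, n_restarts = x$n_restarts,
                 converged = x$converged)
}
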