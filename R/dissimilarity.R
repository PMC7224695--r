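# Compositional comparison: Bray-Curtis dissimilarity between closed
# profiles, a Spearman Mantel test against patristic distances, and NMDS
# ordination (vegan's monoMDS engine, best of several random restarts).

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`, in `[0, 1]`, 0 for
#' identical profiles and 1 for disjoint supports.
#'
#' @param profiles A closed composition tibble (from [close_composition()])
#'   or a species-by-compound numeric matrix.
#' @return A symmetric matrix with zero diagonal and species dimnames.
#' @export
bray_curtis_matrix <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  if (any(rowSums(m) <= 0)) {
    stop("all-zero species row(s): ",
         paste(rownames(m)[rowSums(m) <= 0], collapse = ", "), call. = FALSE)
  }
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      bc <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
      out[i, j] <- out[j, i] <- bc
    }
  }
  out
}

.lower_tri <- function(m) m[lower.tri(m)]

#' Mantel test between two distance matrices
#'
#' Spearman rank correlation over the lower triangles, with significance
#' from joint row/column permutations of the first matrix:
#' `p = (1 + #[rho_perm >= rho_obs]) / (n_perm + 1)` (one-sided, positive
#' association). Ties are midranked.
#'
#' @param m1,m2 Symmetric dissimilarity matrices of equal size. When both
#'   have dimnames, `m2` is aligned to `m1`'s labels.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A `mantel_result`: `rho`, `p_value`, `n_perm`, `n`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2))) {
    stop("matrix size mismatch: ", nrow(m1), " vs ", nrow(m2), call. = FALSE)
  }
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) {
      stop("matrix labels do not match", call. = FALSE)
    }
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  n <- nrow(m1)
  r2 <- rank(.lower_tri(m2))
  rho_of <- function(m) stats::cor(rank(.lower_tri(m)), r2)
  rho_obs <- rho_of(m1)
  rho_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    rho_of(m1[p, p])
  }, numeric(1))
  p <- (1 + sum(rho_perm >= rho_obs)) / (n_perm + 1)
  structure(
    list(rho = rho_obs, p_value = p, n_perm = n_perm, n = n,
         rho_perm = rho_perm),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("<mantel_result> Spearman rho = ", round(x$rho, 4),
      ", p = ", signif(x$p_value, 3), " (", x$n_perm, " permutations)\n",
      sep = "")
  invisible(x)
}

#' NMDS ordination of a dissimilarity matrix
#'
#' Non-metric multidimensional scaling minimizing Kruskal stress-1 via
#' monotone regression (vegan's `monoMDS`), keeping the best of
#' `n_restarts` random starts. Deterministic for a given seed.
#'
#' @param dissim A symmetric dissimilarity matrix or `dist`.
#' @param k Ordination dimension (default 2).
#' @param n_restarts Number of random starts (default 20).
#' @param seed Optional integer seed.
#' @return An `nmds_result`: `points` tibble (species, NMDS1..NMDSk),
#'   `stress` (Kruskal stress-1, 0-1 scale), `n_restarts`, `converged`.
#' @export
nmds_ordination <- function(dissim, k = 2, n_restarts = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- stats::as.dist(dissim)
  n <- attr(d, "Size")
  if (n <= k) stop("need more than k objects for a k-dimensional NMDS",
                   call. = FALSE)
  if (diff(range(d)) == 0) {
    stop("degenerate dissimilarities: all values equal", call. = FALSE)
  }
  best <- vegan::monoMDS(d, k = k, model = "global")
  for (i in seq_len(max(0, n_restarts - 1))) {
    init <- matrix(stats::rnorm(n * k), n, k)
    fit <- vegan::monoMDS(d, y = init, k = k, model = "global")
    if (fit$stress < best$stress - 1e-12) best <- fit
  }
  pts <- tibble::as_tibble(best$points, .name_repair = "minimal")
  names(pts) <- paste0("NMDS", seq_len(k))
  pts <- dplyr::bind_cols(
    tibble::tibble(species = labels(d) %||% as.character(seq_len(n))), pts
  )
  structure(
    list(points = pts, stress = best$stress, n_restarts = n_restarts,
         converged = isTRUE(best$maxits > best$iters) || best$stress < 1e-6,
         engine = "vegan::monoMDS"),
    class = "nmds_result"
  )
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("<nmds_result> k = ", ncol(x$points) - 1L,
      ", stress = ", signif(x$stress, 4),
      ", ", x$n_restarts, " restarts\n", sep = "")
  invisible(x)
}
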