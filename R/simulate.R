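# Seed-deterministic simulators for every input the pipeline consumes:
# clade-structured ultrametric trees (root depth 1, emulating a chronogram
# with root age 1), binary traits evolved under Mk or Brownian-threshold
# models, compositional profiles with tunable phylogenetic signal, and MGF
# spectra with planted compounds, diagnostic fragments, ppm noise and decoys.

.default_clades <- c(pacificus = 10L, maupasi = 7L, entomophagus = 6L,
                     triformis = 5L, outgroup = 4L)

# rescale a phylo so all tips sit at depth `depth`
.make_ultrametric <- function(tree, depth) {
  tip_depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  # stretch terminal branches so every tip reaches the maximum depth
  ext <- max(tip_depths) - tip_depths
  term <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
  tree$edge.length[term] <- tree$edge.length[term] + ext
  tree$edge.length <- tree$edge.length * depth / max(tip_depths)
  tree
}

.pure_birth <- function(n, tip_labels) {
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- tip_labels
  tree
}

#' Simulate a clade-structured ultrametric tree
#'
#' Pure-birth subtrees for each named clade are grafted onto a pure-birth
#' backbone and the whole tree is rescaled to be ultrametric with the given
#' root depth. The default clade layout mirrors a 32-species ingroup split
#' into four major clades plus an outgroup; pass `clades = NULL` for an
#' unstructured pure-birth tree.
#'
#' @param n_tips Number of tips (>= 2); ignored when `clades` is given.
#' @param clades Named integer vector of clade sizes (must sum to `n_tips`
#'   if both are given), or `NULL`.
#' @param root_depth Tip-to-root depth of the ultrametric tree (default 1).
#' @param seed Integer seed (required: all generators are deterministic).
#' @return An ape `phylo`; when clades are used, tip labels are
#'   `<clade>_<i>`, each clade is monophyletic, and the species-to-clade map
#'   is attached as attribute `clade_map` (also via [sim_clade_map()]).
#' @export
simulate_tree <- function(n_tips = 32, clades = .default_clades,
                          root_depth = 1, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  if (is.null(clades)) {
    stopifnot(n_tips >= 2)
    if (n_tips == 2) {
      tree <- ape::read.tree(text = sprintf("(t1:%g,t2:%g);",
                                            root_depth, root_depth))
      return(tree)
    }
    tree <- .pure_birth(n_tips, paste0("t", seq_len(n_tips)))
    return(.make_ultrametric(tree, root_depth))
  }
  if (!missing(n_tips) && sum(clades) != n_tips) {
    stop("clade sizes sum to ", sum(clades), ", not n_tips = ", n_tips,
         call. = FALSE)
  }
  k <- length(clades)
  backbone <- if (k == 2) {
    ape::read.tree(text = "(c1:1,c2:1);")
  } else {
    .pure_birth(k, paste0("c", seq_len(k)))
  }
  backbone <- .make_ultrametric(backbone, 1)
  # graft each clade subtree in place of its backbone tip, shortening the
  # terminal branch so tips remain at depth 1
  clade_depth <- 0.3
  term <- match(seq_len(k), backbone$edge[, 2])
  backbone$edge.length[term] <- pmax(backbone$edge.length[term] - clade_depth,
                                     0.02)
  tree <- backbone
  for (i in seq_len(k)) {
    nm <- names(clades)[i]
    labels <- sprintf("%s_%02d", nm, seq_len(clades[i]))
    sub <- if (clades[i] == 1) NULL else if (clades[i] == 2) {
      ape::read.tree(text = sprintf("(%s:%g,%s:%g);", labels[1], clade_depth,
                                    labels[2], clade_depth))
    } else {
      .make_ultrametric(.pure_birth(clades[i], labels), clade_depth)
    }
    if (is.null(sub)) {
      tree$tip.label[tree$tip.label == paste0("c", i)] <- labels
    } else {
      tree <- ape::bind.tree(tree, sub,
                             where = which(tree$tip.label == paste0("c", i)))
    }
  }
  tree <- .make_ultrametric(tree, root_depth)
  attr(tree, "clade_map") <- tibble::tibble(
    species = tree$tip.label,
    clade = sub("_[0-9]+$", "", tree$tip.label)
  )
  tree
}

#' Species-to-clade map of a simulated tree
#'
#' @param tree A tree from [simulate_tree()] (or any tree whose tip labels
#'   follow the `<clade>_<i>` convention).
#' @return Tibble with columns `species`, `clade`.
#' @export
sim_clade_map <- function(tree) {
  attr(tree, "clade_map") %||%
    tibble::tibble(species = tree$tip.label,
                   clade = sub("_[0-9]+$", "", tree$tip.label))
}

#' Simulate a binary trait under the Mk model
#'
#' Root state drawn from the equal prior; state changes along each branch
#' follow exponential waiting times with rates `q01`, `q10`.
#'
#' @param tree An ape `phylo`.
#' @param q01,q10 Non-negative transition rates.
#' @param seed Integer seed.
#' @return Named 0/1 integer vector over the tips.
#' @export
simulate_mk_trait <- function(tree, q01, q10, seed) {
  stopifnot(!missing(seed), q01 >= 0, q10 >= 0)
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  state <- integer(nn)
  root <- ntip + 1L
  state[root] <- sample(0:1, 1)
  tr <- ape::reorder.phylo(tree, "postorder")
  rates <- c(q01, q10)
  for (k in rev(seq_len(nrow(tr$edge)))) {  # preorder
    par <- tr$edge[k, 1]; chi <- tr$edge[k, 2]
    s <- state[par]; t <- tr$edge.length[k]; tt <- 0
    repeat {
      r <- rates[s + 1L]
      w <- if (r > 0) stats::rexp(1, r) else Inf
      if (tt + w >= t) break
      tt <- tt + w; s <- 1L - s
    }
    state[chi] <- s
  }
  stats::setNames(state[seq_len(ntip)], tree$tip.label)
}

#' Simulate a Brownian-threshold binary trait
#'
#' Brownian values on the tips (variance proportional to depth, shared
#' ancestry inducing covariance), thresholded at the rank that yields
#' exactly `round(prevalence * n_tips)` present states — the generating
#' model under which the D statistic is calibrated to 0.
#'
#' @param tree An ape `phylo`.
#' @param prevalence Target fraction of present tips, strictly inside (0, 1)
#'   and not rounding to 0 or all tips.
#' @param seed Integer seed.
#' @return Named 0/1 integer vector over the tips.
#' @export
simulate_threshold_trait <- function(tree, prevalence, seed) {
  stopifnot(!missing(seed), prevalence > 0, prevalence < 1)
  set.seed(seed)
  n <- ape::Ntip(tree)
  k <- round(prevalence * n)
  if (k %in% c(0L, n)) {
    stop("prevalence ", prevalence, " yields ", k, " present tips of ", n,
         call. = FALSE)
  }
  x <- .brownian_tips(tree, 1)
  stats::setNames(as.integer(.rank_threshold(x, k)), tree$tip.label)
}

#' Simulate compositional profiles with tunable phylogenetic signal
#'
#' Each compound's latent tip values are a mixture
#' `signal_strength * (Brownian on the tree) + (1 - signal_strength) *
#' (independent noise)`, both standardized; profiles are closed to 100% per
#' species through a softmax, which keeps every composition strictly
#' positive (Bray-Curtis is degenerate on all-zero rows).
#'
#' @param tree An ape `phylo`.
#' @param n_compounds Number of compounds (default 46, a realistic
#'   quantifiable-compound count for this study system).
#' @param signal_strength Mixture weight in `[0, 1]`: 0 = pure noise,
#'   1 = pure Brownian signal.
#' @param concentration Softmax temperature scaling (default 1).
#' @param seed Integer seed.
#' @return A closed composition tibble (`species`, `compound`, `percent`,
#'   attribute `mode = "closed_all"`), rows per species summing to 100.
#' @export
simulate_profiles <- function(tree, n_compounds = 46, signal_strength,
                              concentration = 1, seed) {
  stopifnot(!missing(seed), signal_strength >= 0, signal_strength <= 1)
  set.seed(seed)
  n <- ape::Ntip(tree)
  bm <- .brownian_tips(tree, n_compounds)
  bm <- scale(bm)
  noise <- matrix(stats::rnorm(n * n_compounds), n, n_compounds)
  latent <- concentration *
    (signal_strength * bm + (1 - signal_strength) * noise)
  expd <- exp(latent - apply(latent, 1, max))
  comp <- 100 * expd / rowSums(expd)
  dimnames(comp) <- list(tree$tip.label,
                         sprintf("compound_%02d", seq_len(n_compounds)))
  out <- tibble::as_tibble(comp, rownames = "species") |>
    tidyr::pivot_longer(-"species", names_to = "compound",
                        values_to = "percent")
  attr(out, "mode") <- "closed_all"
  out
}

#' Simulate MS/MS spectra with planted compounds
#'
#' One spectrum per planted structure: the precursor sits at the theoretical
#' m/z of the class-appropriate adduct (`[M-H]-` for UPAS, `[M+Na]+`
#' otherwise) perturbed by Gaussian ppm error; class-diagnostic fragment
#' peaks are added for DASC/UBAS/UPAS compounds; `n_decoys` random peaks are
#' drawn uniformly over the scan range. Decoy m/z values are resampled to
#' lie at least `decoy_min_ppm` away from every diagnostic ion so planted
#' and random signals stay separable by construction. Optional decoy spectra
#' carry precursors similarly separated from every library candidate m/z.
#'
#' @param compounds List of `ndmm` structures, or a library tibble with a
#'   `structure` column.
#' @param ppm_sd Gaussian ppm error SD on precursor and fragment m/z.
#' @param n_decoys Random decoy peaks per spectrum.
#' @param intensity Precursor/fragment intensity (scalar or per compound).
#' @param n_decoy_spectra Additional spectra with non-matching precursors.
#' @param scan_range m/z scan window (default 50-1300).
#' @param decoy_min_ppm Minimum ppm separation of decoys from true signals.
#' @param seed Integer seed.
#' @return A list of [spectrum()] objects (writable with [write_mgf()]).
#' @export
simulate_spectra <- function(compounds, ppm_sd = 0, n_decoys = 5,
                             intensity = 5e3, n_decoy_spectra = 0,
                             scan_range = c(50, 1300), decoy_min_ppm = 50,
                             seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  structs <- if (is.data.frame(compounds)) compounds$structure else compounds
  stopifnot(length(structs) > 0)
  intensity <- rep_len(intensity, length(structs))

  pick_adduct <- function(st) if (st$class == "UPAS") "M-H" else "M+Na"
  all_mz <- purrr::map_dbl(structs, ~ ion_mz(.x$formula, pick_adduct(.x)))
  # decoys must avoid every candidate ion the screen could match, not just
  # the planted adducts
  if (is.data.frame(compounds)) {
    mz_cols <- grep("^mz_", names(compounds), value = TRUE)
    all_mz <- unique(c(all_mz, unlist(compounds[mz_cols], use.names = FALSE)))
    all_mz <- all_mz[is.finite(all_mz)]
  }

  jitter_mz <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, ppm_sd) / 1e6)
  draw_decoys <- function(n, avoid) {
    out <- numeric(0)
    while (length(out) < n) {
      cand <- stats::runif(n - length(out), scan_range[1], scan_range[2])
      ok <- vapply(cand, function(x) {
        all(abs(ppm_error(x, avoid)) > decoy_min_ppm)
      }, logical(1))
      out <- c(out, cand[ok])
    }
    out
  }

  spectra <- purrr::imap(structs, function(st, i) {
    adduct <- pick_adduct(st)
    frag <- if (st$class %in% c("DASC", "UBAS", "UPAS")) {
      diagnostic_fragments(st)
    } else NULL
    avoid <- c(all_mz, if (!is.null(frag)) frag$mz)
    frag_peaks <- if (!is.null(frag)) {
      frag <- frag[ndmm_adducts[frag$adduct] == ndmm_adducts[[adduct]], ]
      if (nrow(frag)) {
        tibble::tibble(mz = jitter_mz(frag$mz), intensity = intensity[i] / 2)
      } else NULL
    } else NULL
    decoy_peaks <- if (n_decoys > 0) {
      tibble::tibble(mz = draw_decoys(n_decoys, avoid),
                     intensity = stats::runif(n_decoys, 10, 500))
    } else NULL
    nm <- tryCatch(render_name(st), error = function(e) st$registry_id)
    pk <- dplyr::bind_rows(frag_peaks, decoy_peaks)
    spectrum(
      id = sprintf("planted_%03d_%s", i, nm),
      precursor_mz = jitter_mz(ion_mz(st$formula, adduct)),
      polarity = unname(ndmm_adducts[[adduct]]),
      peaks = if (nrow(pk)) pk else NULL,
      precursor_intensity = intensity[i]
    )
  })

  if (n_decoy_spectra > 0) {
    dmz <- draw_decoys(n_decoy_spectra, all_mz)
    decoy_spectra <- purrr::imap(dmz, function(mz, i) {
      spectrum(
        id = sprintf("decoy_%03d", i),
        precursor_mz = mz, polarity = "positive",
        peaks = tibble::tibble(mz = draw_decoys(n_decoys, all_mz),
                               intensity = stats::runif(n_decoys, 10, 500)),
        precursor_intensity = stats::runif(1, 1e3, 1e4)
      )
    })
    spectra <- c(spectra, decoy_spectra)
  }
  spectra
}
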