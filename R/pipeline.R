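# End-to-end orchestration: spectra -> screen results; replicate areas ->
# profiles and presence matrix; presence + tree -> per-compound comparative
# statistics (model-selected Mk fit, stochastic-map change counts, D with
# FDR flags); closed profiles + tree -> Bray-Curtis, Mantel, NMDS; clade
# MRCA presence probabilities. All tabular outputs are tibbles; TSVs carry
# a header recording the seed and configuration hash.

#' Per-compound comparative statistics table
#'
#' For every compound in the presence matrix: conservation pattern; for
#' variable traits, the LRT-selected Mk model (ER vs ARD), the expected
#' number of state changes over stochastic maps, and the D statistic with
#' two-sided permutation p-values. Constant and singleton compounds carry
#' `NA` statistics (the analyses are undefined for them). FDR flags
#' (Benjamini-Hochberg) are computed separately for the D = 0 and D = 1
#' test families.
#'
#' @param presence A [presence_absence()] tibble covering the tree's tips.
#' @param tree An ape `phylo` (ultrametric).
#' @param class_map Optional compound-to-class tibble to carry class labels.
#' @param n_sim Stochastic maps per compound (default 100).
#' @param n_perm,n_brownian Null-distribution sizes for D (default 1000).
#' @param rate_uncertainty Integrate over Mk rate uncertainty in the maps.
#' @param fdr_q FDR level for significance flags (default 0.10).
#' @param seed Integer seed.
#' @return A tibble with columns `compound`, `class`, `pattern`, `model`,
#'   `simmap_changes`, `D`, `p_d0`, `p_d1`, `sig_d0`, `sig_d1`.
#' @export
comparative_table <- function(presence, tree, class_map = NULL,
                              n_sim = 100, n_perm = 1000, n_brownian = 1000,
                              rate_uncertainty = FALSE, fdr_q = 0.10,
                              seed = 1) {
  pm <- profile_matrix(presence, value = "present")
  matched <- match_tree_species(tree, rownames(pm))
  tree <- matched$tree
  pm <- pm[tree$tip.label, , drop = FALSE]
  patterns <- conservation_pattern(
    presence |> dplyr::filter(.data$species %in% tree$tip.label)
  )

  rows <- purrr::map(seq_len(ncol(pm)), function(j) {
    compound <- colnames(pm)[j]
    states <- stats::setNames(as.integer(pm[, j]), rownames(pm))
    pattern <- patterns$pattern[patterns$compound == compound]
    base <- tibble::tibble(
      compound = compound, pattern = pattern,
      model = NA_character_, simmap_changes = NA_real_,
      D = NA_real_, p_d0 = NA_real_, p_d1 = NA_real_
    )
    if (pattern != "variable") return(base)
    er <- fit_mk(tree, states, "ER")
    ard <- fit_mk(tree, states, "ARD")
    sel <- select_model_lrt(er, ard)
    maps <- sample_stochastic_maps(tree, states, sel$fit, n_sim = n_sim,
                                   rate_uncertainty = rate_uncertainty,
                                   seed = seed + 1000L * j)
    d <- estimate_D(tree, states, n_perm = n_perm, n_brownian = n_brownian,
                    seed = seed + 1000L * j + 1L)
    base |>
      dplyr::mutate(model = sel$model,
                    simmap_changes = mean(maps$changes),
                    D = d$D, p_d0 = d$p_d0, p_d1 = d$p_d1)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(class_map)) {
    out <- dplyr::left_join(out, class_map[c("compound", "class")],
                            by = "compound") |>
      dplyr::relocate("class", .after = "compound")
  }
  variable <- !is.na(out$D)
  out$sig_d0 <- NA
  out$sig_d1 <- NA
  if (any(variable)) {
    out$sig_d0[variable] <- bh_fdr(out$p_d0[variable], q = fdr_q)
    out$sig_d1[variable] <- bh_fdr(out$p_d1[variable], q = fdr_q)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages that the supplied inputs allow: the MS/MS screen
#' (spectra + candidate library), profile construction (replicate areas +
#' class map), the per-compound comparative table, clade-level MRCA presence
#' probabilities for compound classes, and profile-phylogeny correlation
#' (Bray-Curtis + Mantel + NMDS against patristic distances).
#'
#' @param areas Long replicate peak-area tibble (`species`, `compound`,
#'   `replicate`, `area`).
#' @param class_map Tibble `compound`, `class`.
#' @param tree An ape `phylo`.
#' @param spectra Optional list of [spectrum()] objects.
#' @param library Optional candidate library (required with `spectra`).
#' @param clades Optional tibble `species`, `clade` for MRCA summaries.
#' @param config A [screen_config()].
#' @param n_sim,n_perm,n_brownian Simulation sizes (see
#'   [comparative_table()]).
#' @param seed Integer seed controlling every stochastic stage.
#' @param outdir Optional directory; when given, writes
#'   `screen_results.tsv`, `profiles_within_class.tsv`,
#'   `presence_matrix.tsv`, `comparative_statistics.tsv`,
#'   `mrca_probabilities.tsv` with seed/hash headers.
#' @return A list bundle: `screen`, `means`, `profiles_within_class`,
#'   `profiles_closed`, `presence`, `comparative`, `mrca`, `mantel`,
#'   `nmds`, `seed`.
#' @export
run_pipeline <- function(areas, class_map, tree, spectra = NULL,
                         library = NULL, clades = NULL,
                         config = screen_config(),
                         n_sim = 100, n_perm = 1000, n_brownian = 1000,
                         seed = 1, outdir = NULL) {
  validate_tree(tree)
  out <- list(seed = seed)

  if (!is.null(spectra)) {
    if (is.null(library)) {
      stop("pipeline stage 'screen': spectra given without a candidate ",
           "library", call. = FALSE)
    }
    out$screen <- screen_spectra(spectra, library, config)
  }

  out$means <- aggregate_replicates(areas)
  out$profiles_within_class <- within_class_percentages(out$means, class_map)
  totals <- tapply(out$means$mean_area, out$means$species, sum)
  if (any(totals <= 0)) {
    warning("dropping species with no detected compounds from the ",
            "compositional analyses: ",
            paste(names(totals)[totals <= 0], collapse = ", "),
            call. = FALSE)
  }
  out$profiles_closed <- close_composition(
    dplyr::filter(out$means, .data$species %in% names(totals)[totals > 0])
  )
  out$presence <- presence_absence(out$means,
                                   threshold = config$intensity_threshold)

  out$comparative <- comparative_table(
    out$presence, tree, class_map = class_map,
    n_sim = n_sim, n_perm = n_perm, n_brownian = n_brownian, seed = seed
  )

  matched <- match_tree_species(tree, unique(out$means$species))
  ptree <- matched$tree
  if (!is.null(clades)) {
    # class-level presence: a class is present where any member compound is
    class_presence <- out$presence |>
      dplyr::inner_join(class_map[c("compound", "class")], by = "compound") |>
      dplyr::group_by(.data$species, .data$class) |>
      dplyr::summarise(present = any(.data$present), .groups = "drop") |>
      dplyr::filter(.data$species %in% ptree$tip.label)
    classes <- unique(class_presence$class)
    out$mrca <- purrr::map_dfr(classes, function(cl) {
      states <- class_presence |>
        dplyr::filter(.data$class == cl)
      sv <- stats::setNames(as.integer(states$present), states$species)
      k <- sum(sv)
      if (k %in% c(0L, length(sv))) {
        return(tibble::tibble(class = cl, clade = unique(clades$clade),
                              p_present = as.numeric(k > 0)))
      }
      maps <- sample_stochastic_maps(ptree, sv, "ER", n_sim = n_sim,
                                     seed = seed + 77L)
      summarize_maps(maps, clades)$mrca_presence |>
        dplyr::mutate(class = cl) |>
        dplyr::select("class", "clade", "p_present")
    })
  }

  closed <- out$profiles_closed |>
    dplyr::filter(.data$species %in% ptree$tip.label)
  bc <- bray_curtis_matrix(closed)
  pd <- patristic_distances(ptree)
  out$bray_curtis <- bc
  out$mantel <- mantel_test(bc, pd, n_perm = 999, seed = seed + 5L)
  out$nmds <- nmds_ordination(bc, k = 2, seed = seed + 6L)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    hdr <- c(
      paste0("# ndmmtools pipeline  seed=", seed),
      paste0("# config_hash=", .config_hash(list(
        config = unclass(config), n_sim = n_sim, n_perm = n_perm,
        n_brownian = n_brownian, seed = seed)))
    )
    wr <- function(df, file) {
      path <- file.path(outdir, file)
      writeLines(hdr, path)
      suppressWarnings(utils::write.table(
        df, path, sep = "\t", quote = FALSE, row.names = FALSE,
        append = TRUE
      ))
    }
    if (!is.null(out$screen)) {
      wr(dplyr::mutate(out$screen,
                       candidates = purrr::map_chr(
                         .data$candidates, paste, collapse = ";")),
         "screen_results.tsv")
    }
    wr(out$profiles_within_class, "profiles_within_class.tsv")
    wr(out$presence, "presence_matrix.tsv")
    wr(out$comparative, "comparative_statistics.tsv")
    if (!is.null(out$mrca)) wr(out$mrca, "mrca_probabilities.tsv")
  }
  out
}

.config_hash <- function(x) {
  # small deterministic hash of the serialized config (no extra deps)
  bytes <- as.integer(serialize(x, NULL, version = 2)[-(1:14)])
  sprintf("%08x", sum(bytes * seq_along(bytes)) %% .Machine$integer.max)
}
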