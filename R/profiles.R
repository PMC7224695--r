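# Replicate peak-area tables -> mean areas, within-class percentage profiles
# (the heat-map standardization: each NDMM's mean area divided by its class
# total per species, with monomeric and dimeric UBAS standardized
# separately), fully closed compositional profiles for multivariate analysis,
# and presence/absence matrices (trace detections coded absent).

#' Average replicate peak areas
#'
#' Arithmetic mean over a species' replicates. A compound missing from a
#' replicate is a detection absence and contributes zero: the denominator is
#' the number of distinct replicates recorded for the species, not the number
#' of rows for the compound.
#'
#' @param areas Long tibble with columns `species`, `compound`, `replicate`,
#'   `area` (areas >= 0).
#' @return Tibble with columns `species`, `compound`, `mean_area`.
#' @export
aggregate_replicates <- function(areas) {
  stopifnot(all(c("species", "compound", "replicate", "area") %in%
                names(areas)))
  if (any(areas$area < 0)) stop("negative peak area", call. = FALSE)
  nrep <- areas |>
    dplyr::distinct(.data$species, .data$replicate) |>
    dplyr::count(.data$species, name = "n_rep")
  if (any(nrep$n_rep < 1)) {
    stop("species with zero replicates", call. = FALSE)
  }
  areas |>
    dplyr::group_by(.data$species, .data$compound) |>
    dplyr::summarise(total = sum(.data$area), .groups = "drop") |>
    dplyr::left_join(nrep, by = "species") |>
    dplyr::mutate(mean_area = .data$total / .data$n_rep) |>
    dplyr::select("species", "compound", "mean_area")
}

.check_class_map <- function(means, class_map) {
  stopifnot(all(c("compound", "class") %in% names(class_map)))
  unmapped <- setdiff(unique(means$compound), class_map$compound)
  if (length(unmapped)) {
    stop("compound(s) missing from the class map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
}

#' Within-class percentage profiles
#'
#' Per species and per compound class, each mean peak area divided by the
#' class total and expressed as a percentage, so every nonzero class sums to
#' 100 within a species. Monomeric and dimeric UBAS compounds are intended to
#' be standardized separately: give them distinct classes in the map (e.g.
#' `"UBAS-monomeric"` / `"UBAS-dimeric"`). A class absent from a species
#' (total zero) yields zeros, not a division error.
#'
#' @param means Output of [aggregate_replicates()].
#' @param class_map Tibble with columns `compound`, `class` covering every
#'   compound.
#' @return Tibble `species`, `compound`, `class`, `percent` with attribute
#'   `mode = "within_class"`.
#' @export
within_class_percentages <- function(means, class_map) {
  .check_class_map(means, class_map)
  out <- means |>
    dplyr::inner_join(class_map[c("compound", "class")], by = "compound") |>
    dplyr::group_by(.data$species, .data$class) |>
    dplyr::mutate(
      total = sum(.data$mean_area),
      percent = ifelse(.data$total > 0, 100 * .data$mean_area / .data$total, 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("species", "compound", "class", "percent")
  attr(out, "mode") <- "within_class"
  out
}

#' Closed compositional profiles
#'
#' All compounds of a species standardized to sum to 100% — the closure used
#' upstream of Bray-Curtis dissimilarity and ordination, which removes
#' absolute-scale variation in production rates.
#'
#' @param means Output of [aggregate_replicates()].
#' @return Tibble `species`, `compound`, `percent` with attribute
#'   `mode = "closed_all"`.
#' @export
close_composition <- function(means) {
  totals <- means |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(total = sum(.data$mean_area), .groups = "drop")
  if (any(totals$total <= 0)) {
    stop("all-zero species row(s): ",
         paste(totals$species[totals$total <= 0], collapse = ", "),
         call. = FALSE)
  }
  out <- means |>
    dplyr::left_join(totals, by = "species") |>
    dplyr::mutate(percent = 100 * .data$mean_area / .data$total) |>
    dplyr::select("species", "compound", "percent")
  attr(out, "mode") <- "closed_all"
  out
}

#' Presence/absence matrix from peak areas
#'
#' A compound is present in a species when its replicate-mean intensity
#' reaches the threshold; trace-level detections (below threshold) are coded
#' absent, matching the comparative analyses that exclude trace compounds.
#'
#' @param areas Long replicate table (see [aggregate_replicates()]) or a
#'   `species`/`compound`/`mean_area` tibble.
#' @param threshold Intensity threshold (default 1.0e3).
#' @return Tibble `species`, `compound`, `present` (logical), with the
#'   threshold stored as attribute `threshold`.
#' @export
presence_absence <- function(areas, threshold = 1e3) {
  stopifnot(threshold >= 0)
  means <- if ("mean_area" %in% names(areas)) {
    areas
  } else {
    aggregate_replicates(areas)
  }
  out <- means |>
    dplyr::mutate(present = .data$mean_area >= threshold & threshold > 0 |
                    (threshold == 0 & .data$mean_area > 0)) |>
    dplyr::select("species", "compound", "present")
  attr(out, "threshold") <- threshold
  out
}

#' Pivot a long profile or presence table to a species-by-compound matrix
#'
#' @param x A long tibble with `species`, `compound` and one value column
#'   (`percent`, `mean_area`, or `present`).
#' @param value Name of the value column; guessed when omitted.
#' @param fill Fill for missing species-compound pairs (default 0).
#' @return A base matrix with species rownames and compound colnames.
#' @export
profile_matrix <- function(x, value = NULL, fill = 0) {
  value <- value %||%
    intersect(c("percent", "mean_area", "present", "area"), names(x))[1]
  if (is.na(value)) stop("no value column found", call. = FALSE)
  wide <- tidyr::pivot_wider(
    x[c("species", "compound", value)],
    names_from = "compound", values_from = dplyr::all_of(value),
    values_fill = fill
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$species
  m
}

#' Classify compound conservation patterns
#'
#' From a presence/absence table: `constant` (all present or all absent),
#' `singleton` (exactly one species differs from all others), otherwise
#' `variable`. Binary-trait phylogenetic signal and ancestral mapping are
#' defined only for variable traits.
#'
#' @param presence A [presence_absence()] tibble.
#' @return Tibble `compound`, `n_present`, `n_species`, `pattern`.
#' @export
conservation_pattern <- function(presence) {
  presence |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      n_present = sum(.data$present),
      n_species = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pattern = dplyr::case_when(
        .data$n_present %in% c(0L, .data$n_species) ~ "constant",
        .data$n_present %in% c(1L, .data$n_species - 1L) ~ "singleton",
        TRUE ~ "variable"
      )
    )
}
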