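# Targeted tandem-MS screen: match spectra against the candidate library by
# precursor m/z within a ppm tolerance, confirm class-diagnostic fragment
# ions, and classify detections as quantifiable or trace relative to the
# ion-intensity threshold of 1.0e3.

#' Screen configuration
#'
#' @param precursor_tol_ppm Precursor-match tolerance in ppm (default 5;
#'   printed deviations for consistent assignments are below ~5 ppm).
#' @param fragment_tol_ppm Fragment-match tolerance in ppm (default 10).
#' @param intensity_threshold Ion-intensity threshold separating quantifiable
#'   from trace detections (default 1.0e3).
#' @return A `screen_config` list.
#' @export
screen_config <- function(precursor_tol_ppm = 5,
                          fragment_tol_ppm = 10,
                          intensity_threshold = 1e3) {
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0,
            intensity_threshold >= 0)
  structure(
    list(precursor_tol_ppm = precursor_tol_ppm,
         fragment_tol_ppm = fragment_tol_ppm,
         intensity_threshold = intensity_threshold),
    class = "screen_config"
  )
}

#' Construct a tandem-MS spectrum
#'
#' @param id Spectrum identifier.
#' @param precursor_mz Precursor m/z in Da (> 0).
#' @param polarity `"positive"` or `"negative"`.
#' @param peaks A data frame with columns `mz` and `intensity`
#'   (intensities >= 0); stored sorted by m/z.
#' @param precursor_intensity Optional precursor ion intensity used for the
#'   quantifiable/trace call.
#' @return A `spectrum` object.
#' @export
spectrum <- function(id, precursor_mz, polarity = c("positive", "negative"),
                     peaks = NULL, precursor_intensity = NA_real_) {
  polarity <- match.arg(polarity)
  stopifnot(precursor_mz > 0)
  peaks <- if (is.null(peaks)) {
    tibble::tibble(mz = numeric(0), intensity = numeric(0))
  } else {
    tibble::as_tibble(peaks)
  }
  stopifnot(all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) {
    stop("negative peak intensity in spectrum ", id, call. = FALSE)
  }
  peaks <- dplyr::arrange(peaks, .data$mz)
  structure(
    list(id = as.character(id), precursor_mz = precursor_mz,
         polarity = polarity, peaks = peaks,
         precursor_intensity = precursor_intensity),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", x$id, "  precursor m/z ", format(x$precursor_mz),
      " (", x$polarity, "), ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Classify a detection by ion intensity
#'
#' Detections at or above the intensity threshold are quantifiable, those
#' above zero but below it are present only at trace levels, and zero means
#' absent.
#'
#' @param intensity Non-negative ion intensity (vectorized).
#' @param config A [screen_config()].
#' @return A character vector in `{"quantifiable", "trace", "absent"}`.
#' @export
classify_abundance <- function(intensity, config = screen_config()) {
  if (any(is.na(intensity))) {
    stop("missing intensity", call. = FALSE)
  }
  if (any(intensity < 0)) stop("negative intensity", call. = FALSE)
  dplyr::case_when(
    intensity >= config$intensity_threshold ~ "quantifiable",
    intensity > 0 ~ "trace",
    TRUE ~ "absent"
  )
}

.mz_col <- function(adduct) paste0("mz_", gsub("[+]", "p", gsub("-", "m", adduct)))

#' Match one spectrum against the candidate library
#'
#' A candidate matches when, for any configured adduct of the spectrum's
#' polarity, the theoretical m/z lies within `precursor_tol_ppm` of the
#' precursor. Mass-identical candidates (same ion formula and adduct, e.g.
#' 2'- vs 4'-linked dimers, or ascarylose vs paratose sugars) are reported as
#' one isomer set, never as a resolved single structure. For DASC/UBAS/UPAS
#' candidates, `fragments_confirmed` records whether a peak lies within
#' `fragment_tol_ppm` of the class-diagnostic fragment ion.
#'
#' @param spec A [spectrum()].
#' @param lib A library tibble from [build_library()].
#' @param config A [screen_config()].
#' @return A tibble with one row per (isomer set, adduct): columns
#'   `spectrum_id`, `candidates` (list of names), `n_isomers`, `name`
#'   (representative, |ppm|-then-name sorted), `class`, `formula`, `adduct`,
#'   `ppm` (signed), `fragments_confirmed`, `intensity`, `call`. Empty when
#'   nothing matches.
#' @export
match_spectrum <- function(spec, lib, config = screen_config()) {
  stopifnot(inherits(spec, "spectrum"))
  adducts <- attr(lib, "adducts") %||% .default_adducts()
  adducts <- adducts[ndmm_adducts[adducts] == spec$polarity]
  if (length(adducts) == 0) {
    stop("no configured adduct for polarity ", spec$polarity, call. = FALSE)
  }
  intensity <- spec$precursor_intensity
  if (is.na(intensity)) {
    intensity <- if (nrow(spec$peaks)) max(spec$peaks$intensity) else 0
  }

  hits <- purrr::map_dfr(adducts, function(a) {
    mz <- lib[[.mz_col(a)]]
    ppm <- ppm_error(spec$precursor_mz, mz)
    keep <- abs(ppm) <= config$precursor_tol_ppm
    if (!any(keep)) return(NULL)
    tibble::tibble(
      name = lib$name[keep], class = lib$class[keep],
      formula = lib$formula[keep], adduct = a, ppm = ppm[keep],
      structure = lib$structure[keep]
    )
  })
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      spectrum_id = character(0), candidates = list(), n_isomers = integer(0),
      name = character(0), class = character(0), formula = character(0),
      adduct = character(0), ppm = numeric(0),
      fragments_confirmed = logical(0), intensity = numeric(0),
      call = character(0)
    ))
  }

  hits |>
    dplyr::arrange(abs(.data$ppm), .data$name) |>
    dplyr::group_by(.data$formula, .data$adduct, .data$class) |>
    dplyr::summarise(
      candidates = list(.data$name),
      n_isomers = dplyr::n(),
      name = .data$name[1],
      ppm = .data$ppm[1],
      structures = list(.data$structure),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      spectrum_id = spec$id,
      # a peak within tolerance of ANY isomer's diagnostic ion confirms the
      # set; isomers can predict different fragments (e.g. dimers differing
      # in which unit is first), which is how MS/MS narrows the assignment
      fragments_confirmed = purrr::map2_lgl(
        .data$structures, .data$class,
        function(sts, cl) {
          if (!cl %in% c("DASC", "UBAS", "UPAS")) return(NA)
          any(purrr::map_lgl(sts, function(st) {
            fr <- diagnostic_fragments(st)
            any(purrr::map_lgl(fr$mz, function(fmz) {
              any(abs(ppm_error(spec$peaks$mz, fmz)) <=
                    config$fragment_tol_ppm)
            }))
          }))
        }),
      intensity = intensity,
      call = classify_abundance(intensity, config)
    ) |>
    dplyr::arrange(abs(.data$ppm), .data$name) |>
    dplyr::select("spectrum_id", "candidates", "n_isomers", "name", "class",
                  "formula", "adduct", "ppm", "fragments_confirmed",
                  "intensity", "call")
}

#' Screen many spectra against the library
#'
#' @param spectra A list of [spectrum()] objects.
#' @inheritParams match_spectrum
#' @return The row-bound tibble of all [match_spectrum()] results.
#' @export
screen_spectra <- function(spectra, lib, config = screen_config()) {
  purrr::map_dfr(spectra, match_spectrum, lib = lib, config = config)
}

#' Targeted diagnostic-ion screen
#'
#' Returns the spectra that contain a peak within `fragment_tol_ppm` of a
#' diagnostic ion m/z — the strategy used to sweep spectra for the UBAS
#' head-group cation (C11H19N2O5+) and the UPAS head-group anion
#' (C4H7N2O3-).
#'
#' @param spectra A list of [spectrum()] objects.
#' @param diagnostic_mz The diagnostic ion m/z (e.g.
#'   `ion_mz("C11H18N2O5", "M+H")`).
#' @param config A [screen_config()].
#' @param polarity Optional polarity filter consistent with the diagnostic
#'   ion; spectra of the other polarity are skipped.
#' @return Character vector of matching spectrum ids.
#' @export
targeted_fragment_screen <- function(spectra, diagnostic_mz,
                                     config = screen_config(),
                                     polarity = NULL) {
  hits <- purrr::keep(spectra, function(s) {
    if (!is.null(polarity) && s$polarity != polarity) return(FALSE)
    nrow(s$peaks) > 0 &&
      any(abs(ppm_error(s$peaks$mz, diagnostic_mz)) <= config$fragment_tol_ppm)
  })
  purrr::map_chr(hits, "id")
}
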