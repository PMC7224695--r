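# Minimal MGF (Mascot generic format) reader/writer for MS/MS peak lists:
# BEGIN IONS / END IONS blocks with TITLE, PEPMASS (m/z and optional
# intensity), CHARGE (sign carries the polarity), and m/z-intensity pairs.

#' Read spectra from an MGF file
#'
#' @param path Path to an MGF file.
#' @return A list of [spectrum()] objects (empty list for an empty file).
#'   Peaks are sorted by m/z; polarity is inferred from the CHARGE sign.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list())
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path,
         call. = FALSE)
  }
  purrr::map2(begins, ends, function(b, e) {
    block <- lines[(b + 1L):(e - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    fields <- block[kv]
    keys <- toupper(sub("=.*$", "", fields))
    vals <- sub("^[^=]*=", "", fields)
    id <- vals[match("TITLE", keys)]
    pep <- vals[match("PEPMASS", keys)]
    if (is.na(pep)) stop("malformed MGF block: missing PEPMASS", call. = FALSE)
    pep_parts <- strsplit(trimws(pep), "\\s+")[[1]]
    precursor_mz <- as.numeric(pep_parts[1])
    precursor_int <- if (length(pep_parts) > 1) {
      as.numeric(pep_parts[2])
    } else NA_real_
    charge <- vals[match("CHARGE", keys)]
    polarity <- if (!is.na(charge) && grepl("-", charge)) {
      "negative"
    } else "positive"
    peak_lines <- block[!kv]
    peaks <- if (length(peak_lines)) {
      mat <- do.call(rbind, strsplit(peak_lines, "\\s+"))
      tibble::tibble(mz = as.numeric(mat[, 1]),
                     intensity = as.numeric(mat[, 2]))
    } else NULL
    if (!is.null(peaks) && anyNA(peaks)) {
      stop("malformed MGF peak line in block ", id %||% "?", call. = FALSE)
    }
    spectrum(id = id %||% paste0("spectrum_", b),
             precursor_mz = precursor_mz, polarity = polarity,
             peaks = peaks, precursor_intensity = precursor_int)
  })
}

#' Write spectra to an MGF file
#'
#' @param spectra A list of [spectrum()] objects.
#' @param path Output path.
#' @param digits Number of decimal places for m/z values (default 6).
#' @return `path`, invisibly. `read_mgf(write_mgf(x))` round-trips.
#' @export
write_mgf <- function(spectra, path, digits = 6) {
  fmt <- function(x) formatC(x, digits = digits, format = "f")
  out <- purrr::map(spectra, function(s) {
    stopifnot(inherits(s, "spectrum"))
    pep <- if (is.na(s$precursor_intensity)) {
      fmt(s$precursor_mz)
    } else {
      paste(fmt(s$precursor_mz), formatC(s$precursor_intensity, format = "g"))
    }
    c("BEGIN IONS",
      paste0("TITLE=", s$id),
      paste0("PEPMASS=", pep),
      paste0("CHARGE=1", if (s$polarity == "negative") "-" else "+"),
      if (nrow(s$peaks)) {
        paste(fmt(s$peaks$mz), formatC(s$peaks$intensity, format = "g"))
      },
      "END IONS", "")
  })
  writeLines(unlist(out), path, useBytes = FALSE)
  invisible(path)
}
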