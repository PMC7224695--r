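# Molecular-formula arithmetic and monoisotopic ion m/z computation.
#
# Monoisotopic atomic masses are hard-coded to 7 decimals; ion masses carry an
# electron-mass correction (subtracted for cations, added for anions), which is
# required to reproduce printed sub-5-ppm mass deviations for sodiated adducts.

.MONOISOTOPIC_MASS <- c(
  C  = 12.0000000,
  H  = 1.0078250,
  N  = 14.0030740,
  O  = 15.9949146,
  Na = 22.9897693,
  P  = 30.9737615,
  S  = 31.9720707
)

.ELECTRON_MASS <- 0.0005486

#' Supported adducts and their polarities
#'
#' Singly charged adducts used throughout the screen: `M+H` and `M+Na`
#' (positive mode) and `M-H` (negative mode), the only ion forms annotated
#' for modular ascarosides in electrospray LC-MS/MS work.
#'
#' @format A named character vector mapping adduct label to polarity.
#' @export
ndmm_adducts <- c("M+H" = "positive", "M+Na" = "positive", "M-H" = "negative")

.normalize_adduct <- function(adduct) {
  a <- gsub("−", "-", adduct)
  a <- gsub("\\s", "", a)
  if (!a %in% names(ndmm_adducts)) {
    stop("unsupported adduct: ", adduct, " (use one of ",
         paste(names(ndmm_adducts), collapse = ", "), ")", call. = FALSE)
  }
  a
}

new_formula <- function(counts, charge = 0L) {
  counts <- counts[counts != 0]
  if (length(counts)) {
    unknown <- setdiff(names(counts), names(.MONOISOTOPIC_MASS))
    if (length(unknown)) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(counts < 0)) {
      stop("negative element count for: ",
           paste(names(counts)[counts < 0], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(counts = as.integer(counts) |> stats::setNames(names(counts)),
         charge = as.integer(charge)),
    class = "mol_formula"
  )
}

#' Parse a molecular formula string
#'
#' Accepts Hill-order-style element-count strings with an optional trailing
#' charge sign, e.g. `"C17H28NaO8+"` or `"C4H7N2O3-"` (the Unicode minus
#' `−` is also accepted).
#'
#' @param text A formula string.
#' @return A `mol_formula` object with fields `counts` (named integer vector)
#'   and `charge`.
#' @examples
#' parse_formula("C17H28NaO8+")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("−", "-", trimws(text))
  charge <- 0L
  if (grepl("[+-]$", s)) {
    charge <- if (endsWith(s, "+")) 1L else -1L
    s <- substr(s, 1L, nchar(s) - 1L)
  }
  if (!nzchar(s)) return(new_formula(integer(0), charge))
  tokens <- gregexpr("([A-Z][a-z]?)(\\d*)", s)[[1]]
  pieces <- regmatches(s, gregexpr("([A-Z][a-z]?)(\\d*)", s))[[1]]
  if (sum(nchar(pieces)) != nchar(s)) {
    stop("malformed formula string: ", text, call. = FALSE)
  }
  elems <- sub("\\d+$", "", pieces)
  n <- sub("^[A-Za-z]+", "", pieces)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  counts <- tapply(n, elems, sum)
  new_formula(stats::setNames(as.integer(counts), names(counts)), charge)
}

#' Render a molecular formula in canonical Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; the
#' charge (if any) is appended as a trailing sign.
#'
#' @param f A `mol_formula`.
#' @return A single string; `parse_formula(render_formula(f))` equals `f`.
#' @export
render_formula <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  counts <- f$counts
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  counts <- counts[ord]
  body <- paste0(names(counts), ifelse(counts == 1L, "", counts),
                 collapse = "")
  chg <- if (f$charge == 0L) "" else {
    strrep(if (f$charge > 0L) "+" else "-", abs(f$charge))
  }
  paste0(body, chg)
}

#' @export
format.mol_formula <- function(x, ...) render_formula(x)

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", render_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.mol_formula` <- function(e1, e2) {
  identical(render_formula(e1), render_formula(e2))
}

.as_formula <- function(x) {
  if (inherits(x, "mol_formula")) x else parse_formula(x)
}

#' Formula arithmetic
#'
#' Element-wise addition and subtraction of neutral formulas. Subtraction
#' raises an error if any element count would go negative, so condensation
#' bookkeeping (losing one H2O per bond) is checked at every step.
#'
#' @param a,b `mol_formula` objects or formula strings.
#' @param k Integer multiplier for `fml_multiply`.
#' @return A `mol_formula`.
#' @export
fml_add <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  elems <- union(names(a$counts), names(b$counts))
  av <- stats::setNames(integer(length(elems)), elems)
  av[names(a$counts)] <- a$counts
  av[names(b$counts)] <- av[names(b$counts)] + b$counts
  new_formula(av, a$charge + b$charge)
}

#' @rdname fml_add
#' @export
fml_subtract <- function(a, b) {
  a <- .as_formula(a); b <- .as_formula(b)
  elems <- union(names(a$counts), names(b$counts))
  av <- stats::setNames(integer(length(elems)), elems)
  av[names(a$counts)] <- a$counts
  av[names(b$counts)] <- av[names(b$counts)] - b$counts
  if (any(av < 0)) {
    stop("formula subtraction would give a negative count for: ",
         paste(elems[av < 0], collapse = ", "), call. = FALSE)
  }
  new_formula(av, a$charge - b$charge)
}

#' @rdname fml_add
#' @export
fml_multiply <- function(a, k) {
  a <- .as_formula(a)
  stopifnot(k >= 0, k == as.integer(k))
  new_formula(a$counts * as.integer(k), a$charge * as.integer(k))
}

#' Monoisotopic mass of a formula
#'
#' Sum of hard-coded monoisotopic atomic masses, with the electron-mass
#' correction applied according to the formula's charge.
#'
#' @param f A `mol_formula` or formula string.
#' @return Mass (for neutral input) or m/z-relevant ion mass, in Da.
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  m <- if (length(f$counts)) {
    sum(.MONOISOTOPIC_MASS[names(f$counts)] * f$counts)
  } else 0
  m - f$charge * .ELECTRON_MASS
}

#' Theoretical m/z of a singly charged adduct ion
#'
#' @param neutral A neutral `mol_formula` or formula string (charge must be 0).
#' @param adduct One of `"M+H"`, `"M+Na"` (positive) or `"M-H"` (negative).
#' @return Monoisotopic m/z in Da, electron-mass corrected.
#' @examples
#' ion_mz("C17H28O8", "M+Na") # 383.1676, the dasc#3 diagnostic fragment ion
#' @export
ion_mz <- function(neutral, adduct) {
  neutral <- .as_formula(neutral)
  if (neutral$charge != 0L) {
    stop("ion_mz() expects a neutral formula (charge 0), got charge ",
         neutral$charge, call. = FALSE)
  }
  adduct <- .normalize_adduct(adduct)
  m <- monoisotopic_mass(neutral)
  mz <- switch(adduct,
    "M+H"  = m + .MONOISOTOPIC_MASS[["H"]] - .ELECTRON_MASS,
    "M+Na" = m + .MONOISOTOPIC_MASS[["Na"]] - .ELECTRON_MASS,
    "M-H"  = m - .MONOISOTOPIC_MASS[["H"]] + .ELECTRON_MASS
  )
  unname(mz)
}

#' Ion formula of an adduct (charged species)
#'
#' @inheritParams ion_mz
#' @return A charged `mol_formula`, e.g. `C17H28NaO8+` for `C17H28O8` + Na.
#' @export
ion_formula <- function(neutral, adduct) {
  neutral <- .as_formula(neutral)
  adduct <- .normalize_adduct(adduct)
  out <- switch(adduct,
    "M+H"  = fml_add(neutral, new_formula(c(H = 1L), charge = 0L)),
    "M+Na" = fml_add(neutral, new_formula(c(Na = 1L), charge = 0L)),
    "M-H"  = fml_subtract(neutral, new_formula(c(H = 1L), charge = 0L))
  )
  out$charge <- if (adduct == "M-H") -1L else 1L
  out
}

#' Signed parts-per-million mass error
#'
#' `1e6 * (observed - theoretical) / theoretical`. Reports in the package use
#' the absolute value rounded to one decimal, matching the unsigned printed
#' convention for measured-vs-theoretical deviations.
#'
#' @param observed,theoretical Positive m/z values in Da.
#' @return Signed ppm error (vectorized).
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(observed <= 0) || any(theoretical <= 0)) {
    stop("ppm_error() requires positive m/z values", call. = FALSE)
  }
  1e6 * (observed - theoretical) / theoretical
}
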