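# Modular ascaroside structures: sugar + fatty-acid side chain + optional
# ureido head group + optional second ascaroside unit (dimers). Neutral
# formulas are derived by pure element bookkeeping: the sum of component
# formulas minus one H2O per condensation (glycosidic/ester) bond.

# Component formulas. Ascarylose and paratose are isomeric dideoxy sugars
# (C6H12O4); head groups are the free acids.
.SUGAR_FORMULA <- "C6H12O4"
.HEAD_FORMULA <- c(UB = "C5H10N2O3",  # ureidoisobutyric acid
                   UP = "C4H8N2O3")   # ureidopropionic acid
.WATER <- "H2O"

.CHAIN_RANGE <- c(3L, 11L)

#' Construct a fatty-acid side chain
#'
#' The hydroxy-acid side-chain precursor has formula CnH2nO3 when saturated
#' and CnH(2n-2)O3 when carrying one C=C double bond. Chains attach to the
#' sugar through either the (omega-1) or the terminal omega carbon.
#'
#' @param n_carbons Chain length; lengths 3-11 are supported, the observed
#'   range from asc-(omega)C3 to asc-C11.
#' @param unsaturated Logical; one double bond (the &Delta; prefix).
#' @param attachment `"omega_minus_1"` (default) or `"omega"`.
#' @return A `side_chain` object.
#' @export
side_chain <- function(n_carbons, unsaturated = FALSE,
                       attachment = c("omega_minus_1", "omega")) {
  attachment <- match.arg(attachment)
  n_carbons <- as.integer(n_carbons)
  if (is.na(n_carbons) || n_carbons < .CHAIN_RANGE[1] ||
      n_carbons > .CHAIN_RANGE[2]) {
    stop("unsupported chain length ", n_carbons, " (supported: ",
         .CHAIN_RANGE[1], "-", .CHAIN_RANGE[2], ")", call. = FALSE)
  }
  structure(
    list(n_carbons = n_carbons, unsaturated = isTRUE(unsaturated),
         attachment = attachment),
    class = "side_chain"
  )
}

#' @export
format.side_chain <- function(x, ...) {
  paste0(if (x$attachment == "omega") "\u03c9",
         if (x$unsaturated) "\u0394", "C", x$n_carbons)
}

#' @export
print.side_chain <- function(x, ...) {
  cat("<side_chain> ", format(x), "\n", sep = "")
  invisible(x)
}

side_chain_formula <- function(chain) {
  stopifnot(inherits(chain, "side_chain"))
  n <- chain$n_carbons
  h <- if (chain$unsaturated) 2L * n - 2L else 2L * n
  new_formula(c(C = n, H = h, O = 3L))
}

#' Assemble a modular ascaroside structure
#'
#' Builds an NDMM from its components and derives the neutral molecular
#' formula: sugar + side chain (minus one H2O for the glycosidic bond), plus
#' one further H2O loss per attached unit (a 2'- or 4'-linked first
#' ascaroside and/or a 4'-ureido head group). The class label follows from
#' the components: a UB head gives UBAS, a UP head gives UPAS, a dimer
#' without head gives DASC, otherwise simple.
#'
#' @param side_chain A [side_chain()] (the second/terminal unit's chain for
#'   dimers).
#' @param sugar `"ascarylose"` or `"paratose"` (isomers; mass-identical).
#' @param head Optional head group, `"UB"` or `"UP"`, attached at the
#'   4'-position of the (second) sugar.
#' @param first_unit Optional `ndmm` (must itself be a simple structure): the
#'   first ascaroside of a dimer, attached at the 2'- or 4'-position.
#' @param linkage Attachment position of `first_unit`: `"2'"`, `"4'"`, or
#'   `"unresolved"` (MS alone cannot distinguish the two). Required when
#'   `first_unit` is given; when a head occupies the 4'-position the first
#'   unit must be 2'-linked.
#' @return An `ndmm` object carrying the derived `formula` and `class`.
#' @examples
#' assemble_ndmm(side_chain(7))                      # asc-C7 (ascr#1), C13H24O6
#' assemble_ndmm(side_chain(4), head = "UB")         # ubas#5-type monomer
#' assemble_ndmm(side_chain(4),
#'               first_unit = assemble_ndmm(side_chain(5)),
#'               linkage = "2'")                     # dasc#3-type dimer
#' @export
assemble_ndmm <- function(side_chain, sugar = c("ascarylose", "paratose"),
                          head = NULL, first_unit = NULL, linkage = NULL) {
  sugar <- match.arg(sugar)
  stopifnot(inherits(side_chain, "side_chain"))
  if (!is.null(head)) {
    head <- match.arg(head, names(.HEAD_FORMULA))
  }
  if (!is.null(first_unit)) {
    if (!inherits(first_unit, "ndmm") || first_unit$class != "simple") {
      stop("first_unit must be a simple ndmm structure", call. = FALSE)
    }
    if (is.null(linkage)) {
      stop("a dimer needs a linkage: \"2'\", \"4'\" or \"unresolved\"",
           call. = FALSE)
    }
    linkage <- match.arg(linkage, c("2'", "4'", "unresolved"))
    if (!is.null(head) && linkage == "4'") {
      stop("the 4'-position is occupied by the ", head,
           " head group; a dimer first unit must then be 2'-linked",
           call. = FALSE)
    }
  } else if (!is.null(linkage)) {
    stop("linkage given without a first_unit", call. = FALSE)
  }

  fml <- fml_subtract(fml_add(.SUGAR_FORMULA, side_chain_formula(side_chain)),
                      .WATER)
  if (!is.null(first_unit)) {
    fml <- fml_subtract(fml_add(fml, first_unit$formula), .WATER)
  }
  if (!is.null(head)) {
    fml <- fml_subtract(fml_add(fml, .HEAD_FORMULA[[head]]), .WATER)
  }

  cls <- if (!is.null(head)) {
    if (head == "UB") "UBAS" else "UPAS"
  } else if (!is.null(first_unit)) "DASC" else "simple"

  structure(
    list(sugar = sugar, side_chain = side_chain, head = head,
         first_unit = first_unit, linkage = linkage,
         class = cls, registry_id = NULL, formula = fml),
    class = "ndmm"
  )
}

#' Registry-defined NDMM
#'
#' Highly modular NPAR/PASC compounds carry nucleoside- or amino-acid-derived
#' side-chain moieties whose combinatorics are not modeled here; they enter
#' analyses via a registry entry supplying the name and neutral formula
#' directly.
#'
#' @param registry_id Registry name, e.g. `"npar#1"`.
#' @param formula Neutral molecular formula string or `mol_formula`.
#' @param class Compound class label, e.g. `"NPAR"` or `"PASC"`.
#' @return An `ndmm` object of class label `"registry"` unless overridden.
#' @export
registry_ndmm <- function(registry_id, formula, class = "registry") {
  fml <- .as_formula(formula)
  if (fml$charge != 0L) stop("registry formula must be neutral", call. = FALSE)
  structure(
    list(sugar = NULL, side_chain = NULL, head = NULL, first_unit = NULL,
         linkage = NULL, class = class, registry_id = registry_id,
         formula = fml),
    class = "ndmm"
  )
}

#' Read a compound registry
#'
#' CSV with columns `name`, `formula`, `class` (and optional `notes`).
#'
#' @param path Path to the registry CSV.
#' @return A tibble with a `structure` list-column of [registry_ndmm()]s.
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, comment.char = "", stringsAsFactors = FALSE)
  need <- c("name", "formula", "class")
  if (!all(need %in% names(df))) {
    stop("registry must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df) |>
    dplyr::mutate(
      structure = purrr::map2(.data$name, .data$formula,
                              ~ registry_ndmm(.x, .y, class = df$class[
                                match(.x, df$name)]))
    )
}

#' @export
print.ndmm <- function(x, ...) {
  nm <- tryCatch(render_name(x), error = function(e) x$registry_id)
  cat("<ndmm> ", nm %||% "?", "  [", x$class, "]  ",
      render_formula(x$formula), "\n", sep = "")
  invisible(x)
}

#' Predict diagnostic MS/MS fragment ions
#'
#' Class-specific fragments observed on collision-induced dissociation:
#' * DASC: loss of the terminal side chain leaves the first ascaroside
#'   still glycosidically bound to a bare sugar, i.e.
#'   formula(first unit) + sugar - 2 H2O, detected as the sodiated cation.
#'   For dasc#3 this is C17H28O8, whose `[M+Na]+` ion is C17H28NaO8+.
#' * UBAS: the head-plus-sugar fragment C11H18N2O5, detected as `[M+H]+`
#'   (the C11H19N2O5+ cation).
#' * UPAS: the ureidopropionic acid moiety C4H8N2O3, detected as `[M-H]-`
#'   (the C4H7N2O3- anion).
#'
#' @param s An `ndmm` of class DASC, UBAS, or UPAS.
#' @return A tibble with columns `fragment` (neutral `mol_formula`
#'   list-column), `ion_formula` (charged formula string), `adduct`,
#'   `polarity`, `mz`.
#' @export
diagnostic_fragments <- function(s) {
  stopifnot(inherits(s, "ndmm"))
  if (!s$class %in% c("DASC", "UBAS", "UPAS")) {
    stop("no diagnostic fragment rule for class \"", s$class,
         "\" (rules exist for DASC, UBAS, UPAS)", call. = FALSE)
  }
  frag <- switch(s$class,
    DASC = fml_subtract(
      fml_add(s$first_unit$formula, .SUGAR_FORMULA),
      fml_multiply(.WATER, 2L)
    ),
    UBAS = fml_subtract(
      fml_add(.HEAD_FORMULA[["UB"]], .SUGAR_FORMULA),
      fml_multiply(.WATER, 2L)
    ),
    UPAS = parse_formula(.HEAD_FORMULA[["UP"]])
  )
  adduct <- switch(s$class, DASC = "M+Na", UBAS = "M+H", UPAS = "M-H")
  tibble::tibble(
    fragment = list(frag),
    ion_formula = render_formula(ion_formula(frag, adduct)),
    adduct = adduct,
    polarity = unname(ndmm_adducts[[adduct]]),
    mz = ion_mz(frag, adduct)
  )
}
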