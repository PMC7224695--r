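# Structure-based nomenclature for modular ascarosides:
#   (head group-)asc-(omega)(Delta)C#(terminal group)
# with the first ascaroside of a dimer in parentheses, prefixed by its
# attachment position, e.g. "4'-UB-2'-(asc-C5)-asc-C4" (ubas#28).

.OMEGA <- "\u03c9"
.DELTA <- "\u0394"

.CHAIN_RE <- paste0("asc-(", .OMEGA, "?)(", .DELTA, "?)C([0-9]+)")

.parse_chain <- function(text) {
  m <- regmatches(text, regexec(paste0("^", .CHAIN_RE, "$"), text))[[1]]
  if (!length(m)) return(NULL)
  side_chain(
    n_carbons = as.integer(m[4]),
    unsaturated = nzchar(m[3]),
    attachment = if (nzchar(m[2])) "omega" else "omega_minus_1"
  )
}

#' Parse a structure-based ascaroside name
#'
#' Grammar: an optional `4'-UB-` / `4'-UP-` head group, an optional
#' parenthesized first ascaroside with its attachment position (`2'-(asc-...)-`
#' or `4'-(asc-...)-`), then the (second) unit `asc-` + optional `\u03c9` (omega) +
#' optional `\u0394` (Delta) + `C` + chain length. Head groups are only defined at the
#' 4'-position; any other head position is rejected.
#'
#' @param name A name string, e.g. `"asc-\u03c9C3"`, `"4'-(asc-\u0394C7)-asc-\u0394C7"`,
#'   `"4'-UB-2'-(asc-C5)-asc-C4"`.
#' @return An `ndmm` structure; [render_name()] is its inverse on canonical
#'   names.
#' @export
parse_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  s <- trimws(name)

  head <- NULL
  m <- regmatches(s, regexec("^([0-9]')-(UB|UP)-", s))[[1]]
  if (length(m)) {
    if (m[2] != "4'") {
      stop("head group position must be 4' (got ", m[2], ") in: ", name,
           call. = FALSE)
    }
    head <- m[3]
    s <- substring(s, nchar(m[1]) + 1L)
  }

  first_unit <- NULL
  linkage <- NULL
  m <- regmatches(s, regexec("^([24]')-\\(([^)]*)\\)-", s))[[1]]
  if (length(m)) {
    linkage <- m[2]
    chain1 <- .parse_chain(m[3])
    if (is.null(chain1)) {
      stop("malformed first-unit name \"", m[3], "\" in: ", name,
           call. = FALSE)
    }
    first_unit <- assemble_ndmm(chain1)
    s <- substring(s, nchar(m[1]) + 1L)
  }

  chain <- .parse_chain(s)
  if (is.null(chain)) {
    stop("malformed ascaroside name: ", name, call. = FALSE)
  }
  assemble_ndmm(chain, head = head, first_unit = first_unit,
                linkage = linkage)
}

#' Render the canonical structure-based name
#'
#' @param s An `ndmm` expressible in the nomenclature grammar (registry-only
#'   compounds and dimers with unresolved linkage have no canonical name).
#' @return The canonical name string; [parse_name()] is its inverse.
#' @export
render_name <- function(s) {
  stopifnot(inherits(s, "ndmm"))
  if (s$class == "registry" || is.null(s$side_chain)) {
    stop("registry compound ", s$registry_id %||% "",
         " has no structure-based grammar form", call. = FALSE)
  }
  parts <- character(0)
  if (!is.null(s$head)) parts <- c(parts, paste0("4'-", s$head, "-"))
  if (!is.null(s$first_unit)) {
    if (is.null(s$linkage) || s$linkage == "unresolved") {
      stop("dimer with unresolved linkage has no canonical name", call. = FALSE)
    }
    parts <- c(parts, paste0(s$linkage, "-(asc-",
                             format(s$first_unit$side_chain), ")-"))
  }
  paste0(paste(parts, collapse = ""), "asc-", format(s$side_chain))
}
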