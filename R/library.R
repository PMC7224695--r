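# Combinatorial candidate library for the tandem-MS screen: exhaustive,
# duplicate-free enumeration of modular ascaroside structures from configured
# building blocks, each carrying theoretical m/z for the configured adducts.

.default_adducts <- function() names(ndmm_adducts)

#' Build the combinatorial NDMM candidate library
#'
#' Enumerates simple ascarosides (one unit), dimers (ordered pairs of units
#' with a 2'- or 4'-linkage), head-group monomers (UB/UP at the 4'-position),
#' and head-group dimers (head at 4', first unit at 2'), from the configured
#' building blocks. Every candidate carries its neutral formula and the
#' theoretical m/z of each configured adduct.
#'
#' @param chain_lengths Integer vector of side-chain lengths (3-11).
#' @param include_unsaturated Logical; also enumerate chains with one double
#'   bond.
#' @param attachments Chain attachment positions to enumerate
#'   (default omega-1 only; add `"omega"` for terminal attachment).
#' @param heads Character vector of head groups to enumerate (`"UB"`,
#'   `"UP"`); empty for none.
#' @param include_dimers Logical; enumerate dimeric candidates.
#' @param dimer_linkages Linkages for dimer first units (default both `"2'"`
#'   and `"4'"`).
#' @param head_on_dimers Logical; enumerate head-bearing dimers (the
#'   ubas#28-type architecture).
#' @param adducts Adducts to precompute m/z for (default all supported).
#' @return A tibble with columns `name`, `class`, `formula`, a `structure`
#'   list-column, and one `mz_<adduct>` column per configured adduct (`NA`
#'   where the adduct polarity is not applicable).
#' @examples
#' lib <- build_library(chain_lengths = c(4, 5))
#' nrow(lib)  # 2 simple + 8 dimers
#' @export
build_library <- function(chain_lengths,
                          include_unsaturated = FALSE,
                          attachments = "omega_minus_1",
                          heads = character(0),
                          include_dimers = TRUE,
                          dimer_linkages = c("2'", "4'"),
                          head_on_dimers = TRUE,
                          adducts = NULL) {
  if (length(chain_lengths) == 0) {
    stop("empty building-block config: no chain lengths given", call. = FALSE)
  }
  adducts <- adducts %||% .default_adducts()
  adducts <- vapply(adducts, .normalize_adduct, character(1))
  if (length(heads)) heads <- match.arg(heads, c("UB", "UP"), several.ok = TRUE)

  sat <- if (include_unsaturated) c(FALSE, TRUE) else FALSE
  units <- tidyr::expand_grid(
    n = sort(unique(as.integer(chain_lengths))),
    unsaturated = sat,
    attachment = attachments
  )
  unit_structs <- purrr::pmap(units, function(n, unsaturated, attachment) {
    assemble_ndmm(side_chain(n, unsaturated, attachment))
  })

  candidates <- unit_structs

  for (h in heads) {
    candidates <- c(candidates, purrr::map(unit_structs, function(u) {
      assemble_ndmm(u$side_chain, head = h)
    }))
  }

  if (include_dimers) {
    pairs <- tidyr::expand_grid(
      i = seq_along(unit_structs),
      j = seq_along(unit_structs),
      linkage = dimer_linkages
    )
    dimers <- purrr::pmap(pairs, function(i, j, linkage) {
      assemble_ndmm(unit_structs[[j]]$side_chain,
                    first_unit = unit_structs[[i]],
                    linkage = linkage)
    })
    candidates <- c(candidates, dimers)
    if (length(heads) && head_on_dimers) {
      hpairs <- tidyr::expand_grid(
        h = heads,
        i = seq_along(unit_structs),
        j = seq_along(unit_structs)
      )
      hdimers <- purrr::pmap(hpairs, function(h, i, j) {
        assemble_ndmm(unit_structs[[j]]$side_chain, head = h,
                      first_unit = unit_structs[[i]], linkage = "2'")
      })
      candidates <- c(candidates, hdimers)
    }
  }

  lib <- tibble::tibble(
    name = purrr::map_chr(candidates, render_name),
    class = purrr::map_chr(candidates, "class"),
    formula = purrr::map_chr(candidates, ~ render_formula(.x$formula)),
    structure = candidates
  )
  stopifnot(!anyDuplicated(lib$name))
  for (a in adducts) {
    col <- paste0("mz_", gsub("[+]", "p", gsub("-", "m", a)))
    lib[[col]] <- purrr::map_dbl(lib$structure, ~ ion_mz(.x$formula, a))
  }
  attr(lib, "adducts") <- adducts
  lib
}

#' Add registry compounds to a candidate library
#'
#' Appends registry-defined NDMMs (e.g. NPAR/PASC compounds with
#' user-supplied formulas) to a [build_library()] tibble, computing the same
#' adduct m/z columns.
#'
#' @param lib A library tibble from [build_library()].
#' @param registry A tibble from [read_registry()] or with columns `name`,
#'   `formula`, `class`.
#' @return The extended library tibble.
#' @export
add_registry_compounds <- function(lib, registry) {
  adducts <- attr(lib, "adducts")
  structs <- if ("structure" %in% names(registry)) {
    registry$structure
  } else {
    purrr::pmap(registry[c("name", "formula", "class")],
                function(name, formula, class) {
                  registry_ndmm(name, formula, class)
                })
  }
  extra <- tibble::tibble(
    name = registry$name,
    class = purrr::map_chr(structs, "class"),
    formula = purrr::map_chr(structs, ~ render_formula(.x$formula)),
    structure = structs
  )
  for (a in adducts) {
    col <- paste0("mz_", gsub("[+]", "p", gsub("-", "m", a)))
    extra[[col]] <- purrr::map_dbl(extra$structure, ~ ion_mz(.x$formula, a))
  }
  out <- dplyr::bind_rows(lib, extra)
  if (anyDuplicated(out$name)) {
    stop("registry names collide with library candidates", call. = FALSE)
  }
  attr(out, "adducts") <- adducts
  out
}
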