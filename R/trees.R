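# Phylogeny handling. Trees are ape "phylo" objects throughout; this file
# wraps reading/validation, ultrametricity checking, patristic distances and
# clade bookkeeping (species -> named clade maps, MRCA lookup).

#' Read a rooted tree with branch lengths from a Newick file
#'
#' @param path Path to a Newick file.
#' @return An ape `phylo`. Errors on duplicate tip labels or missing branch
#'   lengths; warns (but proceeds) if the tree is not ultrametric, since only
#'   the Brownian-threshold null assumes clock-like depths.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  validate_tree(tree)
  tree
}

#' @rdname read_newick
#' @param tree An ape `phylo`.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }
  if (!is_ultrametric(tree)) {
    warning("tree is not ultrametric (relative tip-depth spread > 1e-6); ",
            "Brownian-threshold nulls assume clock-like depths",
            call. = FALSE)
  }
  invisible(tree)
}

#' Ultrametricity check
#'
#' Relative spread of root-to-tip depths below `tol`.
#'
#' @param tree An ape `phylo`.
#' @param tol Relative tolerance (default 1e-6).
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  diff(range(depths)) <= tol * max(depths)
}

#' Patristic (tip-to-tip path) distances
#'
#' Sum of branch lengths along the path between each pair of tips, as used to
#' relate compositional dissimilarity to evolutionary divergence.
#'
#' @param tree An ape `phylo`.
#' @return A symmetric matrix with zero diagonal and tip-label dimnames.
#' @export
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}

#' MRCA node of a named clade
#'
#' @param tree An ape `phylo`.
#' @param clades Tibble with columns `species`, `clade`.
#' @param clade Clade name to look up.
#' @return Internal node number of the clade's most recent common ancestor.
#' @export
clade_mrca <- function(tree, clades, clade) {
  sp <- clades$species[clades$clade == clade]
  if (!length(sp)) stop("unknown clade name: ", clade, call. = FALSE)
  sp <- intersect(sp, tree$tip.label)
  if (length(sp) < 2) {
    stop("clade ", clade, " has fewer than 2 tips in the tree", call. = FALSE)
  }
  ape::getMRCA(tree, sp)
}

#' Read a species-to-clade map
#'
#' @param path CSV with columns `species`, `clade`.
#' @return A tibble; clade sets must be disjoint (one clade per species).
#' @export
read_clade_map <- function(path) {
  df <- tibble::as_tibble(
    utils::read.csv(path, comment.char = "", stringsAsFactors = FALSE)
  )
  stopifnot(all(c("species", "clade") %in% names(df)))
  if (anyDuplicated(df$species)) {
    stop("clade sets are not disjoint: a species appears twice", call. = FALSE)
  }
  df
}

#' Prune tree and data to their common species
#'
#' Species missing from either side are dropped with a warning, mirroring the
#' practice of pruning tips without profile data before comparative analysis.
#'
#' @param tree An ape `phylo`.
#' @param species Character vector of species with data.
#' @return List with the pruned `tree` and the retained `species`.
#' @export
match_tree_species <- function(tree, species) {
  keep <- intersect(tree$tip.label, species)
  drop_tip <- setdiff(tree$tip.label, keep)
  drop_dat <- setdiff(species, keep)
  if (length(drop_tip)) {
    warning("dropping ", length(drop_tip), " tip(s) without data: ",
            paste(utils::head(drop_tip, 5), collapse = ", "),
            if (length(drop_tip) > 5) ", ...", call. = FALSE)
  }
  if (length(drop_dat)) {
    warning("dropping ", length(drop_dat), " species absent from the tree: ",
            paste(utils::head(drop_dat, 5), collapse = ", "),
            if (length(drop_dat) > 5) ", ...", call. = FALSE)
  }
  if (length(keep) < 3) stop("fewer than 3 species in common", call. = FALSE)
  tree <- if (length(drop_tip)) ape::drop.tip(tree, drop_tip) else tree
  list(tree = tree, species = keep)
}
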