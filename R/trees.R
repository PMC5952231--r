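# Tree handling for the monophyly criterion: Newick in/out, outgroup
# rooting, a deterministic neighbour-joining builder for self-contained
# evaluation, and species-monophyly scoring. Bayesian tree inference is
# deliberately out of scope; trees are consumed, not inferred.

#' Parse / write Newick trees
#'
#' Thin validated wrappers around the `ape` Newick reader and writer.
#' Round trips preserve topology, branch lengths and labels.
#'
#' @param text Newick string (for [parse_newick()]).
#' @param path Optional file path to read from / write to.
#' @param tree A `phylo` tree (for [write_newick()]).
#' @return [parse_newick()] returns an `ape::phylo`; [write_newick()]
#'   returns the Newick string (invisibly when writing to a file).
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  tr <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("parse error: not a well-formed Newick tree")
  if (anyDuplicated(tr$tip.label))
    stop("parse error: duplicate tip label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  tr
}

#' @rdname parse_newick
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour-joining agglomeration (via `ape::nj`), provided so
#' the monophyly criterion can be evaluated without external tree
#' inference. Requires a complete matrix.
#'
#' @param dmat A `pdist_matrix` with no missing entries and >= 3 ids.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dmat) {
  stopifnot(inherits(dmat, "pdist_matrix"))
  if (length(dmat$ids) < 3L) stop("input error: need >= 3 individuals")
  if (anyNA(dmat$values))
    stop("input error: missing entries; neighbour-joining needs a complete matrix")
  ape::nj(dmat$values)
}

#' Root a tree on an outgroup tip
#'
#' Places the root on the outgroup's pendant edge.
#'
#' @param tree A `phylo` tree.
#' @param outgroup Tip label to root on.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label)
    stop("input error: outgroup tip '", outgroup, "' not in tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Test monophyly of a tip set
#'
#' `TRUE` when some node's descendant tip set equals `tips` exactly; a
#' polytomy whose descendant set equals `tips` counts. Singleton sets
#' return `TRUE` with attribute `trivial = TRUE`.
#'
#' @param tree A rooted `phylo` tree.
#' @param tips Character vector of tip labels (subset of the tree tips).
#' @return Logical scalar, with attribute `trivial` for singletons.
#' @export
is_monophyletic_tips <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("input error: unknown tip(s): ", paste(unknown, collapse = ", "))
  if (length(tips) < 1L) stop("input error: need at least one tip")
  if (length(tips) == 1L) return(structure(TRUE, trivial = TRUE))
  structure(ape::is.monophyletic(tree, tips), trivial = FALSE)
}

#' Species-monophyly success on a tree
#'
#' A species is discriminated only when all its tips form an exclusive
#' clade. The rate is computed over species with at least two sampled
#' tips by default; singleton species are trivially monophyletic and
#' reported separately.
#'
#' @param tree A `phylo` tree whose tips are individual ids.
#' @param tab Sample table labelling every tip.
#' @param include_singletons Count singleton species in the denominator
#'   (as trivial successes) instead of excluding them.
#' @return List with `species` (`data.frame`), `rate` (percent) and
#'   counts of evaluated/excluded species.
#' @export
tree_species_success <- function(tree, tab, include_singletons = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  sp <- tab$species[match(tree$tip.label, tab$individual_id)]
  if (anyNA(sp))
    stop("validation error: unlabeled tip(s): ",
         paste(tree$tip.label[is.na(sp)], collapse = ", "))
  species <- sort(unique(sp))
  n_tips <- vapply(species, function(s) sum(sp == s), 0L)
  mono <- vapply(species, function(s) {
    as.logical(is_monophyletic_tips(tree, tree$tip.label[sp == s]))
  }, logical(1))
  evaluable <- n_tips >= 2L
  denom <- if (include_singletons) rep(TRUE, length(species)) else evaluable
  rate <- if (any(denom)) 100 * sum(mono[denom]) / sum(denom) else NA_real_
  list(species = data.frame(species = species, n_tips = n_tips,
                            monophyletic = mono, evaluable = evaluable,
                            stringsAsFactors = FALSE),
       rate = rate, n_evaluated = sum(denom), n_excluded = sum(!denom))
}
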