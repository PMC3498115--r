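# Distance-based trees for testing clade-structure claims.
#
# Bayesian tree inference is deliberately out of scope here: the claims the
# package tests are topological separations (which leaves form clades), and
# neighbor joining on alignment-identity distances assesses those
# deterministically at desk scale.

#' Identity-distance matrix between protein records
#'
#' `d(i, j) = 1 - identity(i, j) / 100`, with identity from the global
#' affine-gap alignment of [pairwise_align_stats()].
#'
#' @param records Tibble with unique `id` and `sequence` columns, at least
#'   3 rows.
#' @param aligner Function of two sequences returning something with an
#'   `identity` percentage; defaults to [pairwise_align_stats()].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
distance_matrix <- function(records, aligner = pairwise_align_stats) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (nrow(records) < 3) abort("distance_matrix needs at least 3 records")
  if (anyDuplicated(records$id)) {
    abort(sprintf("duplicate record id(s): %s",
                  paste(unique(records$id[duplicated(records$id)]), collapse = ", ")))
  }
  n <- nrow(records)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ident <- aligner(records$sequence[[i]], records$sequence[[j]])$identity
      d[i, j] <- d[j, i] <- 1 - ident / 100
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via `ape::nj()`), deterministic given the
#' input. Negative branch lengths, which NJ can produce on non-additive
#' matrices, are clamped to zero with a warning.
#'
#' @param dm Symmetric nonnegative matrix with zero diagonal and labelled
#'   dimnames (see [distance_matrix()]).
#' @return An unrooted `phylo` tree (leaf set = matrix labels),
#'   serializable to Newick with `ape::write.tree()`.
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || !isSymmetric(unname(dm), tol = 1e-8)) {
    abort("dm must be a symmetric distance matrix")
  }
  if (is.null(rownames(dm))) abort("dm must carry labels as dimnames")
  if (nrow(dm) < 3) abort("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(dm)
  if (any(tree$edge.length < 0)) {
    warn(sprintf("%d negative NJ branch length(s) clamped to 0",
                 sum(tree$edge.length < 0)))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Test whether a leaf set is a clade
#'
#' Roots the tree at `outgroup` and asks whether some edge separates
#' exactly `leaf_subset` from the rest, i.e. whether the subset is
#' monophyletic with respect to that rooting.
#'
#' @param tree A `phylo` tree.
#' @param leaf_subset Character vector of leaf labels.
#' @param outgroup A leaf label to root at (must not be in `leaf_subset`).
#' @return `TRUE` or `FALSE`.
#' @export
is_monophyletic <- function(tree, leaf_subset, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(c(leaf_subset, outgroup), tree$tip.label)
  if (length(unknown)) {
    abort(sprintf("unknown leaf label(s): %s", paste(unknown, collapse = ", ")))
  }
  if (outgroup %in% leaf_subset) abort("outgroup must not be inside leaf_subset")
  if (length(leaf_subset) == 1) return(TRUE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips = leaf_subset)
}
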