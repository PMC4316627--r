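#' Non-trivial bipartitions of a tree
#'
#' One bipartition per internal edge; trivial splits (single leaf, or all
#' but one leaf) are excluded. Each split is canonicalized to the side NOT
#' containing a fixed reference leaf (the lexicographically smallest leaf
#' label), so identical splits from differently rooted trees compare equal.
#'
#' @param tree An [ape::phylo] object (rooted or unrooted).
#' @return A list of character vectors (sorted leaf sets), named by a
#'   canonical key.
#' @export
bipartition_set <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  ntip <- length(tips)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next  # pendant edge: trivial split
    side <- tips_below(tree, child)
    side <- canonical_side(side, tips, ref)
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    out[[split_key(side)]] <- side
  }
  # A rooted tree's two root edges describe the same split; de-dup via names.
  out[!duplicated(names(out))]
}

canonical_side <- function(side, all_tips, ref = sort(all_tips)[1]) {
  side <- sort(side)
  if (ref %in% side) side <- sort(setdiff(all_tips, side))
  side
}

split_key <- function(side) paste(side, collapse = "\r")

#' Test monophyly of a leaf set (unrooted convention)
#'
#' A leaf set is monophyletic iff it is trivial (size <= 1, size
#' `n - 1`, or all leaves) or some edge's bipartition isolates exactly that
#' set. The test is independent of where the input tree happens to be
#' rooted.
#'
#' @param tree An [ape::phylo].
#' @param leaves Character vector of leaf labels (subset of the tree's).
#' @return Logical.
#' @examples
#' tr <- parse_newick("((A1:1,A2:1):1,(B1:1,B2:1):1);")
#' is_monophyletic(tr, c("A1", "A2"))  # TRUE
#' @export
is_monophyletic <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- unique(leaves)
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown) > 0L)
    stop_fmt("leaf '%s' not in tree", unknown[1])
  n <- length(tree$tip.label)
  k <- length(leaves)
  if (k <= 1L || k >= n - 1L) return(TRUE)
  key <- split_key(canonical_side(leaves, tree$tip.label))
  key %in% names(bipartition_set(tree))
}
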