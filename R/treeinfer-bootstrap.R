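#' Nonparametric bootstrap support for a distance tree
#'
#' Builds the tree from the full alignment (neighbor joining on corrected
#' distances), then resamples alignment columns i.i.d. with replacement `B`
#' times, rebuilds, and assigns each internal edge of the original tree the
#' percentage of replicates containing its bipartition. Deterministic given
#' `seed`.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param correction,alpha Passed to [distance_matrix()].
#' @return The original unrooted tree with supports in `node.label`
#'   (numeric in `[0, 100]`, `NA` for the basal node).
#' @export
bootstrap_support <- function(seqs, B = 100L, seed = 1L,
                              correction = "kimura", alpha = NULL) {
  B <- as.integer(B)
  stopifnot(B >= 1L)
  check_aligned(seqs)
  tree <- neighbor_joining(distance_matrix(seqs, correction = correction,
                                           alpha = alpha))
  counts <- count_split_support(tree, seqs, B, seed, correction, alpha)
  annotate_supports(tree, counts$support)
}

# Percentage of replicate trees containing each non-trivial split of `tree`.
count_split_support <- function(tree, seqs, B, seed, correction, alpha) {
  splits <- bipartition_set(tree)
  hits <- setNames(numeric(length(splits)), names(splits))
  im <- aln_int_matrix(seqs)
  n <- ncol(im)
  for (b in seq_len(B)) {
    cols <- with_seed(derive_seed(seed, b),
                      sample.int(n, n, replace = TRUE))
    rep_tree <- neighbor_joining(dist_from_int(im[, cols, drop = FALSE],
                                               correction, alpha = alpha))
    rep_keys <- names(bipartition_set(rep_tree))
    present <- names(hits) %in% rep_keys
    hits[present] <- hits[present] + 1
  }
  list(support = hits / B * 100, splits = splits)
}

# Write per-split supports into node.label of the original tree.
annotate_supports <- function(tree, support) {
  ntip <- length(tree$tip.label)
  labels <- rep(NA_real_, tree$Nnode)
  tips <- sort(tree$tip.label)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next
    side <- canonical_side(tips_below(tree, child), tree$tip.label)
    key <- split_key(side)
    if (key %in% names(support))
      labels[child - ntip] <- support[[key]]
  }
  tree$node.label <- labels
  tree
}

#' Bootstrap support for one particular bipartition
#'
#' @inheritParams bootstrap_support
#' @param leaves Character vector: one side of the split of interest.
#' @return Percentage of replicates in which `leaves` forms a clade, plus
#'   attribute `in_original` (was the split in the full-data tree?).
#' @export
split_bootstrap_support <- function(seqs, leaves, B = 100L, seed = 1L,
                                    correction = "kimura", alpha = NULL) {
  check_aligned(seqs)
  im <- aln_int_matrix(seqs)
  n <- ncol(im)
  full_tree <- neighbor_joining(distance_matrix(seqs, correction = correction,
                                                alpha = alpha))
  hit <- 0L
  for (b in seq_len(B)) {
    cols <- with_seed(derive_seed(seed, b),
                      sample.int(n, n, replace = TRUE))
    rep_tree <- neighbor_joining(dist_from_int(im[, cols, drop = FALSE],
                                               correction, alpha = alpha))
    if (is_monophyletic(rep_tree, leaves)) hit <- hit + 1L
  }
  out <- hit / B * 100
  attr(out, "in_original") <- is_monophyletic(full_tree, leaves)
  out
}
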