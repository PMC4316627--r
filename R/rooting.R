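#' Root a tree with an outgroup
#'
#' Requires the outgroup to be monophyletic on the unrooted tree; the root
#' is placed at the midpoint of the stem edge (the edge separating outgroup
#' from ingroup), splitting its length equally between the two root
#' children.
#'
#' @param tree Unrooted [ape::phylo].
#' @param outgroup Character vector of outgroup leaf labels (non-empty,
#'   proper subset of the leaves).
#' @return A rooted [ape::phylo] (root has exactly 2 children).
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  outgroup <- unique(outgroup)
  ingroup <- setdiff(tree$tip.label, outgroup)
  if (length(outgroup) == 0L || length(ingroup) == 0L)
    stop_fmt("outgroup and its complement must both be non-empty")
  if (!is_monophyletic(tree, outgroup))
    stop_fmt("outgroup is not monophyletic; cannot root (violating leaves intermixed with ingroup)")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  root <- length(rooted$tip.label) + 1L
  root_edges <- which(rooted$edge[, 1] == root)
  stopifnot(length(root_edges) == 2L)
  stem <- sum(rooted$edge.length[root_edges])
  rooted$edge.length[root_edges] <- stem / 2
  rooted
}

#' Length of the stem edge separating two groups
#'
#' For an unrooted tree in which `group_a` and `group_b` partition the
#' leaves and both are monophyletic, returns the length of the internal edge
#' (the path between the two groups' MRCA-adjacent nodes) separating them.
#'
#' @param tree Unrooted [ape::phylo].
#' @param group_a,group_b Leaf sets partitioning the tree's leaves.
#' @return Stem length (substitutions/site).
#' @export
interdomain_stem_length <- function(tree, group_a, group_b) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!setequal(c(group_a, group_b), tips) ||
      length(intersect(group_a, group_b)) > 0L)
    stop_fmt("groups must partition the tree's leaves")
  if (!is_monophyletic(tree, group_a) || !is_monophyletic(tree, group_b))
    stop_fmt("both groups must be monophyletic")
  # the stem is the edge whose bipartition equals group_a | group_b
  for (e in seq_len(nrow(tree$edge))) {
    side <- tips_below(tree, tree$edge[e, 2])
    if (setequal(side, group_a) || setequal(side, group_b))
      return(tree$edge.length[e])
  }
  # both groups exist only as the two sides of the basal node of a rooted
  # tree: the stem is then the sum of the two root edges
  root <- length(tips) + 1L
  root_edges <- which(tree$edge[, 1] == root)
  if (length(root_edges) == 2L) {
    sides <- lapply(tree$edge[root_edges, 2], tips_below, tree = tree)
    if (setequal(sides[[1]], group_a) || setequal(sides[[1]], group_b))
      return(sum(tree$edge.length[root_edges]))
  }
  stop_fmt("no edge separates the two groups")
}

#' Ratio of stem lengths between two trees
#'
#' @param tree_1,tree_2 Trees sharing the two groups.
#' @param group_a,group_b Leaf sets (see [interdomain_stem_length()]).
#' @return `stem(tree_1) / stem(tree_2)`.
#' @export
stem_ratio <- function(tree_1, tree_2, group_a, group_b) {
  s1 <- interdomain_stem_length(tree_1, group_a, group_b)
  s2 <- interdomain_stem_length(tree_2, group_a, group_b)
  if (s2 == 0) stop_fmt("zero stem length in the denominator tree")
  s1 / s2
}

#' Long-branch flags per leaf
#'
#' Score = leaf pendant-edge length / median pendant-edge length; a leaf is
#' flagged when the robust z-score of its pendant length
#' (`(x - median) / (1.4826 * MAD)`) exceeds `z_threshold`. Pendant edges do
#' not depend on rooting, so neither do the scores.
#'
#' @param tree [ape::phylo] with >= 4 leaves.
#' @param z_threshold Robust z-score threshold (default 3).
#' @return Data frame with columns `leaf`, `pendant`, `score`, `z`, `flag`.
#' @export
long_branch_flags <- function(tree, z_threshold = 3) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 4L)
  ntip <- length(tree$tip.label)
  pend <- numeric(ntip)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) pend[child] <- tree$edge.length[e]
  }
  med <- median(pend)
  s <- mad(pend)
  z <- if (s > 0) (pend - med) / s else ifelse(pend > med, Inf, 0)
  data.frame(leaf = tree$tip.label, pendant = pend,
             score = if (med > 0) pend / med else rep(1, ntip),
             z = z, flag = z > z_threshold, stringsAsFactors = FALSE)
}

#' Report on a rooted tree
#'
#' Names the two root-adjacent clades by their class composition, records
#' the stem length (sum of the two root edges) and per-side monophyly
#' supports (copied from the tree's `node.label` when present), and flags
#' classes straddling the root.
#'
#' @param rooted A rooted [ape::phylo] (2-child root).
#' @param taxonomy A `taxonomy` data frame.
#' @return An object of class `rooting_report`.
#' @export
root_report <- function(rooted, taxonomy) {
  stopifnot(inherits(rooted, "phylo"), ape::is.rooted(rooted))
  ntip <- length(rooted$tip.label)
  root <- ntip + 1L
  root_edges <- which(rooted$edge[, 1] == root)
  sides <- lapply(rooted$edge[root_edges, 2], tips_below, tree = rooted)
  rec <- taxonomy_lookup(taxonomy, rooted$tip.label)
  side_info <- lapply(sides, function(s) {
    r <- rec[match(s, rec$leaf), ]
    list(leaves = s, classes = sort(unique(r$class)),
         domains = sort(unique(r$domain)))
  })
  straddlers <- intersect(side_info[[1]]$classes, side_info[[2]]$classes)
  supports <- vapply(rooted$edge[root_edges, 2], function(nd) {
    if (nd > ntip && !is.null(rooted$node.label)) {
      suppressWarnings(as.numeric(rooted$node.label[nd - ntip]))
    } else NA_real_
  }, numeric(1))
  structure(list(stem_length = sum(rooted$edge.length[root_edges]),
                 side_1 = side_info[[1]], side_2 = side_info[[2]],
                 side_supports = supports,
                 straddling_classes = straddlers),
            class = "rooting_report")
}

#' @export
print.rooting_report <- function(x, ...) {
  cat(sprintf("<rooting_report: stem %.4f; %s | %s%s>\n", x$stem_length,
              paste(x$side_1$classes, collapse = "+"),
              paste(x$side_2$classes, collapse = "+"),
              if (length(x$straddling_classes) > 0L)
                paste0("; STRADDLERS: ",
                       paste(x$straddling_classes, collapse = ","))
              else ""))
  invisible(x)
}
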