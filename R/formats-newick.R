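#' Parse a Newick string into a phylogenetic tree
#'
#' The accepted dialect has branch lengths after `:` and internal-node
#' numeric labels interpreted as support values (the style most ML programs
#' emit); quoted labels and comments are not supported. Missing branch
#' lengths default to 0. A tree is rooted iff its top-level node has exactly
#' two children; rootedness is inferred from arity, never from metadata.
#'
#' @param text A single Newick string (terminated by `;`).
#' @return An [ape::phylo] object. Internal numeric labels are kept in
#'   `node.label` (support values in `[0, 100]`).
#' @examples
#' parse_newick("((A:1,B:2):0.5,C:3);")   # rooted: top node has 2 children
#' parse_newick("(A:1,B:1,C:1);")         # unrooted: basal degree 3
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  end <- NA_integer_
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop_fmt("Newick parse error: unbalanced ')' at character %d", i)
    }
    if (chars[i] == ";") { end <- i; break }
  }
  if (is.na(end)) stop_fmt("Newick parse error: missing ';' terminator")
  if (depth != 0L)
    stop_fmt("Newick parse error: %d unclosed '(' at character %d", depth, end)
  if (end < length(chars) && nzchar(trimws(substr(txt, end + 1L, nchar(txt)))))
    stop_fmt("Newick parse error: trailing garbage at character %d", end + 1L)
  phy <- tryCatch(ape::read.tree(text = substr(txt, 1L, end)),
                  error = function(e) NULL)
  if (is.null(phy))
    stop_fmt("Newick parse error: could not parse '%s'", txt)
  if (is.null(phy$edge.length)) {
    phy$edge.length <- rep(0, nrow(phy$edge))
  } else {
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  if (any(phy$edge.length < 0))
    stop_fmt("Newick parse error: negative branch length")
  if (anyDuplicated(phy$tip.label))
    stop_fmt("duplicate leaf labels in Newick tree")
  phy
}

#' Serialize a phylogenetic tree to Newick
#'
#' Round-trips with [parse_newick()]: topology, branch lengths (to the
#' stated precision) and numeric internal labels (supports) are preserved.
#' Zero-length edges are serialized explicitly.
#'
#' @param tree An [ape::phylo] object.
#' @param precision Number of decimal places for branch lengths.
#' @return A single Newick string.
#' @export
write_newick <- function(tree, precision = 6L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  ape::write.tree(tree, digits = as.integer(precision) + 1L)
}

#' Is a tree rooted (top-level arity 2)?
#'
#' @param tree An [ape::phylo] object.
#' @return Logical.
#' @export
is_rooted_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::is.rooted(tree)
}
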