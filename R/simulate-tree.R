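#' Configure the simulated two-kingdom world
#'
#' The simulated world mirrors the shape of a domain-level phylogeny rooted
#' with a distant outgroup: two ingroup kingdoms, each containing several
#' monophyletic classes; and a multi-phylum outgroup joined to the ingroup
#' by a long stem edge. Clade depths are controlled by `ingroup_depth` and
#' `outgroup_depth`; within each side, edge lengths are fixed fractions of
#' the depth (class stem 0.4, class ladder spacing 0.2, kingdom edge 0.25,
#' species-ladder edges depth/15; outgroup: phylum stem 0.3, phylum spacing
#' 0.1). `fast_clades` plants rate-accelerated (long-branch) lineages: each
#' entry scales all edges of one named class/phylum subtree, and its stem
#' edge, by a multiplier.
#'
#' @param n_classes_per_kingdom Classes per ingroup kingdom.
#' @param n_species_per_class Species per ingroup class.
#' @param n_outgroup_phyla Number of outgroup phyla (the downstream coverage
#'   filter defaults to requiring 24).
#' @param species_per_outgroup_phylum Species per outgroup phylum.
#' @param stem_length Length (substitutions/site) of the edge joining the
#'   ingroup and the outgroup.
#' @param ingroup_depth,outgroup_depth Approximate root-to-tip depth
#'   (substitutions/site) on each side.
#' @param fast_clades List of `list(clade = <class or phylum name>,
#'   rate = <multiplier >= 1>)`.
#' @param seed Integer seed recorded with the config (tree construction is
#'   deterministic).
#' @return An object of class `world_config`.
#' @export
world_config <- function(n_classes_per_kingdom = 3L,
                         n_species_per_class = 3L,
                         n_outgroup_phyla = 24L,
                         species_per_outgroup_phylum = 1L,
                         stem_length = 0.5,
                         ingroup_depth = 0.75,
                         outgroup_depth = 0.75,
                         fast_clades = list(),
                         seed = 1L) {
  cfg <- list(n_classes_per_kingdom = as.integer(n_classes_per_kingdom),
              n_species_per_class = as.integer(n_species_per_class),
              n_outgroup_phyla = as.integer(n_outgroup_phyla),
              species_per_outgroup_phylum = as.integer(species_per_outgroup_phylum),
              stem_length = stem_length,
              ingroup_depth = ingroup_depth,
              outgroup_depth = outgroup_depth,
              fast_clades = fast_clades,
              seed = as.integer(seed))
  counts <- unlist(cfg[1:4])
  if (any(counts < 1L)) stop_fmt("world_config counts must be >= 1")
  if (stem_length <= 0 || ingroup_depth <= 0 || outgroup_depth <= 0)
    stop_fmt("world_config depths and stem length must be > 0")
  for (fc in fast_clades) {
    if (is.null(fc$clade) || is.null(fc$rate) || fc$rate < 1)
      stop_fmt("fast_clades entries need a clade name and a rate >= 1")
  }
  structure(cfg, class = "world_config")
}

# Ladder (caterpillar) Newick for labels with uniform edge length, attached
# by a stem edge. A single label collapses to a pendant of stem + edge.
ladder_newick <- function(labels, edge, stem) {
  m <- length(labels)
  fmt <- function(x) sprintf("%.10g", x)
  if (m == 1L) return(paste0(labels, ":", fmt(stem + edge)))
  x <- paste0(labels[1], ":", fmt(edge))
  for (i in 2:m) {
    x <- paste0("(", x, ",", labels[i], ":", fmt(edge), ")",
                if (i < m) paste0(":", fmt(edge)) else "")
  }
  paste0(x, ":", fmt(stem))
}

# Fold already-stemmed clade strings into a ladder with given spacing and an
# outer stem on the whole group.
fold_clades <- function(strs, spacing, stem) {
  n <- length(strs)
  fmt <- function(x) sprintf("%.10g", x)
  if (n == 1L) return(add_stem(strs, stem))
  x <- strs[1]
  for (i in 2:n) {
    x <- paste0("(", x, ",", strs[i], ")",
                if (i < n) paste0(":", fmt(spacing)) else "")
  }
  paste0(x, ":", fmt(stem))
}

add_stem <- function(str, extra) {
  len <- as.numeric(sub("^.*:", "", str))
  paste0(sub(":[0-9.eE+-]+$", "", str), ":", sprintf("%.10g", len + extra))
}

#' Simulate the species tree and its taxonomy
#'
#' Builds the unrooted species tree implied by a [world_config()]: the
#' ingroup|outgroup bipartition edge has length `stem_length`; every class
#' and every outgroup phylum is a monophyletic subtree; `fast_clades`
#' subtrees (and their stem edges) are scaled by their rate multipliers.
#' Construction is deterministic given the config.
#'
#' @param config A [world_config()].
#' @return A list with elements `tree` (unrooted [ape::phylo]) and
#'   `taxonomy` (a `taxonomy` data frame; domains are `ingroup-A`,
#'   `ingroup-B`, `outgroup`).
#' @export
sample_species_tree <- function(config) {
  stopifnot(inherits(config, "world_config"))
  nc <- config$n_classes_per_kingdom
  ns <- config$n_species_per_class
  np <- config$n_outgroup_phyla
  mp <- config$species_per_outgroup_phylum
  Din <- config$ingroup_depth
  Dout <- config$outgroup_depth
  sp_edge <- Din / 15
  class_stem <- 0.4 * Din
  class_spacing <- 0.2 * Din
  kingdom_edge <- 0.25 * Din
  og_edge <- Dout / 15
  phylum_stem <- 0.3 * Dout
  phylum_spacing <- 0.1 * Dout

  tx <- list()
  kingdom_str <- character(2)
  for (k in 1:2) {
    klab <- c("kA", "kB")[k]
    cls <- character(nc)
    for (ci in seq_len(nc)) {
      clab <- sprintf("%s_c%d", klab, ci)
      sp <- sprintf("%s_s%d", clab, seq_len(ns))
      cls[ci] <- ladder_newick(sp, sp_edge, class_stem)
      tx[[length(tx) + 1L]] <- data.frame(
        leaf = sp, species = sp, class = clab, phylum = klab,
        domain = paste0("ingroup-", c("A", "B")[k]),
        stringsAsFactors = FALSE)
    }
    kingdom_str[k] <- fold_clades(cls, class_spacing, kingdom_edge)
  }
  phyla <- character(np)
  for (pi in seq_len(np)) {
    plab <- sprintf("og_p%d", pi)
    sp <- sprintf("%s_s%d", plab, seq_len(mp))
    phyla[pi] <- ladder_newick(sp, og_edge, phylum_stem)
    tx[[length(tx) + 1L]] <- data.frame(
      leaf = sp, species = sp, class = plab, phylum = plab,
      domain = "outgroup", stringsAsFactors = FALSE)
  }
  og_str <- fold_clades(phyla, phylum_spacing, config$stem_length)
  newick <- paste0("(", kingdom_str[1], ",", kingdom_str[2], ",", og_str, ");")
  tree <- parse_newick(newick)
  taxonomy <- validate_taxonomy(do.call(rbind, tx))

  for (fc in config$fast_clades) {
    members <- taxonomy$leaf[taxonomy$class == fc$clade |
                             taxonomy$phylum == fc$clade]
    if (length(members) == 0L)
      stop_fmt("fast clade '%s' matches no class or phylum", fc$clade)
    tree <- scale_clade_edges(tree, members, fc$rate)
  }
  list(tree = tree, taxonomy = taxonomy)
}

# Multiply the lengths of all edges inside the clade spanned by `leaves`
# (and the clade's stem edge) by `rate`.
scale_clade_edges <- function(tree, leaves, rate) {
  tips <- match(leaves, tree$tip.label)
  stopifnot(!anyNA(tips))
  if (length(tips) == 1L) {
    node <- tips
  } else {
    node <- ape::getMRCA(tree, tips)
  }
  below <- edges_below(tree, node)
  stem <- which(tree$edge[, 2] == node)
  tree$edge.length[c(below, stem)] <- tree$edge.length[c(below, stem)] * rate
  tree
}

# Indices of edges strictly inside the subtree rooted at `node`.
edges_below <- function(tree, node) {
  children <- which(tree$edge[, 1] == node)
  if (length(children) == 0L) return(integer())
  out <- children
  for (e in children) out <- c(out, edges_below(tree, tree$edge[e, 2]))
  out
}

# Tip labels contained in the subtree below `node` (node may be a tip).
tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  unlist(lapply(which(tree$edge[, 1] == node),
                function(e) tips_below(tree, tree$edge[e, 2])))
}
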