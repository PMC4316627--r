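#' With/without-outgroup placement experiment
#'
#' The diagnostic contrast for long-branch attraction: a focal taxon set is
#' placed twice — once on the full supermatrix (with the outgroup) and once
#' after pruning the outgroup — and its sister clade is recorded under each
#' condition. A fast-evolving focal clade that attaches next to the outgroup
#' stem when the outgroup is present, but next to its true sister when it is
#' absent, is behaving exactly like an LBA artifact.
#'
#' The "sister" is the class-majority label of the smaller of the two
#' subtrees adjacent to the focal clade's attachment node (outgroup taxa
#' count under their domain label, so a basal attraction reads as sister =
#' the outgroup label).
#'
#' @param dataset A [concatenate()] supermatrix (rows are species).
#' @param taxonomy A `taxonomy` data frame.
#' @param focal Character vector of focal species (subset of ingroup rows).
#' @param conditions Subset of `c("with_outgroup", "without_outgroup")`.
#' @param B Bootstrap replicates for the focal-clade support (0 = skip).
#' @param seed Integer seed.
#' @param correction,alpha Distance engine settings (see
#'   [distance_matrix()]).
#' @param outgroup_domain Domain label marking outgroup rows.
#' @return Data frame with one row per condition: `condition`,
#'   `monophyletic`, `sister_label`, `sister_size`, `support`.
#' @export
placement_experiment <- function(dataset, taxonomy, focal,
                                 conditions = c("with_outgroup",
                                                "without_outgroup"),
                                 B = 0L, seed = 1L, correction = "kimura",
                                 alpha = NULL, outgroup_domain = "outgroup") {
  stopifnot(inherits(dataset, "supermatrix"), length(focal) > 0L)
  conditions <- match.arg(conditions, several.ok = TRUE)
  taxa <- names(dataset$seqs)
  rec <- taxonomy_lookup(taxonomy, taxa)
  og <- rec$leaf[rec$domain == outgroup_domain]
  if (length(intersect(focal, og)) > 0L || !all(focal %in% taxa))
    stop_fmt("focal must be a subset of the ingroup rows")
  out <- list()
  for (cond in conditions) {
    keep <- if (cond == "with_outgroup") taxa else setdiff(taxa, og)
    seqs <- dataset$seqs[keep]
    tree <- neighbor_joining(distance_matrix(seqs, correction = correction,
                                             alpha = alpha))
    mono <- is_monophyletic(tree, focal)
    sister_label <- NA_character_
    sister_size <- NA_integer_
    if (mono) {
      sis <- sister_components(tree, focal)
      smallest <- sis[[which.min(lengths(sis))]]
      sister_label <- majority_label(smallest, taxonomy, outgroup_domain)
      sister_size <- length(smallest)
    }
    support <- NA_real_
    if (B > 0L)
      support <- as.numeric(split_bootstrap_support(seqs, focal, B = B,
                                                    seed = seed,
                                                    correction = correction,
                                                    alpha = alpha))
    out[[cond]] <- data.frame(condition = cond, monophyletic = mono,
                              sister_label = sister_label,
                              sister_size = sister_size, support = support,
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# The leaf sets of the subtrees adjacent to the focal clade's attachment
# node (excluding the focal clade itself).
sister_components <- function(tree, focal) {
  tips <- tree$tip.label
  v <- NA_integer_
  for (e in seq_len(nrow(tree$edge))) {
    side <- tips_below(tree, tree$edge[e, 2])
    if (setequal(side, focal)) { v <- tree$edge[e, 1]; break }
    if (setequal(setdiff(tips, side), focal)) { v <- tree$edge[e, 2]; break }
  }
  if (is.na(v)) stop_fmt("focal clade has no isolating edge")
  comps <- list()
  ntip <- length(tips)
  for (e in which(tree$edge[, 1] == v)) {
    comp <- tips_below(tree, tree$edge[e, 2])
    if (!setequal(comp, focal)) comps[[length(comps) + 1L]] <- comp
  }
  if (v != ntip + 1L) {  # component through v's parent edge
    above <- setdiff(tips, tips_below(tree, v))
    if (length(above) > 0L && !setequal(above, focal))
      comps[[length(comps) + 1L]] <- above
  }
  comps
}

majority_label <- function(leaves, taxonomy, outgroup_domain = "outgroup") {
  rec <- taxonomy_lookup(taxonomy, leaves)
  lab <- ifelse(rec$domain == outgroup_domain, rec$domain, rec$class)
  tab <- sort(table(lab), decreasing = TRUE)
  names(tab)[1]
}
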