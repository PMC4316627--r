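#' Per-class monophyly report
#'
#' For each class (within the scoped domains) with at least two leaves in
#' the tree, tests whether its leaves form a clean bipartition against
#' everything else (unrooted convention, full tree including any outgroup
#' leaves). Singleton classes are vacuously monophyletic.
#'
#' @param tree Gene tree ([ape::phylo]).
#' @param taxonomy A `taxonomy` data frame.
#' @param scope Domain label(s) whose classes are tested; `NULL` = all.
#' @return Named logical vector, one entry per class.
#' @export
class_monophyly_report <- function(tree, taxonomy, scope = NULL) {
  rec <- taxonomy_lookup(taxonomy, tree$tip.label)
  if (!is.null(scope)) rec <- rec[rec$domain %in% scope, , drop = FALSE]
  classes <- unique(rec$class)
  out <- setNames(logical(length(classes)), classes)
  for (cl in classes) {
    leaves <- rec$leaf[rec$class == cl]
    out[cl] <- length(leaves) <= 1L || is_monophyletic(tree, leaves)
  }
  out
}

#' Detect inter-domain HGT in a gene tree
#'
#' Flags the family when the domain-level bipartition (all ingroup leaves
#' vs. all outgroup leaves) is absent from the tree. Candidate culprits are
#' found greedily: repeatedly remove the single leaf whose removal most
#' reduces the distance to a clean domain split (capped at 5 removals).
#'
#' @param tree Gene tree.
#' @param taxonomy A `taxonomy` data frame.
#' @param outgroup_domain Domain label marking outgroup leaves.
#' @return List with `applicable`, `flag` and `candidates` (character).
#' @export
detect_interdomain_hgt <- function(tree, taxonomy,
                                   outgroup_domain = "outgroup") {
  rec <- taxonomy_lookup(taxonomy, tree$tip.label)
  og <- rec$leaf[rec$domain == outgroup_domain]
  ig <- rec$leaf[rec$domain != outgroup_domain]
  if (length(og) == 0L || length(ig) == 0L)
    return(list(applicable = FALSE, flag = FALSE, candidates = character()))
  if (split_violations(tree, og) == 0L)
    return(list(applicable = TRUE, flag = FALSE, candidates = character()))
  candidates <- character()
  cur <- tree
  for (i in 1:5) {
    leaves <- cur$tip.label
    og_cur <- intersect(og, leaves)
    if (length(og_cur) == 0L || length(setdiff(leaves, og_cur)) == 0L) break
    v <- vapply(sort(leaves), function(lf) {
      pruned <- ape::drop.tip(cur, lf)
      if (is.null(pruned) || length(pruned$tip.label) < 4L) return(0)
      split_violations(pruned, intersect(og, pruned$tip.label))
    }, numeric(1))
    best <- names(v)[which.min(v)]
    candidates <- c(candidates, best)
    cur <- ape::drop.tip(cur, best)
    if (v[best] == 0) break
  }
  list(applicable = TRUE, flag = TRUE, candidates = candidates)
}

# Distance of a leaf set from being a clean split: the minimum, over all
# edges (including pendant ones), of the symmetric-difference size between
# the edge's bipartition side and the set.
split_violations <- function(tree, leaves) {
  n <- length(tree$tip.label)
  k <- length(leaves)
  if (k == 0L || k == n) return(0L)
  all_tips <- tree$tip.label
  best <- Inf
  for (e in seq_len(nrow(tree$edge))) {
    side <- tips_below(tree, tree$edge[e, 2])
    d1 <- length(setdiff(side, leaves)) + length(setdiff(leaves, side))
    other <- setdiff(all_tips, side)
    d2 <- length(setdiff(other, leaves)) + length(setdiff(leaves, other))
    best <- min(best, d1, d2)
  }
  as.integer(best)
}

#' Detect recent HGT inside the outgroup
#'
#' Prunes the gene tree to outgroup leaves and flags any outgroup phylum
#' with >= 2 members that is not monophyletic there. Deep inter-phylum
#' disorder is deliberately not tested — only "recent" (within-phylum
#' violating) events are.
#'
#' @inheritParams detect_interdomain_hgt
#' @return List with `flag` and `violated_phyla`.
#' @export
detect_outgroup_internal_hgt <- function(tree, taxonomy,
                                         outgroup_domain = "outgroup") {
  rec <- taxonomy_lookup(taxonomy, tree$tip.label)
  og <- rec$leaf[rec$domain == outgroup_domain]
  if (length(og) < 4L)
    return(list(flag = FALSE, violated_phyla = character()))
  sub <- ape::keep.tip(tree, og)
  rec_og <- rec[rec$domain == outgroup_domain, , drop = FALSE]
  violated <- character()
  for (ph in unique(rec_og$phylum)) {
    leaves <- rec_og$leaf[rec_og$phylum == ph]
    if (length(leaves) >= 2L && !is_monophyletic(sub, leaves))
      violated <- c(violated, ph)
  }
  list(flag = length(violated) > 0L, violated_phyla = violated)
}

#' Detect paralogy in a gene family
#'
#' Flags the family if any species contributes two or more sequences
#' (copy-number evidence). A class split without any multi-copy species is
#' charged to HGT by [class_monophyly_report()], not to paralogy.
#'
#' @param family A `gene_family` (members = tree leaves).
#' @param tree Gene tree.
#' @param taxonomy A `taxonomy` data frame.
#' @return List with `flag` and `offending_species`.
#' @export
detect_paralogy <- function(family, tree, taxonomy) {
  rec <- taxonomy_lookup(taxonomy, names(family$seqs))
  tab <- table(rec$species)
  offenders <- names(tab)[tab >= 2L]
  list(flag = length(offenders) > 0L, offending_species = offenders)
}

#' Screen a gene family against the taxonomic-consistency criteria
#'
#' Runs all checks — class monophyly (ingroup classes, full tree),
#' inter-domain HGT, within-outgroup HGT, paralogy, partial-length members,
#' and coverage — and renders a retain/reject verdict: retain iff every
#' enforced check passes and the coverage thresholds hold.
#'
#' @param family A `gene_family`.
#' @param tree Gene tree whose leaves are the family members (e.g. from
#'   [gene_tree()]).
#' @param taxonomy A `taxonomy` data frame.
#' @param criteria A [filter_criteria()].
#' @param enforce Character subset of
#'   `c("class_monophyly", "interdomain_hgt", "outgroup_hgt", "paralogy",
#'   "partial", "coverage")`.
#' @param require_outgroup Enforce outgroup phylum coverage inside the
#'   coverage check?
#' @param outgroup_domain Domain label marking outgroup leaves.
#' @return An object of class `screen_report`.
#' @export
screen_family <- function(family, tree, taxonomy,
                          criteria = filter_criteria(),
                          enforce = c("class_monophyly", "interdomain_hgt",
                                      "outgroup_hgt", "paralogy", "partial",
                                      "coverage"),
                          require_outgroup = TRUE,
                          outgroup_domain = "outgroup") {
  stopifnot(inherits(family, "gene_family"), inherits(tree, "phylo"))
  rec <- taxonomy_lookup(taxonomy, names(family$seqs))
  ingroup_domains <- setdiff(unique(rec$domain), outgroup_domain)
  mono <- class_monophyly_report(tree, taxonomy, scope = ingroup_domains)
  inter <- detect_interdomain_hgt(tree, taxonomy, outgroup_domain)
  og_hgt <- detect_outgroup_internal_hgt(tree, taxonomy, outgroup_domain)
  para <- detect_paralogy(family, tree, taxonomy)
  lens <- nongap_lengths(family$seqs)
  partials <- names(lens)[lens < criteria$partial_fraction * median(lens)]
  cov <- apply_family_filters(family, taxonomy, criteria,
                              require_outgroup = require_outgroup,
                              outgroup_domain = outgroup_domain)
  reasons <- character()
  if ("class_monophyly" %in% enforce && !all(mono))
    reasons <- c(reasons, sprintf("class_monophyly:%s",
                                  paste(names(mono)[!mono], collapse = "+")))
  if ("interdomain_hgt" %in% enforce && inter$flag)
    reasons <- c(reasons, "interdomain_hgt")
  if ("outgroup_hgt" %in% enforce && og_hgt$flag)
    reasons <- c(reasons, "outgroup_hgt")
  if ("paralogy" %in% enforce && para$flag)
    reasons <- c(reasons, "paralogy")
  if ("partial" %in% enforce && length(partials) > 0L)
    reasons <- c(reasons, "partial")
  if ("coverage" %in% enforce && !cov$kept)
    reasons <- c(reasons, cov$reasons)
  structure(list(family_id = family$id,
                 class_monophyly = mono,
                 interdomain_hgt = inter,
                 outgroup_internal_hgt = og_hgt,
                 paralogy = para,
                 partial_members = partials,
                 coverage = cov,
                 verdict = if (length(reasons) == 0L) "retain" else "reject",
                 reasons = reasons),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report '%s': %s%s>\n", x$family_id, x$verdict,
              if (length(x$reasons) > 0L)
                paste0(" [", paste(x$reasons, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Retained family ids from a list of screen reports
#'
#' @param reports List of `screen_report` objects.
#' @return Character vector of family ids with verdict `retain`, in input
#'   order.
#' @export
select_markers <- function(reports) {
  keep <- vapply(reports, function(r) r$verdict == "retain", logical(1))
  vapply(reports[keep], function(r) r$family_id, character(1))
}

#' Build a gene tree for screening
#'
#' Neighbor joining on corrected distances — the package's default
#' screening engine; user-supplied Newick gene trees can be passed to
#' [screen_family()] instead.
#'
#' @param family An aligned `gene_family`.
#' @param correction,alpha Passed to [distance_matrix()].
#' @return An unrooted [ape::phylo].
#' @export
gene_tree <- function(family, correction = "kimura", alpha = NULL) {
  stopifnot(inherits(family, "gene_family"))
  if (!family$aligned) stop_fmt("family '%s' is not aligned", family$id)
  neighbor_joining(distance_matrix(family$seqs, correction = correction,
                                   alpha = alpha))
}
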