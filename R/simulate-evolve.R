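#' Simulate an aligned gene family along a tree
#'
#' The root sequence is drawn from the model's equilibrium frequencies; each
#' site is independently assigned one of the model's discrete-gamma rate
#' categories; descendant states are drawn from transition probabilities
#' `exp(Q * branch length * category rate)`. There is no indel process:
#' the simulated sites are homologous columns, so the output is trivially
#' aligned ("partial" sequences are produced downstream by [degrade()]
#' truncation masks, which is what the length filter reacts to).
#'
#' @param tree An [ape::phylo] with branch lengths in substitutions/site.
#' @param model A [substitution_model()].
#' @param n_sites Number of sites (> 0).
#' @param seed Integer seed; output is deterministic given
#'   `(tree, model, n_sites, seed)`.
#' @param id Family identifier.
#' @return A `gene_family` object: list with `id`, `seqs` (named character,
#'   one per tip), `is_partial` (named logical), `aligned = TRUE`, `truth`
#'   (event log, empty), plus the site categories and model needed to
#'   re-evolve sequences for planted events.
#' @export
evolve_alignment <- function(tree, model, n_sites, seed = 1L, id = "fam1") {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"))
  n_sites <- as.integer(n_sites)
  if (n_sites <= 0L) stop_fmt("n_sites must be > 0")
  s <- length(model$states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  edges <- reorder_preorder(tree)
  with_seed(seed, {
    cats <- sample.int(model$n_categories, n_sites, replace = TRUE)
    node_states <- vector("list", nnode)
    node_states[[root]] <- sample.int(s, n_sites, replace = TRUE,
                                      prob = model$freqs)
    for (e in edges) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      node_states[[child]] <- evolve_states(node_states[[parent]],
                                            tree$edge.length[e], model, cats)
    }
    tipmat <- do.call(rbind, node_states[seq_len(ntip)])
    rownames(tipmat) <- tree$tip.label
    new_gene_family(id = id,
                    seqs = int_matrix_to_seqs(tipmat, model$states),
                    site_categories = cats, model = model)
  })
}

new_gene_family <- function(id, seqs, site_categories = NULL, model = NULL,
                            is_partial = NULL, truth = list(),
                            aligned = TRUE) {
  if (is.null(is_partial))
    is_partial <- setNames(rep(FALSE, length(seqs)), names(seqs))
  structure(list(id = id, seqs = seqs, is_partial = is_partial,
                 aligned = aligned, truth = truth,
                 site_categories = site_categories, model = model),
            class = "gene_family")
}

#' @export
print.gene_family <- function(x, ...) {
  cat(sprintf("<gene_family '%s': %d sequences, %s, %d planted event(s)>\n",
              x$id, length(x$seqs),
              if (x$aligned) sprintf("%d aligned sites", nchar(x$seqs[[1]]))
              else "unaligned", length(x$truth)))
  invisible(x)
}

# Edge indices in parent-before-child (depth-first from the root) order.
reorder_preorder <- function(tree) {
  stats::setNames(ape::reorder.phylo(tree, "cladewise", index.only = TRUE), NULL)
}

# Evolve integer state vector `x` (0 = gap, preserved) along branch length t
# under `model`, with per-site gamma categories `cats`. Uses the caller's
# RNG stream.
evolve_states <- function(x, t, model, cats) {
  s <- length(model$states)
  out <- x
  for (c in seq_len(model$n_categories)) {
    sel_c <- which(cats == c & x > 0L)
    if (length(sel_c) == 0L) next
    P <- transition_matrix(model, t * model$rates[c])
    for (a in unique(x[sel_c])) {
      idx <- sel_c[x[sel_c] == a]
      out[idx] <- sample.int(s, length(idx), replace = TRUE, prob = P[a, ])
    }
  }
  out
}

# Integer-matrix view of a family's sequences under its own model alphabet.
family_int_matrix <- function(family) {
  aln_int_matrix(family$seqs, states = family_states(family))
}

family_states <- function(family) {
  if (!is.null(family$model)) family$model$states else AA_STATES
}

#' Plant a horizontal gene transfer event
#'
#' Replaces the recipient's sequence with the donor's sequence re-evolved
#' along a branch of the given divergence (sequence replacement, not
#' topology surgery), and appends the event to the family's truth log. With
#' `divergence = 0` the recipient becomes an exact copy of the donor.
#'
#' @param family A `gene_family` produced by [evolve_alignment()].
#' @param tree The species tree (unused by the replacement itself; kept for
#'   interface symmetry and validation).
#' @param donor_leaf,recipient_leaf Leaf identifiers present in the family.
#' @param divergence Branch length (substitutions/site) for re-evolution.
#' @param seed Integer seed.
#' @return The modified `gene_family`.
#' @export
inject_hgt <- function(family, tree, donor_leaf, recipient_leaf,
                       divergence = 0.05, seed = 1L) {
  stopifnot(inherits(family, "gene_family"), divergence >= 0)
  for (lf in c(donor_leaf, recipient_leaf)) {
    if (!lf %in% names(family$seqs))
      stop_fmt("leaf '%s' not in family '%s'", lf, family$id)
  }
  im <- family_int_matrix(family)
  new_states <- with_seed(seed, evolve_states(im[donor_leaf, ], divergence,
                                              family$model,
                                              family$site_categories))
  family$seqs[[recipient_leaf]] <-
    int_matrix_to_seqs(matrix(new_states, 1L), family_states(family))
  family$truth <- c(family$truth,
                    list(list(type = "hgt", donor = donor_leaf,
                              recipient = recipient_leaf,
                              divergence = divergence)))
  family
}

#' Plant a lineage-specific duplication (paralog)
#'
#' Adds a second sequence for a species, re-evolved from the original copy
#' along `2 * divergence` (the two copies sit at total distance
#' `2 * divergence` from each other). The new leaf id is the source leaf id
#' with a `#<copy>` suffix, which taxonomy lookups resolve to the same
#' species.
#'
#' @param family A `gene_family`.
#' @param species Species (leaf) identifier with at least one sequence in
#'   the family.
#' @param divergence Per-copy divergence (substitutions/site).
#' @param seed Integer seed.
#' @return The modified `gene_family`.
#' @export
inject_paralogy <- function(family, species, divergence = 0.1, seed = 1L) {
  stopifnot(inherits(family, "gene_family"), divergence >= 0)
  base <- sub("#[0-9]+$", "", names(family$seqs))
  src <- which(base == species)[1]
  if (is.na(src)) stop_fmt("species '%s' has no sequence in family '%s'",
                           species, family$id)
  copy_n <- sum(base == species) + 1L
  new_id <- sprintf("%s#%d", species, copy_n)
  im <- family_int_matrix(family)
  new_states <- with_seed(seed, evolve_states(im[src, ], 2 * divergence,
                                              family$model,
                                              family$site_categories))
  family$seqs[new_id] <- int_matrix_to_seqs(matrix(new_states, 1L),
                                            family_states(family))
  family$is_partial[new_id] <- FALSE
  family$truth <- c(family$truth,
                    list(list(type = "duplication", species = species,
                              copy = new_id, divergence = divergence)))
  family
}

#' Degrade family members (loss, truncation, masking)
#'
#' Emulates genome-reduction data pathologies: `loss` removes members;
#' `truncate` keeps a contiguous window of `fraction` of the sites and
#' replaces the rest with gaps (setting the member's partial flag); `mask`
#' replaces a random `fraction` of sites with gaps.
#'
#' @param family A `gene_family`.
#' @param selector Character vector of member leaf ids (>= 1 member).
#' @param mode One of `"loss"`, `"truncate"`, `"mask"`.
#' @param fraction For `truncate`: kept fraction; for `mask`: gapped
#'   fraction. Must lie in (0, 1).
#' @param seed Integer seed (window position / masked sites).
#' @return The modified `gene_family`.
#' @export
degrade <- function(family, selector, mode = c("loss", "truncate", "mask"),
                    fraction = 0.4, seed = 1L) {
  stopifnot(inherits(family, "gene_family"))
  mode <- match.arg(mode)
  missing_sel <- setdiff(selector, names(family$seqs))
  if (length(missing_sel) > 0L)
    stop_fmt("selector member(s) not in family: %s",
             paste(missing_sel, collapse = ", "))
  if (mode != "loss" && (fraction <= 0 || fraction >= 1))
    stop_fmt("fraction must lie strictly between 0 and 1")
  if (mode == "loss") {
    family$seqs <- family$seqs[setdiff(names(family$seqs), selector)]
    family$is_partial <- family$is_partial[names(family$seqs)]
    family$truth <- c(family$truth,
                      list(list(type = "loss", members = selector)))
    return(family)
  }
  n <- nchar(family$seqs[[1]])
  for (m in selector) {
    ch <- strsplit(family$seqs[[m]], "", fixed = TRUE)[[1]]
    if (mode == "truncate") {
      keep_n <- max(1L, round(fraction * n))
      start <- with_seed(derive_seed(seed, match(m, selector)),
                         sample.int(n - keep_n + 1L, 1L))
      gap_idx <- setdiff(seq_len(n), seq(start, start + keep_n - 1L))
      family$is_partial[m] <- TRUE
      family$truth <- c(family$truth,
                        list(list(type = "truncation", member = m,
                                  kept_fraction = fraction)))
    } else {
      gap_idx <- with_seed(derive_seed(seed, match(m, selector)),
                           which(runif(n) < fraction))
      family$truth <- c(family$truth,
                        list(list(type = "mask", member = m,
                                  fraction = fraction)))
    }
    ch[gap_idx] <- "-"
    family$seqs[[m]] <- paste(ch, collapse = "")
  }
  family
}
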