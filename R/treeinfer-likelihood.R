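#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' Per-site likelihoods are averaged over the model's discrete-gamma
#' categories; gaps (and `X`) are missing data (partial likelihood 1 over
#' all states). Identical site patterns are compressed and weighted. Under a
#' reversible model the value is invariant to re-rooting.
#'
#' @param tree An [ape::phylo] whose tips all have rows in `seqs`.
#' @param seqs Named character vector of aligned sequences.
#' @param model A [substitution_model()].
#' @return The log-likelihood (numeric scalar).
#' @export
tree_log_likelihood <- function(tree, seqs, model) {
  lk <- likelihood_workspace(tree, seqs, model)
  lnl_from_workspace(lk)
}

# --- internal likelihood machinery ------------------------------------------

# Pattern-compressed representation plus per-category partials ("D", the
# likelihood of the data below each node).
likelihood_workspace <- function(tree, seqs, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"))
  check_aligned(seqs)
  missing_rows <- setdiff(tree$tip.label, names(seqs))
  if (length(missing_rows) > 0L)
    stop_fmt("no alignment row for leaf '%s'", missing_rows[1])
  im <- aln_int_matrix(seqs[tree$tip.label], states = model$states)
  keys <- apply(im, 2L, paste, collapse = ",")
  first <- !duplicated(keys)
  pat <- im[, first, drop = FALSE]
  w <- as.vector(table(factor(keys, levels = keys[first])))
  ntip <- length(tree$tip.label)
  env <- new.env(parent = emptyenv())
  env$tree <- tree
  env$model <- model
  env$pat <- pat
  env$w <- w
  env$ntip <- ntip
  env$root <- ntip + 1L
  env$nnode <- ntip + tree$Nnode
  env$children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  env$postorder <- rev(reorder_preorder(tree))
  env$D <- lapply(seq_len(model$n_categories),
                  function(c) vector("list", env$nnode))
  for (c in seq_len(model$n_categories)) refresh_partials(env, c)
  env
}

# Tip partial-likelihood matrix (s x npat): indicator columns, all-ones for
# missing states.
tip_partial <- function(env, tip) {
  s <- length(env$model$states)
  x <- env$pat[tip, ]
  L <- matrix(0, s, length(x))
  known <- x > 0L
  L[cbind(x[known], which(known))] <- 1
  L[, !known] <- 1
  L
}

edge_P <- function(env, e, cat, len = NULL) {
  t <- if (is.null(len)) env$tree$edge.length[e] else len
  transition_matrix(env$model, t * env$model$rates[cat])
}

# Recompute D for all nodes (postorder) in one category.
refresh_partials <- function(env, cat) {
  for (e in env$postorder) {
    child <- env$tree$edge[e, 2]
    if (is.null(env$D[[cat]][[child]]) || child <= env$ntip)
      env$D[[cat]][[child]] <- node_partial(env, child, cat)
  }
  env$D[[cat]][[env$root]] <- node_partial(env, env$root, cat)
  invisible(env)
}

node_partial <- function(env, node, cat) {
  if (node <= env$ntip) return(tip_partial(env, node))
  es <- env$children[[as.character(node)]]
  L <- NULL
  for (e in es) {
    child <- env$tree$edge[e, 2]
    Dc <- env$D[[cat]][[child]]
    if (is.null(Dc)) Dc <- env$D[[cat]][[child]] <- node_partial(env, child, cat)
    term <- edge_P(env, e, cat) %*% Dc
    L <- if (is.null(L)) term else L * term
  }
  L
}

# Force full recomputation of D in every category.
recompute_all_partials <- function(env) {
  for (c in seq_len(env$model$n_categories)) {
    env$D[[c]] <- vector("list", env$nnode)
    refresh_partials(env, c)
  }
  invisible(env)
}

# log-likelihood from root partials.
lnl_from_workspace <- function(env) {
  k <- env$model$n_categories
  site <- 0
  for (c in seq_len(k))
    site <- site + colSums(env$model$freqs * env$D[[c]][[env$root]])
  sum(env$w * log(site / k))
}

# "Above" partial U at `node` in one category: the likelihood message from
# the rest of the tree, computed by walking down from the root.
above_partial <- function(env, node, cat) {
  path <- integer()
  v <- node
  while (v != env$root) {
    e <- which(env$tree$edge[, 2] == v)
    path <- c(e, path)
    v <- env$tree$edge[e, 1]
  }
  U <- matrix(env$model$freqs, length(env$model$states), ncol(env$pat))
  for (e in path) {
    p <- env$tree$edge[e, 1]
    c_node <- env$tree$edge[e, 2]
    W <- U
    for (e2 in env$children[[as.character(p)]]) {
      if (e2 == e) next
      W <- W * (edge_P(env, e2, cat) %*% env$D[[cat]][[env$tree$edge[e2, 2]]])
    }
    U <- crossprod(edge_P(env, e, cat), W)
  }
  U
}

# After changing the length of the edge above `child`, refresh D on the path
# child's parent -> root.
update_path_partials <- function(env, child) {
  v <- child
  while (v != env$root) {
    e <- which(env$tree$edge[, 2] == v)
    v <- env$tree$edge[e, 1]
    for (c in seq_len(env$model$n_categories))
      env$D[[c]][[v]] <- node_partial(env, v, c)
  }
  invisible(env)
}

#' Optimize branch lengths by coordinate ascent
#'
#' One-dimensional bounded maximization (Brent) edge by edge, with partial
#' likelihoods updated after every accepted move, so the log-likelihood is
#' non-decreasing; sweeps repeat until the gain falls below `tol`.
#'
#' @inheritParams tree_log_likelihood
#' @param tol Minimum log-likelihood gain per sweep to continue.
#' @param max_sweeps Sweep cap; a warning is issued if reached without
#'   convergence.
#' @param max_length Upper bound for any single branch length.
#' @return The tree with optimized `edge.length`; attributes `lnL` (final
#'   log-likelihood) and `lnL_sweeps` (per-sweep trace, non-decreasing).
#' @export
optimize_branch_lengths <- function(tree, seqs, model, tol = 1e-3,
                                    max_sweeps = 10L, max_length = 10) {
  env <- likelihood_workspace(tree, seqs, model)
  k <- model$n_categories
  trace <- lnl_from_workspace(env)
  edges_pre <- reorder_preorder(tree)
  for (sweep in seq_len(max_sweeps)) {
    for (e in edges_pre) {
      p <- env$tree$edge[e, 1]
      child <- env$tree$edge[e, 2]
      W <- vector("list", k)
      for (c in seq_len(k)) {
        Wc <- above_partial(env, p, c)
        for (e2 in env$children[[as.character(p)]]) {
          if (e2 == e) next
          Wc <- Wc * (edge_P(env, e2, c) %*%
                        env$D[[c]][[env$tree$edge[e2, 2]]])
        }
        W[[c]] <- Wc
      }
      obj <- function(t) {
        site <- 0
        for (c in seq_len(k))
          site <- site + colSums(W[[c]] * (edge_P(env, e, c, len = t) %*%
                                             env$D[[c]][[child]]))
        sum(env$w * log(site / k))
      }
      cur <- env$tree$edge.length[e]
      opt <- optimize(obj, interval = c(0, max(max_length, 2 * cur)),
                      maximum = TRUE, tol = 1e-4)
      if (opt$objective > obj(cur)) {
        env$tree$edge.length[e] <- opt$maximum
        update_path_partials(env, child)
      }
    }
    lnl <- lnl_from_workspace(env)
    trace <- c(trace, lnl)
    if (lnl - trace[length(trace) - 1L] < tol) break
  }
  if (sweep == max_sweeps &&
      (trace[length(trace)] - trace[length(trace) - 1L]) >= tol)
    warning("branch-length optimization did not converge; returning last iterate")
  out <- env$tree
  attr(out, "lnL") <- trace[length(trace)]
  attr(out, "lnL_sweeps") <- trace
  out
}
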