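# Independent oracles used across the suite. These deliberately avoid the
# package's own split/alignment machinery.

# Monophyly by exhaustive edge enumeration using phangorn's descendant sets.
brute_monophyletic <- function(tree, leaves) {
  n <- length(tree$tip.label)
  k <- length(unique(leaves))
  if (k <= 1L || k >= n - 1L) return(TRUE)
  target <- sort(unique(leaves))
  for (e in seq_len(nrow(tree$edge))) {
    node <- tree$edge[e, 2]
    side <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    if (identical(sort(side), target) ||
        identical(sort(setdiff(tree$tip.label, side)), target))
      return(TRUE)
  }
  FALSE
}

# Global affine-gap alignment score of two full (sub)strings via a 3-state
# Gotoh recursion with memoisation; local score = max over all substring
# pairs and 0. Only usable for very short sequences.
brute_local_score <- function(a, b, submat, gap_open, gap_extend) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  global_affine <- function(x, y) {
    n <- length(x); m <- length(y)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
    M[1, 1] <- 0
    for (j in seq_len(m)) Y[1, j + 1] <- gap_open + gap_extend * j
    for (i in seq_len(n)) X[i + 1, 1] <- gap_open + gap_extend * i
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        s <- submat[x[i], y[j]]
        M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
        X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                               X[i, j + 1] + gap_extend)
        Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                               Y[i + 1, j] + gap_extend)
      }
    }
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  }
  best <- 0
  for (i1 in seq_along(av)) for (i2 in i1:length(av)) {
    for (j1 in seq_along(bv)) for (j2 in j1:length(bv)) {
      best <- max(best, global_affine(av[i1:i2], bv[j1:j2]))
    }
  }
  best
}

# Brute-force tree likelihood by summation over internal-node states.
brute_log_likelihood <- function(tree, seqs, model) {
  states <- model$states
  s <- length(states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  internal <- (ntip + 1L):nnode
  n_sites <- nchar(seqs[[1]])
  tipchars <- lapply(seqs[tree$tip.label],
                     function(x) strsplit(x, "", fixed = TRUE)[[1]])
  P <- lapply(seq_len(model$n_categories), function(c) {
    lapply(seq_len(nrow(tree$edge)), function(e)
      phyloroot:::transition_matrix(model,
                                    tree$edge.length[e] * model$rates[c]))
  })
  grids <- expand.grid(rep(list(seq_len(s)), length(internal)))
  total <- 0
  for (site in seq_len(n_sites)) {
    site_lik <- 0
    for (c in seq_len(model$n_categories)) {
      lik_c <- 0
      for (g in seq_len(nrow(grids))) {
        assign_int <- as.integer(grids[g, ])
        state_of <- function(node) {
          if (node <= ntip) match(tipchars[[node]][site], states)
          else assign_int[node - ntip]
        }
        pr <- model$freqs[state_of(ntip + 1L)]
        for (e in seq_len(nrow(tree$edge))) {
          from <- state_of(tree$edge[e, 1])
          to <- state_of(tree$edge[e, 2])
          if (is.na(to)) next  # gap: sum over states handled by skipping
          pr <- pr * P[[c]][[e]][from, to]
        }
        lik_c <- lik_c + pr
      }
      site_lik <- site_lik + lik_c
    }
    total <- total + log(site_lik / model$n_categories)
  }
  total
}

# Small fixed worlds reused by several tests.
tiny_world <- function(stem = 0.5, fast = list()) {
  sample_species_tree(world_config(n_classes_per_kingdom = 2L,
                                   n_species_per_class = 2L,
                                   n_outgroup_phyla = 3L,
                                   species_per_outgroup_phylum = 2L,
                                   stem_length = stem, fast_clades = fast))
}

model4 <- function(alpha = Inf, k = 1L) {
  substitution_model(states = c("A", "C", "G", "T"), alpha = alpha,
                     n_categories = k)
}
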