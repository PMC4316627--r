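#' Simulate a clean multi-marker supermatrix
#'
#' Evolves `n_markers` independent gene families on the world's species
#' tree (no planted events) and concatenates them. Useful as the baseline
#' dataset for rooting and placement experiments.
#'
#' @param config A [world_config()].
#' @param n_markers Number of markers.
#' @param n_sites_range Per-marker length range.
#' @param model A [substitution_model()].
#' @param seed Integer seed.
#' @return List with `supermatrix`, `tree`, `taxonomy`, `families`.
#' @export
simulate_supermatrix <- function(config, n_markers = 20L,
                                 n_sites_range = c(300L, 600L),
                                 model = substitution_model(), seed = 1L) {
  world <- sample_species_tree(config)
  families <- vector("list", n_markers)
  for (i in seq_len(n_markers)) {
    n_sites <- with_seed(derive_seed(seed, i),
                         sample(seq(n_sites_range[1], n_sites_range[2]), 1L))
    families[[i]] <- evolve_alignment(world$tree, model, n_sites,
                                      seed = derive_seed(seed, 1000L + i),
                                      id = sprintf("M%03d", i))
  }
  sm <- concatenate(families, taxa = world$taxonomy$leaf,
                    taxonomy = world$taxonomy)
  list(supermatrix = sm, tree = world$tree, taxonomy = world$taxonomy,
       families = families)
}

#' Root-recovery experiment over seeds
#'
#' For each seed, simulates a clean multi-marker dataset on a two-kingdom
#' world, infers the tree, and records whether the ingroup|outgroup split is
#' present and its bootstrap support.
#'
#' @param n_seeds Number of replicate datasets.
#' @param config A [world_config()].
#' @param n_markers,n_sites_range,model Dataset settings (see
#'   [simulate_supermatrix()]).
#' @param B Bootstrap replicates.
#' @param seed Root seed.
#' @param correction,alpha Distance engine settings.
#' @return Data frame: `seed`, `in_original`, `support`, `recovered`
#'   (split present with support >= 90).
#' @export
root_recovery_experiment <- function(n_seeds = 20L,
                                     config = world_config(
                                       n_classes_per_kingdom = 3L,
                                       n_species_per_class = 3L,
                                       n_outgroup_phyla = 12L,
                                       stem_length = 0.5),
                                     n_markers = 20L,
                                     n_sites_range = c(300L, 600L),
                                     model = substitution_model(),
                                     B = 100L, seed = 1L,
                                     correction = "kimura", alpha = NULL) {
  out <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    rep_seed <- derive_seed(seed, 7000L + i)
    sim <- simulate_supermatrix(config, n_markers, n_sites_range, model,
                                seed = rep_seed)
    og <- sim$taxonomy$leaf[sim$taxonomy$domain == "outgroup"]
    sup <- split_bootstrap_support(sim$supermatrix$seqs, og, B = B,
                                   seed = rep_seed,
                                   correction = correction, alpha = alpha)
    out[[i]] <- data.frame(seed = rep_seed,
                           in_original = attr(sup, "in_original"),
                           support = as.numeric(sup),
                           recovered = attr(sup, "in_original") &&
                             as.numeric(sup) >= 90)
  }
  do.call(rbind, out)
}

#' Stem-length recovery experiment
#'
#' Simulates one alignment on a small two-kingdom world with a known
#' ingroup-outgroup stem length and re-estimates the stem. The `"nj"` engine
#' reads the stem edge off the neighbor-joining tree built from
#' gamma-corrected maximum-likelihood distances; the `"ml"` engine
#' additionally re-optimizes all branch lengths by maximum likelihood on
#' that topology.
#'
#' @param stem_length True stem length (substitutions/site).
#' @param n_sites Alignment length.
#' @param config A [world_config()] (stem length is overridden).
#' @param model A [substitution_model()].
#' @param seed Integer seed.
#' @param engine `"nj"` or `"ml"`.
#' @return List with `estimate`, `true` and `tree`.
#' @export
stem_recovery_experiment <- function(stem_length = 0.8, n_sites = 20000L,
                                     config = world_config(
                                       n_classes_per_kingdom = 2L,
                                       n_species_per_class = 2L,
                                       n_outgroup_phyla = 4L),
                                     model = substitution_model(),
                                     seed = 1L, engine = c("nj", "ml")) {
  engine <- match.arg(engine)
  config$stem_length <- stem_length
  world <- sample_species_tree(config)
  fam <- evolve_alignment(world$tree, model, n_sites, seed = seed)
  tree <- neighbor_joining(distance_matrix(fam$seqs,
                                           correction = "ml-poisson",
                                           alpha = model$alpha,
                                           n_categories = model$n_categories))
  if (engine == "ml")
    tree <- optimize_branch_lengths(tree, fam$seqs, model)
  og <- world$taxonomy$leaf[world$taxonomy$domain == "outgroup"]
  ig <- setdiff(world$taxonomy$leaf, og)
  list(estimate = interdomain_stem_length(tree, ig, og),
       true = stem_length, tree = tree)
}

#' Stem-ratio experiment (two marker sets)
#'
#' Simulates two datasets that differ only in their true stem lengths and
#' returns the ratio of the re-estimated stems — the comparison used to
#' contrast marker sets whose inter-domain branch differs in length.
#'
#' @param stems Numeric vector of two true stem lengths.
#' @param n_sites Sites per dataset.
#' @param seed Integer seed.
#' @inheritParams stem_recovery_experiment
#' @return List with `ratio`, `true_ratio`, `estimates`.
#' @export
stem_ratio_experiment <- function(stems = c(1.3, 0.5), n_sites = 20000L,
                                  config = world_config(
                                    n_classes_per_kingdom = 2L,
                                    n_species_per_class = 2L,
                                    n_outgroup_phyla = 4L),
                                  model = substitution_model(), seed = 1L,
                                  engine = "nj") {
  e1 <- stem_recovery_experiment(stems[1], n_sites, config, model,
                                 seed = derive_seed(seed, 1L), engine = engine)
  e2 <- stem_recovery_experiment(stems[2], n_sites, config, model,
                                 seed = derive_seed(seed, 2L), engine = engine)
  list(ratio = e1$estimate / e2$estimate, true_ratio = stems[1] / stems[2],
       estimates = c(e1$estimate, e2$estimate))
}

#' Long-branch-attraction contrast experiment
#'
#' Replicated placement experiment with a rate-accelerated focal clade and a
#' remote outgroup: in each replicate the focal clade (the first class of
#' kingdom A, all its edges and stem scaled by `rate_multiplier`) is placed
#' with and without the outgroup. The LBA signature is: sister = outgroup
#' (basal attachment) with the outgroup present, sister = the true sister
#' class without it.
#'
#' The default engine is neighbor joining on *uncorrected* p-distances: the
#' artifact requires an engine that underestimates deep divergences, which
#' is the classical mechanism behind long-branch attraction (simple,
#' under-fitting models pull fast-evolving lineages toward a distant
#' outgroup). With distance corrections adequate for the simulated rate
#' heterogeneity the same datasets place the focal clade with its true
#' sister under both conditions — the "better model removes the artifact"
#' direction.
#'
#' @param n_replicates Number of seeded replicates.
#' @param stem_length Ingroup-outgroup stem (substitutions/site).
#' @param rate_multiplier Rate multiplier of the focal clade.
#' @param n_markers,n_sites_range Dataset size per replicate.
#' @param model A [substitution_model()].
#' @param seed Root seed.
#' @param correction,alpha Distance engine settings.
#' @return Data frame with one row per replicate: `basal_with_outgroup`,
#'   `true_sister_without_outgroup`, `contrast` (both behaviors observed);
#'   attribute `rates` holds the three observed proportions.
#' @export
lba_contrast_experiment <- function(n_replicates = 20L, stem_length = 1.5,
                                    rate_multiplier = 8,
                                    n_markers = 10L,
                                    n_sites_range = c(300L, 600L),
                                    model = substitution_model(), seed = 1L,
                                    correction = "p", alpha = NULL) {
  config <- world_config(n_classes_per_kingdom = 3L, n_species_per_class = 3L,
                         n_outgroup_phyla = 6L, stem_length = stem_length,
                         fast_clades = list(list(clade = "kA_c1",
                                                 rate = rate_multiplier)))
  true_sister <- "kA_c2"
  out <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, 9000L + i)
    sim <- simulate_supermatrix(config, n_markers, n_sites_range, model,
                                seed = rep_seed)
    focal <- sim$taxonomy$leaf[sim$taxonomy$class == "kA_c1"]
    pl <- placement_experiment(sim$supermatrix, sim$taxonomy, focal,
                               B = 0L, seed = rep_seed,
                               correction = correction, alpha = alpha)
    with_row <- pl[pl$condition == "with_outgroup", ]
    wo_row <- pl[pl$condition == "without_outgroup", ]
    basal <- isTRUE(with_row$monophyletic) &&
      identical(with_row$sister_label, "outgroup")
    true_sis <- isTRUE(wo_row$monophyletic) &&
      identical(wo_row$sister_label, true_sister)
    out[[i]] <- data.frame(seed = rep_seed, basal_with_outgroup = basal,
                           true_sister_without_outgroup = true_sis,
                           contrast = basal && true_sis)
  }
  res <- do.call(rbind, out)
  attr(res, "rates") <- c(basal_with = mean(res$basal_with_outgroup),
                          true_without = mean(res$true_sister_without_outgroup),
                          contrast = mean(res$contrast))
  res
}
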