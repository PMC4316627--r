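#' Generate a benchmark set of gene families with a truth table
#'
#' Each family is simulated independently on the world's species tree and
#' then receives planted events by Bernoulli draws at the stated rates:
#' an HGT (recipient drawn among ingroup leaves, donor among leaves of a
#' different class, so the event is either between ingroup classes or
#' between domains), a duplication (paralog) of an ingroup species, and/or a
#' truncation ("partial" sequence, kept fraction drawn uniformly in
#' `partial_kept_range`). The truth table records the non-exclusive labels
#' `{clean, hgt, paralog, partial}` per family. Per-family seeds are derived
#' from `seed` by a fixed counter scheme, so any family can be regenerated
#' in isolation.
#'
#' @param config A [world_config()].
#' @param n_families Number of families.
#' @param event_rates Numeric vector `c(hgt=, paralog=, partial=)` of
#'   Bernoulli rates in `[0, 1]`.
#' @param n_sites_range Integer range (min, max) for per-family alignment
#'   length.
#' @param seed Integer root seed.
#' @param model A [substitution_model()] (default Poisson, gamma alpha 0.7,
#'   6 categories).
#' @param hgt_divergence,paralog_divergence Re-evolution branch lengths for
#'   planted events (substitutions/site).
#' @param partial_kept_range Kept-fraction range for truncations.
#' @return A list with `families` (list of `gene_family`), `truth` (data
#'   frame: family, hgt, paralog, partial, clean), `tree`, `taxonomy`,
#'   `config`.
#' @export
make_benchmark <- function(config, n_families = 500L,
                           event_rates = c(hgt = 0.2, paralog = 0.1,
                                           partial = 0.1),
                           n_sites_range = c(300L, 600L), seed = 1L,
                           model = substitution_model(),
                           hgt_divergence = 0.05, paralog_divergence = 0.1,
                           partial_kept_range = c(0.25, 0.45)) {
  stopifnot(inherits(config, "world_config"))
  stopifnot(length(event_rates) == 3L)
  if (!is.null(names(event_rates)) && all(nzchar(names(event_rates)))) {
    rates <- c(hgt = unname(event_rates[["hgt"]]),
               paralog = unname(event_rates[["paralog"]]),
               partial = unname(event_rates[["partial"]]))
  } else {
    rates <- c(hgt = event_rates[[1]], paralog = event_rates[[2]],
               partial = event_rates[[3]])
  }
  if (any(is.na(rates)) || any(rates < 0) || any(rates > 1))
    stop_fmt("event rates must lie in [0, 1]")
  world <- sample_species_tree(config)
  tree <- world$tree
  tx <- world$taxonomy
  ingroup <- tx$leaf[tx$domain != "outgroup"]
  families <- vector("list", n_families)
  truth <- data.frame(family = sprintf("fam%04d", seq_len(n_families)),
                      hgt = FALSE, paralog = FALSE, partial = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_families)) {
    fseed <- derive_seed(seed, i)
    fam <- with_seed(fseed, {
      n_sites <- sample(seq(n_sites_range[1], n_sites_range[2]), 1L)
      draws <- runif(3) < rates
      ev <- list()
      if (draws[1]) {
        recipient <- sample(ingroup, 1L)
        rec_class <- tx$class[tx$leaf == recipient]
        donors <- tx$leaf[tx$class != rec_class]
        ev$hgt <- list(donor = sample(donors, 1L), recipient = recipient)
      }
      if (draws[2]) ev$paralog <- list(species = sample(ingroup, 1L))
      if (draws[3]) {
        ev$partial <- list(member = sample(tx$leaf, 1L),
                           kept = runif(1, partial_kept_range[1],
                                        partial_kept_range[2]))
      }
      list(n_sites = n_sites, ev = ev)
    })
    f <- evolve_alignment(tree, model, fam$n_sites,
                          seed = derive_seed(fseed, 1L),
                          id = truth$family[i])
    if (!is.null(fam$ev$hgt)) {
      f <- inject_hgt(f, tree, fam$ev$hgt$donor, fam$ev$hgt$recipient,
                      divergence = hgt_divergence,
                      seed = derive_seed(fseed, 2L))
      truth$hgt[i] <- TRUE
    }
    if (!is.null(fam$ev$paralog)) {
      f <- inject_paralogy(f, fam$ev$paralog$species,
                           divergence = paralog_divergence,
                           seed = derive_seed(fseed, 3L))
      truth$paralog[i] <- TRUE
    }
    if (!is.null(fam$ev$partial)) {
      f <- degrade(f, fam$ev$partial$member, mode = "truncate",
                   fraction = fam$ev$partial$kept,
                   seed = derive_seed(fseed, 4L))
      truth$partial[i] <- TRUE
    }
    families[[i]] <- f
  }
  truth$clean <- !(truth$hgt | truth$paralog | truth$partial)
  list(families = families, truth = truth, tree = tree, taxonomy = tx,
       config = config)
}
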