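#' Default pipeline configuration
#'
#' Returns the full default config as a nested list; [run_pipeline()] and
#' [run_benchmark()] deep-merge user overrides (from a list or a YAML file)
#' into these defaults and echo the merged config into the output directory.
#'
#' @return Nested list of parameter blocks.
#' @export
default_run_config <- function() {
  list(seed = 1L,
       outdir = "phyloroot_run",
       world = list(n_classes_per_kingdom = 3L, n_species_per_class = 3L,
                    n_outgroup_phyla = 24L, species_per_outgroup_phylum = 1L,
                    stem_length = 0.5, ingroup_depth = 0.75,
                    outgroup_depth = 0.75),
       model = list(alpha = 0.7, n_categories = 6L),
       benchmark = list(n_families = 100L,
                        event_rates = c(hgt = 0.2, paralog = 0.1,
                                        partial = 0.1),
                        n_sites_range = c(300L, 600L),
                        hgt_divergence = 0.05, paralog_divergence = 0.1),
       screen = list(correction = "kimura",
                     min_archaeal_members = 4L, min_outgroup_phyla = 24L,
                     partial_fraction = 0.5, require_outgroup = TRUE),
       trim = list(max_gap_fraction = 0.2, max_entropy = 1.0),
       infer = list(correction = "kimura", bootstrap_B = 100L),
       stages = c("simulate", "screen", "concat", "infer", "root"))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a run configuration
#'
#' @param config A nested list of overrides, a path to a YAML file, or
#'   `NULL` for defaults.
#' @return The merged config list.
#' @export
read_run_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(default_run_config(), config %||% list())
}

#' Run the simulate -> screen -> concatenate -> infer -> root pipeline
#'
#' Stage outputs are written under stable names in `outdir`; a JSON manifest
#' records parameters and the per-stage family counts (the screening
#' funnel). Reruns with the same config and seed are deterministic.
#'
#' @param config See [read_run_config()].
#' @return Invisibly, a list with the manifest and main in-memory results.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- read_run_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  model <- substitution_model(alpha = cfg$model$alpha,
                              n_categories = cfg$model$n_categories)
  wc <- do.call(world_config, c(cfg$world, list(seed = cfg$seed)))
  manifest <- list(seed = cfg$seed, stages = cfg$stages, funnel = list())
  results <- list()

  bench <- make_benchmark(wc, n_families = cfg$benchmark$n_families,
                          event_rates = unlist(cfg$benchmark$event_rates),
                          n_sites_range = unlist(cfg$benchmark$n_sites_range),
                          seed = cfg$seed, model = model,
                          hgt_divergence = cfg$benchmark$hgt_divergence,
                          paralog_divergence = cfg$benchmark$paralog_divergence)
  results$benchmark <- bench
  if ("simulate" %in% cfg$stages) {
    write_taxonomy(bench$taxonomy, file.path(outdir, "taxonomy.tsv"))
    writeLines(write_newick(bench$tree), file.path(outdir, "species_tree.nwk"))
    write.table(bench$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  manifest$funnel$simulated <- length(bench$families)

  criteria <- filter_criteria(
    min_archaeal_members = cfg$screen$min_archaeal_members,
    partial_fraction = cfg$screen$partial_fraction,
    min_outgroup_phyla = cfg$screen$min_outgroup_phyla)
  reports <- NULL
  if (any(c("screen", "concat", "infer", "root") %in% cfg$stages)) {
    reports <- lapply(bench$families, function(f) {
      screen_family(f, gene_tree(f, correction = cfg$screen$correction),
                    bench$taxonomy, criteria,
                    require_outgroup = cfg$screen$require_outgroup)
    })
    rep_df <- data.frame(
      family = vapply(reports, `[[`, character(1), "family_id"),
      verdict = vapply(reports, `[[`, character(1), "verdict"),
      reasons = vapply(reports, function(r)
        paste(r$reasons, collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
    if ("screen" %in% cfg$stages)
      write.table(rep_df, file.path(outdir, "screen_report.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    results$screen <- rep_df
    manifest$funnel$retained <- sum(rep_df$verdict == "retain")
  }

  sm <- NULL
  if (any(c("concat", "infer", "root") %in% cfg$stages)) {
    kept_ids <- select_markers(reports)
    kept <- bench$families[vapply(bench$families, function(f)
      f$id %in% kept_ids, logical(1))]
    kept <- lapply(kept, function(f) {
      tr <- trim_alignment(f$seqs,
                           max_gap_fraction = cfg$trim$max_gap_fraction,
                           max_entropy = cfg$trim$max_entropy)
      f$seqs <- tr$seqs
      f
    })
    kept <- kept[vapply(kept, function(f) nchar(f$seqs[[1]]) > 0L, logical(1))]
    if (length(kept) == 0L) stop_fmt("no families survived screening/trimming")
    sm <- concatenate(kept, taxa = bench$taxonomy$leaf, bench$taxonomy)
    if ("concat" %in% cfg$stages) {
      write_fasta(sm$seqs, file.path(outdir, "supermatrix.fasta"))
      writeLines(write_partitions(sm$partitions),
                 file.path(outdir, "partitions.txt"))
      write.table(data.frame(species = names(sm$missing),
                             missing_fraction = round(sm$missing, 6)),
                  file.path(outdir, "missing_data.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    results$supermatrix <- sm
    manifest$funnel$concatenated <- nrow(sm$partitions)
    manifest$funnel$sites <- sm$n_sites
  }

  tree <- NULL
  if (any(c("infer", "root") %in% cfg$stages)) {
    tree <- bootstrap_support(sm$seqs, B = cfg$infer$bootstrap_B,
                              seed = cfg$seed,
                              correction = cfg$infer$correction)
    if ("infer" %in% cfg$stages)
      writeLines(write_newick(tree), file.path(outdir, "supermatrix_tree.nwk"))
    results$tree <- tree
  }

  if ("root" %in% cfg$stages) {
    og <- bench$taxonomy$leaf[bench$taxonomy$domain == "outgroup"]
    rooted <- root_with_outgroup(tree, og)
    rep <- root_report(rooted, bench$taxonomy)
    writeLines(write_newick(rooted), file.path(outdir, "rooted_tree.nwk"))
    jsonlite::write_json(
      list(stem_length = rep$stem_length,
           side_1 = rep$side_1$classes, side_2 = rep$side_2$classes,
           side_supports = rep$side_supports,
           straddling_classes = rep$straddling_classes),
      file.path(outdir, "rooting_report.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    results$rooting <- rep
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(list(manifest = manifest), results))
}

#' Score the screen against the simulator's truth table
#'
#' Runs the benchmark generator and the screening stage, then scores the
#' reject decision against the planted events: a family's true status is
#' "reject" iff it carries any planted event (HGT, paralog or partial).
#' Precision and recall are reported for both the reject and the retain
#' decision, plus per-event detection recall.
#'
#' @param config See [read_run_config()]; `benchmark` and `screen` blocks
#'   are used.
#' @param bench Optionally, a pre-built [make_benchmark()] result (the
#'   config's benchmark block is then ignored).
#' @return List of metrics; `$table` holds the per-family decisions.
#' @export
run_benchmark <- function(config = NULL, bench = NULL) {
  cfg <- read_run_config(config)
  if (is.null(bench)) {
    model <- substitution_model(alpha = cfg$model$alpha,
                                n_categories = cfg$model$n_categories)
    wc <- do.call(world_config, c(cfg$world, list(seed = cfg$seed)))
    bench <- make_benchmark(wc, n_families = cfg$benchmark$n_families,
                            event_rates = unlist(cfg$benchmark$event_rates),
                            n_sites_range = unlist(cfg$benchmark$n_sites_range),
                            seed = cfg$seed, model = model,
                            hgt_divergence = cfg$benchmark$hgt_divergence,
                            paralog_divergence = cfg$benchmark$paralog_divergence)
  }
  criteria <- filter_criteria(
    min_archaeal_members = cfg$screen$min_archaeal_members,
    partial_fraction = cfg$screen$partial_fraction,
    min_outgroup_phyla = cfg$screen$min_outgroup_phyla)
  verdicts <- vapply(bench$families, function(f) {
    screen_family(f, gene_tree(f, correction = cfg$screen$correction),
                  bench$taxonomy, criteria,
                  require_outgroup = cfg$screen$require_outgroup)$verdict
  }, character(1))
  truth <- bench$truth
  truth$predicted_reject <- verdicts == "reject"
  truth$true_reject <- !truth$clean
  tp <- sum(truth$predicted_reject & truth$true_reject)
  fp <- sum(truth$predicted_reject & !truth$true_reject)
  fn <- sum(!truth$predicted_reject & truth$true_reject)
  tn <- sum(!truth$predicted_reject & !truth$true_reject)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  metrics <- list(
    n_families = nrow(truth),
    reject_precision = safe_div(tp, tp + fp),
    reject_recall = safe_div(tp, tp + fn),
    retain_precision = safe_div(tn, tn + fn),
    retain_recall = safe_div(tn, tn + fp),
    hgt_detection_recall = safe_div(sum(truth$predicted_reject & truth$hgt),
                                    sum(truth$hgt)),
    paralog_detection_recall = safe_div(
      sum(truth$predicted_reject & truth$paralog), sum(truth$paralog)),
    partial_detection_recall = safe_div(
      sum(truth$predicted_reject & truth$partial), sum(truth$partial)))
  f1 <- function(p, r) if (is.na(p) || is.na(r) || p + r == 0) NA_real_
                       else 2 * p * r / (p + r)
  metrics$reject_f1 <- f1(metrics$reject_precision, metrics$reject_recall)
  metrics$table <- truth
  metrics
}
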