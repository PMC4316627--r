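#' Retention criteria for candidate marker families
#'
#' Defaults follow the screening thresholds used for domain-level marker
#' detection: hits at E <= 1e-5, families kept only with at least 4 distinct
#' ingroup species, partial sequences shorter than 50% of the family median
#' length removed, and (when outgroup coverage is enforced) presence in at
#' least 24 outgroup phyla.
#'
#' @param e_value_max Maximum E-value for a hit to count.
#' @param min_archaeal_members Minimum number of distinct ingroup species.
#' @param partial_fraction Members shorter than this fraction of the family
#'   median length are flagged/removed (in (0, 1)).
#' @param min_outgroup_phyla Minimum number of distinct outgroup phyla.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(e_value_max = 1e-5, min_archaeal_members = 4L,
                            partial_fraction = 0.5, min_outgroup_phyla = 24L) {
  stopifnot(e_value_max > 0, min_archaeal_members > 0,
            partial_fraction > 0, partial_fraction < 1,
            min_outgroup_phyla > 0)
  structure(list(e_value_max = e_value_max,
                 min_archaeal_members = as.integer(min_archaeal_members),
                 partial_fraction = partial_fraction,
                 min_outgroup_phyla = as.integer(min_outgroup_phyla)),
            class = "filter_criteria")
}

#' Optimal local alignment (Smith-Waterman with affine gaps)
#'
#' @param a,b Ungapped amino-acid sequences (character strings).
#' @param matrix Substitution matrix name (e.g. `"BLOSUM62"`) or a numeric
#'   matrix.
#' @param gap_open,gap_extend Gap penalties (<= 0); a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @return List with `score` (>= 0), `a_span` and `b_span` (integer
#'   `c(start, end)` pairs, `c(0, 0)` if no positively scoring alignment
#'   exists).
#' @export
local_align <- function(a, b, matrix = "BLOSUM62", gap_open = -10,
                        gap_extend = -1) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop_fmt("empty sequence")
  stopifnot(gap_open <= 0, gap_extend <= 0)
  submat <- if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    get(matrix, envir = e)
  } else matrix
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = submat, gapOpening = -gap_open,
    gapExtension = -gap_extend)
  score <- Biostrings::score(aln)
  if (score <= 0)
    return(list(score = 0, a_span = c(0L, 0L), b_span = c(0L, 0L)))
  list(score = score,
       a_span = c(Biostrings::start(Biostrings::pattern(aln)),
                  Biostrings::end(Biostrings::pattern(aln))),
       b_span = c(Biostrings::start(Biostrings::subject(aln)),
                  Biostrings::end(Biostrings::subject(aln))))
}

#' Calibrate an E-value model from decoy scores
#'
#' Fits a Gumbel (extreme-value) distribution to local-alignment scores of
#' shuffled (decoy) sequences by maximum likelihood, yielding parameters
#' `(lambda, K)` such that the expected number of chance hits at score
#' `>= s` between sequences of lengths `m` and `n` is
#' `E = K * m * n * exp(-lambda * s)`.
#'
#' @param decoy_scores Numeric vector of >= 200 decoy scores.
#' @param len_a,len_b Sequence lengths used to generate the decoys.
#' @return An object of class `evalue_calibration` with `lambda` and `K`.
#' @export
calibrate_evalue <- function(decoy_scores, len_a, len_b) {
  if (length(decoy_scores) < 200L)
    stop_fmt("need at least 200 decoy scores (got %d)", length(decoy_scores))
  if (stats::sd(decoy_scores) < 1e-9)
    stop_fmt("degenerate calibration: decoy scores have zero variance")
  fit <- fit_gumbel(decoy_scores)
  lambda <- 1 / fit$beta
  # P(S >= s) ~ exp(-(s - mu)/beta) in the Gumbel tail; absorb mu and the
  # calibration lengths into K.
  K <- exp(fit$mu / fit$beta) / (len_a * len_b)
  structure(list(lambda = lambda, K = K, mu = fit$mu, beta = fit$beta,
                 len_a = len_a, len_b = len_b, n_decoys = length(decoy_scores)),
            class = "evalue_calibration")
}

# Maximum-likelihood Gumbel fit (location mu, scale beta > 0).
fit_gumbel <- function(x) {
  nll <- function(par) {
    beta <- exp(par[2])
    z <- (x - par[1]) / beta
    length(x) * log(beta) + sum(z) + sum(exp(-z))
  }
  init <- c(mean(x) - 0.5772 * stats::sd(x) * sqrt(6) / pi,
            log(stats::sd(x) * sqrt(6) / pi))
  fit <- optim(init, nll, method = "Nelder-Mead")
  list(mu = fit$par[1], beta = exp(fit$par[2]))
}

#' E-value of a local-alignment score
#'
#' `E = K * len_a * len_b * exp(-lambda * score)`: strictly decreasing in
#' the score and linear in each sequence length.
#'
#' @param score Alignment score.
#' @param len_a,len_b Lengths of the two sequences.
#' @param calibration An `evalue_calibration` from [calibrate_evalue()].
#' @return The E-value (positive numeric).
#' @export
estimate_evalue <- function(score, len_a, len_b, calibration) {
  stopifnot(inherits(calibration, "evalue_calibration"))
  calibration$K * len_a * len_b * exp(-calibration$lambda * score)
}

shuffle_seq <- function(s) {
  paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' All-against-all homology search
#'
#' Aligns every query against every database sequence (full local dynamic
#' programming — no heuristic seeding; fine at desk scale), estimates
#' E-values from a shuffled-decoy Gumbel calibration, and returns hits
#' passing `criteria$e_value_max`. Self-hits (identical identifiers) are
#' excluded.
#'
#' @param queries,database Named character vectors of ungapped sequences.
#' @param criteria A [filter_criteria()].
#' @param n_decoys Decoy count for the E-value calibration.
#' @param seed Integer seed (decoy shuffling).
#' @return A data frame (hit table) with columns `query, subject, score,
#'   e_value, q_start, q_end, s_start, s_end`.
#' @export
search_homologs <- function(queries, database, criteria = filter_criteria(),
                            n_decoys = 200L, seed = 1L) {
  check_named_seqs(queries, "queries")
  if (length(database) == 0L) stop_fmt("empty database")
  check_named_seqs(database, "database")
  mlen_q <- round(median(nchar(queries)))
  mlen_d <- round(median(nchar(database)))
  decoys <- with_seed(seed, {
    vapply(seq_len(n_decoys), function(i) {
      q <- shuffle_seq(queries[[sample.int(length(queries), 1L)]])
      d <- shuffle_seq(database[[sample.int(length(database), 1L)]])
      local_align(q, d)$score
    }, numeric(1))
  })
  cal <- calibrate_evalue(decoys, mlen_q, mlen_d)
  rows <- list()
  for (q in names(queries)) {
    for (s in names(database)) {
      if (q == s) next
      al <- local_align(queries[[q]], database[[s]])
      ev <- estimate_evalue(al$score, nchar(queries[[q]]),
                            nchar(database[[s]]), cal)
      if (ev <= criteria$e_value_max) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = q, subject = s, score = al$score, e_value = ev,
          q_start = al$a_span[1], q_end = al$a_span[2],
          s_start = al$b_span[1], s_end = al$b_span[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(query = character(), subject = character(),
                      score = numeric(), e_value = numeric(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer()))
  do.call(rbind, rows)
}

#' Build per-seed gene families from a hit table
#'
#' One family per seed query: the seed plus all subjects it hit at
#' threshold. No transitive closure by default (mirrors a per-query search
#' design); `single_linkage = TRUE` merges families sharing members.
#'
#' @param hits Hit table from [search_homologs()].
#' @param seeds Character vector of seed query ids.
#' @param sequences Optional named character vector supplying member
#'   sequences.
#' @param single_linkage Merge overlapping families?
#' @return List of `gene_family` objects (unaligned; `aligned = FALSE`).
#' @export
build_families <- function(hits, seeds, sequences = NULL,
                           single_linkage = FALSE) {
  member_sets <- lapply(seeds, function(sd) {
    if (!is.null(sequences) && !sd %in% names(sequences))
      stop_fmt("unknown seed id '%s'", sd)
    unique(c(sd, hits$subject[hits$query == sd]))
  })
  names(member_sets) <- seeds
  if (single_linkage) {
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      i <- 1L
      while (i < length(member_sets)) {
        j <- i + 1L
        while (j <= length(member_sets)) {
          if (length(intersect(member_sets[[i]], member_sets[[j]])) > 0L) {
            member_sets[[i]] <- unique(c(member_sets[[i]], member_sets[[j]]))
            member_sets[[j]] <- NULL
            changed <- TRUE
          } else j <- j + 1L
        }
        i <- i + 1L
      }
    }
  }
  lapply(seq_along(member_sets), function(i) {
    ids <- member_sets[[i]]
    seqs <- if (is.null(sequences)) setNames(rep("", length(ids)), ids)
            else sequences[ids]
    new_gene_family(id = names(member_sets)[i] %||% sprintf("fam%d", i),
                    seqs = seqs, aligned = FALSE)
  })
}

#' Remove partial sequences from a family
#'
#' Members whose (non-gap) length is below `partial_fraction` times the
#' family median length are removed; removals are recorded in the
#' `removed_partials` attribute. A family with fewer than 2 members is
#' returned unchanged with a warning.
#'
#' @param family A `gene_family`.
#' @param partial_fraction Fraction of the median length below which a
#'   member counts as partial.
#' @return The filtered `gene_family`.
#' @export
flag_partials <- function(family, partial_fraction = 0.5) {
  stopifnot(inherits(family, "gene_family"))
  if (length(family$seqs) < 2L) {
    warning("family has fewer than 2 members; partial filter skipped")
    return(family)
  }
  lens <- nongap_lengths(family$seqs)
  med <- median(lens)
  drop <- names(lens)[lens < partial_fraction * med]
  family$seqs <- family$seqs[setdiff(names(family$seqs), drop)]
  family$is_partial <- family$is_partial[names(family$seqs)]
  attr(family, "removed_partials") <- drop
  family
}

nongap_lengths <- function(seqs) {
  vapply(seqs, function(s) {
    sum(!strsplit(s, "", fixed = TRUE)[[1]] %in% GAP_CHARS)
  }, numeric(1))
}

#' Coverage filters for a candidate family
#'
#' A family is kept iff it contains at least `min_archaeal_members` distinct
#' ingroup species and (when `require_outgroup`) members from at least
#' `min_outgroup_phyla` distinct outgroup phyla. Reasons enumerate every
#' failed rule.
#'
#' @param family A `gene_family`.
#' @param taxonomy A `taxonomy` data frame resolving every member.
#' @param criteria A [filter_criteria()].
#' @param require_outgroup Enforce the outgroup phylum-coverage rule?
#' @param outgroup_domain Domain label marking outgroup leaves.
#' @return List with `kept` (logical) and `reasons` (character vector).
#' @export
apply_family_filters <- function(family, taxonomy,
                                 criteria = filter_criteria(),
                                 require_outgroup = TRUE,
                                 outgroup_domain = "outgroup") {
  stopifnot(inherits(family, "gene_family"))
  rec <- taxonomy_lookup(taxonomy, names(family$seqs))
  ingroup_species <- unique(rec$species[rec$domain != outgroup_domain])
  outgroup_phyla <- unique(rec$phylum[rec$domain == outgroup_domain])
  reasons <- character()
  if (length(ingroup_species) < criteria$min_archaeal_members)
    reasons <- c(reasons, "min_archaeal_members")
  if (require_outgroup && length(outgroup_phyla) < criteria$min_outgroup_phyla)
    reasons <- c(reasons, "min_outgroup_phyla")
  list(kept = length(reasons) == 0L, reasons = reasons,
       n_ingroup_species = length(ingroup_species),
       n_outgroup_phyla = length(outgroup_phyla))
}
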