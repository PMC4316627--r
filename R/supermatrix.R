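#' Trim alignment columns by gap fraction and entropy
#'
#' A column is kept iff its gap fraction is at most `max_gap_fraction` and
#' its normalized Shannon entropy (base = alphabet size, gaps excluded from
#' the residue distribution) is at most `max_entropy`. This is a deliberate,
#' deterministic simplification of window-based trimmers such as BMGE:
#' pre-trimmed alignments can be supplied instead when fidelity to an
#' external trimmer matters.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param max_gap_fraction Maximum fraction of gaps per kept column.
#' @param max_entropy Maximum normalized column entropy in `[0, 1]`.
#' @param n_states Alphabet size for entropy normalization (default 20).
#' @return List with `seqs` (trimmed alignment; zero-width if everything was
#'   removed, with a warning) and `kept` (1-based kept column indices).
#' @export
trim_alignment <- function(seqs, max_gap_fraction = 0.2, max_entropy = 0.5,
                           n_states = 20L) {
  cm <- aln_char_matrix(seqs)
  n <- ncol(cm)
  keep <- logical(n)
  for (j in seq_len(n)) {
    col <- cm[, j]
    gap <- col %in% GAP_CHARS
    if (mean(gap) > max_gap_fraction) next
    res <- col[!gap]
    if (length(res) == 0L) next
    freq <- table(res) / length(res)
    h <- -sum(freq * log(freq)) / log(n_states)
    keep[j] <- h <= max_entropy
  }
  if (!any(keep)) {
    warning("all columns removed by trimming")
    return(list(seqs = setNames(rep("", length(seqs)), names(seqs)),
                kept = integer()))
  }
  trimmed <- setNames(apply(cm[, keep, drop = FALSE], 1L, paste,
                            collapse = ""), rownames(cm))
  list(seqs = trimmed, kept = which(keep))
}

#' Concatenate trimmed gene families into a supermatrix
#'
#' Species absent from a family receive an all-gap block; partitions are
#' recorded in input order with 1-based inclusive coordinates; the
#' missing-data fraction per species counts gap characters plus absent
#' blocks over the total concatenation length.
#'
#' @param families List of aligned `gene_family` objects (at most one
#'   sequence per species each; paralogous families must have been screened
#'   out).
#' @param taxa Character vector of species to include (row order).
#' @param taxonomy A `taxonomy` data frame mapping leaves to species.
#' @return An object of class `supermatrix`: list with `seqs` (named rows),
#'   `partitions` (data frame `name,start,end`), `missing` (named numeric),
#'   `n_sites`.
#' @export
concatenate <- function(families, taxa, taxonomy) {
  stopifnot(length(families) > 0L)
  rows <- setNames(rep("", length(taxa)), taxa)
  parts <- data.frame(name = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  pos <- 0L
  for (fam in families) {
    stopifnot(inherits(fam, "gene_family"), fam$aligned)
    len <- nchar(fam$seqs[[1]])
    rec <- taxonomy_lookup(taxonomy, names(fam$seqs))
    dup <- unique(rec$species[duplicated(rec$species)])
    if (length(dup) > 0L)
      stop_fmt("family '%s' has multiple sequences for species '%s'",
               fam$id, dup[1])
    block <- setNames(rep(strrep("-", len), length(taxa)), taxa)
    present <- rec$species %in% taxa
    block[rec$species[present]] <- unname(fam$seqs[present])
    rows <- paste0(rows, block)
    names(rows) <- taxa
    parts <- rbind(parts, data.frame(name = fam$id, start = pos + 1L,
                                     end = pos + len))
    pos <- pos + len
  }
  miss <- vapply(rows, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    mean(ch %in% GAP_CHARS)
  }, numeric(1))
  structure(list(seqs = rows, partitions = parts, missing = miss,
                 n_sites = pos),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix: %d taxa, %d sites, %d partitions; max missing %.1f%%>\n",
              length(x$seqs), x$n_sites, nrow(x$partitions),
              100 * max(x$missing)))
  invisible(x)
}

#' Mean pairwise identity between two groups
#'
#' For every cross pair, identity = identical shared non-gap columns /
#' shared non-gap columns; the result is the mean over pairs, in percent.
#' Pairs without shared columns are skipped with a warning; if all pairs are
#' skipped, an error is raised.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param group_a,group_b Disjoint, non-empty sets of row names.
#' @return Mean identity in percent.
#' @export
mean_pairwise_identity <- function(seqs, group_a, group_b) {
  stopifnot(length(group_a) > 0L, length(group_b) > 0L,
            length(intersect(group_a, group_b)) == 0L)
  im <- aln_int_matrix(seqs)
  vals <- numeric()
  skipped <- 0L
  for (a in group_a) {
    for (b in group_b) {
      x <- im[a, ]; y <- im[b, ]
      shared <- x > 0L & y > 0L
      if (!any(shared)) { skipped <- skipped + 1L; next }
      vals <- c(vals, mean(x[shared] == y[shared]) * 100)
    }
  }
  if (skipped > 0L)
    warning(sprintf("%d pair(s) without shared columns skipped", skipped))
  if (length(vals) == 0L) stop_fmt("no pair shares any non-gap column")
  mean(vals)
}
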