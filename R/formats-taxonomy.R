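#' Construct a taxonomy map
#'
#' A taxonomy map assigns every leaf identifier to four ranks:
#' species, class, phylum and domain. Domains distinguish the two ingroup
#' kingdoms from the outgroup (labels are free strings, e.g.
#' `"Euryarchaeota"`, `"Proteoarchaeota"`, `"Bacteria"`, or the simulator's
#' `"ingroup-A"`, `"ingroup-B"`, `"outgroup"`).
#'
#' @param leaf,species,class_,phylum,domain Character vectors of equal
#'   length; all entries non-empty, leaves unique.
#' @return A data frame of class `taxonomy` with columns
#'   `leaf, species, class, phylum, domain`.
#' @export
taxonomy_map <- function(leaf, species, class_, phylum, domain) {
  tx <- data.frame(leaf = as.character(leaf),
                   species = as.character(species),
                   class = as.character(class_),
                   phylum = as.character(phylum),
                   domain = as.character(domain),
                   stringsAsFactors = FALSE)
  validate_taxonomy(tx)
}

validate_taxonomy <- function(tx) {
  need <- c("leaf", "species", "class", "phylum", "domain")
  miss <- setdiff(need, names(tx))
  if (length(miss) > 0L)
    stop_fmt("taxonomy is missing column(s): %s", paste(miss, collapse = ", "))
  tx <- tx[, need]
  empty <- which(apply(tx, 1L, function(r) any(is.na(r) | r == "")))
  if (length(empty) > 0L)
    stop_fmt("taxonomy row %d has an empty rank", empty[1])
  dup <- tx$leaf[duplicated(tx$leaf)]
  if (length(dup) > 0L)
    stop_fmt("duplicate leaf identifier(s) in taxonomy: %s",
             paste(unique(dup), collapse = ", "))
  class(tx) <- c("taxonomy", "data.frame")
  tx
}

#' Read a taxonomy table
#'
#' Tab-separated with the fixed header `leaf	species	class	phylum	domain`.
#'
#' @param path Path to the TSV file.
#' @return A `taxonomy` data frame (see [taxonomy_map()]).
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop_fmt("taxonomy file not found: %s", path)
  tx <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  validate_taxonomy(tx)
}

#' Write a taxonomy table
#' @param tx A `taxonomy` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_taxonomy <- function(tx, path) {
  tx <- validate_taxonomy(tx)
  write.table(tx, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Resolve leaves against a taxonomy. Paralogous copies created by the
# simulator carry a "#<n>" suffix on the source species' leaf id and resolve
# to the same record.
taxonomy_lookup <- function(tx, leaves) {
  tx <- validate_taxonomy(tx)
  base <- sub("#[0-9]+$", "", leaves)
  idx <- match(base, tx$leaf)
  if (anyNA(idx))
    stop_fmt("leaf '%s' not found in taxonomy", leaves[which(is.na(idx))[1]])
  out <- tx[idx, , drop = FALSE]
  out$leaf <- leaves
  rownames(out) <- NULL
  out
}

# Leaves belonging to a given domain label (after copy-suffix resolution).
domain_leaves <- function(tx, leaves, domain) {
  rec <- taxonomy_lookup(tx, leaves)
  rec$leaf[rec$domain %in% domain]
}
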