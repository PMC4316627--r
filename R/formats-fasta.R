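#' Read an amino-acid FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header; the
#' remainder of the header is kept as a `descriptions` attribute. Sequences
#' are uppercased; gap (`-`) and unknown (`X`) characters are preserved.
#'
#' @param path Path to a FASTA file (aligned or unaligned).
#' @return Named character vector of sequences (names are identifiers), with
#'   attribute `descriptions` (named character vector, possibly empty
#'   strings).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first seq", "MK", ">b", "M-K"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_fmt("FASTA file %s contains no records", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop_fmt("empty identifier in FASTA file %s", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop_fmt("duplicate identifier(s) in %s: %s", path,
             paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  allowed <- c(AA_STATES, "X", "-", "*")
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% allowed)
    if (length(bad) > 0L)
      stop_fmt("illegal residue '%s' at position %d of record '%s'",
               ch[bad[1]], bad[1], ids[i])
  }
  names(seqs) <- ids
  attr(seqs, "descriptions") <- setNames(desc, ids)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  check_named_seqs(seqs, "seqs")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
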