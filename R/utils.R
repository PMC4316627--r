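# Internal helpers shared across modules.

# Canonical amino-acid alphabet (20 states, alphabetical one-letter codes).
AA_STATES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Characters treated as missing data in alignments.
GAP_CHARS <- c("-", "X")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

check_named_seqs <- function(seqs, what = "alignment") {
  if (!is.character(seqs) || is.null(names(seqs)) || any(names(seqs) == ""))
    stop_fmt("%s must be a named character vector of sequences", what)
  if (anyDuplicated(names(seqs)))
    stop_fmt("duplicate sequence identifiers in %s", what)
  invisible(seqs)
}

check_aligned <- function(seqs, what = "alignment") {
  check_named_seqs(seqs, what)
  if (length(unique(nchar(seqs))) > 1L)
    stop_fmt("%s rows are not all the same length", what)
  invisible(seqs)
}

# Split aligned sequences into a character matrix (rows = taxa).
aln_char_matrix <- function(seqs) {
  check_aligned(seqs)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

# Encode an alignment as an integer matrix: 0 = gap/unknown, 1..s = state
# index in `states`.
aln_int_matrix <- function(seqs, states = AA_STATES) {
  cm <- aln_char_matrix(seqs)
  im <- match(cm, states)
  im[is.na(im)] <- 0L
  dim(im) <- dim(cm)
  rownames(im) <- rownames(cm)
  im
}

int_matrix_to_seqs <- function(im, states = AA_STATES) {
  chars <- c("-", states)[im + 1L]
  dim(chars) <- dim(im)
  setNames(apply(chars, 1L, paste, collapse = ""), rownames(im))
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) withr::with_seed(seed, expr)

# Documented counter scheme for deriving per-unit seeds from a root seed,
# kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 100003 + index) %% 2147483647)
}
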