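#' Serialize concatenation partitions
#'
#' One line per partition, 1-based inclusive coordinates, e.g.
#' `"M001 = 1-120"`. Partitions must tile the concatenation: contiguous,
#' ordered, non-overlapping, starting at 1.
#'
#' @param partitions A data frame with columns `name`, `start`, `end`, or a
#'   list of `(name, start, end)` triples.
#' @return A single string (empty string for an empty partition list).
#' @examples
#' write_partitions(data.frame(name = c("g1", "g2"),
#'                             start = c(1, 121), end = c(120, 200)))
#' @export
write_partitions <- function(partitions) {
  p <- as_partition_df(partitions)
  if (nrow(p) == 0L) return("")
  check_partition_tiling(p)
  paste(sprintf("%s = %d-%d", p$name, p$start, p$end), collapse = "\n")
}

as_partition_df <- function(partitions) {
  if (is.data.frame(partitions)) {
    stopifnot(all(c("name", "start", "end") %in% names(partitions)))
    p <- partitions[, c("name", "start", "end")]
  } else if (is.list(partitions)) {
    p <- do.call(rbind, lapply(partitions, function(x) {
      data.frame(name = as.character(x[[1]]), start = as.integer(x[[2]]),
                 end = as.integer(x[[3]]), stringsAsFactors = FALSE)
    }))
    if (is.null(p)) p <- data.frame(name = character(), start = integer(),
                                    end = integer())
  } else stop_fmt("partitions must be a data frame or list of triples")
  p$start <- as.integer(p$start)
  p$end <- as.integer(p$end)
  p
}

check_partition_tiling <- function(p) {
  if (nrow(p) == 0L) return(invisible(p))
  if (p$start[1] != 1L)
    stop_fmt("partitions must start at 1 (got %d)", p$start[1])
  if (any(p$end < p$start))
    stop_fmt("partition '%s' has end < start", p$name[which(p$end < p$start)[1]])
  if (nrow(p) > 1L) {
    gaps <- p$start[-1] - p$end[-nrow(p)]
    bad <- which(gaps != 1L)
    if (length(bad) > 0L)
      stop_fmt("partitions '%s' and '%s' %s", p$name[bad[1]], p$name[bad[1] + 1L],
               if (gaps[bad[1]] > 1L) "leave a gap" else "overlap")
  }
  invisible(p)
}
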