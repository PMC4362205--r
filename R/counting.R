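# Strand-merged counting of gapped subsequences in SELEX reads.

#' Count gapped subsequences in a read set
#'
#' Enumerates every gapped pattern within the configured bounds (defined
#' bases between `min_defined` and `max_defined`, a single internal gap of
#' up to `max_gap` undefined positions) and counts its matches in the reads.
#' A pattern matches at a read position when all its defined bases equal the
#' read; gap positions are unconstrained.  With `strand_policy = "merge"`,
#' forward and reverse-complement occurrences accumulate under the
#' strand-canonical pattern.  In `"per_read"` mode a read contributes at
#' most once per pattern (robust to PCR jackpots, the default); in
#' `"per_occurrence"` mode every match counts.
#'
#' @param reads Character vector or [cycle_reads()] object.
#' @param min_defined,max_defined Bounds on the number of defined bases.
#' @param max_gap Maximum internal gap length.
#' @param counting_mode `"per_read"` (default) or `"per_occurrence"`.
#' @param strand_policy `"merge"` (default) or `"forward_only"`.
#' @return A `pattern_count_table`: a data.frame with columns `pattern` and
#'   `count`, sorted by count descending then pattern, with the counting
#'   configuration in attributes.
#' @examples
#' count_patterns("ACGTACGT", min_defined = 4, max_defined = 4, max_gap = 0,
#'                counting_mode = "per_occurrence",
#'                strand_policy = "forward_only")
#' @export
count_patterns <- function(reads, min_defined = 4L, max_defined = 8L,
                           max_gap = 10L,
                           counting_mode = c("per_read", "per_occurrence"),
                           strand_policy = c("merge", "forward_only")) {
  counting_mode <- match.arg(counting_mode)
  strand_policy <- match.arg(strand_policy)
  cyc <- if (inherits(reads, "cycle_reads")) reads$cycle else NA_integer_
  reads <- as_reads(reads)
  if (length(reads) == 0L) stop("no reads to count")
  stopifnot(min_defined >= 1L, max_defined >= min_defined, max_gap >= 0L)
  res <- cpp_count_patterns(reads, as.integer(min_defined),
                            as.integer(max_defined), as.integer(max_gap),
                            counting_mode == "per_read",
                            strand_policy == "merge")
  df <- data.frame(pattern = as.character(res$pattern),
                   count = as.numeric(res$count),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$pattern), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            class = c("pattern_count_table", "data.frame"),
            cycle = cyc,
            total_reads = length(reads),
            counting_mode = counting_mode,
            strand_policy = strand_policy,
            bounds = list(min_defined = as.integer(min_defined),
                          max_defined = as.integer(max_defined),
                          max_gap = as.integer(max_gap)))
}

#' @export
print.pattern_count_table <- function(x, n = 10L, ...) {
  cat(sprintf(
    "<pattern count table> %d patterns from %s reads (%s, %s)\n",
    nrow(x), attr(x, "total_reads"), attr(x, "counting_mode"),
    attr(x, "strand_policy")))
  print.data.frame(head(as.data.frame(x), n))
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

#' Write / read a pattern count table as TSV
#'
#' @param table A `pattern_count_table` (or any data.frame with columns
#'   `pattern`, `count`).
#' @param path File path.
#' @return `path` invisibly / the table.
#' @export
write_count_table <- function(table, path) {
  write.table(as.data.frame(table)[, c("pattern", "count")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric"))
  structure(df, class = c("pattern_count_table", "data.frame"))
}
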