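# Gapped subsequence patterns and the Huddinge distance.
#
# A pattern is a string over {A,C,G,T,n} where "n" marks an undefined
# position.  Canonical form has a defined base at both ends; the counting and
# neighbour space additionally restricts patterns to a single internal run of
# n ("one gap in the middle").

PATTERN_ALPHABET <- c("A", "C", "G", "T", "n")

#' Parse a gapped pattern
#'
#' Parses a string over `A`,`C`,`G`,`T`,`n` into its canonical gapped-pattern
#' form: leading and trailing `n` are stripped, so both ends are defined
#' bases.  The number of defined (non-`n`) bases and the total internal gap
#' length are recorded.
#'
#' @param text Pattern string, e.g. `"ACnGT"`.
#' @return An object of class `gapped_pattern`: a list with elements
#'   `symbols` (canonical string), `n_defined`, `gap_len` and `span`.
#' @examples
#' parse_pattern("ACnGT")   # 4 defined bases, gap of 1
#' parse_pattern("nACGTn")  # canonicalized to "ACGT"
#' @export
parse_pattern <- function(text) {
  if (inherits(text, "gapped_pattern")) return(text)
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  sym <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(sym), PATTERN_ALPHABET)
  if (length(bad) > 0L)
    stop("illegal pattern symbol(s): ", paste(bad, collapse = ", "))
  if (all(sym == "n")) stop("pattern must contain at least one defined base")
  s <- canonical_pattern(text)
  structure(
    list(
      symbols = s,
      n_defined = pattern_n_defined(s),
      gap_len = sum(strsplit(s, "", fixed = TRUE)[[1]] == "n"),
      span = nchar(s)
    ),
    class = "gapped_pattern"
  )
}

#' @export
print.gapped_pattern <- function(x, ...) {
  cat(sprintf("<gapped pattern> %s  (defined: %d, gap: %d, span: %d)\n",
              x$symbols, x$n_defined, x$gap_len, x$span))
  invisible(x)
}

#' @export
format.gapped_pattern <- function(x, ...) x$symbols

as_pattern_string <- function(p) {
  if (inherits(p, "gapped_pattern")) p$symbols else parse_pattern(p)$symbols
}

canonical_pattern <- function(text) {
  gsub("^n+|n+$", "", text)
}

pattern_n_defined <- function(s) {
  nchar(gsub("n", "", s, fixed = TRUE))
}

#' Reverse complement of a gapped pattern
#'
#' Reverses the pattern and complements its defined bases; `n` maps to `n`.
#' The operation is an involution.
#'
#' @param p A `gapped_pattern` or a pattern string.
#' @return A pattern string (reverse complement).
#' @examples
#' revcomp_pattern("AACG")  # "CGTT"
#' @export
revcomp_pattern <- function(p) {
  s <- as_pattern_string(p)
  comp <- c(A = "T", C = "G", G = "C", T = "A", n = "n")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

#' Strand-canonical form of a pattern
#'
#' The lexicographically smaller of a pattern and its reverse complement
#' under the symbol order `A < C < G < T < n`; strand-merged counting
#' accumulates occurrences under this representative.
#'
#' @inheritParams revcomp_pattern
#' @return A pattern string.
#' @export
canonical_strand <- function(p) {
  s <- as_pattern_string(p)
  r <- revcomp_pattern(s)
  # plain byte order ranks A < C < G < T < n
  if (r < s) r else s
}

#' Huddinge distance between gapped patterns
#'
#' The distance is `d - a`, where `d` is the larger number of defined bases
#' in the two patterns and `a` is the maximum number of positions at which
#' both patterns carry equal defined bases over all rigid relative offsets
#' (patterns are not internally re-gapped during alignment).  With
#' `strand_policy = "merge"` the minimum over the second pattern and its
#' reverse complement is returned, so the metric agrees with strand-merged
#' counting.
#'
#' @param p1,p2 Patterns (strings or `gapped_pattern` objects).
#' @param strand_policy `"merge"` (default) or `"forward_only"`.
#' @return Non-negative integer distance; 0 iff the canonical forms are
#'   identical (up to strand when merging).
#' @examples
#' huddinge_distance("ACGT", "ACGA")    # 1 (substitution)
#' huddinge_distance("ACGT", "ACG")     # 1 (shorter)
#' huddinge_distance("TAATnnATTA", "TAATnnnATTA")  # 1 (spacing change)
#' @export
huddinge_distance <- function(p1, p2, strand_policy = c("merge", "forward_only")) {
  strand_policy <- match.arg(strand_policy)
  s1 <- as_pattern_string(p1)
  s2 <- as_pattern_string(p2)
  cpp_huddinge(s1, s2, strand_policy == "merge")
}

#' Alignment profile underlying the Huddinge distance
#'
#' For every rigid relative offset of `p2` against `p1`, the number of
#' positions at which both patterns have equal defined bases.  Offset 0
#' aligns the first symbols of the two canonical patterns.
#'
#' @inheritParams huddinge_distance
#' @return Named integer vector (names are offsets).
#' @export
huddinge_profile <- function(p1, p2) {
  cpp_alignment_profile(as_pattern_string(p1), as_pattern_string(p2))
}

#' Minimum Huddinge distance of shift-type neighbours
#'
#' A shift-type neighbour of a pattern is a pattern with the same number of
#' defined bases and the same gap structure, considered at a nonzero
#' relative offset.  The best such neighbour matches the original wherever
#' the two defined-base structures overlap, so its Huddinge distance is
#' `d - max_off` over nonzero offsets of the structural overlap (the number
#' of positions at which both copies carry a defined base).  For ungapped
#' patterns this minimum is 1; a gap forces the defined-base structures out
#' of register, so shifts of gapped patterns sit at distance 2 or more.
#'
#' @param p Pattern (string or `gapped_pattern`).
#' @return The minimum Huddinge distance over shift-type neighbours.
#' @examples
#' shift_min_distance("ACGT")   # 1
#' shift_min_distance("ACnGT")  # 2
#' @export
shift_min_distance <- function(p) {
  pp <- parse_pattern(p)
  sym <- strsplit(pp$symbols, "", fixed = TRUE)[[1]]
  def <- which(sym != "n")
  best <- 0L
  for (off in setdiff(seq(-(pp$span - 1L), pp$span - 1L), 0L))
    best <- max(best, length(intersect(def, def + off)))
  pp$n_defined - best
}

#' Huddinge distance-1 neighbours of a pattern
#'
#' Enumerates exactly the set of patterns at Huddinge distance one from `p`
#' within the configured pattern space (at most `max_defined` defined bases,
#' a single internal gap of at most `max_gap`).  The set covers all
#' neighbour classes: substitutions, one-base shorter/longer patterns,
#' shifts, and gap-length variants.
#'
#' @inheritParams huddinge_distance
#' @param p Pattern (string or `gapped_pattern`).
#' @param max_defined Upper bound on defined bases in the neighbour space.
#' @param max_gap Upper bound on the internal gap length.
#' @return Character vector of canonical pattern strings (strand-canonical
#'   when `strand_policy = "merge"`), sorted.
#' @examples
#' nb <- huddinge_neighbors("ACGT", max_defined = 5, max_gap = 1,
#'                          strand_policy = "forward_only")
#' "ACGA" %in% nb
#' @export
huddinge_neighbors <- function(p, max_defined = 8L, max_gap = 10L,
                               strand_policy = c("merge", "forward_only")) {
  strand_policy <- match.arg(strand_policy)
  s <- as_pattern_string(p)
  pp <- parse_pattern(s)
  if (pp$n_defined > max_defined || pp$gap_len > max_gap)
    stop("pattern exceeds the requested bounds (max_defined = ", max_defined,
         ", max_gap = ", max_gap, ")")
  as.character(cpp_neighbors(s, as.integer(max_defined), as.integer(max_gap),
                             strand_policy == "merge"))
}
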