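# Autoseed: local-maxima seed discovery in gapped k-mer space, and
# classification of primary vs secondary binding models.

#' Find local maxima in a gapped pattern count table
#'
#' A pattern is a local maximum when it is enriched more than any closely
#' related pattern, where "closely related" means Huddinge distance one:
#' (i) its count strictly exceeds that of every distance-1 neighbour with
#' the same number of defined bases; (ii) against neighbours with one fewer
#' defined base its count must exceed `theta` times theirs (shorter patterns
#' contained in longer ones are expected at equal-or-higher counts, so a
#' threshold corrects the comparison); (iii) it is not dominated by a
#' distance-1 neighbour with one more defined base whose count exceeds
#' `theta` times its own; and (iv) its count is at least `min_count`.
#'
#' @param table A `pattern_count_table` from [count_patterns()] (or a
#'   data.frame with columns `pattern`, `count` plus a `bounds` attribute).
#' @param theta Cross-length dominance threshold in (0, 1).  Under a null of
#'   no enrichment the long/short count ratio per added defined base is
#'   about 1/4; under perfect enrichment it approaches 1; 0.5 is the
#'   midpoint on the log scale.
#' @param min_count Minimum count for a reported maximum.
#' @param max_candidates Number of highest-count patterns evaluated as
#'   candidates; `Inf` (default) scans the whole table.  A finite value
#'   leaves the top of the ranking unchanged as long as at least one
#'   candidate passes, and is intended for the "top seeds" question on
#'   large tables.
#' @param bounds Pattern-space bounds; defaults to the `bounds` attribute of
#'   `table`.
#' @return A data.frame of class `seed_models` with columns `rank`,
#'   `pattern`, `count`, sorted by count descending (ties lexicographic).
#' @export
find_local_maxima <- function(table, theta = 0.5, min_count = 10,
                              max_candidates = Inf, bounds = NULL) {
  stopifnot(theta > 0, theta < 1)
  if (is.null(bounds)) bounds <- attr(table, "bounds")
  if (is.null(bounds))
    stop("pattern-space bounds are required (pass `bounds` or use a table ",
         "from count_patterns())")
  sp <- attr(table, "strand_policy")
  merge <- is.null(sp) || identical(sp, "merge")
  df <- as.data.frame(table)
  if (nrow(df) == 0L) stop("empty count table")
  mc <- if (is.finite(max_candidates)) as.integer(max_candidates) else 0L
  is_max <- cpp_local_maxima(df$pattern, as.numeric(df$count),
                             theta, min_count,
                             as.integer(bounds$max_defined),
                             as.integer(bounds$max_gap),
                             merge, mc)
  out <- df[is_max, c("pattern", "count"), drop = FALSE]
  out <- out[order(-out$count, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(rank = seq_len(nrow(out)), out)
  structure(out, class = c("seed_models", "data.frame"),
            theta = theta, min_count = min_count,
            strand_policy = if (merge) "merge" else "forward_only",
            bounds = bounds)
}

#' @export
print.seed_models <- function(x, n = 10L, ...) {
  cat(sprintf("<seed models> %d local maxima (theta = %s, min_count = %s)\n",
              nrow(x), attr(x, "theta"), attr(x, "min_count")))
  print.data.frame(head(as.data.frame(x), n))
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

#' Classify the relation of a secondary model to the primary
#'
#' Secondary binding modes fall into three structural classes relative to
#' the primary site: `spacing_orientation` (same defined bases / half-sites
#' but a different gap length or half-site orientation), `flank` (one
#' pattern extends the other with extra defined bases at the ends), and
#' `dinucleotide` (the best rigid alignment differs at exactly two adjacent
#' defined positions).  Precedence is spacing_orientation > flank >
#' dinucleotide; anything else is `unrelated`.
#'
#' @param secondary,primary Canonical patterns (strings or
#'   `gapped_pattern`s).
#' @param strand_policy `"merge"` (default) considers reverse complements.
#' @return One of `"spacing_orientation"`, `"flank"`, `"dinucleotide"`,
#'   `"unrelated"`.
#' @examples
#' classify_model_relation("TAATnnnATTA", "TAATnnATTA")  # spacing_orientation
#' classify_model_relation("GACGTC", "ACGT")             # flank
#' @export
classify_model_relation <- function(secondary, primary,
                                    strand_policy = c("merge", "forward_only")) {
  strand_policy <- match.arg(strand_policy)
  s <- as_pattern_string(secondary)
  p <- as_pattern_string(primary)
  variants <- if (strand_policy == "merge") c(s, revcomp_pattern(s)) else s
  if (any(vapply(variants, identical, logical(1), p))) return("unrelated")

  if (any(vapply(variants, is_spacing_orientation_of, logical(1), p)))
    return("spacing_orientation")
  if (any(vapply(variants, is_flank_extension_pair, logical(1), p)))
    return("flank")
  if (any(vapply(variants, is_dinucleotide_variant, logical(1), p)))
    return("dinucleotide")
  "unrelated"
}

strip_gaps <- function(s) gsub("n", "", s, fixed = TRUE)

split_half_sites <- function(s) {
  # split a single-gap pattern at its gap run; ungapped patterns yield
  # themselves
  parts <- strsplit(s, "n+")[[1]]
  parts[nzchar(parts)]
}

is_spacing_orientation_of <- function(a, b) {
  if (identical(a, b)) return(FALSE)
  # same defined-base string, different gap structure
  if (identical(strip_gaps(a), strip_gaps(b))) return(TRUE)
  # same two half-sites up to per-half reverse complement (orientation flip)
  ha <- split_half_sites(a)
  hb <- split_half_sites(b)
  if (length(ha) == 2L && length(hb) == 2L) {
    canon <- function(h) vapply(h, canonical_strand, character(1))
    if (identical(sort(unname(canon(ha))), sort(unname(canon(hb)))))
      return(TRUE)
  }
  FALSE
}

is_flank_extension_pair <- function(a, b) {
  # one pattern equals the other plus extra defined bases at the ends: the
  # best rigid alignment covers every defined base of the shorter pattern
  if (pattern_n_defined(a) == pattern_n_defined(b)) return(FALSE)
  short <- if (pattern_n_defined(a) < pattern_n_defined(b)) a else b
  long <- if (identical(short, a)) b else a
  best <- max(cpp_alignment_profile(long, short))
  best == pattern_n_defined(short)
}

is_dinucleotide_variant <- function(a, b) {
  if (pattern_n_defined(a) != pattern_n_defined(b)) return(FALSE)
  if (nchar(a) != nchar(b)) return(FALSE)
  # examine the best rigid alignments: differing defined positions must be
  # exactly two, and adjacent
  prof <- cpp_alignment_profile(a, b)
  best <- max(prof)
  offs <- as.integer(names(prof)[prof == best])
  for (off in offs) {
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    ia <- seq_along(av)
    ib <- ia - off
    ok <- ib >= 1L & ib <= length(bv)
    pos <- ia[ok]
    mism <- pos[av[pos] != "n" & bv[pos - off] != "n" &
                  av[pos] != bv[pos - off]]
    aligned_def <- sum(av[pos] != "n" & bv[pos - off] != "n")
    # all defined bases must align (same footprint), with exactly two
    # adjacent differing positions
    if (aligned_def == pattern_n_defined(a) && length(mism) == 2L &&
        diff(mism) == 1L)
      return(TRUE)
  }
  FALSE
}

#' Annotate local maxima as primary and secondary models
#'
#' The rank-1 maximum becomes the primary binding model; every other
#' maximum is annotated with its structural relation to the primary via
#' [classify_model_relation()].
#'
#' @param maxima A `seed_models` data.frame from [find_local_maxima()].
#' @return The input with `role` and `relation_to_primary` columns.
#' @export
pick_primary_and_secondary <- function(maxima) {
  if (nrow(maxima) == 0L) stop("no local maxima to annotate")
  df <- as.data.frame(maxima)
  df$role <- c("primary", rep("secondary", nrow(df) - 1L))
  df$relation_to_primary <- c(
    "none",
    vapply(df$pattern[-1L], classify_model_relation, character(1),
           primary = df$pattern[1L])
  )
  structure(df, class = class(maxima),
            theta = attr(maxima, "theta"),
            min_count = attr(maxima, "min_count"),
            bounds = attr(maxima, "bounds"))
}

#' Discover and annotate seeds from reads in one call
#'
#' Convenience wrapper: [count_patterns()], [find_local_maxima()],
#' [pick_primary_and_secondary()].
#'
#' @inheritParams count_patterns
#' @inheritParams find_local_maxima
#' @param top Keep at most this many ranked maxima.
#' @return Annotated `seed_models` data.frame.
#' @export
autoseed <- function(reads, theta = 0.5, min_count = 10,
                     min_defined = 4L, max_defined = 8L, max_gap = 10L,
                     counting_mode = "per_read", strand_policy = "merge",
                     top = Inf, max_candidates = Inf) {
  tab <- count_patterns(reads, min_defined = min_defined,
                        max_defined = max_defined, max_gap = max_gap,
                        counting_mode = counting_mode,
                        strand_policy = strand_policy)
  mx <- find_local_maxima(tab, theta = theta, min_count = min_count,
                          max_candidates = max_candidates)
  if (is.finite(top) && nrow(mx) > top) {
    at <- attributes(mx)
    mx <- mx[seq_len(top), , drop = FALSE]
    attributes(mx) <- modifyList(at, list(row.names = rownames(mx)))
  }
  pick_primary_and_secondary(mx)
}
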