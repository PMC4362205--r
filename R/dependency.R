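# Pairwise base interdependency (dinucleotide preference) within bound
# sites: joint distributions vs the mononucleotide (PWM) prediction.

#' Joint base-pair counts over seed-matching windows
#'
#' Selects each read's best seed-matching window (as in
#' [multinomial_matrix()], allowing up to `max_mismatch` mismatches over
#' the seed's defined bases) and tallies the 4 x 4 base-pair counts for
#' every ordered position pair (i < j) in the window.
#'
#' @inheritParams multinomial_matrix
#' @param max_mismatch Maximum mismatches for a window to qualify
#'   (default 0: exact seed matches).
#' @return List with `width`, `n_sites` and `joint`, a list indexed
#'   `"i,j"` of 4 x 4 count matrices (rows = base at i, cols = base at j).
#' @export
joint_pair_counts <- function(reads, seed, flank = 0L, max_mismatch = 0L,
                              strand_policy = c("merge", "forward_only")) {
  strand_policy <- match.arg(strand_policy)
  reads <- as_reads(reads)
  s <- as_pattern_string(seed)
  wins <- cpp_seed_windows(reads, s, as.integer(flank),
                           as.integer(max_mismatch),
                           strand_policy == "merge")
  if (length(wins) == 0L) stop("empty site set: no reads match the seed")
  w <- nchar(s) + 2L * flank
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(wins, "", fixed = TRUE))
  joint <- list()
  for (i in seq_len(w - 1L)) {
    fi <- factor(mat[, i], levels = bases)
    for (j in (i + 1L):w) {
      joint[[paste(i, j, sep = ",")]] <-
        unclass(table(fi, factor(mat[, j], levels = bases),
                      dnn = NULL))
    }
  }
  joint <- lapply(joint, function(m) {
    dimnames(m) <- list(bases, bases)
    m
  })
  list(width = w, n_sites = length(wins), joint = joint)
}

#' Dinucleotide dependency score of a joint distribution
#'
#' The fraction of counts mispredicted when a mononucleotide model (the
#' product of the joint's marginals) is used to predict the dinucleotide
#' counts at a position pair, scaled so that 0% means the bases bind
#' independently and 100% means half of all counts are mispredicted.  The
#' mispredicted fraction is the total variation distance
#' `(1/2) * sum |joint - marginal product|`, and the score is 200 times it.
#'
#' @param joint 4 x 4 matrix of dinucleotide frequencies (sums to 1) or
#'   counts (normalized internally when `counts = TRUE`).
#' @param counts Set `TRUE` to normalize a count matrix first.
#' @param clip Cap the score at 100 (a fully coupled 4-state diagonal joint
#'   exceeds 100 under this scaling).
#' @return Score in percent.
#' @examples
#' j <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
#' j["A", "A"] <- 0.5; j["T", "T"] <- 0.5
#' dependency_score(j)  # 100
#' @export
dependency_score <- function(joint, counts = FALSE, clip = FALSE) {
  m <- as.matrix(joint)
  stopifnot(identical(dim(m), c(4L, 4L)), all(m >= 0))
  if (counts) m <- m / sum(m)
  if (abs(sum(m) - 1) > 1e-6)
    stop("joint distribution must sum to 1 (or pass counts = TRUE)")
  pred <- outer(rowSums(m), colSums(m))
  tv <- 0.5 * sum(abs(m - pred))
  score <- 200 * tv
  if (clip) score <- min(score, 100)
  score
}

#' Pairwise dependency table for a binding site
#'
#' Computes, for every position pair of the seed window, the observed
#' joint dinucleotide distribution, the mononucleotide
#' (product-of-marginals) prediction, the scaled dependency score, and the
#' over/under-representation sign of every base pair (the dots of the
#' dependency heatmap).
#'
#' @inheritParams joint_pair_counts
#' @param clip Cap scores at 100.
#' @param eps Tolerance for calling a base pair over/under-represented.
#' @return An object of class `pair_dependency`: list with `width`,
#'   `n_sites`, `pairs` (per-pair list of `joint`, `predicted`, `score_pct`,
#'   `sign`) and `scores`, a w x w symmetric matrix of scores (diagonal NA).
#' @export
dependency_table <- function(reads, seed, flank = 0L, max_mismatch = 0L,
                             strand_policy = "merge", clip = FALSE,
                             eps = 1e-6) {
  jc <- joint_pair_counts(reads, seed, flank = flank,
                          max_mismatch = max_mismatch,
                          strand_policy = strand_policy)
  w <- jc$width
  scores <- matrix(NA_real_, w, w)
  pairs <- lapply(names(jc$joint), function(key) {
    ij <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    m <- jc$joint[[key]] / sum(jc$joint[[key]])
    pred <- outer(rowSums(m), colSums(m))
    sgn <- matrix("neutral", 4L, 4L, dimnames = dimnames(m))
    sgn[m > pred + eps] <- "over"
    sgn[m < pred - eps] <- "under"
    list(i = ij[1], j = ij[2], joint = m, predicted = pred,
         score_pct = dependency_score(m, clip = clip), sign = sgn)
  })
  names(pairs) <- names(jc$joint)
  for (p in pairs) {
    scores[p$i, p$j] <- p$score_pct
    scores[p$j, p$i] <- p$score_pct
  }
  structure(list(width = w, n_sites = jc$n_sites, pairs = pairs,
                 scores = scores),
            class = "pair_dependency")
}

#' @export
print.pair_dependency <- function(x, ...) {
  cat(sprintf("<pair dependency> width %d, %d sites; top pairs:\n",
              x$width, x$n_sites))
  sc <- vapply(x$pairs, `[[`, numeric(1), "score_pct")
  top <- head(sort(sc, decreasing = TRUE), 5L)
  for (k in names(top))
    cat(sprintf("  (%s): %.1f%%\n", k, top[[k]]))
  invisible(x)
}

#' Write a dependency table as TSV
#'
#' Columns `i`, `j`, `score_pct`; one row per position pair.
#'
#' @param table A `pair_dependency` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dependency_table <- function(table, path) {
  df <- do.call(rbind, lapply(table$pairs, function(p)
    data.frame(i = p$i, j = p$j, score_pct = p$score_pct)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
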