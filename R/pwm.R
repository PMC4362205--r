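# Background-corrected multinomial PWM construction around a seed.

#' Multinomial count matrix around a seed
#'
#' Aligns each read to the seed at its best-matching window (fewest
#' mismatches over the seed's defined bases; ties to the leftmost position,
#' then the forward strand; the full window of width `span + 2*flank` must
#' lie inside the read) and tallies base counts per window position under
#' the multinomial rule of order `n`: a window contributes to the cell
#' (base `b`, position `i`) when its base at `i` is `b` and it mismatches
#' the seed's defined bases at *other* positions in at most `n - 1` places.
#' Gap and flank positions are unconstrained.  Order 1 therefore counts
#' exact seed matches at every position, plus single-mismatch windows at
#' the mismatched position only.
#'
#' @param reads Character vector or [cycle_reads()].
#' @param seed Seed pattern (string or `gapped_pattern`), may be gapped.
#' @param order Multinomial order, >= 1.
#' @param flank Number of flanking positions on each side.
#' @param strand_policy `"merge"` (default) scans both strands.
#' @return 4 x w count matrix (rows A,C,G,T), w = span + 2*flank.
#' @examples
#' multinomial_matrix(c(rep("ACG", 5), rep("TCG", 2), "AGG"), "ACG")
#' @export
multinomial_matrix <- function(reads, seed, order = 1L, flank = 0L,
                               strand_policy = c("merge", "forward_only")) {
  strand_policy <- match.arg(strand_policy)
  reads <- as_reads(reads)
  s <- as_pattern_string(seed)
  w <- nchar(s) + 2L * flank
  if (any(nchar(reads) < w))
    stop("seed window (width ", w, ") is wider than some reads")
  stopifnot(order >= 1L, flank >= 0L)
  m <- cpp_multinomial_matrix(reads, s, as.integer(order), as.integer(flank),
                              strand_policy == "merge")
  dimnames(m) <- list(c("A", "C", "G", "T"), seq_len(w))
  m
}

#' Background-correct a multinomial count matrix
#'
#' `mode = "cycle0"` divides each observed cell by the matched-rule
#' expectation obtained by applying the same multinomial counting to the
#' unselected (cycle 0) reads, scaled to the observed total; a pseudocount
#' is added symmetrically to observed and background cells so that an
#' observed matrix identical to its background corrects to the uniform
#' matrix exactly and zero background cells never divide by zero.
#' `mode = "uniform"` divides by 0.25 (a no-op after renormalization);
#' `mode = "none"` returns observed column proportions.  `method =
#' "subtract"` replaces the ratio by `max(observed - background, 0)`.
#'
#' @param observed 4 x w count matrix from [multinomial_matrix()].
#' @param background Cycle-0 reads (for `mode = "cycle0"`), or a 4 x w
#'   background count matrix.
#' @param mode `"cycle0"`, `"uniform"` or `"none"`.
#' @param seed,order,flank,strand_policy Passed to [multinomial_matrix()]
#'   when `background` is a read set.
#' @param pseudocount Added to observed and background cells before the
#'   ratio; default 1.
#' @param method `"divide"` (default) or `"subtract"`.
#' @return 4 x w frequency matrix; columns sum to 1.
#' @export
background_correct <- function(observed, background = NULL,
                               mode = c("cycle0", "uniform", "none"),
                               seed = NULL, order = 1L, flank = 0L,
                               strand_policy = "merge",
                               pseudocount = 1, method = c("divide", "subtract")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  obs <- pwm_matrix(observed)
  if (sum(obs) == 0) stop("observed matrix is empty")
  if (mode == "none" || mode == "uniform") {
    f <- sweep(obs, 2L, colSums(obs), "/")
    return(f)
  }
  bg <- if (is.matrix(background) ||
            inherits(background, "selex_pwm")) {
    pwm_matrix(background)
  } else {
    if (is.null(background) || is.null(seed))
      stop("mode 'cycle0' needs background reads (plus the seed) or a ",
           "background matrix")
    multinomial_matrix(background, seed, order = order, flank = flank,
                       strand_policy = strand_policy)
  }
  if (!identical(dim(bg), dim(obs)))
    stop("background matrix dimensions do not match the observed matrix")
  bg_scaled <- bg * sum(obs) / max(sum(bg), .Machine$double.eps)
  corrected <- if (method == "divide") {
    (obs + pseudocount) / (bg_scaled + pseudocount)
  } else {
    pmax(obs - bg_scaled, 0)
  }
  cs <- colSums(corrected)
  cs[cs == 0] <- 1
  sweep(corrected, 2L, cs, "/")
}

#' Construct a SELEX PWM object
#'
#' Bundles a count matrix and frequency matrix with the seed, cycle,
#' multinomial order, flank and background metadata.
#'
#' @param counts 4 x w count matrix.
#' @param frequencies 4 x w frequency matrix (columns sum to 1); defaults
#'   to column proportions of `counts`.
#' @param seed Seed pattern string.
#' @param cycle SELEX cycle the counts came from.
#' @param order Multinomial order used.
#' @param flank Flank width used.
#' @param background_mode `"none"`, `"cycle0"` or `"uniform"`.
#' @return An object of class `selex_pwm`.
#' @export
selex_pwm <- function(counts, frequencies = NULL, seed = NA_character_,
                      cycle = NA_integer_, order = 1L, flank = 0L,
                      background_mode = "none") {
  counts <- pwm_matrix(counts)
  if (is.null(frequencies)) {
    cs <- colSums(counts)
    cs[cs == 0] <- 1
    frequencies <- sweep(counts, 2L, cs, "/")
  }
  stopifnot(identical(dim(counts), dim(frequencies)),
            all(counts >= 0),
            all(abs(colSums(frequencies) - 1) < 1e-9))
  structure(
    list(counts = counts, frequencies = frequencies,
         seed = if (is.na(seed)) seed else as_pattern_string(seed),
         cycle_used = as.integer(cycle),
         multinomial_order = as.integer(order),
         flank = as.integer(flank),
         background_mode = background_mode),
    class = "selex_pwm"
  )
}

#' @export
print.selex_pwm <- function(x, ...) {
  cat(sprintf(
    "<selex PWM> width %d | seed %s | cycle %s | multinomial %d | flank %d | background %s\n",
    ncol(x$counts), x$seed, x$cycle_used, x$multinomial_order, x$flank,
    x$background_mode))
  print(round(x$frequencies, 3))
  invisible(x)
}

#' @export
dim.selex_pwm <- function(x) dim(x$counts)

#' Build a background-corrected multinomial PWM
#'
#' Composition of [multinomial_matrix()] and [background_correct()] with
#' metadata recorded in the result.
#'
#' @inheritParams multinomial_matrix
#' @inheritParams background_correct
#' @param cycle Cycle index recorded in the result (taken from `reads` when
#'   it is a [cycle_reads()] object).
#' @return A [selex_pwm()] object.
#' @export
build_pwm <- function(reads, seed, order = 1L, flank = 0L,
                      background = NULL,
                      background_mode = c("none", "cycle0", "uniform"),
                      strand_policy = "merge", pseudocount = 1,
                      method = "divide", cycle = NULL) {
  background_mode <- match.arg(background_mode)
  if (is.null(cycle))
    cycle <- if (inherits(reads, "cycle_reads")) reads$cycle else NA_integer_
  counts <- multinomial_matrix(reads, seed, order = order, flank = flank,
                               strand_policy = strand_policy)
  freq <- background_correct(counts, background = background,
                             mode = background_mode, seed = seed,
                             order = order, flank = flank,
                             strand_policy = strand_policy,
                             pseudocount = pseudocount, method = method)
  selex_pwm(counts, freq, seed = as_pattern_string(seed), cycle = cycle,
            order = order, flank = flank, background_mode = background_mode)
}

pwm_frequencies <- function(pwm) {
  if (inherits(pwm, "selex_pwm")) return(pwm$frequencies)
  m <- pwm_matrix(pwm)
  cs <- colSums(m)
  if (all(abs(cs - 1) < 1e-6)) return(m)
  cs[cs == 0] <- 1
  sweep(m, 2L, cs, "/")
}

pwm_information <- function(freq) {
  # per-column information content in bits
  apply(freq, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

revcomp_pwm_matrix <- function(m) {
  m <- m[4:1, ncol(m):1, drop = FALSE]
  dimnames(m) <- list(c("A", "C", "G", "T"), seq_len(ncol(m)))
  m
}

#' Classify a PWM's site structure
#'
#' Heuristic classification of a binding model into non-repetitive sites
#' (monomer) and sites with two, three or four similar subsequences (dimer,
#' trimer, dimer of dimers).  The PWM's most informative contiguous
#' subregion (the core) is slid against the full PWM on both strands; the
#' number of non-overlapping placements whose column-wise correlation with
#' the core exceeds `threshold` determines the class.
#'
#' @param pwm A [selex_pwm()] or 4 x w matrix.
#' @param core_width Width of the core subregion; default
#'   `min(5, floor(w/2) + 1)` capped at w.
#' @param threshold Mean column correlation required to call a repeat.
#' @return One of `"monomer"`, `"dimer"`, `"trimer"`, `"dimer_of_dimers"`.
#' @export
classify_site_structure <- function(pwm, core_width = NULL, threshold = 0.8) {
  f <- pwm_frequencies(pwm)
  w <- ncol(f)
  stopifnot(w >= 4L)
  if (is.null(core_width)) core_width <- max(3L, min(5L, w))
  core_width <- min(core_width, w)
  ic <- pwm_information(f)
  sums <- vapply(seq_len(w - core_width + 1L),
                 function(i) sum(ic[i:(i + core_width - 1L)]), numeric(1))
  ci <- which.max(sums)
  core <- f[, ci:(ci + core_width - 1L), drop = FALSE]
  core_rc <- revcomp_pwm_matrix(core)
  col_cor <- function(a, b) {
    v <- vapply(seq_len(ncol(a)), function(j) {
      if (sd(a[, j]) < 1e-12 || sd(b[, j]) < 1e-12) {
        # flat columns: count as matching if both flat
        as.numeric(sd(a[, j]) < 1e-12 && sd(b[, j]) < 1e-12)
      } else cor(a[, j], b[, j])
    }, numeric(1))
    mean(v)
  }
  pos <- seq_len(w - core_width + 1L)
  scores <- vapply(pos, function(i) {
    win <- f[, i:(i + core_width - 1L), drop = FALSE]
    max(col_cor(core, win), col_cor(core_rc, win))
  }, numeric(1))
  hit <- pos[scores >= threshold]
  # greedy non-overlapping selection, best scores first
  hit <- hit[order(-scores[scores >= threshold], hit)]
  sel <- integer(0)
  for (h in hit) {
    if (all(abs(h - sel) >= core_width)) sel <- c(sel, h)
  }
  k <- min(length(sel), 4L)
  c("monomer", "dimer", "trimer", "dimer_of_dimers")[max(k, 1L)]
}
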