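# Independent brute-force oracles used across the suite.  These are
# deliberately naive re-derivations from the definitions (string padding,
# double loops) and share no code with the package internals.

BASES <- c("A", "C", "G", "T")

r_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", n = "n")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Huddinge distance by definition: d - a with a maximized over all rigid
# offsets of p2 against p1.
r_huddinge <- function(p1, p2, merge = TRUE) {
  one <- function(a, b) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    d <- max(sum(av != "n"), sum(bv != "n"))
    best <- 0
    for (off in -(length(bv) - 1):(length(av) - 1)) {
      ia <- seq_along(av)
      ib <- ia - off
      ok <- ib >= 1 & ib <= length(bv)
      m <- sum(av[ia[ok]] != "n" & av[ia[ok]] == bv[ib[ok]])
      best <- max(best, m)
    }
    d - best
  }
  if (merge) min(one(p1, p2), one(p1, r_revcomp(p2))) else one(p1, p2)
}

# All canonical patterns with a single internal gap within bounds.
r_enumerate_patterns <- function(min_def = 1, max_def = 4, max_gap = 2,
                                 strand_canonical = FALSE) {
  out <- character(0)
  for (d in min_def:max_def) {
    words <- do.call(paste0, do.call(expand.grid,
                                     c(rep(list(BASES), d),
                                       stringsAsFactors = FALSE)))
    out <- c(out, words)
    if (d >= 2 && max_gap >= 1) {
      for (g in 1:max_gap) for (k in 1:(d - 1)) {
        out <- c(out, paste0(substr(words, 1, k), strrep("n", g),
                             substr(words, k + 1, d)))
      }
    }
  }
  if (strand_canonical) {
    rc <- vapply(out, r_revcomp, character(1))
    out <- unique(pmin(out, rc))
  }
  unique(out)
}

# Occurrence counting by definition: slide each pattern over each read.
r_count_patterns <- function(reads, patterns, per_read = TRUE,
                             merge = TRUE) {
  hits <- function(read, pat) {
    pv <- strsplit(pat, "")[[1]]
    rv <- strsplit(read, "")[[1]]
    n <- 0
    if (length(rv) >= length(pv)) {
      for (st in 1:(length(rv) - length(pv) + 1)) {
        win <- rv[st:(st + length(pv) - 1)]
        if (all(pv == "n" | pv == win)) n <- n + 1
      }
    }
    n
  }
  sapply(patterns, function(pat) {
    tot <- 0
    for (read in reads) {
      k <- hits(read, pat)
      if (merge && r_revcomp(pat) != pat) k <- k + hits(read, r_revcomp(pat))
      tot <- tot + if (per_read) as.numeric(k > 0) else k
    }
    tot
  })
}

# Local-maxima predicate applied literally to every pattern of a space.
r_local_maxima <- function(space, counts, theta, min_count, merge = TRUE) {
  cnt <- function(p) if (p %in% names(counts)) counts[[p]] else 0
  ndef <- function(p) nchar(gsub("n", "", p))
  keep <- character(0)
  for (p in space) {
    cp <- cnt(p)
    if (cp < min_count) next
    nb <- space[vapply(space, function(q)
      r_huddinge(p, q, merge) == 1, logical(1))]
    ok <- TRUE
    for (q in nb) {
      cq <- cnt(q)
      if (ndef(q) == ndef(p) && cq >= cp) ok <- FALSE
      if (ndef(q) == ndef(p) - 1 && !(cp > theta * cq)) ok <- FALSE
      if (ndef(q) == ndef(p) + 1 && cq > theta * cp) ok <- FALSE
      if (!ok) break
    }
    if (ok) keep <- c(keep, p)
  }
  keep
}

# Multinomial matrix by definition (forward strand): per read pick the
# best window, then apply the per-cell mismatch rule.
r_multinomial <- function(reads, seed, order = 1, flank = 0) {
  sv <- strsplit(seed, "")[[1]]
  span <- length(sv)
  w <- span + 2 * flank
  m <- matrix(0, 4, w, dimnames = list(BASES, 1:w))
  for (read in reads) {
    rv <- strsplit(read, "")[[1]]
    best <- NULL
    for (st in 1:(length(rv) - w + 1)) {
      win <- rv[st:(st + w - 1)]
      mis <- sum(sv != "n" & win[(flank + 1):(flank + span)] != sv)
      if (is.null(best) || mis < best$mis) best <- list(mis = mis, win = win)
    }
    if (best$mis > order) next
    for (i in 1:w) {
      si <- i - flank
      others <- best$mis
      if (si >= 1 && si <= span && sv[si] != "n" && best$win[i] != sv[si])
        others <- others - 1
      if (others <= order - 1)
        m[best$win[i], i] <- m[best$win[i], i] + 1
    }
  }
  m
}

# Gotoh local alignment with affine gaps, mirroring blastp-like scoring:
# opening a gap of length L costs open + L * extend.
r_local_align_score <- function(a, b, submat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i - 1, j - 1] + s,
                     Y[i - 1, j - 1] + s)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Near-one-hot PWM spelling a word.
onehot_pwm <- function(word, p = 0.99) {
  m <- matrix((1 - p) / 3, 4, nchar(word),
              dimnames = list(BASES, 1:nchar(word)))
  s <- strsplit(word, "")[[1]]
  for (i in seq_along(s)) m[s[i], i] <- p
  m
}

# Small deterministic read generator for fixtures.
random_reads <- function(n, len, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), character(1))
}
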