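# Synthetic HT-SELEX: barcoded randomized ligands enriched over selection
# cycles by a planted binding model with known ground truth.

#' Binding-site components for the SELEX simulator
#'
#' A ground-truth model mixes one or more site components.  `site_pwm()`
#' plants a mononucleotide PWM; `site_coupled()` additionally couples one
#' position pair through a 4 x 4 joint distribution (a dinucleotide
#' preference a PWM cannot express); `site_consensus()` plants a gapped
#' consensus, optionally with several spacing/orientation variants, through
#' near-one-hot PWMs (`match_prob` at defined bases, uniform at gaps).
#'
#' @param pwm 4 x w frequency (or count) matrix, rows A,C,G,T.
#' @param weight Mixture weight of the component.
#' @param pair Integer pair `c(i, j)` of coupled positions.
#' @param joint 4 x 4 joint distribution for the coupled pair.
#' @param variants Character vector of gapped consensus patterns.
#' @param match_prob Probability of the consensus base at defined
#'   positions.
#' @return A `site_component` list.
#' @export
site_pwm <- function(pwm, weight = 1) {
  structure(list(type = "pwm", pwm = pwm_frequencies(pwm), weight = weight),
            class = "site_component")
}

#' @rdname site_pwm
#' @export
site_coupled <- function(pwm, pair, joint, weight = 1) {
  f <- pwm_frequencies(pwm)
  joint <- joint / sum(joint)
  stopifnot(length(pair) == 2L, pair[1] < pair[2], pair[2] <= ncol(f),
            identical(dim(as.matrix(joint)), c(4L, 4L)))
  structure(list(type = "coupled", pwm = f, pair = as.integer(pair),
                 joint = as.matrix(joint), weight = weight),
            class = "site_component")
}

#' @rdname site_pwm
#' @export
site_consensus <- function(variants, match_prob = 0.97, weight = 1) {
  pwms <- lapply(variants, function(v) {
    s <- strsplit(as_pattern_string(v), "", fixed = TRUE)[[1]]
    m <- matrix(1 / 4, 4L, length(s),
                dimnames = list(c("A", "C", "G", "T"), seq_along(s)))
    for (i in seq_along(s)) if (s[i] != "n") {
      m[, i] <- (1 - match_prob) / 3
      m[s[i], i] <- match_prob
    }
    m
  })
  structure(list(type = "consensus", variants = variants, pwms = pwms,
                 weight = weight),
            class = "site_component")
}

#' Ground-truth model for a synthetic SELEX experiment
#'
#' @param components List of `site_component`s; weights are normalized to
#'   sum to 1.
#' @param selection_strength Non-negative selection strength; 0 means no
#'   selection (the null).
#' @param cycles Number of selection cycles (>= 1).
#' @param reads_per_cycle Reads sampled per cycle.
#' @param design [ligand_design()] describing the ligand.
#' @param rng_seed Integer seed; the whole experiment is reproducible from
#'   it.
#' @return A `ground_truth_model`.
#' @export
ground_truth_model <- function(components, selection_strength = 5,
                               cycles = 3L, reads_per_cycle = 50000L,
                               design = ligand_design(), rng_seed = 1L) {
  if (inherits(components, "site_component")) components <- list(components)
  stopifnot(length(components) >= 1L, selection_strength >= 0, cycles >= 1L)
  wsum <- sum(vapply(components, `[[`, numeric(1), "weight"))
  components <- lapply(components, function(cmp) {
    cmp$weight <- cmp$weight / wsum
    cmp
  })
  structure(
    list(components = components,
         selection_strength = selection_strength,
         cycles = as.integer(cycles),
         reads_per_cycle = as.integer(reads_per_cycle),
         design = design, rng_seed = as.integer(rng_seed)),
    class = "ground_truth_model")
}

#' Sample the unselected initial library (cycle 0)
#'
#' @param n Number of reads.
#' @param design [ligand_design()].
#' @param rng_seed Integer seed (NULL: use the current RNG state).
#' @return A [cycle_reads()] with i.i.d. uniform reads of the randomized
#'   region length.
#' @export
sample_initial_library <- function(n, design = ligand_design(),
                                   rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  L <- design$random_len
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), nrow = n)
  cycle_reads(apply(m, 1L, paste, collapse = ""), cycle = 0L)
}

component_affinity <- function(reads, cmp) {
  # max over placements/strands of the site probability ratio vs uniform
  # background, on the log scale
  max_odds <- function(f) {
    lo <- log(pmax(f, 1e-12) / 0.25)
    cpp_pwm_max_odds(reads, lo, TRUE)
  }
  if (cmp$type == "pwm") return(exp(max_odds(cmp$pwm)))
  if (cmp$type == "consensus") {
    s <- lapply(cmp$pwms, max_odds)
    return(exp(do.call(pmax, s)))
  }
  stop("unknown site component type: ", cmp$type)
}

# Coupled sites replace the product-of-marginals at one position pair by a
# joint table; the per-window adjustment is done in R (the simulator is not
# the inner loop of the analysis path).
coupled_affinity <- function(reads, cmp) {
  f <- cmp$pwm
  w <- ncol(f)
  i <- cmp$pair[1L]; j <- cmp$pair[2L]
  mi <- rowSums(cmp$joint); mj <- colSums(cmp$joint)
  lo <- log(pmax(f, 1e-12) / 0.25)
  bases <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  best <- rep(-Inf, length(reads))
  L <- nchar(reads[1L])
  enc <- function(x) {
    m <- matrix(bases[strsplit(paste(x, collapse = ""), "", fixed = TRUE)[[1]]],
                ncol = L, byrow = TRUE)
    m
  }
  for (strand in 1:2) {
    rs <- if (strand == 1L) reads
          else vapply(reads, revcomp_pattern, character(1), USE.NAMES = FALSE)
    em <- enc(rs)
    for (o in 0:(L - w)) {
      sc <- rep(0, length(reads))
      for (p in seq_len(w)) sc <- sc + lo[cbind(em[, o + p], p)]
      bi <- em[, o + i]; bj <- em[, o + j]
      adj <- log(pmax(cmp$joint[cbind(bi, bj)], 1e-12)) -
        log(pmax(mi[bi] * mj[bj], 1e-12))
      best <- pmax(best, sc + adj)
    }
  }
  exp(best)
}

model_affinity <- function(reads, model) {
  reads <- as_reads(reads)
  aff <- rep(0, length(reads))
  for (cmp in model$components) {
    a <- if (cmp$type == "coupled") coupled_affinity(reads, cmp)
         else component_affinity(reads, cmp)
    aff <- pmax(aff, cmp$weight * a)
  }
  aff
}

#' One round of selection and amplification
#'
#' Each read is retained with probability proportional to
#' `1 + selection_strength * affinity`, where affinity is the maximum over
#' placements, strands and model components of the component's site
#' probability ratio against the uniform background (winner-take-all
#' single-site binding).  Retained reads are resampled with replacement to
#' `reads_per_cycle`, emulating PCR amplification (duplicates are real and
#' intentional).
#'
#' @param reads A [cycle_reads()] (or character vector).
#' @param model A [ground_truth_model()].
#' @return A [cycle_reads()] for the next cycle.
#' @export
select_round <- function(reads, model) {
  rv <- as_reads(reads)
  if (length(rv) == 0L) stop("no reads to select from")
  aff <- model_affinity(rv, model)
  wt <- 1 + model$selection_strength * aff
  if (all(aff == 0) && model$selection_strength > 0) {
    warning("all affinities are zero; resampling uniformly")
    wt <- rep(1, length(rv))
  }
  keep <- runif(length(rv)) < wt / max(wt)
  pool <- rv[keep]
  if (length(pool) == 0L) pool <- rv
  nxt <- sample(pool, model$reads_per_cycle, replace = TRUE)
  cyc <- if (inherits(reads, "cycle_reads")) reads$cycle + 1L else NA_integer_
  cycle_reads(nxt, cycle = cyc,
              experiment_id = if (inherits(reads, "cycle_reads"))
                reads$experiment_id else "")
}

#' Simulate a whole SELEX experiment
#'
#' Samples the initial library and chains [select_round()] for
#' `model$cycles` rounds; fully reproducible from `model$rng_seed`.
#'
#' @param model A [ground_truth_model()].
#' @return List of [cycle_reads()] for cycles 0..K, with the model attached
#'   as attribute `ground_truth`.
#' @export
simulate_experiment <- function(model) {
  set.seed(model$rng_seed)
  cyc <- sample_initial_library(model$reads_per_cycle, model$design,
                                rng_seed = NULL)
  out <- vector("list", model$cycles + 1L)
  out[[1L]] <- cyc
  for (k in seq_len(model$cycles)) {
    cyc <- select_round(cyc, model)
    out[[k + 1L]] <- cyc
  }
  names(out) <- paste0("cycle", 0:model$cycles)
  attr(out, "ground_truth") <- model
  out
}

#' Fraction of reads containing a pattern
#'
#' Convenience for enrichment-monotonicity checks: the fraction of reads
#' with at least one match of the (possibly gapped) pattern, strand-merged.
#'
#' @param reads [cycle_reads()] or character vector.
#' @param pattern Gapped pattern string.
#' @return Fraction between 0 and 1.
#' @export
pattern_read_fraction <- function(reads, pattern) {
  rv <- as_reads(reads)
  s <- as_pattern_string(pattern)
  wins <- cpp_seed_windows(rv, s, 0L, 0L, TRUE)
  length(wins) / length(rv)
}
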