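# The central fitting interface: from enriched-cycle reads to a binding
# model (seed, PWM, dependency structure) with the usual model methods.

#' Fit a binding model to SELEX reads
#'
#' Runs the core estimation path on one experiment: counts gapped
#' subsequences, discovers local-maxima seeds (Autoseed), builds the
#' background-corrected multinomial PWM around the chosen seed, and
#' quantifies pairwise base dependencies within the site.
#'
#' @param reads Enriched-cycle reads ([cycle_reads()] or character vector).
#' @param cycle0 Optional unselected (cycle 0) reads for background
#'   correction; when supplied, `background_mode` defaults to `"cycle0"`.
#' @param seed `"auto"` (default) uses the rank-1 Autoseed local maximum;
#'   or a gapped pattern string to bypass seed discovery (the place for
#'   expert-refined seeds).
#' @param theta,min_count,max_candidates Autoseed parameters, see
#'   [find_local_maxima()].
#' @param min_defined,max_defined,max_gap Pattern-space bounds, see
#'   [count_patterns()].
#' @param order Multinomial order for the PWM.
#' @param flank Flanking positions added on each side of the seed.
#' @param background_mode `"none"`, `"cycle0"` or `"uniform"`.
#' @param strand_policy `"merge"` or `"forward_only"`.
#' @param top Maximum number of ranked seed models kept.
#' @return An object of class `selex_fit` with components `pwm`
#'   ([selex_pwm()]), `seeds` (annotated `seed_models`), `dependency`
#'   ([dependency_table()]), `site_structure`, `counts`
#'   (`pattern_count_table`) and `call`.
#' @examples
#' \donttest{
#' sim <- simulate_experiment(ground_truth_model(
#'   site_consensus("GGCGTG"), reads_per_cycle = 2000, rng_seed = 7))
#' fit <- selex_fit(sim$cycle3, cycle0 = sim$cycle0,
#'                  max_defined = 6, max_gap = 2)
#' fit
#' coef(fit)[, 1:4]
#' }
#' @export
selex_fit <- function(reads, cycle0 = NULL, seed = "auto",
                      theta = 0.5, min_count = 10, max_candidates = Inf,
                      min_defined = 4L, max_defined = 8L, max_gap = 10L,
                      order = 1L, flank = 2L,
                      background_mode = NULL,
                      strand_policy = c("merge", "forward_only"),
                      top = 25L) {
  strand_policy <- match.arg(strand_policy)
  cl <- match.call()
  if (is.null(background_mode))
    background_mode <- if (is.null(cycle0)) "none" else "cycle0"

  counts <- count_patterns(reads, min_defined = min_defined,
                           max_defined = max_defined, max_gap = max_gap,
                           strand_policy = strand_policy)
  seeds <- NULL
  if (identical(seed, "auto")) {
    mx <- find_local_maxima(counts, theta = theta, min_count = min_count,
                            max_candidates = max_candidates)
    if (nrow(mx) == 0L)
      stop("no local maxima found; lower min_count or supply a seed")
    if (is.finite(top) && nrow(mx) > top) {
      at <- attributes(mx)
      mx <- mx[seq_len(top), , drop = FALSE]
      attributes(mx) <- modifyList(at, list(row.names = rownames(mx)))
    }
    seeds <- pick_primary_and_secondary(mx)
    seed <- seeds$pattern[1L]
  } else {
    seed <- as_pattern_string(seed)
    seeds <- structure(
      data.frame(rank = 1L, pattern = seed,
                 count = NA_real_, role = "primary",
                 relation_to_primary = "none",
                 stringsAsFactors = FALSE),
      class = c("seed_models", "data.frame"))
  }
  pwm <- build_pwm(reads, seed, order = order, flank = flank,
                   background = cycle0, background_mode = background_mode,
                   strand_policy = strand_policy)
  dep <- dependency_table(reads, seed, flank = flank,
                          strand_policy = strand_policy)
  structure(
    list(pwm = pwm, seeds = seeds, dependency = dep,
         site_structure = classify_site_structure(pwm),
         counts = counts, strand_policy = strand_policy, call = cl),
    class = "selex_fit")
}

#' @export
print.selex_fit <- function(x, ...) {
  cat("SELEX binding model\n")
  cat(sprintf("  seed: %s (%s)\n", x$pwm$seed, x$site_structure))
  cat(sprintf("  PWM: width %d, multinomial order %d, flank %d, background %s\n",
              ncol(x$pwm$counts), x$pwm$multinomial_order, x$pwm$flank,
              x$pwm$background_mode))
  cat(sprintf("  seed models: %d (%d secondary)\n", nrow(x$seeds),
              sum(x$seeds$role == "secondary")))
  sc <- x$dependency$scores
  cat(sprintf("  max pairwise dependency: %.1f%%\n", max(sc, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.selex_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.selex_fit")
}

#' @export
print.summary.selex_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nRanked seed models:\n")
  print.data.frame(head(as.data.frame(f$seeds), 10L))
  cat("\nPWM frequencies:\n")
  print(round(f$pwm$frequencies, 3))
  invisible(x)
}

#' @describeIn selex_fit Frequency matrix of the fitted PWM.
#' @param object,x A `selex_fit`.
#' @param ... Unused.
#' @export
coef.selex_fit <- function(object, ...) object$pwm$frequencies

#' @describeIn selex_fit Maximum log2-odds PWM match score per new read.
#' @param newdata Character vector (or [cycle_reads()]) of sequences to
#'   score.
#' @export
predict.selex_fit <- function(object, newdata, ...) {
  f <- object$pwm$frequencies
  lo <- log2((f + 0.01) / 0.25)
  as.numeric(cpp_pwm_max_odds(as_reads(newdata), lo,
                              object$strand_policy == "merge"))
}

#' @describeIn selex_fit Draw the fitted motif as a barcode or sequence
#'   logo using base graphics.
#' @param style `"barcode"` or `"sequence"`.
#' @export
plot.selex_fit <- function(x, style = c("barcode", "sequence"), ...) {
  style <- match.arg(style)
  f <- x$pwm$frequencies
  w <- ncol(f)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, w), ylim = c(0, 1))
  cols <- DEFAULT_BASE_COLORS
  if (style == "barcode") {
    for (j in seq_len(w)) {
      m <- max(f[, j])
      xx <- j - 1
      for (b in c("A", "C", "G", "T")) {
        bw <- f[b, j]
        if (bw > 0)
          graphics::rect(xx, 0, xx + bw, m,
                         col = blend_to_white(cols[[b]], m), border = NA)
        xx <- xx + bw
      }
    }
  } else {
    ic <- pwm_information(f)
    for (j in seq_len(w)) {
      y <- 0
      for (b in rownames(f)[order(f[, j])]) {
        hb <- f[b, j] * ic[j] / 2
        if (hb > 0) {
          graphics::rect(j - 1 + 0.1, y, j - 0.1, y + hb,
                         col = cols[[b]], border = NA)
          if (hb > 0.04)
            graphics::text(j - 0.5, y + hb / 2, b, col = "white", cex = 0.7)
          y <- y + hb
        }
      }
    }
  }
  graphics::axis(1, at = seq_len(w) - 0.5, labels = seq_len(w))
  graphics::title(xlab = "position",
                  ylab = if (style == "barcode") "max base frequency"
                         else "bits / 2",
                  main = sprintf("seed %s", x$pwm$seed))
  invisible(x)
}

#' @describeIn selex_fit Simulate SELEX reads from the fitted PWM (the
#'   fitted model becomes the ground truth of a synthetic experiment).
#' @param nsim Number of cycles to simulate.
#' @param seed RNG seed for the simulation.
#' @param n_reads Reads per cycle.
#' @param selection_strength Selection strength of the synthetic rounds.
#' @export
simulate.selex_fit <- function(object, nsim = 1, seed = 1L,
                               n_reads = 10000L, selection_strength = 5,
                               ...) {
  w <- ncol(object$pwm$frequencies)
  design <- ligand_design(random_len = max(20L, w))
  model <- ground_truth_model(site_pwm(object$pwm$frequencies),
                              selection_strength = selection_strength,
                              cycles = nsim, reads_per_cycle = n_reads,
                              design = design, rng_seed = seed)
  simulate_experiment(model)
}
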