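# Autoseed local-maxima discovery and secondary-model classification.

bounds45 <- list(min_defined = 2L, max_defined = 5L, max_gap = 1L)

make_table <- function(counts, policy = "forward_only",
                       bounds = bounds45) {
  structure(data.frame(pattern = names(counts), count = unname(counts),
                       stringsAsFactors = FALSE),
            class = c("pattern_count_table", "data.frame"),
            strand_policy = policy, bounds = bounds)
}

test_that("a pattern dominating its whole neighbourhood is the sole maximum", {
  nb <- huddinge_neighbors("GACGTC", 6, 1, "forward_only")
  counts <- setNames(c(100, sample(10:50, length(nb), replace = TRUE)),
                     c("GACGTC", nb))
  tab <- make_table(counts, bounds = list(min_defined = 2L,
                                          max_defined = 6L, max_gap = 1L))
  mx <- find_local_maxima(tab, theta = 0.5, min_count = 10)
  expect_equal(mx$pattern[1], "GACGTC")
  expect_equal(mx$rank[1], 1L)
})

test_that("the theta rule lets a longer extension dominate its prefix", {
  # ACGTA count 60 beats theta * 100 = 50, so ACGT is not reported
  tab <- make_table(c(ACGT = 100, ACGTA = 60))
  mx <- find_local_maxima(tab, theta = 0.5, min_count = 10)
  expect_true("ACGTA" %in% mx$pattern)
  expect_false("ACGT" %in% mx$pattern)

  # with a weak extension (40 <= 50) the shorter pattern survives instead
  tab2 <- make_table(c(ACGT = 100, ACGTA = 40))
  mx2 <- find_local_maxima(tab2, theta = 0.5, min_count = 10)
  expect_true("ACGT" %in% mx2$pattern)
  expect_false("ACGTA" %in% mx2$pattern)
})

test_that("equal-length ties break dominance (strict inequality)", {
  tab <- make_table(c(ACGT = 100, ACGA = 100))
  mx <- find_local_maxima(tab, theta = 0.5, min_count = 10)
  expect_false("ACGT" %in% mx$pattern)
  expect_false("ACGA" %in% mx$pattern)
})

test_that("local maxima equal exhaustive predicate evaluation", {
  space <- r_enumerate_patterns(2, 3, 1)
  set.seed(31)
  for (rep in 1:4) {
    pats <- sample(space, 40)
    counts <- setNames(sample(5:200, 40, replace = TRUE), pats)
    tab <- make_table(counts,
                      bounds = list(min_defined = 2L, max_defined = 3L,
                                    max_gap = 1L))
    mx <- find_local_maxima(tab, theta = 0.5, min_count = 10)
    want <- r_local_maxima(pats, as.list(counts), theta = 0.5,
                           min_count = 10, merge = FALSE)
    expect_setequal(mx$pattern, want)
    # determinism
    mx2 <- find_local_maxima(tab, theta = 0.5, min_count = 10)
    expect_identical(as.data.frame(mx), as.data.frame(mx2))
  }
})

test_that("reported maxima strictly dominate their equal-length neighbours", {
  reads <- random_reads(500, 16, seed = 41)
  tab <- count_patterns(reads, 4, 5, 1)
  mx <- find_local_maxima(tab, min_count = 2)
  cnt <- setNames(tab$count, tab$pattern)
  for (p in head(mx$pattern, 10)) {
    nb <- huddinge_neighbors(p, 5, 1)
    nb <- nb[nchar(gsub("n", "", nb)) == nchar(gsub("n", "", p))]
    present <- nb[nb %in% names(cnt)]
    if (length(present))
      expect_true(all(cnt[present] < cnt[[p]]))
  }
})

test_that("planted motifs are recovered as the top local maximum", {
  model <- ground_truth_model(site_consensus("GGCGTG"),
                              selection_strength = 5, cycles = 3,
                              reads_per_cycle = 5000, rng_seed = 42)
  sim <- simulate_experiment(model)
  seeds <- autoseed(sim$cycle3, min_defined = 5, max_defined = 7,
                    max_gap = 2)
  expect_equal(seeds$pattern[1], canonical_strand("GGCGTG"))
  expect_equal(seeds$role[1], "primary")
})

test_that("secondary-model relations are classified by structure", {
  expect_equal(classify_model_relation("TAATnnATTA", "TAATnnnATTA"),
               "spacing_orientation")
  # orientation flip of one half-site
  expect_equal(classify_model_relation("TAATnnTAAT", "TAATnnATTA"),
               "spacing_orientation")
  expect_equal(classify_model_relation("GACGTC", "ACGT"), "flank")
  expect_equal(classify_model_relation("ACGT", "GACGTC"), "flank")
  expect_equal(classify_model_relation("AACGTT", "AAGCTT"), "dinucleotide")
  expect_equal(classify_model_relation("AAAAAA", "CCGGCC"), "unrelated")
})

test_that("primary/secondary annotation follows rank and the classifier", {
  mx <- make_seed_df <- structure(
    data.frame(rank = 1:3,
               pattern = c("TAATnnATTA", "TAATnnnATTA", "GTAATnnATTAC"),
               count = c(90, 40, 30), stringsAsFactors = FALSE),
    class = c("seed_models", "data.frame"))
  ann <- pick_primary_and_secondary(mx)
  expect_equal(ann$role, c("primary", "secondary", "secondary"))
  expect_equal(ann$relation_to_primary,
               c("none", "spacing_orientation", "flank"))

  single <- structure(data.frame(rank = 1L, pattern = "ACGTAC", count = 50,
                                 stringsAsFactors = FALSE),
                      class = c("seed_models", "data.frame"))
  one <- pick_primary_and_secondary(single)
  expect_equal(one$role, "primary")
  expect_error(pick_primary_and_secondary(single[0, ]), "no local maxima")
})
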