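# Motif and protein-domain similarity, clustering, networks, k-mer tables.

test_that("gapped k-mer vectors: uniform PWMs, top k-mer, strand symmetry", {
  uni <- matrix(0.25, 4, 8, dimnames = list(BASES, 1:8))
  v <- gapped_kmer_score_vector(uni, k = 6, max_gap = 2)
  expect_true(all(abs(v - v[1]) < 1e-12))  # no preference
  expect_length(v, 4^6 * 3)

  p <- onehot_pwm("GACGTC")
  v2 <- gapped_kmer_score_vector(p, k = 6, max_gap = 0)
  expect_equal(names(v2)[which.max(v2)], "GACGTC")

  # exact reverse-complement invariance of the whole vector
  prc <- p[4:1, 6:1]
  rownames(prc) <- BASES
  expect_equal(gapped_kmer_score_vector(p, 6, 2),
               gapped_kmer_score_vector(prc, 6, 2))

  expect_error(gapped_kmer_score_vector(onehot_pwm("ACGT"), k = 6),
               "smaller than k")
})

test_that("motif similarity: self, reverse complement, unrelated", {
  p <- onehot_pwm("GACGTCAA")
  expect_equal(motif_similarity(p, p, max_gap = 2), 1)
  prc <- p[4:1, 8:1]
  rownames(prc) <- BASES
  expect_equal(motif_similarity(p, prc, max_gap = 2), 1)

  q <- onehot_pwm("TTTTAGGC")
  s <- motif_similarity(p, q, max_gap = 2)
  expect_lt(abs(s), 0.5)

  uni <- matrix(0.25, 4, 8, dimnames = list(BASES, 1:8))
  expect_error(motif_similarity(p, uni, max_gap = 2), "degenerate")
})

test_that("similarity matrices are symmetric with unit diagonal", {
  pwms <- list(a = onehot_pwm("GACGTCAA"), b = onehot_pwm("TGACTCAT"),
               c = onehot_pwm("AAAGGTCA"))
  m <- motif_similarity_matrix(pwms, max_gap = 2)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(rownames(m), c("a", "b", "c"))
})

test_that("aa similarity follows the score x length / shorter formula", {
  s <- "MKVLAARWQNPFGHD"
  # identical sequences: L = n = shorter, so the score is the self score
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  self <- sum(B62[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])])
  expect_equal(aa_similarity_score(s, s), self)

  # oracle: Gotoh local alignment on a toy pair whose optimum spans the
  # full 8 residues without gaps (flanking residues score positively)
  a <- "MKVLAARW"
  b <- "MKVLHARW"
  got <- aa_similarity_score(a, b)
  S <- r_local_align_score(a, b, B62)
  expect_equal(got, S * 8 / 8)

  # multi-domain handling
  expect_equal(aa_similarity_score(c("MKVLAARW", "GGGGGG"), s),
               max(aa_similarity_score("MKVLAARW", s),
                   aa_similarity_score("GGGGGG", s)))
  expect_error(aa_similarity_score("", "MKV"))
})

test_that("clustering reproduces hand-computed average linkage", {
  # rows engineered so pairwise euclidean distances are 1, 5, sqrt(26)
  m <- rbind(x = c(1, 0, 0), y = c(1, 1, 0), z = c(1, 0, 5))
  colnames(m) <- c("a", "b", "c")
  tr <- cluster_motifs(m)
  hc <- attr(tr, "hclust")
  # x,y merge first at height 1; z joins at mean(d(x,z), d(y,z))
  expect_equal(hc$height[1], 1)
  expect_equal(hc$height[2], mean(c(5, sqrt(26))))
  expect_setequal(tr$tip.label, c("x", "y", "z"))

  # identical motifs merge first
  pwms <- list(m1 = onehot_pwm("GACGTCAA"), m2 = onehot_pwm("GACGTCAA"),
               m3 = onehot_pwm("TTTTAGGC"))
  sim <- motif_similarity_matrix(pwms, max_gap = 1)
  hc2 <- attr(cluster_motifs(sim), "hclust")
  first <- rownames(sim)[-hc2$merge[1, ]]
  expect_setequal(first, c("m1", "m2"))

  # Newick round-trip preserves the leaf set
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, c("x", "y", "z"))
})

test_that("network thresholding keeps isolated nodes and all edges", {
  sim <- matrix(c(1, .9, .1, .9, 1, .2, .1, .2, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  none <- motif_network(sim, threshold = 0.95)
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "nodes"), c("a", "b", "c"))

  full <- motif_network(sim, threshold = 0)
  expect_equal(nrow(full), 3L)  # n(n-1)/2

  one <- motif_network(sim, threshold = 0.5)
  expect_equal(one$from, "a")
  expect_equal(one$to, "b")

  # two planted clusters -> two connected components
  blk <- matrix(0.05, 6, 6)
  blk[1:3, 1:3] <- 0.9
  blk[4:6, 4:6] <- 0.9
  diag(blk) <- 1
  dimnames(blk) <- list(letters[1:6], letters[1:6])
  net <- motif_network(blk, threshold = 0.5)
  g <- igraph::graph_from_data_frame(net, directed = FALSE,
                                     vertices = attr(net, "nodes"))
  expect_equal(igraph::count_components(g), 2)

  # graphml export parses back with the same node count
  path <- tempfile(fileext = ".graphml")
  write_network(net, path, format = "graphml")
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g2), 6)
})

test_that("k-mer log-odds enrichment matches the pseudocount arithmetic", {
  k <- 3
  tails <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)),
                           BASES, paste0))
  early <- c(rep("AAA", 25), rep("CGT", 375))
  late <- c(rep("AAA", 100), rep("CGT", 300))
  tab <- kmer_enrichment_table(early, late, early, early, k = 3)
  row <- tab[tab$kmer == "AAA", ]
  want <- log2((100 + 1) / (400 + 64)) - log2((25 + 1) / (400 + 64))
  expect_equal(row$logodds_a, want)
  expect_equal(want, log2(101 / 26))          # ~2 in the large-count limit
  expect_equal(row$logodds_b, 0)              # identical early/late
  expect_error(kmer_enrichment_table(early, late, early, early, k = 5),
               "read length")
})
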