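# Motif-motif similarity via gapped-6-mer score vectors, protein-domain
# similarity, clustering, network export, and k-mer enrichment tables.

gapped_kmer_names <- function(k = 6L, max_gap = 10L) {
  half <- k %/% 2L
  bases <- c("A", "C", "G", "T")
  combos <- do.call(expand.grid,
                    c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE))
  words <- do.call(paste0, combos)  # first position varies fastest
  unlist(lapply(0:max_gap, function(g)
    paste0(substr(words, 1L, half),
           strrep("n", g),
           substr(words, half + 1L, k))),
    use.names = FALSE)
}

#' Gapped k-mer score vector of a PWM
#'
#' Scores every gapped k-mer (k/2 defined bases, a middle gap of 0 to
#' `max_gap`, then k/2 defined bases) against the PWM: the score is the
#' maximum over all rigid placements inside the PWM, on both strands, of
#' the summed log frequencies (plus pseudocount) at the k-mer's defined
#' positions.  Gap variants that do not fit inside the PWM score the
#' background value `k * log(0.25 + pseudocount)`.  These vectors put
#' motifs of different widths on a common axis for correlation.
#'
#' @param pwm A [selex_pwm()] or 4 x w matrix.
#' @param k Number of defined bases (even; default 6).
#' @param max_gap Largest middle gap considered.
#' @param pseudocount Added to frequencies before the log.
#' @return Named numeric vector over the fixed gapped k-mer enumeration;
#'   attribute `motif` carries an id when the input has one.
#' @export
gapped_kmer_score_vector <- function(pwm, k = 6L, max_gap = 10L,
                                     pseudocount = 0.01) {
  stopifnot(k %% 2L == 0L, k >= 2L)
  f <- pwm_frequencies(pwm)
  w <- ncol(f)
  if (w < k) stop("PWM width (", w, ") is smaller than k = ", k)
  half <- k %/% 2L
  lf <- log(f + pseudocount)
  bg <- k * log(0.25 + pseudocount)
  n_words <- 4L^k
  score_strand <- function(lfm) {
    out <- matrix(bg, nrow = n_words, ncol = max_gap + 1L)
    half_scores <- function(cols) {
      # summed log-frequencies for all 4^half words over given columns;
      # first column's base varies fastest
      s <- lfm[, cols[1L]]
      for (c2 in cols[-1L]) s <- outer(s, lfm[, c2], "+")
      as.vector(s)
    }
    for (g in 0:max_gap) {
      span <- k + g
      if (span > w) next
      best <- rep(-Inf, n_words)
      for (o in 1:(w - span + 1L)) {
        left <- half_scores(o:(o + half - 1L))
        right <- half_scores((o + half + g):(o + span - 1L))
        tot <- as.vector(outer(left, right, "+"))
        best <- pmax(best, tot)
      }
      out[, g + 1L] <- best
    }
    as.vector(out)
  }
  lf_rc <- log(revcomp_pwm_matrix(f) + pseudocount)
  v <- pmax(score_strand(lf), score_strand(lf_rc))
  names(v) <- gapped_kmer_names(k, max_gap)
  v
}

#' Motif similarity as gapped k-mer score correlation
#'
#' Pearson (default) correlation between the gapped k-mer score vectors of
#' two PWMs.  Because each vector takes the maximum over strands, the
#' similarity is exactly invariant to reverse-complementing either motif.
#'
#' @param pwm1,pwm2 PWMs ([selex_pwm()] or matrices).
#' @param k,max_gap,pseudocount Passed to [gapped_kmer_score_vector()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Similarity between -1 and 1.
#' @export
motif_similarity <- function(pwm1, pwm2, k = 6L, max_gap = 10L,
                             pseudocount = 0.01,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v1 <- gapped_kmer_score_vector(pwm1, k, max_gap, pseudocount)
  v2 <- gapped_kmer_score_vector(pwm2, k, max_gap, pseudocount)
  if (sd(v1) < 1e-12 || sd(v2) < 1e-12)
    stop("degenerate motif: zero-variance gapped k-mer score vector")
  cor(v1, v2, method = method)
}

#' Pairwise motif similarity matrix
#'
#' @param pwms Named list of PWMs.
#' @inheritParams motif_similarity
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
motif_similarity_matrix <- function(pwms, k = 6L, max_gap = 10L,
                                    pseudocount = 0.01,
                                    method = "pearson") {
  stopifnot(length(pwms) >= 1L)
  if (is.null(names(pwms))) names(pwms) <- paste0("motif", seq_along(pwms))
  vecs <- lapply(pwms, gapped_kmer_score_vector, k = k, max_gap = max_gap,
                 pseudocount = pseudocount)
  vm <- do.call(cbind, vecs)
  m <- cor(vm, method = method)
  dimnames(m) <- list(names(pwms), names(pwms))
  m
}

#' Amino-acid similarity score between DNA-binding domains
#'
#' Local alignment (BLOSUM62, affine gaps with open 11 / extend 1,
#' blastp-like defaults) of two protein sequences; the similarity is the
#' alignment score multiplied by the alignment length and divided by the
#' length of the shorter query sequence.  When a protein has several
#' domains, pass them as a character vector: `mode = "max_domain"` scores
#' all domain pairs and keeps the highest, `mode = "concatenate"` joins the
#' domains into a single sequence first.
#'
#' @param seq1,seq2 Protein sequences (character vectors; several elements
#'   = several domains).
#' @param mode `"max_domain"` (default) or `"concatenate"`.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Non-negative similarity score.
#' @export
aa_similarity_score <- function(seq1, seq2,
                                mode = c("max_domain", "concatenate"),
                                gap_opening = 11, gap_extension = 1) {
  mode <- match.arg(mode)
  stopifnot(length(seq1) >= 1L, length(seq2) >= 1L,
            all(nzchar(seq1)), all(nzchar(seq2)))
  if (mode == "concatenate") {
    seq1 <- paste(seq1, collapse = "")
    seq2 <- paste(seq2, collapse = "")
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  one <- function(a, b) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = get("BLOSUM62", envir = environment()),
      gapOpening = gap_opening, gapExtension = gap_extension)
    s <- Biostrings::score(aln)
    len <- nchar(as.character(Biostrings::alignedPattern(aln)))
    s * len / min(nchar(a), nchar(b))
  }
  max(vapply(seq1, function(a)
    max(vapply(seq2, function(b) one(a, b), numeric(1))), numeric(1)))
}

#' Cluster motifs by similarity
#'
#' Agglomerative clustering of the rows of a similarity matrix using the
#' euclidean distance metric with average linkage; the result is returned
#' as an `ape` phylogeny for Newick serialization.
#'
#' @param matrix Symmetric similarity matrix with row/column names.
#' @return An object of class `phylo` (see [ape::as.phylo()]); attribute
#'   `hclust` holds the underlying tree with merge heights.
#' @export
cluster_motifs <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2L)
  if (anyNA(matrix)) stop("similarity matrix contains NA")
  hc <- hclust(dist(matrix, method = "euclidean"), method = "average")
  tr <- ape::as.phylo(hc)
  attr(tr, "hclust") <- hc
  tr
}

#' Write a motif tree as Newick
#'
#' @param tree A `phylo` object from [cluster_motifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Threshold a similarity matrix into a network
#'
#' Draws an undirected edge between every pair of motifs whose similarity
#' reaches the threshold; isolated nodes are retained in the `nodes`
#' attribute.
#'
#' @param matrix Symmetric similarity matrix with names.
#' @param threshold Minimum similarity for an edge.
#' @return data.frame with columns `from`, `to`, `similarity`; attribute
#'   `nodes` lists all motif ids.
#' @export
motif_network <- function(matrix, threshold) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- paste0("motif", seq_len(nrow(matrix)))
  idx <- which(upper.tri(matrix) & matrix >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                      similarity = matrix[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "nodes") <- ids
  edges
}

#' Write a motif network as edge-list TSV or GraphML
#'
#' @param edges Edge data.frame from [motif_network()].
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = attr(edges, "nodes")))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' k-mer enrichment table for two experiments
#'
#' For every ungapped k-mer, the log-odds enrichment between an early and a
#' late SELEX cycle, computed per experiment as
#' `log2((count_late + 1)/(total_late + 4^k)) -
#'  log2((count_early + 1)/(total_early + 4^k))`,
#' where totals are summed k-mer occurrences.  Feeds the two-experiment
#' scatter plot; optional PWM match scores supply the colour scale.
#'
#' @param early_a,late_a Early/late cycle reads of experiment A.
#' @param early_b,late_b Early/late cycle reads of experiment B.
#' @param k k-mer length (default 10).
#' @param pwm_a,pwm_b Optional PWMs scored against each k-mer (max summed
#'   log-odds over placements and strands).
#' @param keep_all Keep k-mers absent from all four read sets.
#' @return data.frame with columns `kmer`, `logodds_a`, `logodds_b`, and
#'   `score_a`/`score_b` when PWMs are given.
#' @export
kmer_enrichment_table <- function(early_a, late_a, early_b, late_b, k = 10L,
                                  pwm_a = NULL, pwm_b = NULL,
                                  keep_all = FALSE) {
  count1 <- function(x) {
    x <- as_reads(x)
    if (any(nchar(x) < k)) stop("k = ", k, " exceeds some read lengths")
    Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(x), width = k, simplify.as = "collapse")
  }
  ca0 <- count1(early_a); ca1 <- count1(late_a)
  cb0 <- count1(early_b); cb1 <- count1(late_b)
  lo <- function(late, early)
    log2((late + 1) / (sum(late) + 4^k)) -
    log2((early + 1) / (sum(early) + 4^k))
  df <- data.frame(kmer = names(ca0),
                   logodds_a = lo(ca1, ca0),
                   logodds_b = lo(cb1, cb0),
                   stringsAsFactors = FALSE)
  if (!keep_all) {
    nz <- (ca0 + ca1 + cb0 + cb1) > 0
    df <- df[nz, , drop = FALSE]
  }
  score_kmers <- function(pwm, kmers) {
    f <- pwm_frequencies(pwm)
    lo_m <- log2((f + 0.01) / 0.25)
    if (ncol(f) <= k) as.numeric(cpp_pwm_max_odds(kmers, lo_m, TRUE))
    else {
      # k-mer shorter than PWM: scan the PWM with the k-mer via its one-hot
      # matrix is equivalent to scanning the k-mer sequence over reversed
      # roles; score each k-mer against every width-k sub-PWM
      subs <- lapply(1:(ncol(f) - k + 1L), function(o)
        lo_m[, o:(o + k - 1L), drop = FALSE])
      do.call(pmax, lapply(subs, function(m)
        as.numeric(cpp_pwm_max_odds(kmers, m, TRUE))))
    }
  }
  if (!is.null(pwm_a)) df$score_a <- score_kmers(pwm_a, df$kmer)
  if (!is.null(pwm_b)) df$score_b <- score_kmers(pwm_b, df$kmer)
  rownames(df) <- NULL
  df
}

#' Load an externally computed similarity matrix
#'
#' Motif similarities from external tools (e.g. SSTAT-style scores) can be
#' plugged in as a labelled TSV matrix and used with [cluster_motifs()],
#' [motif_network()] and [similarity_heatmap_2d()].
#'
#' @param path TSV file: header of ids, first column ids, numeric cells.
#' @return Symmetric numeric matrix.
#' @export
read_similarity_matrix <- function(path) {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                            check.names = FALSE))
  storage.mode(m) <- "double"
  m
}

#' Write a similarity matrix as TSV
#'
#' @param matrix Labelled numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(matrix, path) {
  df <- data.frame(id = rownames(matrix), matrix, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
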