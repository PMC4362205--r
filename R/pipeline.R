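# End-to-end pipeline: demux -> count -> autoseed -> pwm -> dependency ->
# logos, plus cross-experiment similarity outputs.

#' Read a pipeline run configuration
#'
#' YAML layout:
#' ```
#' output_dir: out
#' bounds: {min_defined: 4, max_defined: 6, max_gap: 2}
#' theta: 0.5
#' min_count: 10
#' experiments:
#'   - id: TF1
#'     reads: tf1_cycle3.fasta     # randomized regions (FASTA/FASTQ)
#'     cycle0: tf1_cycle0.fasta    # optional background reads
#'     cycle: 3
#'     seed: auto                  # or an explicit gapped pattern
#'     order: 1
#'     flank: 2
#' ```
#' An experiment table may instead be given as TSV with the same column
#' names (`id`, `reads`, `cycle0`, `cycle`, `seed`, `order`, `flank`).
#'
#' @param path YAML (or TSV) configuration file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    cfg <- yaml::read_yaml(path)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    cfg <- list(experiments = lapply(seq_len(nrow(tab)),
                                     function(i) as.list(tab[i, ])))
  }
  defaults <- list(output_dir = "selexmotif_out",
                   bounds = list(min_defined = 4L, max_defined = 6L,
                                 max_gap = 2L),
                   theta = 0.5, min_count = 10)
  cfg <- modifyList(defaults, cfg)
  if (is.null(cfg$experiments) || length(cfg$experiments) == 0L)
    stop("run config lists no experiments")
  for (e in cfg$experiments)
    if (is.null(e$id) || is.null(e$reads))
      stop("every experiment needs at least `id` and `reads`")
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Per experiment: pattern count table, ranked seed models, PWM (TSV +
#' MEME), dependency table, barcode and sequence logos, dependency heatmap.
#' Across experiments (when more than one): gapped-6-mer similarity matrix,
#' average-linkage dendrogram (Newick) and similarity network edge list.
#' Rerunning with the same configuration and inputs reproduces the outputs
#' byte for byte.
#'
#' @param config A `run_config` from [read_run_config()], or a list with
#'   the same structure.
#' @param output_dir Overrides `config$output_dir`.
#' @param verbose Log progress with `message()`.
#' @return Invisibly, a named list of per-experiment [selex_fit()] objects;
#'   artifact paths in attribute `files`.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = TRUE) {
  if (!inherits(config, "run_config")) class(config) <- "run_config"
  out <- output_dir %||% config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (verbose) message(sprintf(...))
  b <- config$bounds
  fits <- list()
  files <- character(0)
  emit <- function(path) { files <<- c(files, path); path }
  for (e in config$experiments) {
    log("[%s] reading inputs", e$id)
    reads <- cycle_reads(read_sequences(e$reads),
                         cycle = e$cycle %||% NA_integer_,
                         experiment_id = e$id)
    bg <- if (!is.null(e$cycle0) && nzchar(e$cycle0))
      cycle_reads(read_sequences(e$cycle0), cycle = 0L) else NULL
    seed <- e$seed %||% "auto"
    log("[%s] fitting binding model (seed: %s)", e$id, seed)
    fit <- tryCatch(
      selex_fit(reads, cycle0 = bg, seed = seed,
                theta = config$theta, min_count = config$min_count,
                min_defined = b$min_defined, max_defined = b$max_defined,
                max_gap = b$max_gap,
                order = e$order %||% 1L, flank = e$flank %||% 2L),
      error = function(err)
        stop("stage 'fit' failed for experiment '", e$id, "': ",
             conditionMessage(err), call. = FALSE))
    fits[[e$id]] <- fit
    pre <- file.path(out, e$id)
    write_count_table(fit$counts, emit(paste0(pre, "_counts.tsv")))
    write.table(as.data.frame(fit$seeds),
                emit(paste0(pre, "_seeds.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_pwm(fit$pwm, emit(paste0(pre, "_pwm.tsv")), format = "tsv")
    write_pwm(fit$pwm, emit(paste0(pre, "_pwm.meme")),
              format = "meme-minimal", name = e$id)
    write_dependency_table(fit$dependency,
                           emit(paste0(pre, "_dependency.tsv")))
    write_svg(barcode_logo(fit$pwm), emit(paste0(pre, "_barcode.svg")))
    write_svg(sequence_logo(fit$pwm), emit(paste0(pre, "_logo.svg")))
    write_svg(dependency_heatmap(fit$dependency),
              emit(paste0(pre, "_dependency.svg")))
  }
  if (length(fits) >= 2L) {
    log("cross-experiment similarity over %d motifs", length(fits))
    pwms <- lapply(fits, function(f) f$pwm)
    k <- min(6L, min(vapply(pwms, function(p) ncol(p$counts), integer(1))))
    if (k %% 2L == 1L) k <- k - 1L
    sim <- motif_similarity_matrix(pwms, k = k, max_gap = b$max_gap)
    write_similarity_matrix(sim, emit(file.path(out, "similarity.tsv")))
    write_newick(cluster_motifs(sim), emit(file.path(out, "motifs.nwk")))
    net <- motif_network(sim, threshold = 0.5)
    write_network(net, emit(file.path(out, "network.tsv")))
  }
  log("pipeline complete: %d files in %s", length(files), out)
  invisible(structure(fits, files = files, output_dir = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
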