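# Reading/writing the on-disk formats and binning raw reads by barcode.

#' Describe the SELEX ligand design
#'
#' HT-SELEX selection ligands carry a 6 bp barcode before and a 2-3 bp
#' barcode after a randomized region of 20 or 40 bp; demultiplexing
#' extracts the randomized region of reads whose barcodes match.
#'
#' @param five_prime_barcode 6 bp barcode preceding the randomized region.
#' @param random_len Length of the randomized region (20 or 40 typical).
#' @param three_prime_barcode 2-3 bp barcode following the randomized region.
#' @return An object of class `ligand_design`.
#' @export
ligand_design <- function(five_prime_barcode = "TGGTAG", random_len = 20L,
                          three_prime_barcode = "GA") {
  stopifnot(
    is.character(five_prime_barcode), nchar(five_prime_barcode) == 6L,
    is.character(three_prime_barcode),
    nchar(three_prime_barcode) %in% c(2L, 3L),
    random_len > 0L
  )
  chk <- function(s) grepl("^[ACGT]+$", s)
  if (!chk(five_prime_barcode) || !chk(three_prime_barcode))
    stop("barcodes must be strings over A,C,G,T")
  structure(
    list(five_prime_barcode = five_prime_barcode,
         random_len = as.integer(random_len),
         three_prime_barcode = three_prime_barcode),
    class = "ligand_design"
  )
}

#' @export
print.ligand_design <- function(x, ...) {
  cat(sprintf("<ligand design> 5'-%s-[N x %d]-%s-3'\n",
              x$five_prime_barcode, x$random_len, x$three_prime_barcode))
  invisible(x)
}

#' Read a ligand design from a YAML file
#'
#' The file must define `five_prime_barcode`, `random_len` and
#' `three_prime_barcode`.
#'
#' @param path Path to a YAML file.
#' @return A [ligand_design()] object.
#' @export
read_ligand_design <- function(path) {
  y <- yaml::read_yaml(path)
  ligand_design(y$five_prime_barcode, y$random_len, y$three_prime_barcode)
}

#' Per-cycle read set
#'
#' Container for the randomized regions of one SELEX cycle (cycle 0 is the
#' unselected initial library).
#'
#' @param reads Character vector of reads over A,C,G,T.
#' @param cycle Integer cycle index, >= 0.
#' @param experiment_id Free-text experiment identifier.
#' @return An object of class `cycle_reads`.
#' @export
cycle_reads <- function(reads, cycle = NA_integer_, experiment_id = "") {
  stopifnot(is.character(reads))
  structure(
    list(experiment_id = experiment_id,
         cycle = as.integer(cycle),
         reads = reads),
    class = "cycle_reads"
  )
}

#' @export
print.cycle_reads <- function(x, ...) {
  cat(sprintf("<cycle reads> experiment '%s', cycle %s: %d reads%s\n",
              x$experiment_id, x$cycle, length(x$reads),
              if (length(x$reads))
                sprintf(" (length %s)",
                        paste(unique(range(nchar(x$reads))), collapse = "-"))
              else ""))
  invisible(x)
}

as_reads <- function(x) {
  if (inherits(x, "cycle_reads")) x$reads
  else if (is.character(x)) x
  else stop("expected a character vector or a cycle_reads object")
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over `Biostrings` sequence readers that returns plain
#' character vectors in file order (quality strings are discarded).
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"` or `"fastq"`; inferred from the file extension
#'   when `NULL`.
#' @return Character vector of sequences.
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
                     fq = , fastq = "fastq",
                     fa = , fna = , fasta = "fasta",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format = \"fasta\" or \"fastq\""))
  }
  format <- match.arg(format, c("fasta", "fastq"))
  if (format == "fastq") {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L)
      stop("malformed fastq file '", path, "': truncated record near line ",
           length(lines) - length(lines) %% 4L + 1L)
    heads <- lines[seq(1L, length(lines), by = 4L)]
    quals <- lines[seq(4L, length(lines), by = 4L)]
    seqs_ <- lines[seq(2L, length(lines), by = 4L)]
    bad <- which(!startsWith(heads, "@") | nchar(quals) != nchar(seqs_))
    if (length(bad))
      stop("malformed fastq file '", path, "': bad record at line ",
           (bad[1L] - 1L) * 4L + 1L)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      stop("malformed ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  as.character(seqs, use.names = FALSE)
}

#' Write sequences to FASTA
#'
#' @param reads Character vector or [cycle_reads()] object.
#' @param path Output path.
#' @param prefix Name prefix for the records.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path, prefix = "read") {
  reads <- as_reads(reads)
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s_%d", prefix, seq_along(reads))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Demultiplex raw reads into a per-cycle read set
#'
#' Retains reads whose 5' and 3' barcodes match the design exactly and whose
#' extracted randomized region has the design length and contains no N; the
#' randomized region is returned.  Barcode matching is exact: the barcodes
#' are short, and binning (not error correction) is the intent.
#'
#' @param raw_reads Character vector of full-length raw reads.
#' @param design A [ligand_design()].
#' @param cycle Cycle index recorded in the result.
#' @param experiment_id Identifier recorded in the result.
#' @param verbose Log the retention fraction via `message()`.
#' @return A [cycle_reads()] object of randomized regions.
#' @export
demultiplex_cycles <- function(raw_reads, design, cycle = NA_integer_,
                               experiment_id = "", verbose = TRUE) {
  stopifnot(inherits(design, "ligand_design"))
  raw_reads <- as_reads(raw_reads)
  b5 <- design$five_prime_barcode
  b3 <- design$three_prime_barcode
  need <- nchar(b5) + design$random_len + nchar(b3)
  keep <- nchar(raw_reads) >= need &
    substr(raw_reads, 1L, nchar(b5)) == b5
  region <- substr(raw_reads, nchar(b5) + 1L, nchar(b5) + design$random_len)
  after <- substr(raw_reads, nchar(b5) + design$random_len + 1L,
                  nchar(b5) + design$random_len + nchar(b3))
  keep <- keep & after == b3 & grepl("^[ACGT]*$", region) &
    nchar(region) == design$random_len
  kept <- region[keep]
  frac <- if (length(raw_reads)) length(kept) / length(raw_reads) else NA_real_
  if (verbose && length(raw_reads))
    message(sprintf("demultiplex: retained %d/%d reads (%.1f%%)",
                    length(kept), length(raw_reads), 100 * frac))
  out <- cycle_reads(kept, cycle = cycle, experiment_id = experiment_id)
  attr(out, "retention") <- frac
  out
}

# ---- PWM file formats ----

#' Read a PWM from a labelled TSV file
#'
#' The dialect is a tab-separated table whose first column holds the row
#' labels `A`, `C`, `G`, `T` in that order and whose header gives 1-based
#' column indices; entries are non-negative reals.
#'
#' @param path Path to the TSV file.
#' @return A 4 x w numeric matrix with rownames A,C,G,T (class `matrix`);
#'   wrap with [selex_pwm()] to attach metadata.
#' @export
read_pwm <- function(path) {
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", row.names = 1L,
               check.names = FALSE),
    error = function(e) stop("cannot parse PWM TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  m <- as.matrix(tab)
  if (!identical(rownames(m), c("A", "C", "G", "T")))
    stop("PWM TSV must have row labels A, C, G, T in that order")
  if (ncol(m) < 1L) stop("PWM TSV must have at least one column")
  if (!is.numeric(m) || anyNA(m) || any(m < 0))
    stop("PWM entries must be non-negative numbers")
  storage.mode(m) <- "double"
  colnames(m) <- as.character(seq_len(ncol(m)))
  m
}

#' Write a PWM to TSV or MEME minimal format
#'
#' TSV round-trips counts exactly through [read_pwm()]; the MEME minimal
#' format writes per-column letter frequencies (columns sum to 1).
#'
#' @param pwm A [selex_pwm()] object or a 4 x w matrix (rows A,C,G,T).
#' @param path Output path.
#' @param format `"tsv"` or `"meme-minimal"`.
#' @param name Motif name used in MEME output.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path, format = c("tsv", "meme-minimal"),
                      name = "motif") {
  format <- match.arg(format)
  m <- pwm_matrix(pwm)
  if (any(m < 0)) stop("PWM entries must be non-negative")
  if (format == "tsv") {
    df <- data.frame(base = rownames(m), m, check.names = FALSE)
    colnames(df) <- c("base", seq_len(ncol(m)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    f <- sweep(m, 2L, colSums(m), "/")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "strands: + -", "",
                 "Background letter frequencies",
                 "A 0.25 C 0.25 G 0.25 T 0.25", "",
                 sprintf("MOTIF %s", name),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         ncol(f))), con)
    writeLines(apply(f, 2L, function(col)
      paste(sprintf("%.10f", col), collapse = "  ")), con)
  }
  invisible(path)
}

pwm_matrix <- function(pwm) {
  if (inherits(pwm, "selex_pwm")) return(pwm$counts)
  m <- as.matrix(pwm)
  if (nrow(m) != 4L) stop("a PWM must have 4 rows (A, C, G, T)")
  if (is.null(rownames(m))) rownames(m) <- c("A", "C", "G", "T")
  storage.mode(m) <- "double"
  m
}
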