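# SVG renderers: barcode logos, sequence logos, dependency heatmaps and the
# 2D motif x amino-acid similarity heatmap.  All renderers are pure
# functions of their inputs and emit byte-identical SVG on re-run.

DEFAULT_BASE_COLORS <- c(A = "#33A02C", C = "#1F78B4",
                         G = "#FF7F00", T = "#E31A1C")

num <- function(x) sprintf("%.8f", x)

svg_document <- function(body, width, height) {
  structure(
    paste0(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
      sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                     "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">\n"),
              num(width), num(height), num(width), num(height)),
      body, "</svg>\n"),
    class = "svg_document")
}

#' @export
print.svg_document <- function(x, ...) {
  cat(sprintf("<svg document> %d bytes; write with write_svg()\n", nchar(x)))
  invisible(x)
}

#' Write an SVG document to file
#'
#' @param svg An `svg_document` from one of the renderers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(svg, path) {
  # single write without trailing-newline surprises -> byte-stable output
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(as.character(svg), con, eos = NULL)
  invisible(path)
}

blend_to_white <- function(hex, intensity) {
  rgb <- grDevices::col2rgb(hex)[, 1L]
  out <- round(255 + intensity * (rgb - 255))
  sprintf("#%02X%02X%02X", out[1L], out[2L], out[3L])
}

#' Barcode logo of a PWM
#'
#' A compact motif visualization designed for visual alignment of many
#' motifs by their colour profiles.  Each position is one column of four
#' bars (A, C, G, T left to right); the width of each bar is proportional
#' to the frequency of its base (range 0-1), and the height and colour
#' intensity of all bars at a position are proportional to the frequency of
#' the most common base there (range 0.25-1, mapped identically: a uniform
#' column has height fraction 0.25).
#'
#' @param pwm A [selex_pwm()] or 4 x w matrix.
#' @param pos_width,pos_height Pixel size of one position cell.
#' @param colors Named base colours.
#' @return An `svg_document`.
#' @export
barcode_logo <- function(pwm, pos_width = 20, pos_height = 60,
                         colors = DEFAULT_BASE_COLORS) {
  f <- pwm_frequencies(pwm)
  w <- ncol(f)
  body <- character(0)
  for (j in seq_len(w)) {
    m <- max(f[, j])               # in [0.25, 1]
    h <- m * pos_height            # proportional, identity map
    y0 <- pos_height - h
    x <- (j - 1) * pos_width
    for (b in c("A", "C", "G", "T")) {
      bw <- f[b, j] * pos_width
      if (f[b, j] > 0) {
        body <- c(body, sprintf(
          paste0("<rect class=\"bar\" data-base=\"%s\" data-pos=\"%d\" ",
                 "x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" ",
                 "fill=\"%s\"/>\n"),
          b, j, num(x), num(y0), num(bw), num(h),
          blend_to_white(colors[[b]], m)))
      }
      x <- x + bw
    }
  }
  svg_document(paste(body, collapse = ""), w * pos_width, pos_height)
}

#' Sequence logo of a PWM
#'
#' Conventional information-content logo: letter heights are base frequency
#' times the column information content in bits (at most 2 bits per
#' column), letters stacked with the most frequent on top.
#'
#' @inheritParams barcode_logo
#' @param bits_height Pixel height corresponding to 2 bits.
#' @return An `svg_document`.
#' @export
sequence_logo <- function(pwm, pos_width = 20, bits_height = 60,
                          colors = DEFAULT_BASE_COLORS) {
  f <- pwm_frequencies(pwm)
  w <- ncol(f)
  ic <- pwm_information(f)
  body <- character(0)
  for (j in seq_len(w)) {
    heights <- f[, j] * ic[j]            # bits per letter
    ord <- order(heights)                # draw small first, top = largest
    y <- bits_height
    for (b in rownames(f)[ord]) {
      hb <- heights[[b]] / 2 * bits_height
      if (hb <= 0) next
      y <- y - hb
      body <- c(body, sprintf(
        paste0("<text class=\"letter\" data-base=\"%s\" data-pos=\"%d\" ",
               "data-bits=\"%s\" x=\"0\" y=\"0\" font-family=\"monospace\" ",
               "font-size=\"10\" fill=\"%s\" transform=",
               "\"translate(%s,%s) scale(%s,%s)\">%s</text>\n"),
        b, j, num(heights[[b]]),
        colors[[b]], num((j - 1) * pos_width), num(y + hb),
        num(pos_width / 10), num(hb / 10), b))
    }
  }
  svg_document(paste(body, collapse = ""), w * pos_width, bits_height)
}

score_to_heat <- function(score_pct, max_score = 100) {
  # white -> red ramp, deterministic
  s <- min(max(score_pct / max_score, 0), 1)
  out <- round(c(255, 255 * (1 - s), 255 * (1 - s)))
  sprintf("#%02X%02X%02X", out[1L], out[2L], out[3L])
}

#' Dependency heatmap as SVG
#'
#' Upper-triangle w x w grid of position-pair tiles coloured by the scaled
#' dependency score; inside each tile a 4 x 4 dot grid marks base pairs
#' that are over- (yellow) or under- (blue) represented relative to the
#' mononucleotide prediction.
#'
#' @param table A `pair_dependency` from [dependency_table()].
#' @param tile Tile pixel size.
#' @return An `svg_document`.
#' @export
dependency_heatmap <- function(table, tile = 24) {
  w <- table$width
  body <- character(0)
  for (p in table$pairs) {
    x <- (p$j - 1) * tile
    y <- (p$i - 1) * tile
    body <- c(body, sprintf(
      paste0("<rect class=\"tile\" data-i=\"%d\" data-j=\"%d\" ",
             "data-score=\"%s\" x=\"%s\" y=\"%s\" width=\"%s\" ",
             "height=\"%s\" fill=\"%s\" stroke=\"#888888\" ",
             "stroke-width=\"0.5\"/>\n"),
      p$i, p$j, num(p$score_pct), num(x), num(y), num(tile), num(tile),
      score_to_heat(p$score_pct)))
    for (a in 1:4) for (b in 1:4) {
      sgn <- p$sign[a, b]
      if (sgn == "neutral") next
      body <- c(body, sprintf(
        paste0("<circle class=\"dot\" data-pair=\"%s%s\" data-sign=\"%s\" ",
               "cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\"/>\n"),
        rownames(p$sign)[a], colnames(p$sign)[b], sgn,
        num(x + (b - 0.5) * tile / 4), num(y + (a - 0.5) * tile / 4),
        num(tile / 12), if (sgn == "over") "#FFD700" else "#1E90FF"))
    }
  }
  svg_document(paste(body, collapse = ""), w * tile, w * tile)
}

#' Two-dimensional motif x amino-acid similarity heatmap
#'
#' Each cell is coloured on a two-dimensional scale: one axis encodes motif
#' similarity (green channel), the other amino-acid similarity (red
#' channel); yellow marks pairs similar in both.  Rows and columns follow
#' the leaf order of the supplied clustering tree.
#'
#' @param motif_sim,aa_sim Symmetric similarity matrices over the same ids.
#' @param ordering A `phylo` tree (e.g. from [cluster_motifs()]) whose tip
#'   labels order the rows, or a character vector of ids.
#' @param tile Tile pixel size.
#' @return An `svg_document`.
#' @export
similarity_heatmap_2d <- function(motif_sim, aa_sim, ordering = NULL,
                                  tile = 12) {
  ids <- rownames(motif_sim)
  if (is.null(ids) || !setequal(ids, rownames(aa_sim)))
    stop("motif and amino-acid matrices must share the same ids")
  ord <- if (is.null(ordering)) ids
         else if (inherits(ordering, "phylo")) ordering$tip.label
         else as.character(ordering)
  if (!setequal(ord, ids)) stop("ordering ids do not match the matrices")
  ms <- motif_sim[ord, ord]
  as_ <- aa_sim[ord, ord]
  norm01 <- function(m) {
    r <- range(m)
    if (diff(r) < 1e-12) matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
    else (m - r[1L]) / diff(r)
  }
  mn <- norm01(ms)
  an <- norm01(as_)
  n <- length(ord)
  body <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    col <- sprintf("#%02X%02X%02X", round(255 * an[i, j]),
                   round(255 * mn[i, j]), 40L)
    body <- c(body, sprintf(
      paste0("<rect class=\"cell\" data-row=\"%s\" data-col=\"%s\" ",
             "data-motif=\"%s\" data-aa=\"%s\" x=\"%s\" y=\"%s\" ",
             "width=\"%s\" height=\"%s\" fill=\"%s\"/>\n"),
      ord[i], ord[j], num(mn[i, j]), num(an[i, j]),
      num((j - 1) * tile), num((i - 1) * tile), num(tile), num(tile), col))
  }
  svg_document(paste(body, collapse = ""), n * tile, n * tile)
}
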