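# SVG renderers: geometry recoverable from the output, deterministic bytes.

library(xml2)

svg_nodes <- function(svg, xpath) {
  doc <- read_xml(as.character(svg))
  xml_find_all(doc, xpath, ns = xml_ns(doc))
}

test_that("barcode logo geometry encodes the frequency/intensity spec", {
  f <- cbind(c(0.25, 0.25, 0.25, 0.25),  # uniform column
             c(1, 0, 0, 0),              # one-hot column
             c(0.5, 0.3, 0.1, 0.1))
  rownames(f) <- BASES
  svg <- barcode_logo(f, pos_width = 20, pos_height = 60)
  bars <- svg_nodes(svg, "//*[local-name()='rect']")
  pos <- as.integer(xml_attr(bars, "data-pos"))
  wdt <- as.numeric(xml_attr(bars, "width"))
  hgt <- as.numeric(xml_attr(bars, "height"))
  y <- as.numeric(xml_attr(bars, "y"))

  # widths per column sum to the column width
  for (j in 1:3)
    expect_equal(sum(wdt[pos == j]), 20, tolerance = 1e-6)
  # uniform column: minimal height fraction 0.25 of the cell
  expect_equal(unique(hgt[pos == 1]), 0.25 * 60, tolerance = 1e-6)
  # one-hot column: one full-width, full-height bar
  expect_length(wdt[pos == 2], 1L)
  expect_equal(wdt[pos == 2], 20, tolerance = 1e-6)
  expect_equal(hgt[pos == 2], 60, tolerance = 1e-6)
  expect_equal(y[pos == 2], 0, tolerance = 1e-6)
  # intermediate column: height = max frequency
  expect_equal(unique(hgt[pos == 3]), 0.5 * 60, tolerance = 1e-6)
  # bar widths equal base frequencies x cell width
  expect_equal(sort(wdt[pos == 3]), sort(c(0.5, 0.3, 0.1, 0.1) * 20),
               tolerance = 1e-6)
})

test_that("barcode logo intensity blends toward white at low information", {
  f <- cbind(c(0.25, 0.25, 0.25, 0.25), c(1, 0, 0, 0))
  rownames(f) <- BASES
  svg <- as.character(barcode_logo(f))
  bars <- svg_nodes(svg, "//*[local-name()='rect']")
  fills <- xml_attr(bars, "fill")
  pos <- as.integer(xml_attr(bars, "data-pos"))
  base <- xml_attr(bars, "data-base")
  # the one-hot A bar keeps the pure base colour; the uniform A bar is
  # blended 25% toward it from white
  a_full <- grDevices::col2rgb(fills[pos == 2 & base == "A"])
  a_uni <- grDevices::col2rgb(fills[pos == 1 & base == "A"])
  expect_equal(as.vector(a_full),
               as.vector(grDevices::col2rgb("#33A02C")))
  expect_equal(as.vector(a_uni),
               as.vector(round(255 + 0.25 *
                                 (grDevices::col2rgb("#33A02C") - 255))))
})

test_that("sequence logo letter heights follow information content", {
  f <- cbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25),
             c(0.5, 0, 0, 0.5))
  rownames(f) <- BASES
  svg <- sequence_logo(f)
  letters_ <- svg_nodes(svg, "//*[local-name()='text']")
  bits <- as.numeric(xml_attr(letters_, "data-bits"))
  pos <- as.integer(xml_attr(letters_, "data-pos"))
  expect_equal(bits[pos == 1], 2)            # one-hot: single 2-bit letter
  expect_length(bits[pos == 2], 0L)          # uniform: zero bits, no letters
  expect_equal(sort(bits[pos == 3]), c(0.5, 0.5))  # 1-bit column split
})

test_that("dependency heatmap draws one tile per position pair plus dots", {
  sites <- c(rep("CAGGATAA", 30), rep("CAGGATTT", 30))
  dep <- dependency_table(sites, "GGAT", flank = 2,
                          strand_policy = "forward_only")
  svg <- dependency_heatmap(dep)
  tiles <- svg_nodes(svg, "//*[local-name()='rect']")
  expect_length(tiles, 8 * 7 / 2)
  sc <- as.numeric(xml_attr(tiles, "data-score"))
  ii <- as.integer(xml_attr(tiles, "data-i"))
  jj <- as.integer(xml_attr(tiles, "data-j"))
  expect_equal(sc[ii == 7 & jj == 8], 100)
  dots <- svg_nodes(svg, "//*[local-name()='circle']")
  expect_equal(sum(xml_attr(dots, "data-sign") == "over"), 2L)   # AA, TT
  expect_equal(sum(xml_attr(dots, "data-sign") == "under"), 2L)  # AT, TA
})

test_that("2D similarity heatmap orders by the tree and colours corners", {
  ids <- c("a", "b", "c")
  ms <- matrix(c(1, .9, .1, .9, 1, .1, .1, .1, 1), 3, 3,
               dimnames = list(ids, ids))
  as_ <- matrix(c(1, .2, .9, .2, 1, .1, .9, .1, 1), 3, 3,
                dimnames = list(ids, ids))
  tr <- cluster_motifs(ms)
  svg <- similarity_heatmap_2d(ms, as_, ordering = tr)
  cells <- svg_nodes(svg, "//*[local-name()='rect']")
  expect_length(cells, 9L)
  diagcells <- cells[xml_attr(cells, "data-row") ==
                       xml_attr(cells, "data-col")]
  # diagonal = both scales maximal
  expect_true(all(as.numeric(xml_attr(diagcells, "data-motif")) == 1))
  expect_true(all(as.numeric(xml_attr(diagcells, "data-aa")) == 1))
  # high-motif/low-aa differs from the both-high corner colour
  offd <- cells[xml_attr(cells, "data-row") == "a" &
                  xml_attr(cells, "data-col") == "b"]
  expect_false(xml_attr(offd, "fill") == xml_attr(diagcells[1], "fill"))
  expect_error(similarity_heatmap_2d(ms, as_, ordering = c("a", "b")),
               "ordering")
  bad <- as_
  rownames(bad) <- colnames(bad) <- c("a", "b", "x")
  expect_error(similarity_heatmap_2d(ms, bad), "ids")
})

test_that("renderers are pure: byte-identical SVG on re-run", {
  f <- onehot_pwm("GACGTC")
  expect_identical(as.character(barcode_logo(f)),
                   as.character(barcode_logo(f)))
  expect_identical(as.character(sequence_logo(f)),
                   as.character(sequence_logo(f)))
  path1 <- tempfile(fileext = ".svg")
  path2 <- tempfile(fileext = ".svg")
  write_svg(barcode_logo(f), path1)
  write_svg(barcode_logo(f), path2)
  expect_identical(readBin(path1, "raw", file.size(path1)),
                   readBin(path2, "raw", file.size(path2)))
})
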