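# fully determined CACG motif with known methylation, pseudocount 0
render_fixture <- function() {
  pad <- strrep("TA", 12L)
  unit <- paste0("ACACGT", pad)
  s <- paste0(pad, strrep(unit, 5L), pad)
  g <- tiny_genome(chr1 = s)
  starts <- as.integer(gregexpr("ACACGT", s, fixed = TRUE)[[1L]]) - 1L
  sites <- region_set("chr1", starts + 1L, starts + 5L, "+") # "CACG"
  cyt <- genome_cytosines(g)
  mt <- mt_df(cyt$chrom, cyt$pos, cyt$strand, rep(0.7, nrow(cyt)))
  sm <- extract_site_matrix(g, sites, mt, flank = 3L)
  motif <- build_motif_model(sm, pseudocount = 0)
  bg0 <- fab_bg0(c(0.3, 0.2, 0.2, 0.3))
  joint <- outer(c(0.3, 0.2, 0.2, 0.3), c(0.3, 0.2, 0.2, 0.3))
  dimnames(joint) <- list(bases4, bases4)
  joint["C", "G"] <- joint["C", "G"] / 4
  joint <- (joint + t(joint[c("T", "G", "C", "A"), c("T", "G", "C", "A")])[bases4, bases4]) / 2
  joint <- joint / sum(joint)
  bg1 <- fab_bg1(joint)
  mbg <- fab_mbg(c(CG = 0.5, CHG = 0.05, CHH = 0.02))
  tracks <- track_set(motif, bg0 = bg0, bg1 = bg1, mbg = mbg)
  list(tracks = tracks, motif = motif, mbg = mbg, bg0 = bg0)
}

svg_of <- function(fx, cfg = render_config()) {
  f <- tempfile(fileext = ".svg")
  render_logo(fx$tracks, fx$motif, fx$mbg, fx$bg0, cfg, f)
  f
}

attr_num <- function(nodes, attr) as.numeric(xml2::xml_attr(nodes, attr))

test_that("the SVG contains the expected structural elements", {
  fx <- render_fixture()
  f <- svg_of(fx)
  doc <- xml2::read_xml(f)
  glyphs <- xml2::xml_find_all(doc, "//*[@data-role='seq-glyph']")
  expect_length(glyphs, fx$tracks$L) # fully determined: one letter per column
  bars <- xml2::xml_find_all(doc, "//*[@data-role='dimer-bar']")
  expect_length(bars, fx$tracks$L - 1L)
  bounds <- xml2::xml_find_all(doc, "//*[@data-role='dimer-bound']")
  expect_length(bounds, 2L)
  expect_length(xml2::xml_find_all(doc, "//*[@data-role='key-box']"), 1L)
  # key lists 3 context methylation values and 4 base probabilities
  expect_length(xml2::xml_find_all(doc, "//*[@data-role='key-meth']"), 3L)
  expect_length(xml2::xml_find_all(doc, "//*[@data-role='key-base']"), 4L)
})

test_that("rendered glyph and bar geometry reproduces the track values", {
  fx <- render_fixture()
  cfg <- render_config()
  f <- svg_of(fx, cfg)
  doc <- xml2::read_xml(f)
  glyphs <- xml2::xml_find_all(doc, "//*[@data-role='seq-glyph']")
  for (gl in glyphs) {
    tr <- xml2::xml_attr(xml2::xml_find_first(gl, "./*[local-name()='path']"), "transform")
    nums <- as.numeric(regmatches(tr, gregexpr("-?[0-9.]+", tr))[[1L]])
    h_px <- nums[4L] # scale height
    bits <- as.numeric(xml2::xml_attr(gl, "data-bits"))
    expect_lt(abs(h_px / cfg$px_per_bit - bits), 1e-6)
    col <- as.integer(xml2::xml_attr(gl, "data-col"))
    base <- xml2::xml_attr(gl, "data-base")
    expect_equal(bits, unname(fx$tracks$letters[col + 1L, base]), tolerance = 1e-9)
  }
  bars <- xml2::xml_find_all(doc, "//*[@data-role='dimer-bar']")
  for (b in bars) {
    h_px <- attr_num(b, "height")
    bits <- as.numeric(xml2::xml_attr(b, "data-bits"))
    expect_lt(abs(h_px / cfg$px_per_bit - abs(bits)), 1e-6)
    j <- as.integer(xml2::xml_attr(b, "data-step"))
    expect_equal(bits, fx$tracks$dimer_heights[j + 1L], tolerance = 1e-9)
  }
  segs <- xml2::xml_find_all(doc, "//*[@data-role='meth-seg']")
  expect_gt(length(segs), 0L)
  for (sgm in segs) {
    h_px <- attr_num(sgm, "height")
    bits <- as.numeric(xml2::xml_attr(sgm, "data-bits"))
    expect_lt(abs(h_px / cfg$px_per_bit - bits), 1e-6)
  }
})

test_that("C/G glyph shading covers the observed methylation fraction", {
  fx <- render_fixture()
  f <- svg_of(fx)
  doc <- xml2::read_xml(f)
  glyphs <- xml2::xml_find_all(doc, "//*[@data-role='seq-glyph']")
  n_shaded <- 0L
  for (gl in glyphs) {
    base <- xml2::xml_attr(gl, "data-base")
    shade <- xml2::xml_find_first(gl, ".//*[@data-role='meth-shade']")
    if (base %in% c("C", "G")) {
      col <- as.integer(xml2::xml_attr(gl, "data-col"))
      strand <- if (base == "C") "+" else "-"
      obs <- fx$tracks$observed[col + 1L, strand]
      if (!is.na(obs) && obs > 0) {
        n_shaded <- n_shaded + 1L
        tr <- xml2::xml_attr(xml2::xml_find_first(gl, "./*[local-name()='path']"), "transform")
        nums <- as.numeric(regmatches(tr, gregexpr("-?[0-9.]+", tr))[[1L]])
        frac <- attr_num(shade, "height") / nums[4L]
        expect_lt(abs(frac - obs), 1e-6)
        # dashed expected line sits at the expected fraction of the glyph
        exp_line <- xml2::xml_find_first(gl, ".//*[@data-role='expected-line']")
        y_line <- attr_num(exp_line, "y1")
        y_top <- nums[2L]
        expect_equal(1 - (y_line - y_top) / nums[4L],
          unname(fx$tracks$expected[col + 1L, strand]),
          tolerance = 1e-6
        )
      }
    } else {
      expect_length(xml2::xml_find_all(gl, ".//*[@data-role='meth-shade']"), 0L)
    }
  }
  expect_equal(n_shaded, 3L) # C, C, and the G of CACG carry observations
})

test_that("rendering is deterministic: identical inputs give identical bytes", {
  fx <- render_fixture()
  f1 <- svg_of(fx)
  f2 <- svg_of(fx)
  expect_identical(
    readBin(f1, "raw", file.size(f1)),
    readBin(f2, "raw", file.size(f2))
  )
})

test_that("methylation at background renders an empty top track", {
  fx <- render_fixture()
  # force observed methylation equal to background everywhere
  mbg <- fab_mbg(c(CG = 0.7, CHG = 0.7, CHH = 0.7))
  tracks <- track_set(fx$motif, bg0 = fx$bg0, bg1 = fab_bg1(outer(
    fx$bg0$q, fx$bg0$q
  )), mbg = mbg)
  f <- tempfile(fileext = ".svg")
  render_logo(tracks, fx$motif, mbg, fx$bg0, render_config(), f)
  doc <- xml2::read_xml(f)
  expect_length(xml2::xml_find_all(doc, "//*[@data-role='meth-seg']"), 0L)
  expect_length(xml2::xml_find_all(doc, "//*[@data-role='dimer-bar']"), 0L)
  # dashed expected lines coincide with the shading tops
  glyphs <- xml2::xml_find_all(doc, "//*[@data-role='seq-glyph']")
  for (gl in glyphs) {
    shade <- xml2::xml_find_all(gl, ".//*[@data-role='meth-shade']")
    exp_line <- xml2::xml_find_all(gl, ".//*[@data-role='expected-line']")
    if (length(shade) == 1L && length(exp_line) == 1L) {
      expect_equal(attr_num(shade, "y"), attr_num(exp_line, "y1"), tolerance = 1e-6)
    }
  }
})

test_that("the flanking-profile panel renders 3x3 with bands and curves", {
  fx <- scape_fixture(n_sites = 40L, seed = 12L)
  pr <- methylscape_profile(fx$sm, fx$mbg, window = 12L)
  f <- tempfile(fileext = ".svg")
  render_methylscape(pr, render_config(), f)
  doc <- xml2::read_xml(f)
  expect_length(xml2::xml_find_all(doc, "//*[@data-role='panel']"), 9L)
  expect_length(xml2::xml_find_all(doc, "//*[@data-role='bg-band']"), 3L)
  curves <- xml2::xml_find_all(doc, "//*[@data-role='scape-curve']")
  expect_gte(length(curves), 6L)
  # determinism
  f2 <- tempfile(fileext = ".svg")
  render_methylscape(pr, render_config(), f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("pdf and png backends write non-empty files", {
  fx <- render_fixture()
  fp <- tempfile(fileext = ".pdf")
  render_logo(fx$tracks, fx$motif, fx$mbg, fx$bg0, render_config(), fp)
  expect_gt(file.size(fp), 1000)
  fg <- tempfile(fileext = ".png")
  render_logo(fx$tracks, fx$motif, fx$mbg, fx$bg0, render_config(format = "png"), fg)
  expect_gt(file.size(fg), 1000)
})
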