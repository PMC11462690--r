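test_that("zero-order counting is double-stranded (hand counts)", {
  # AACT + revcomp AGTT: A3 C1 G1 T3 over 8 bases
  g <- tiny_genome(chr = "AACT")
  bg <- estimate_zero_order(g, pseudocount = 0)
  expect_equal(unname(bg$q), c(3, 1, 1, 3) / 8)
  # AACG + revcomp CGTT is uniform
  g2 <- tiny_genome(chr = "AACG")
  bg2 <- estimate_zero_order(g2, pseudocount = 0)
  expect_equal(unname(bg2$q), rep(0.25, 4L))
  # forced strand symmetry
  expect_equal(bg$q[["A"]], bg$q[["T"]])
  expect_equal(bg$q[["C"]], bg$q[["G"]])
})

test_that("zero-order estimation respects regions and rejects empty coverage", {
  g <- tiny_genome(chr = "AAAACCCC")
  bg <- estimate_zero_order(g, region_set("chr", 0, 4), pseudocount = 0)
  expect_equal(unname(bg$q), c(0.5, 0, 0, 0.5))
  gn <- tiny_genome(chr = "NNNN")
  expect_error(estimate_zero_order(gn), "zero non-N bases")
})

test_that("zero-order frequencies on a uniform random genome are near 0.25", {
  g <- tiny_genome(chr = random_dna(100000L, seed = 1L))
  bg <- estimate_zero_order(g)
  expect_true(all(abs(bg$q - 0.25) < 0.01))
})

test_that("dimer counting is per-block, both strands, never across boundaries", {
  # single region "CG": one + dimer CG and one - dimer CG
  g <- tiny_genome(chr = "CG")
  bg <- estimate_first_order(g, pseudocount = 0)
  expect_equal(unname(bg$counts["C", "G"]), 2)
  expect_equal(sum(bg$counts), 2)
  # two regions split the same sequence: the boundary dimer disappears
  g2 <- tiny_genome(chr = "ACGT")
  whole <- estimate_first_order(g2, pseudocount = 0)
  split <- estimate_first_order(g2, region_set("chr", c(0, 2), c(2, 4)), pseudocount = 0)
  expect_equal(sum(whole$counts), 6) # 3 dimers x 2 strands
  expect_equal(unname(whole$counts["C", "G"]), 2)
  expect_equal(sum(split$counts), 4) # AC and GT remain, each on both strands
  expect_equal(unname(split$counts["C", "G"]), 0) # boundary CG never counted
})

test_that("dimer counts are invariant under reverse-complementing the genome", {
  s <- random_dna(5000L, seed = 8L)
  a <- estimate_first_order(tiny_genome(chr = s), pseudocount = 0)
  b <- estimate_first_order(tiny_genome(chr = revcomp(s)), pseudocount = 0)
  expect_equal(a$counts, b$counts)
  a0 <- estimate_zero_order(tiny_genome(chr = s), pseudocount = 0)
  b0 <- estimate_zero_order(tiny_genome(chr = revcomp(s)), pseudocount = 0)
  expect_equal(a0$q, b0$q)
})

test_that("an independent genome yields near-product dimer frequencies", {
  g <- simulate_genome(200000L,
    base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
    seed = 21L
  )
  bg <- estimate_first_order(g)
  prod <- outer(bg$marginal, bg$marginal)
  expect_true(max(abs(bg$joint - prod)) < 0.005)
})

test_that("first-order chain parameters are recovered from a simulated genome", {
  trans <- cpg_depleted_chain(5)
  g <- simulate_genome(400000L, transition = trans, seed = 13L)
  bg <- estimate_first_order(g)
  # the chain has q(G|C) = 0.0625 on the forward strand; pooling both strands
  # mixes the C row with the reverse-strand inflow of G, so the pooled
  # conditional converges to pi_C/16 / ((pi_C + pi_G)/2) = 1/14
  expect_true(abs(bg$conditional["C", "G"] - 1 / 14) < 0.01)
  # the CpG joint cell itself is strand-invariant: pi_C/16 = 1/60
  expect_true(abs(bg$joint["C", "G"] - 1 / 60) < 0.005)
})

test_that("probability invariants hold after smoothing", {
  g <- tiny_genome(chr = random_dna(1000L, seed = 2L))
  bg0 <- estimate_zero_order(g)
  bg1 <- estimate_first_order(g)
  expect_equal(sum(bg0$q), 1, tolerance = 1e-12)
  expect_equal(sum(bg1$joint), 1, tolerance = 1e-12)
  expect_true(all(bg0$q > 0) && all(bg1$joint > 0))
  expect_equal(unname(rowSums(bg1$conditional)), rep(1, 4L), tolerance = 1e-12)
})

test_that("methylation background pools strands per context and clamps", {
  g <- tiny_genome(chr = "AACGTACAGTACATTTTTT")
  # CG at pos 2 (+) / 3 (-); CAG at 6 (+); CAT at 11 (+)
  mt <- mt_df(
    rep("chr", 4L), c(2L, 3L, 6L, 11L), c("+", "-", "+", "+"),
    c(0.8, 0.6, 1.0, 0.0)
  )
  mbg <- estimate_methyl_background(mt, g)
  expect_equal(mbg$m[["CG"]], 0.7)
  expect_equal(mbg$m[["CHG"]], 1 - 1e-4) # clamped
  expect_equal(mbg$m[["CHH"]], 1e-4) # clamped
  expect_equal(unname(mbg$n), c(2L, 1L, 1L))
})

test_that("a context with no covered cytosines is an error naming it", {
  g <- tiny_genome(chr = "AACGTACAGTACATTTTTT")
  mt <- mt_df("chr", c(2L, 6L), c("+", "+"), c(0.8, 0.1))
  expect_error(estimate_methyl_background(mt, g), "CHH")
})

test_that("methylation background respects region restriction", {
  g <- tiny_genome(chr = "AACGTACAGTACATTTTTT")
  mt <- mt_df(
    rep("chr", 4L), c(2L, 3L, 6L, 11L), c("+", "-", "+", "+"),
    c(0.8, 0.6, 0.3, 0.1)
  )
  mbg <- estimate_methyl_background(mt, g, region_set("chr", 0, 20))
  expect_equal(mbg$m[["CG"]], 0.7)
  expect_error(
    estimate_methyl_background(mt, g, region_set("chr", 15, 19)),
    "empty over the regions"
  )
})

test_that("background bundles serialize to JSON and read back identically", {
  g <- tiny_genome(chr = random_dna(3000L, seed = 4L))
  cyt <- genome_cytosines(g)
  mt <- mt_df(cyt$chrom, cyt$pos, cyt$strand, rep_len(c(0.9, 0.7, 0.1), nrow(cyt)))
  bundle <- background_bundle(g, mt)
  f <- tempfile(fileext = ".json")
  write_background(bundle, f)
  back <- read_background(f)
  expect_equal(back$bg0$q, bundle$bg0$q)
  expect_equal(back$bg1$joint, bundle$bg1$joint)
  expect_equal(back$mbg$m, bundle$mbg$m)
  expect_equal(back$label, "WG")
  # rerun writes identical bytes
  f2 <- tempfile(fileext = ".json")
  write_background(bundle, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("the bundle zero-order model is the symmetrised marginal of its dimer model", {
  g <- tiny_genome(chr = random_dna(2000L, seed = 6L))
  cyt <- genome_cytosines(g)
  mt <- mt_df(cyt$chrom, cyt$pos, cyt$strand, rep(0.5, nrow(cyt)))
  bundle <- background_bundle(g, mt)
  expect_equal(
    bundle$bg0$q,
    (rowSums(bundle$bg1$joint) + colSums(bundle$bg1$joint)) / 2
  )
  # exactly strand-symmetric
  expect_identical(bundle$bg0$q[["A"]], bundle$bg0$q[["T"]])
  expect_identical(bundle$bg0$q[["C"]], bundle$bg0$q[["G"]])
  # and within one edge base of the raw row marginal
  expect_equal(bundle$bg0$q, rowSums(bundle$bg1$joint), tolerance = 1e-2)
})
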