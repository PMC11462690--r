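test_that("sequence column heights follow the relative-entropy formula", {
  bg <- fab_bg0(rep(0.25, 4L))
  m <- fab_motif(rbind(
    c(0.25, 0.25, 0.25, 0.25), # = background -> 0 bits
    c(1, 0, 0, 0), # determined -> 2 bits
    c(0.5, 0.5, 0, 0) # two equally likely -> 1 bit
  ))
  st <- sequence_track_heights(m, bg)
  expect_equal(st$heights, c(0, 2, 1), tolerance = 1e-12)
  # letter heights are proportional to base probability
  expect_equal(unname(st$letters[3L, ]), c(0.5, 0.5, 0, 0), tolerance = 1e-12)
  # non-uniform background
  bg2 <- fab_bg0(c(0.4, 0.1, 0.1, 0.4))
  m2 <- fab_motif(matrix(c(0, 1, 0, 0), 1L))
  expect_equal(sequence_track_heights(m2, bg2)$heights, log2(10), tolerance = 1e-12)
})

test_that("dimer bars vanish for independent backgrounds and score depletion", {
  q <- c(0.25, 0.25, 0.25, 0.25)
  ind <- fab_bg1(outer(q, q))
  m <- fab_motif(rbind(c(0.1, 0.2, 0.3, 0.4), c(0.4, 0.3, 0.2, 0.1)))
  d <- dimer_track_heights(m, ind)
  expect_equal(d$heights, 0, tolerance = 1e-12)
  # 5x depleted CpG with a motif always reading CG at the step
  joint <- outer(q, q)
  dimnames(joint) <- list(bases4, bases4)
  joint["C", "G"] <- 0.0125
  joint <- joint / sum(joint)
  # renormalise marginals shift slightly; evaluate against the exact formula
  bg1 <- fab_bg1(joint)
  pcg <- matrix(0, 4L, 4L, dimnames = list(bases4, bases4))
  pcg["C", "G"] <- 1
  mm <- fab_motif(rbind(c(0, 1, 0, 0), c(0, 0, 1, 0)), pairs = list(pcg))
  d2 <- dimer_track_heights(mm, bg1)
  expect_equal(
    d2$heights,
    log2(bg1$marginal[["C"]] * bg1$marginal[["G"]] / bg1$joint["C", "G"]),
    tolerance = 1e-12
  )
  # with unrenormalised 5x depletion the single term is lg 5
  joint5 <- outer(q, q)
  dimnames(joint5) <- list(bases4, bases4)
  joint5["C", "G"] <- 0.0125
  bg5 <- structure(
    list(
      joint = joint5, marginal = q, conditional = joint5 / q,
      counts = NULL, pseudocount = 0
    ),
    class = "bg_first"
  )
  names(bg5$marginal) <- bases4
  expect_equal(dimer_track_heights(mm, bg5, fab_bg0(q))$heights, log2(5),
    tolerance = 1e-12
  )
})

test_that("dimer bars always lie within the theoretical bounds", {
  set.seed(31)
  for (r in 1:25) {
    L <- sample(2:6, 1L)
    p <- t(vapply(seq_len(L), function(i) random_simplex(4L), numeric(4L)))
    m <- fab_motif(p)
    bg1 <- fab_bg1(random_rc_symmetric_joint())
    d <- dimer_track_heights(m, bg1)
    expect_true(all(d$heights <= d$bound_max + 1e-12))
    expect_true(all(d$heights >= d$bound_min - 1e-12))
  }
})

test_that("track sums match brute-force relative entropies over all 4^L sequences", {
  set.seed(101)
  worst <- 0
  for (r in 1:100) {
    L <- sample(1:5, 1L)
    p <- t(vapply(seq_len(L), function(i) random_simplex(4L), numeric(4L)))
    joint <- random_rc_symmetric_joint()
    motif <- fab_motif(p)
    bg1 <- fab_bg1(joint)
    bg0 <- fab_bg0(bg1$marginal)
    seqh <- sequence_track_heights(motif, bg0)$heights
    dimh <- dimer_track_heights(motif, bg1, bg0)$heights
    oracle <- brute_force_relent(p, joint)
    worst <- max(
      worst, abs(sum(seqh) - oracle$D0),
      abs(sum(seqh) + sum(dimh) - oracle$D1)
    )
  }
  expect_lt(worst, 1e-9)
})

test_that("methylation components multiply context probability by binary KL", {
  mbg <- fab_mbg(c(CG = 0.8, CHG = 0.05, CHH = 0.02))
  ctx <- array(0, c(1L, 3L, 2L), dimnames = list(NULL, c("CG", "CHG", "CHH"), c("+", "-")))
  mv <- array(NA_real_, dim(ctx), dimnames = dimnames(ctx))
  # methylation equal to background -> zero height
  ctx[1L, "CG", "+"] <- 1
  mv[1L, "CG", "+"] <- 0.8
  m0 <- fab_motif(matrix(c(0, 1, 0, 0), 1L), ctx_prob = ctx, m = mv)
  expect_equal(sum(methylation_track_heights(m0, mbg)), 0, tolerance = 1e-12)
  # saturated methylation against 0.8: kl2(1-eps || 0.8)
  mv[1L, "CG", "+"] <- 1
  m1 <- fab_motif(matrix(c(0, 1, 0, 0), 1L), ctx_prob = ctx, m = mv)
  got <- methylation_track_heights(m1, mbg)
  expect_equal(unname(got[1L, "CG+"]), kl2(1, 0.8), tolerance = 1e-12)
  expect_equal(unname(got[1L, "CG+"]), log2(1 / 0.8), tolerance = 5e-3) # ~0.32 bits
  # halved context probability halves the component
  ctx[1L, "CG", "+"] <- 0.5
  m2 <- fab_motif(matrix(c(0, 1, 0, 0), 1L), ctx_prob = ctx, m = mv)
  expect_equal(
    methylation_track_heights(m2, mbg)[1L, "CG+"], got[1L, "CG+"] / 2,
    tolerance = 1e-12, ignore_attr = TRUE
  )
  # a present context with no observation is skipped with a warning
  mv[1L, "CG", "+"] <- NA_real_
  ctx[1L, "CG", "+"] <- 1
  m3 <- fab_motif(matrix(c(0, 1, 0, 0), 1L), ctx_prob = ctx, m = mv)
  expect_warning(h <- methylation_track_heights(m3, mbg), "skipped")
  expect_equal(sum(h), 0)
})

test_that("methylation column height is monotone in distance from background", {
  mbg <- fab_mbg(c(CG = 0.5, CHG = 0.05, CHH = 0.02))
  ctx <- array(0, c(1L, 3L, 2L), dimnames = list(NULL, c("CG", "CHG", "CHH"), c("+", "-")))
  ctx[1L, "CG", "+"] <- 0.7
  hs <- vapply(seq(0.5, 0.999, length.out = 30L), function(lev) {
    mv <- array(NA_real_, dim(ctx), dimnames = dimnames(ctx))
    mv[1L, "CG", "+"] <- lev
    sum(methylation_track_heights(
      fab_motif(matrix(c(0, 1, 0, 0), 1L), ctx_prob = ctx, m = mv), mbg
    ))
  }, numeric(1L))
  expect_true(all(diff(hs) >= -1e-12))
  expect_true(all(hs >= 0))
})

test_that("the expected-methylation line is the context-weighted background mean", {
  mbg <- fab_mbg(c(CG = 0.8, CHG = 0.05, CHH = 0.02))
  ctx <- array(0, c(2L, 3L, 2L), dimnames = list(NULL, c("CG", "CHG", "CHH"), c("+", "-")))
  ctx[1L, "CG", "+"] <- 1
  ctx[2L, "CG", "+"] <- 0.3 # renormalises to 0.6 CG / 0.4 CHH
  ctx[2L, "CHH", "+"] <- 0.2
  m <- fab_motif(rbind(c(0, 1, 0, 0), c(0, 0.5, 0, 0.5)), ctx_prob = ctx)
  e <- expected_methylation_line(m, mbg)
  expect_equal(unname(e[1L, "+"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(e[2L, "+"]), 0.6 * 0.8 + 0.4 * 0.02, tolerance = 1e-12)
  expect_true(is.na(e[1L, "-"])) # no strand-relative C there
})

test_that("total information adds the three tracks and is zero at background", {
  q <- rep(0.25, 4L)
  bg1 <- fab_bg1(outer(q, q))
  bg0 <- fab_bg0(q)
  mbg <- fab_mbg(c(CG = 0.8, CHG = 0.05, CHH = 0.02))
  p <- matrix(0.25, 3L, 4L)
  motif <- fab_motif(p)
  ts <- track_set(motif, bg0 = bg0, bg1 = bg1, mbg = mbg)
  expect_equal(total_information(ts), 0, tolerance = 1e-12)
  # and a non-trivial case agrees with the component sums
  p2 <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1))
  ts2 <- track_set(fab_motif(p2), bg0 = bg0, bg1 = bg1, mbg = mbg)
  expect_equal(
    total_information(ts2),
    sum(ts2$seq_heights) + sum(ts2$dimer_heights) + sum(ts2$meth)
  )
})

test_that("all tracks mirror exactly under reverse complementation of the sites", {
  s <- random_dna(6000L, seed = 55L)
  g <- tiny_genome(chr1 = s)
  set.seed(9)
  st <- seq(30L, 5800L, by = 95L)
  sites <- region_set("chr1", st, st + 9L, sample(c("+", "-"), length(st), TRUE))
  cyt <- genome_cytosines(g)
  mt <- mt_df(cyt$chrom, cyt$pos, cyt$strand, rep_len(c(0.95, 0.6, 0.15, 0), nrow(cyt)))
  sm <- extract_site_matrix(g, sites, mt, flank = 4L)
  bundle <- background_bundle(g, mt)
  fwd <- track_set(build_motif_model(sm, 0.5), bundle)
  rev <- track_set(build_motif_model(revcomp_sites(sm), 0.5), bundle)
  L <- fwd$L
  expect_equal(rev$seq_heights, fwd$seq_heights[L:1L], tolerance = 1e-12)
  if (L >= 2L) {
    expect_equal(rev$dimer_heights, fwd$dimer_heights[(L - 1L):1L], tolerance = 1e-12)
  }
  for (cx in c("CG", "CHG", "CHH")) {
    expect_equal(rev$meth[, paste0(cx, "+")], fwd$meth[L:1L, paste0(cx, "-")],
      tolerance = 1e-12
    )
    expect_equal(rev$meth[, paste0(cx, "-")], fwd$meth[L:1L, paste0(cx, "+")],
      tolerance = 1e-12
    )
  }
  expect_equal(rev$expected[, "+"], fwd$expected[L:1L, "-"], tolerance = 1e-12)
  expect_equal(rev$observed[, "-"], fwd$observed[L:1L, "+"], tolerance = 1e-12)
})

test_that("track tables are tidy and write as TSV", {
  q <- rep(0.25, 4L)
  ts <- track_set(fab_motif(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))),
    bg0 = fab_bg0(q), bg1 = fab_bg1(outer(q, q)),
    mbg = fab_mbg(c(0.8, 0.05, 0.02))
  )
  df <- as.data.frame(ts)
  expect_named(df, c("track", "pos", "element", "value"))
  expect_equal(sum(df$track == "sequence"), 8L)
  expect_equal(sum(df$track == "dimer"), 1L)
  f <- tempfile(fileext = ".tsv")
  write_tracks(ts, f)
  back <- utils::read.delim(f)
  expect_equal(nrow(back), nrow(df))
})
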