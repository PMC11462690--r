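# Synthetic data generators with known ground truth. Everything is
# deterministic under a fixed seed, so the whole pipeline is testable
# without external downloads.

#' Simulate a genome from a zero- or first-order Markov chain
#'
#' @param length Sequence length in bp (> 0).
#' @param base_probs Zero-order base probabilities (named A/C/G/T), used
#'   when `transition` is NULL and for the first base otherwise.
#' @param transition Optional 4 x 4 first-order transition matrix
#'   (rows = previous base, rows sum to 1).
#' @param seed Random seed (mandatory: generators are reproducible).
#' @param chrom Chromosome name.
#' @return A `genome_seq` with one chromosome.
#' @export
simulate_genome <- function(length, base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            transition = NULL, seed, chrom = "chr1") {
  if (length <= 0L) stop("genome length must be positive")
  if (missing(seed)) stop("seed is mandatory")
  base_probs <- base_probs[BASES] / sum(base_probs[BASES])
  set.seed(seed)
  if (is.null(transition)) {
    s <- sample(BASES, length, replace = TRUE, prob = base_probs)
  } else {
    transition <- transition[BASES, BASES]
    if (any(abs(rowSums(transition) - 1) > 1e-8)) {
      stop("transition rows must sum to 1")
    }
    cum <- t(apply(transition, 1L, cumsum))
    u <- stats::runif(length)
    idx <- integer(length)
    idx[1L] <- sample.int(4L, 1L, prob = base_probs)
    for (i in 2:length) {
      idx[i] <- findInterval(u[i], cum[idx[i - 1L], ]) + 1L
    }
    s <- BASES[idx]
  }
  g <- genome_seq(stats::setNames(paste(s, collapse = ""), chrom))
  g
}

#' Write a genome as FASTA
#' @param genome A `genome_seq`.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Plant binding sites into a genome
#'
#' Draws `n` site sequences from a per-position base distribution (or an
#' exact consensus), writes them into the genome at non-overlapping
#' positions on random strands, and returns the modified genome together
#' with the site intervals and the ground-truth composition. Placements
#' keep an exclusion margin of `2 * flank` around each site so context
#' windows never collide.
#'
#' @param genome A `genome_seq`.
#' @param motif Either a consensus string (planted exactly) or a 4 x L
#'   matrix of per-position base probabilities (rows A/C/G/T).
#' @param n Number of sites.
#' @param flank Flank width the downstream analysis will use (sets the
#'   exclusion margin and keeps sites off chromosome edges).
#' @param seed Random seed.
#' @param strand Site strands: `"random"` (default), `"+"` or `"-"`.
#' @return List with `genome` (modified), `sites` (a stranded
#'   `region_set`), `pwm` (the true 4 x L composition).
#' @export
plant_sites <- function(genome, motif, n, flank = 10L, seed, strand = "random") {
  if (missing(seed)) stop("seed is mandatory")
  if (is.character(motif)) {
    cons <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
    if (!all(cons %in% BASES)) stop("consensus must be over ACGT")
    pwm <- matrix(0, 4L, length(cons), dimnames = list(BASES, NULL))
    pwm[cbind(match(cons, BASES), seq_along(cons))] <- 1
  } else {
    pwm <- motif[BASES, , drop = FALSE]
    pwm <- sweep(pwm, 2L, colSums(pwm), "/")
  }
  L <- ncol(pwm)
  chrom <- names(genome$seq)[1L]
  glen <- genome$lengths[[chrom]]
  if (L > glen) stop("motif longer than genome")
  set.seed(seed)
  margin <- 2L * flank + 2L
  lo <- margin
  hi <- glen - L - margin
  if (hi <= lo) stop("genome too short to place sites")
  if (n == 0L) {
    return(list(
      genome = genome,
      sites = region_set("chr", 0L, 1L)[0L, , drop = FALSE],
      pwm = pwm
    ))
  }
  # rejection-sample non-overlapping starts with the exclusion margin
  starts <- integer(0L)
  tries <- 0L
  while (length(starts) < n) {
    tries <- tries + 1L
    if (tries > 200L * n) {
      stop("cannot place ", n, " non-overlapping sites in ", glen, " bp")
    }
    cand <- sample(lo:hi, 1L)
    if (all(abs(cand - starts) >= L + margin)) starts <- c(starts, cand)
  }
  starts <- sort(starts)
  strands <- switch(strand,
    random = sample(c("+", "-"), n, replace = TRUE),
    rep(strand, n)
  )
  seqchars <- strsplit(genome$seq[[chrom]], "", fixed = TRUE)[[1L]]
  for (i in seq_len(n)) {
    drawn <- vapply(
      seq_len(L),
      function(j) sample(BASES, 1L, prob = pwm[, j]),
      character(1L)
    )
    inserted <- if (strands[i] == "-") {
      rev(chartr("ACGT", "TGCA", drawn))
    } else {
      drawn
    }
    seqchars[(starts[i] + 1L):(starts[i] + L)] <- inserted
  }
  g2 <- genome_seq(stats::setNames(paste(seqchars, collapse = ""), chrom))
  list(
    genome = g2,
    sites = region_set(chrom, starts, starts + L, strands),
    pwm = pwm
  )
}

#' Simulate replicate WGBS methylation calls
#'
#' For every strand-relative cytosine in the genome (both strands), the true
#' methylation level is its context's probability, unless overridden (e.g.
#' inside planted binding sites). Each replicate then observes
#' `Binomial(depth, true) / depth` at a per-site read depth drawn from the
#' chosen distribution.
#'
#' @param genome A `genome_seq`.
#' @param context_levels Named true methylation probabilities for CG, CHG,
#'   CHH.
#' @param depth Mean (or fixed) read depth.
#' @param depth_dist `"fixed"` or `"poisson"`.
#' @param n_reps Number of replicates.
#' @param seed Random seed.
#' @param overrides Optional data frame `chrom`, `pos`, `strand`, `level`
#'   of true levels that replace the context default at those cytosines.
#' @return List of `wgbs_calls` data frames, one per replicate.
#' @export
simulate_methylome <- function(genome,
                               context_levels = c(CG = 0.8, CHG = 0.05, CHH = 0.02),
                               depth = 30L, depth_dist = c("fixed", "poisson"),
                               n_reps = 2L, seed, overrides = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  depth_dist <- match.arg(depth_dist)
  cyt <- genome_cytosines(genome)
  ctx <- classify_context(genome, cyt$chrom, cyt$pos, cyt$strand)
  keep <- ctx != "UNDEFINED"
  cyt <- cyt[keep, , drop = FALSE]
  ctx <- ctx[keep]
  true <- unname(context_levels[ctx])
  if (!is.null(overrides) && nrow(overrides)) {
    i <- match(
      paste(cyt$chrom, cyt$pos, cyt$strand, sep = "\r"),
      paste(overrides$chrom, overrides$pos, overrides$strand, sep = "\r")
    )
    hit <- !is.na(i)
    true[hit] <- overrides$level[i[hit]]
  }
  set.seed(seed)
  m <- nrow(cyt)
  lapply(seq_len(n_reps), function(r) {
    d <- switch(depth_dist,
      fixed = rep(as.integer(depth), m),
      poisson = stats::rpois(m, depth)
    )
    obs <- ifelse(d > 0L, stats::rbinom(m, d, true) / pmax(d, 1L), 0)
    calls <- data.frame(
      chrom = cyt$chrom, pos = cyt$pos, strand = cyt$strand,
      level = obs, depth = d, stringsAsFactors = FALSE
    )
    class(calls) <- c("wgbs_calls", "data.frame")
    calls
  })
}

#' Simulate random transcription start sites
#'
#' @param genome A `genome_seq`.
#' @param n Number of TSS.
#' @param seed Random seed.
#' @return Data frame `chrom`, `pos` (0-based), `strand`.
#' @export
simulate_tss <- function(genome, n, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  chrom <- names(genome$seq)[1L]
  glen <- genome$lengths[[chrom]]
  data.frame(
    chrom = chrom,
    pos = sort(sample.int(glen, n)) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Generate and write a complete synthetic dataset
#'
#' Simulates a genome (with a CpG-depleted first-order chain by default, as
#' in mammalian genomes), plants hypo-methylatable binding sites, simulates
#' two replicate WGBS call sets, and writes FASTA, two WGBS TSVs, a BED6
#' site file, a TSS table and a JSON manifest recording the parameters and
#' seed.
#'
#' @param dir Output directory (created if needed).
#' @param genome_length Genome size in bp.
#' @param consensus Planted motif consensus.
#' @param n_sites Number of planted sites.
#' @param site_cg_level True methylation level of CpG cytosines inside
#'   planted sites (hypo-methylated against the CG background by default).
#' @param context_levels Background true methylation per context.
#' @param cg_depletion Factor by which C-to-G transitions are depleted in
#'   the background chain.
#' @param depth Read depth of the simulated WGBS.
#' @param n_tss Number of simulated TSS.
#' @param flank Flank width used for the exclusion margin.
#' @param seed Random seed.
#' @return Named list of written paths (`fasta`, `wgbs`, `sites_bed`, `tss`,
#'   `manifest`) plus the in-memory objects (`genome`, `sites` as a
#'   `region_set`, `replicates`, `tss_table`, `pwm`).
#' @export
simulate_dataset <- function(dir,
                             genome_length = 100000L,
                             consensus = "CACGTG",
                             n_sites = 200L,
                             site_cg_level = 0.05,
                             context_levels = c(CG = 0.8, CHG = 0.05, CHH = 0.02),
                             cg_depletion = 5,
                             depth = 30L,
                             n_tss = 20L,
                             flank = 10L,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trans <- cpg_depleted_chain(cg_depletion)
  g <- simulate_genome(genome_length,
    transition = trans, seed = seed,
    base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  )
  pl <- plant_sites(g, consensus, n_sites, flank = flank, seed = seed + 1L)
  # hypo-methylate the CpG cytosines of every planted site
  ov <- site_cpg_overrides(pl$genome, pl$sites, site_cg_level)
  reps <- simulate_methylome(pl$genome,
    context_levels = context_levels,
    depth = depth, seed = seed + 2L, overrides = ov
  )
  tss <- simulate_tss(pl$genome, n_tss, seed = seed + 3L)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    wgbs = file.path(dir, c("wgbs_rep1.tsv", "wgbs_rep2.tsv")),
    sites_bed = file.path(dir, "sites.bed"),
    tss = file.path(dir, "tss.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_fasta(pl$genome, paths$fasta)
  write_wgbs(reps[[1L]], paths$wgbs[1L])
  write_wgbs(reps[[2L]], paths$wgbs[2L])
  write_bed6(pl$sites, paths$sites_bed)
  utils::write.table(
    data.frame(tss$chrom, tss$pos + 1L, tss$strand),
    paths$tss,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  jsonlite::write_json(
    list(
      generator = "methylogo::simulate_dataset", seed = seed,
      genome_length = genome_length, consensus = consensus,
      n_sites = n_sites, site_cg_level = site_cg_level,
      context_levels = as.list(context_levels),
      cg_depletion = cg_depletion, depth = depth, n_tss = n_tss,
      flank = flank
    ),
    paths$manifest,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  c(paths, list(
    genome = pl$genome, sites = pl$sites, replicates = reps,
    tss_table = tss, pwm = pl$pwm
  ))
}

#' CpG-depleted first-order transition matrix
#'
#' A background chain whose stationary composition is roughly uniform but
#' whose C-to-G transition probability is divided by `factor`, emulating the
#' CpG depletion of mammalian genomes.
#'
#' @param factor Depletion factor (> 1 depletes CpG).
#' @return 4 x 4 transition matrix (rows sum to 1).
#' @export
cpg_depleted_chain <- function(factor = 5) {
  m <- matrix(0.25, 4L, 4L, dimnames = list(BASES, BASES))
  m["C", "G"] <- 0.25 / factor
  m["C", ] <- m["C", ] / sum(m["C", ])
  m
}

# true-level overrides for the CpG cytosines (both strands) inside sites
site_cpg_overrides <- function(genome, sites, level) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    s <- genome_slice(genome, sites$chrom[i], sites$start[i], sites$end[i])
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    pos <- sites$start[i] + seq_along(ch) - 1L
    is_cg_fwd <- ch == "C" & c(ch[-1L], "") == "G"
    is_cg_rev <- ch == "G" & c("", ch[-length(ch)]) == "C"
    if (any(is_cg_fwd | is_cg_rev)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = sites$chrom[i],
        pos = c(pos[is_cg_fwd], pos[is_cg_rev]),
        strand = rep(c("+", "-"), c(sum(is_cg_fwd), sum(is_cg_rev))),
        level = level, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}
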