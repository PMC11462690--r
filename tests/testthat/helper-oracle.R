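# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive (enumeration, O(n*m) scans) so it cannot share a bug
# with the implementation it checks.

bases4 <- c("A", "C", "G", "T")

random_simplex <- function(k) {
  x <- stats::runif(k) + 1e-3
  x / sum(x)
}

# fabricate a motif model directly from probabilities (independent-position
# pairs unless given); bypasses site counting entirely
fab_motif <- function(p, pairs = NULL, ctx_prob = NULL, m = NULL, n = 100L) {
  L <- nrow(p)
  dimnames(p) <- list(NULL, bases4)
  if (is.null(pairs) && L >= 2L) {
    pairs <- lapply(seq_len(L - 1L), function(j) outer(p[j, ], p[j + 1L, ]))
  }
  pairs <- lapply(pairs, function(x) {
    dimnames(x) <- list(bases4, bases4)
    x
  })
  if (is.null(ctx_prob)) {
    ctx_prob <- array(0, c(L, 3L, 2L),
      dimnames = list(NULL, c("CG", "CHG", "CHH"), c("+", "-"))
    )
  }
  if (is.null(m)) m <- array(NA_real_, dim(ctx_prob), dimnames = dimnames(ctx_prob))
  structure(
    list(
      L = L, n = n, p = p, pairs = pairs, ctx_prob = ctx_prob, m = m,
      observed = matrix(NA_real_, L, 2L, dimnames = list(NULL, c("+", "-"))),
      pseudocount = 0
    ),
    class = "motif_model"
  )
}

fab_bg0 <- function(q) {
  names(q) <- bases4
  structure(list(q = q, counts = NULL, pseudocount = 0), class = "bg_zero")
}

fab_bg1 <- function(joint) {
  dimnames(joint) <- list(bases4, bases4)
  marg <- rowSums(joint)
  structure(
    list(
      joint = joint, marginal = marg, conditional = joint / marg,
      counts = NULL, pseudocount = 0
    ),
    class = "bg_first"
  )
}

fab_mbg <- function(m, eps = 1e-4) {
  m <- pmin(pmax(m, eps), 1 - eps)
  names(m) <- c("CG", "CHG", "CHH")
  structure(list(m = m, n = c(CG = 1L, CHG = 1L, CHH = 1L), eps = eps),
    class = "bg_methyl"
  )
}

random_rc_symmetric_joint <- function() {
  # random dimer joint invariant under reverse complement, as double-strand
  # counting produces
  x <- matrix(stats::runif(16) + 0.05, 4L, 4L, dimnames = list(bases4, bases4))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  y <- x
  for (a in bases4) {
    for (b in bases4) {
      y[a, b] <- x[a, b] + x[comp[b], comp[a]]
    }
  }
  y / sum(y)
}

# brute-force relative entropies by enumerating all 4^L sequences under the
# independent-position motif model; the first-order background emits its
# first base from the marginal of the dimer joint
brute_force_relent <- function(p, joint) {
  L <- nrow(p)
  marg <- rowSums(joint)
  cond <- joint / marg
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  pm <- rep(1, nrow(grid))
  pb0 <- rep(1, nrow(grid))
  pb1 <- marg[grid[, 1L]]
  for (i in seq_len(L)) {
    pm <- pm * p[i, grid[, i]]
    pb0 <- pb0 * marg[grid[, i]]
    if (i >= 2L) pb1 <- pb1 * cond[cbind(grid[, i - 1L], grid[, i])]
  }
  nz <- pm > 0
  list(
    D0 = sum(pm[nz] * log2(pm[nz] / pb0[nz])),
    D1 = sum(pm[nz] * log2(pm[nz] / pb1[nz]))
  )
}

# naive O(n*m) interval filter under half-open coordinates
naive_intersect <- function(a, b, mode = "overlap-any") {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      same <- a$chrom[i] == b$chrom[j]
      if (!same) next
      hit <- if (mode == "contained") {
        a$start[i] >= b$start[j] && a$end[i] <= b$end[j]
      } else {
        a$start[i] < b$end[j] && b$start[j] < a$end[i]
      }
      if (hit) {
        keep[i] <- TRUE
        break
      }
    }
  }
  a[keep, , drop = FALSE]
}

# brute-force per-context cytosine counts over both strands of a sequence,
# skipping cytosines within 2 bp of either end
brute_context_counts <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cnt <- c(CG = 0L, CHG = 0L, CHH = 0L)
  cls <- function(d1, d2) {
    if (d1 == "G") {
      "CG"
    } else if (d2 == "G") {
      "CHG"
    } else {
      "CHH"
    }
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (i in seq_len(n)) {
    if (i <= 2L || i > n - 2L) next
    if (ch[i] == "C") {
      cx <- cls(ch[i + 1L], ch[i + 2L])
      cnt[cx] <- cnt[cx] + 1L
    }
    if (ch[i] == "G") {
      cx <- cls(comp[ch[i - 1L]], comp[ch[i - 2L]])
      cnt[cx] <- cnt[cx] + 1L
    }
  }
  cnt
}

# quick builders ------------------------------------------------------------

tiny_genome <- function(...) {
  seqs <- c(...)
  genome_seq(seqs)
}

calls_df <- function(chrom, pos, strand, level, depth) {
  df <- data.frame(
    chrom = chrom, pos = as.integer(pos), strand = strand,
    level = level, depth = as.integer(depth), stringsAsFactors = FALSE
  )
  class(df) <- c("wgbs_calls", "data.frame")
  df
}

mt_df <- function(chrom = character(), pos = integer(), strand = character(),
                  level = numeric()) {
  methyl_table(data.frame(
    chrom = chrom, pos = pos, strand = strand,
    level = level, stringsAsFactors = FALSE
  ))
}

# a small deterministic random genome string over ACGT
random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(bases4, n, replace = TRUE), collapse = "")
}

# plant unmethylated-CpG sites in a genome whose CpGs are otherwise highly
# methylated; flanks then behave like background
scape_fixture <- function(n_sites = 80L, seed = 77L) {
  sim <- simulate_dataset(tempfile("scape"),
    genome_length = 60000L,
    consensus = "CACGTG", n_sites = n_sites, site_cg_level = 0.02,
    depth = 40L, seed = seed
  )
  mt <- merge_replicates(sim$replicates)
  sm <- extract_site_matrix(sim$genome, sim$sites, mt, flank = 20L)
  mbg <- estimate_methyl_background(mt, sim$genome)
  list(sm = sm, mbg = mbg, sim = sim)
}

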