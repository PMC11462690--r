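#' Binary Kullback-Leibler divergence in bits
#'
#' `kl2(p, q) = p lg(p/q) + (1-p) lg((1-p)/(1-q))` with both arguments
#' clamped into `[eps, 1-eps]` so the value stays finite at 0 and 1.
#'
#' @param p,q Bernoulli parameters (vectorised).
#' @param eps Clamping width.
#' @return Divergence in bits (non-negative).
#' @export
kl2 <- function(p, q, eps = 1e-4) {
  p <- pmin(pmax(p, eps), 1 - eps)
  q <- pmin(pmax(q, eps), 1 - eps)
  p * log2(p / q) + (1 - p) * log2((1 - p) / (1 - q))
}

xlog2x_ratio <- function(p, q) {
  # p * lg(p/q) with the convention 0 * lg(0/q) = 0
  out <- rep(0, length(p))
  nz <- p > 0
  out[nz] <- p[nz] * log2(p[nz] / q[nz])
  out
}

#' Sequence-logo track heights
#'
#' The height of column i is the relative entropy (bits) of the motif base
#' distribution against the zero-order background,
#' `sum_b p_i(b) lg(p_i(b) / q(b))`; letters within the column get height
#' proportional to their probability, so relative letter height equals base
#' frequency.
#'
#' @param motif A `motif_model`.
#' @param bg0 A `bg_zero` background.
#' @return List with `heights` (length L, bits) and `letters` (L x 4 matrix
#'   of per-base letter heights in bits).
#' @export
sequence_track_heights <- function(motif, bg0) {
  L <- motif$L
  h <- vapply(
    seq_len(L),
    function(i) sum(xlog2x_ratio(motif$p[i, ], bg0$q)),
    numeric(1L)
  )
  letters <- motif$p * h
  dimnames(letters) <- list(NULL, BASES)
  list(heights = h, letters = letters)
}

#' Dimer track heights and theoretical bounds
#'
#' The dimer track displays, between each pair of adjacent positions, the
#' difference between the relative entropy of the motif against a first-order
#' background and against the zero-order background. This difference
#' decomposes exactly into one term per adjacent pair,
#' `sum_ab p_{j,j+1}(a,b) lg( q(a) q(b) / q(a,b) )`,
#' provided the zero-order q is the marginal of the dimer joint (the
#' first-order chain emits its first base from that marginal). Positive bars
#' flag under-represented dimers in the background (typically CpG); negative
#' bars over-represented ones. The theoretical bounds are the extrema of the
#' per-pair log-ratio over the 16 ordered dimers.
#'
#' @param motif A `motif_model`.
#' @param bg1 A `bg_first` background.
#' @param bg0 Optional `bg_zero`; defaults to the marginal of `bg1`, which
#'   makes the decomposition exact.
#' @return List with `heights` (length L-1, signed bits), `bound_max`,
#'   `bound_min`.
#' @export
dimer_track_heights <- function(motif, bg1, bg0 = NULL) {
  qa <- if (is.null(bg0)) bg1$marginal else bg0$q
  ratio <- log2(outer(qa, qa) / bg1$joint) # lg(q(a)q(b)/q(a,b))
  h <- vapply(
    motif$pairs,
    function(pp) sum(pp * ratio),
    numeric(1L)
  )
  list(
    heights = if (motif$L >= 2L) h else numeric(0L),
    bound_max = max(ratio), bound_min = min(ratio)
  )
}

#' Methylation track component heights
#'
#' The methylation information at position i decomposes over the six
#' strand-specific contexts (CG, CHG, CHH on the motif-forward and
#' motif-reverse strand). Each component is
#' `P(ctx, s | i) * kl2( m_{i,ctx,s} || m_bg(ctx) )`:
#' the probability that a site carries such a cytosine there, times the
#' binary relative entropy between the observed and background methylation
#' probability. The multiplicative context-probability term makes the track
#' robust to estimation noise in rare contexts. Components with positive
#' context probability but no surviving methylation observation are skipped
#' with a warning.
#'
#' @param motif A `motif_model`.
#' @param mbg A `bg_methyl` background.
#' @return L x 6 matrix of non-negative component heights (bits); columns
#'   named `"CG+", "CHG+", "CHH+", "CG-", "CHG-", "CHH-"`.
#' @export
methylation_track_heights <- function(motif, mbg) {
  L <- motif$L
  cols <- as.vector(outer(CONTEXTS, STRANDS, paste0))
  comp <- matrix(0, L, 6L, dimnames = list(NULL, cols))
  skipped <- character(0L)
  for (s in STRANDS) {
    for (cx in CONTEXTS) {
      cn <- paste0(cx, s)
      for (i in seq_len(L)) {
        pc <- motif$ctx_prob[i, cx, s]
        if (pc > 0) {
          mi <- motif$m[i, cx, s]
          if (is.na(mi)) {
            skipped <- c(skipped, sprintf("position %d %s%s", i - 1L, cx, s))
          } else {
            comp[i, cn] <- pc * kl2(mi, mbg$m[[cx]], eps = mbg$eps)
          }
        }
      }
    }
  }
  if (length(skipped)) {
    warning(
      "methylation component skipped (context present, no observation): ",
      paste(skipped, collapse = "; ")
    )
  }
  comp
}

#' Expected methylation line
#'
#' The methylation level one would expect at each motif position per strand
#' if binding sites were methylated like the background: the background
#' probabilities of the contexts present at that position, weighted by their
#' context probabilities, `sum_ctx P(ctx,s|i) m_bg(ctx) / sum_ctx P(ctx,s|i)`.
#' Undefined (NA) where the position has no strand-relative cytosine.
#'
#' @param motif A `motif_model`.
#' @param mbg A `bg_methyl` background.
#' @return L x 2 matrix (columns `"+"`, `"-"`) of expected levels.
#' @export
expected_methylation_line <- function(motif, mbg) {
  L <- motif$L
  out <- matrix(NA_real_, L, 2L, dimnames = list(NULL, STRANDS))
  for (s in STRANDS) {
    for (i in seq_len(L)) {
      pc <- motif$ctx_prob[i, , s]
      tot <- sum(pc)
      if (tot > 0) out[i, s] <- sum(pc * mbg$m[CONTEXTS]) / tot
    }
  }
  out
}

#' Compute all three information tracks
#'
#' Assembles the sequence, dimer and methylation tracks plus the expected-
#' and observed-methylation lines into one object.
#'
#' @param motif A `motif_model`.
#' @param background A `background_bundle` (or pass `bg0`, `bg1`, `mbg`).
#' @param bg0,bg1,mbg Individual backgrounds, used when `background` is NULL.
#' @return A `track_set` with components `seq_heights`, `letters`,
#'   `dimer_heights`, `dimer_bound_max`, `dimer_bound_min`, `meth` (L x 6),
#'   `expected` (L x 2), `observed` (L x 2), `L`.
#' @export
track_set <- function(motif, background = NULL, bg0 = NULL, bg1 = NULL, mbg = NULL) {
  if (!is.null(background)) {
    stopifnot(inherits(background, "background_bundle"))
    bg0 <- background$bg0
    bg1 <- background$bg1
    mbg <- background$mbg
  }
  seq <- sequence_track_heights(motif, bg0)
  dim <- dimer_track_heights(motif, bg1, bg0)
  meth <- methylation_track_heights(motif, mbg)
  structure(
    list(
      seq_heights = seq$heights, letters = seq$letters,
      dimer_heights = dim$heights,
      dimer_bound_max = dim$bound_max, dimer_bound_min = dim$bound_min,
      meth = meth,
      expected = expected_methylation_line(motif, mbg),
      observed = motif$observed,
      L = motif$L
    ),
    class = "track_set"
  )
}

#' Total information of a track set
#'
#' Sum of all sequence-column heights, dimer bars, and methylation component
#' heights, in bits: the quantity a reader estimates by visually adding up
#' all elements of the display.
#'
#' @param tracks A `track_set`.
#' @return Total information in bits.
#' @export
total_information <- function(tracks) {
  stopifnot(inherits(tracks, "track_set"))
  sum(tracks$seq_heights) + sum(tracks$dimer_heights) + sum(tracks$meth)
}

#' @export
print.track_set <- function(x, ...) {
  cat("<track_set> L =", x$L, "\n")
  cat(sprintf("  sequence track: %.3f bits\n", sum(x$seq_heights)))
  cat(sprintf("  dimer track:    %.3f bits\n", sum(x$dimer_heights)))
  cat(sprintf("  methyl track:   %.3f bits\n", sum(x$meth)))
  cat(sprintf("  total:          %.3f bits\n", total_information(x)))
  invisible(x)
}

#' Tidy per-position table of track values
#'
#' One row per (position, element): sequence letter heights, dimer bars,
#' methylation components and the expected/observed methylation lines.
#'
#' @param x A `track_set`.
#' @param ... Unused.
#' @return A data frame with columns `track`, `pos`, `element`, `value`.
#' @export
as.data.frame.track_set <- function(x, ...) {
  L <- x$L
  rows <- list()
  rows$seq <- data.frame(
    track = "sequence",
    pos = rep(0:(L - 1L), 4L),
    element = rep(BASES, each = L),
    value = as.vector(x$letters)
  )
  if (L >= 2L) {
    rows$dimer <- data.frame(
      track = "dimer", pos = 0:(L - 2L), element = "bar",
      value = x$dimer_heights
    )
  }
  rows$meth <- data.frame(
    track = "methylation",
    pos = rep(0:(L - 1L), 6L),
    element = rep(colnames(x$meth), each = L),
    value = as.vector(x$meth)
  )
  for (s in STRANDS) {
    rows[[paste0("exp", s)]] <- data.frame(
      track = "expected_methylation", pos = 0:(L - 1L),
      element = s, value = x$expected[, s]
    )
    rows[[paste0("obs", s)]] <- data.frame(
      track = "observed_methylation", pos = 0:(L - 1L),
      element = s, value = x$observed[, s]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write track values as TSV
#' @param tracks A `track_set`.
#' @param path Output path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.table(as.data.frame(tracks), path,
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
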