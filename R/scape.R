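#' Flanking-window methylation profile around binding sites
#'
#' For every motif-oriented offset d in `[-window, L + window)` and every
#' trinucleotide context, computes over the aligned sites (both strands
#' pooled):
#'
#' * `P_ctx(d)` — the fraction of sites carrying a strand-relative cytosine
#'   of that context at d,
#' * `m(d, ctx)` — the mean available merged methylation level of those
#'   cytosines (`NA` when none passed the depth filter),
#' * `e(d, ctx)` — the methylation relative entropy
#'   `P_ctx(d) * kl2( m(d,ctx) || m_bg(ctx) )` (bits), 0 wherever
#'   `P_ctx(d) = 0`; with `weighted = FALSE` the context-probability factor
#'   is dropped.
#'
#' @param sm A `site_matrix` whose flank is at least `window`.
#' @param mbg A `bg_methyl` background.
#' @param window Half-width of the profile in bp beyond the motif ends.
#' @param weighted Multiply the divergence by `P_ctx(d)` (default).
#' @return A `scape_profile` with matrices `P`, `m`, `e` (offsets x 3
#'   contexts), `offsets`, `L`, `window`, `n`, `mbg`, `weighted`.
#' @export
methylscape_profile <- function(sm, mbg, window = 500L, weighted = TRUE) {
  stopifnot(inherits(sm, "site_matrix"), inherits(mbg, "bg_methyl"))
  if (window > sm$flank) {
    stop("window (", window, ") exceeds available flank (", sm$flank, ")")
  }
  sel <- which(sm$offsets >= -window & sm$offsets <= sm$L - 1L + window)
  offs <- sm$offsets[sel]
  D <- length(sel)
  P <- matrix(0, D, 3L, dimnames = list(NULL, CONTEXTS))
  m <- matrix(NA_real_, D, 3L, dimnames = list(NULL, CONTEXTS))
  e <- matrix(0, D, 3L, dimnames = list(NULL, CONTEXTS))
  for (k in seq_len(D)) {
    j <- sel[k]
    ctx <- c(sm$ctx_fwd[, j], sm$ctx_rev[, j])
    lev <- c(sm$meth_fwd[, j], sm$meth_rev[, j])
    undef <- sum(!is.na(ctx) & ctx == "UNDEFINED")
    denom <- sm$n - undef
    for (cx in CONTEXTS) {
      in_class <- !is.na(ctx) & ctx == cx
      if (denom > 0L) P[k, cx] <- sum(in_class) / denom
      obs <- lev[in_class & !is.na(lev)]
      if (length(obs)) m[k, cx] <- mean(obs)
      if (P[k, cx] > 0 && !is.na(m[k, cx])) {
        d <- kl2(m[k, cx], mbg$m[[cx]], eps = mbg$eps)
        e[k, cx] <- if (weighted) P[k, cx] * d else d
      }
    }
  }
  structure(
    list(
      P = P, m = m, e = e, offsets = offs, L = sm$L,
      window = window, n = sm$n, mbg = mbg, weighted = weighted
    ),
    class = "scape_profile"
  )
}

#' @export
print.scape_profile <- function(x, ...) {
  cat(
    "<scape_profile> offsets ", min(x$offsets), "..", max(x$offsets),
    " (motif 0..", x$L - 1L, "), ", x$n, " sites\n",
    sep = ""
  )
  peak <- x$offsets[which.max(rowSums(x$e))]
  cat(sprintf("  peak methylation entropy at offset %d\n", peak))
  invisible(x)
}

#' Tidy long table of a flanking profile
#' @param x A `scape_profile`.
#' @param ... Unused.
#' @return Data frame with columns `offset`, `context`, `context_prob`,
#'   `methylation`, `entropy_bits`.
#' @export
as.data.frame.scape_profile <- function(x, ...) {
  data.frame(
    offset = rep(x$offsets, 3L),
    context = rep(CONTEXTS, each = length(x$offsets)),
    context_prob = as.vector(x$P),
    methylation = as.vector(x$m),
    entropy_bits = as.vector(x$e)
  )
}

#' Write a flanking profile as TSV
#' @param profile A `scape_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path,
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
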