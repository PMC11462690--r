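#' Assemble the aligned binding-site matrix
#'
#' Builds the central data structure of the package: `n` aligned binding
#' sites x (motif length `L` + two flanks of width `flank`) cells. Sites on
#' the minus strand are reverse-complemented into motif orientation so that
#' column `i` is homologous across sites. Each cell records its base; cells
#' holding a strand-relative cytosine (base C on the motif-forward strand,
#' base G meaning a cytosine on the motif-reverse strand) additionally carry
#' their trinucleotide context — classified from genomic flanking bases, so a
#' site-final cytosine's context can depend on bases beyond the motif — and,
#' when the site passed the WGBS depth filter, its merged methylation level.
#'
#' Strand labels on cytosine observations are motif-relative: `"+"` is the
#' motif-forward strand. For a minus-strand site this corresponds to the
#' genome minus strand, and lookups into the methylation table are performed
#' genome-strand-aware.
#'
#' Sites too close to a chromosome edge for the flank plus the 2-bp context
#' window, or whose window contains N, are dropped with a warning.
#'
#' @param genome A `genome_seq`.
#' @param sites A `region_set` of equal-length stranded intervals.
#' @param methyl A `methyl_table` (may be empty).
#' @param flank Flank width in bp on each side of the motif (>= 2).
#' @return A `site_matrix` object with components `base`, `ctx_fwd`,
#'   `ctx_rev`, `meth_fwd`, `meth_rev` (n x (L + 2*flank) matrices),
#'   `offsets` (motif-relative column offsets, `-flank .. L-1+flank`), `L`,
#'   `flank`, `n`, and `sites` (the retained intervals).
#' @export
extract_site_matrix <- function(genome, sites, methyl = NULL, flank = 10L) {
  stopifnot(inherits(genome, "genome_seq"))
  if (is.null(methyl)) {
    methyl <- methyl_table(data.frame(
      chrom = character(), pos = integer(),
      strand = character(), level = numeric()
    ))
  }
  if (flank < 2L) stop("flank must be >= 2 (context lookup needs 2 bp)")
  if (nrow(sites) == 0L) stop("empty site set")
  widths <- sites$end - sites$start
  if (length(unique(widths)) != 1L) {
    off <- which(widths != widths[1L])
    stop(
      "sites must have equal length; offending rows: ",
      paste(utils::head(off, 5L), collapse = ", ")
    )
  }
  if (!all(sites$strand %in% c("+", "-"))) {
    stop("binding sites must be stranded (+/-)")
  }
  L <- widths[1L]
  W <- L + 2L * flank
  len <- genome$lengths[sites$chrom]
  if (any(is.na(len))) {
    stop("unknown chromosome in sites: ", sites$chrom[is.na(len)][1L])
  }
  ok_edge <- sites$start - flank - 2L >= 0L & sites$end + flank + 2L <= len
  n_edge <- sum(!ok_edge)
  kept <- sites[ok_edge, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no sites remain after edge filtering")

  # window sequences in motif orientation (including context padding checks)
  win <- character(nrow(kept))
  has_n <- logical(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    s <- genome_slice(
      genome, kept$chrom[i],
      kept$start[i] - flank - 2L, kept$end[i] + flank + 2L
    )
    has_n[i] <- grepl("N", s, fixed = TRUE)
    s <- substring(s, 3L, 2L + W)
    win[i] <- if (kept$strand[i] == "-") revcomp(genome_slice(
      genome, kept$chrom[i], kept$start[i] - flank, kept$end[i] + flank
    )) else s
  }
  if (any(has_n)) {
    kept <- kept[!has_n, , drop = FALSE]
    win <- win[!has_n]
  }
  n_drop <- n_edge + sum(has_n)
  if (n_drop > 0L) {
    warning(
      n_drop, " site(s) dropped (", n_edge, " at chromosome edge, ",
      sum(has_n), " containing N)"
    )
  }
  n <- nrow(kept)
  if (n == 0L) stop("no sites remain after N filtering")

  base <- matrix(unlist(strsplit(win, "", fixed = TRUE)),
    nrow = n, ncol = W, byrow = TRUE
  )
  ctx_f <- matrix(NA_character_, n, W)
  ctx_r <- matrix(NA_character_, n, W)
  meth_f <- matrix(NA_real_, n, W)
  meth_r <- matrix(NA_real_, n, W)

  # genomic coordinate of column j for each site
  col_off <- seq_len(W) - 1L
  for (i in seq_len(n)) {
    plus <- kept$strand[i] == "+"
    gpos <- if (plus) kept$start[i] - flank + col_off else kept$end[i] - 1L + flank - col_off
    is_c <- base[i, ] == "C" # motif-forward cytosine
    is_g <- base[i, ] == "G" # motif-reverse cytosine
    # genome strand carrying the cytosine
    gs_fwd <- if (plus) "+" else "-"
    gs_rev <- if (plus) "-" else "+"
    if (any(is_c)) {
      ctx_f[i, is_c] <- classify_context(genome, kept$chrom[i], gpos[is_c], gs_fwd)
      meth_f[i, is_c] <- methyl_lookup(methyl, kept$chrom[i], gpos[is_c], gs_fwd)
    }
    if (any(is_g)) {
      ctx_r[i, is_g] <- classify_context(genome, kept$chrom[i], gpos[is_g], gs_rev)
      meth_r[i, is_g] <- methyl_lookup(methyl, kept$chrom[i], gpos[is_g], gs_rev)
    }
  }
  structure(
    list(
      base = base, ctx_fwd = ctx_f, ctx_rev = ctx_r,
      meth_fwd = meth_f, meth_rev = meth_r,
      offsets = -flank:(L - 1L + flank), L = L, flank = flank, n = n,
      sites = kept
    ),
    class = "site_matrix"
  )
}

#' @export
print.site_matrix <- function(x, ...) {
  cat(
    "<site_matrix> ", x$n, " sites x ", ncol(x$base), " columns (L = ", x$L,
    ", flank = ", x$flank, ")\n",
    sep = ""
  )
  nobs <- sum(!is.na(x$meth_fwd)) + sum(!is.na(x$meth_rev))
  cat("  methylation observations: ", nobs, "\n", sep = "")
  invisible(x)
}

#' Reverse-complement an aligned site matrix
#'
#' Reverses columns, complements bases and swaps the motif-forward /
#' motif-reverse cytosine annotations. Used to verify strand bookkeeping:
#' column `i` of the result equals column `W - 1 - i` of the input with
#' strand labels swapped.
#'
#' @param sm A `site_matrix`.
#' @return The reverse-complemented `site_matrix`.
#' @export
revcomp_sites <- function(sm) {
  stopifnot(inherits(sm, "site_matrix"))
  W <- ncol(sm$base)
  rev_cols <- W:1L
  base <- matrix(comp_base(sm$base[, rev_cols, drop = FALSE]), sm$n, W)
  out <- sm
  out$base <- base
  out$ctx_fwd <- sm$ctx_rev[, rev_cols, drop = FALSE]
  out$ctx_rev <- sm$ctx_fwd[, rev_cols, drop = FALSE]
  out$meth_fwd <- sm$meth_rev[, rev_cols, drop = FALSE]
  out$meth_rev <- sm$meth_fwd[, rev_cols, drop = FALSE]
  out
}

core_columns <- function(sm) sm$flank + seq_len(sm$L)
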