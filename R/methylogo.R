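#' Fit a methylation-aware sequence logo model
#'
#' The central fitting function of the package: from a genome, merged WGBS
#' methylation calls and a set of equal-length aligned binding sites, it
#' estimates the background models (zero-order base, first-order dimer and
#' per-context methylation probabilities over the whole genome or a supplied
#' region set), builds the motif model (position weight matrix, adjacent-pair
#' joints, per-position strand x context probabilities and mean methylation),
#' and computes the three information tracks in bits.
#'
#' @param sites A stranded `region_set` of equal-length binding sites, or a
#'   path to a BED6 file.
#' @param genome A `genome_seq`, or a path to a FASTA file.
#' @param methyl A `methyl_table` (see [merge_replicates()]), a
#'   `wgbs_calls` data frame, or a list of them (replicates to merge).
#' @param background A precomputed `background_bundle` (see
#'   [read_background()]); when `NULL` it is estimated from `genome` and
#'   `methyl` over `regions`.
#' @param regions Optional `region_set` the background is estimated over
#'   (e.g. promoters); `NULL` means the whole genome.
#' @param flank Flank width in bp kept around the motif (>= 2; also sets how
#'   far [methylscape()] can look).
#' @param pseudocount Pseudocount per motif count cell.
#' @param min_depth Depth filter used when `methyl` is given as replicate
#'   call sets.
#' @param label Background label for figures (`"WG"`/`"PR"`); defaults by
#'   whether `regions` is given.
#' @return An object of class `methylogo` with components `sites`
#'   (`site_matrix`), `motif` (`motif_model`), `background`
#'   (`background_bundle`) and `tracks` (`track_set`). Methods: `print`,
#'   `summary`, `plot`, `as.data.frame`.
#' @seealso [methylscape()], [render_logo()], [write_tracks()]
#' @examples
#' sim <- simulate_dataset(tempfile("mlg"), genome_length = 20000L,
#'   n_sites = 40L, seed = 7L)
#' mt <- merge_replicates(sim$replicates)
#' fit <- methylogo(sim$sites, sim$genome, mt)
#' print(fit)
#' @export
methylogo <- function(sites, genome, methyl, background = NULL,
                      regions = NULL, flank = 10L, pseudocount = 0.5,
                      min_depth = 5L,
                      label = if (is.null(regions)) "WG" else "PR") {
  cl <- match.call()
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(sites)) sites <- read_bed6(sites)
  methyl <- as_methyl_table(methyl, min_depth)
  if (is.null(background)) {
    background <- background_bundle(genome, methyl, regions, label = label)
  }
  sm <- extract_site_matrix(genome, sites, methyl, flank = flank)
  motif <- build_motif_model(sm, pseudocount = pseudocount)
  tracks <- track_set(motif, background)
  structure(
    list(
      sites = sm, motif = motif, background = background,
      tracks = tracks, call = cl
    ),
    class = "methylogo"
  )
}

as_methyl_table <- function(methyl, min_depth = 5L) {
  if (inherits(methyl, "methyl_table")) {
    return(methyl)
  }
  if (inherits(methyl, "wgbs_calls")) {
    return(merge_replicates(list(methyl), min_depth = min_depth))
  }
  if (is.list(methyl) && all(vapply(methyl, inherits, logical(1L), "wgbs_calls"))) {
    return(merge_replicates(methyl, min_depth = min_depth))
  }
  stop("methyl must be a methyl_table, wgbs_calls, or list of wgbs_calls")
}

#' @export
print.methylogo <- function(x, ...) {
  cat("Methylation-aware sequence logo model\n\n")
  cat(
    "  sites:      ", x$motif$n, " aligned binding sites, L = ", x$motif$L,
    ", flank = ", x$sites$flank, " bp\n",
    sep = ""
  )
  cat("  background: ", x$background$label, "\n", sep = "")
  cons <- BASES[apply(x$motif$p, 1L, which.max)]
  cat("  consensus:  ", paste(cons, collapse = ""), "\n\n", sep = "")
  cat(sprintf("  sequence track  %8.3f bits\n", sum(x$tracks$seq_heights)))
  cat(sprintf("  dimer track     %8.3f bits\n", sum(x$tracks$dimer_heights)))
  cat(sprintf("  methyl track    %8.3f bits\n", sum(x$tracks$meth)))
  cat(sprintf("  total           %8.3f bits\n", total_information(x$tracks)))
  invisible(x)
}

#' @export
summary.methylogo <- function(object, ...) {
  x <- object
  tab <- data.frame(
    pos = seq_len(x$motif$L) - 1L,
    consensus = BASES[apply(x$motif$p, 1L, which.max)],
    seq_bits = x$tracks$seq_heights,
    meth_bits = rowSums(x$tracks$meth),
    obs_meth_fwd = x$tracks$observed[, "+"],
    obs_meth_rev = x$tracks$observed[, "-"],
    exp_meth_fwd = x$tracks$expected[, "+"],
    exp_meth_rev = x$tracks$expected[, "-"]
  )
  out <- list(
    table = tab,
    dimer = x$tracks$dimer_heights,
    totals = c(
      sequence = sum(x$tracks$seq_heights),
      dimer = sum(x$tracks$dimer_heights),
      methylation = sum(x$tracks$meth),
      total = total_information(x$tracks)
    ),
    background = x$background
  )
  class(out) <- "summary.methylogo"
  out
}

#' @export
print.summary.methylogo <- function(x, ...) {
  cat("Per-position track values (bits; methylation levels as fractions):\n")
  print(format(x$table, digits = 3L), row.names = FALSE)
  if (length(x$dimer)) {
    cat("\nDimer bars (bits):", paste(sprintf("%.3f", x$dimer), collapse = " "), "\n")
  }
  cat("\nTotals (bits):\n")
  print(round(x$totals, 4L))
  invisible(x)
}

#' Plot a fitted logo model
#'
#' Draws the three-track logo on the active graphics device, or writes a
#' vector figure when `file` is given.
#'
#' @param x A `methylogo` object.
#' @param file Optional output path (`.svg`, `.pdf` or `.png`).
#' @param cfg A [render_config()]; its `label` defaults to the fit's
#'   background label.
#' @param ... Unused.
#' @return `x` invisibly (or the output path when `file` is given).
#' @export
plot.methylogo <- function(x, file = NULL, cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- render_config(label = x$background$label)
  if (is.null(file)) {
    sc <- build_logo_scene(
      x$tracks, x$motif, x$background$mbg,
      x$background$bg0, cfg
    )
    draw_scene_device(sc)
    return(invisible(x))
  }
  render_logo(x$tracks, x$motif, x$background$mbg, x$background$bg0, cfg, file)
}

#' @export
as.data.frame.methylogo <- function(x, ...) as.data.frame(x$tracks)

#' Fit a flanking-window methylation profile around binding sites
#'
#' Companion summary to [methylogo()]: context probability, methylation
#' probability and (context-probability-weighted) methylation relative
#' entropy at every offset in a window around the motif.
#'
#' @inheritParams methylogo
#' @param window Window half-width in bp beyond the motif ends.
#' @param weighted Weight the divergence by the context probability.
#' @return An object of class `methylscape` wrapping the `scape_profile`,
#'   with `print`, `plot` and `as.data.frame` methods.
#' @export
methylscape <- function(sites, genome, methyl, background = NULL,
                        regions = NULL, window = 500L, weighted = TRUE,
                        min_depth = 5L,
                        label = if (is.null(regions)) "WG" else "PR") {
  cl <- match.call()
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(sites)) sites <- read_bed6(sites)
  methyl <- as_methyl_table(methyl, min_depth)
  if (is.null(background)) {
    background <- background_bundle(genome, methyl, regions, label = label)
  }
  sm <- extract_site_matrix(genome, sites, methyl, flank = window)
  profile <- methylscape_profile(sm, background$mbg,
    window = window,
    weighted = weighted
  )
  structure(
    list(profile = profile, background = background, call = cl),
    class = "methylscape"
  )
}

#' @export
print.methylscape <- function(x, ...) {
  cat("Flanking-window methylation profile\n")
  print(x$profile)
  invisible(x)
}

#' @export
as.data.frame.methylscape <- function(x, ...) as.data.frame(x$profile)

#' Plot a flanking-window methylation profile
#'
#' @param x A `methylscape` object.
#' @param file Optional output path.
#' @param cfg A [render_config()].
#' @param ... Unused.
#' @export
plot.methylscape <- function(x, file = NULL, cfg = NULL, ...) {
  if (is.null(cfg)) cfg <- render_config(label = x$background$label)
  if (is.null(file)) {
    draw_scene_device(build_scape_scene(x$profile, cfg))
    return(invisible(x))
  }
  render_methylscape(x$profile, cfg, file)
}
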