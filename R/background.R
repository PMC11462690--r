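BASES <- c("A", "C", "G", "T")

region_seqs <- function(genome, regions = NULL) {
  if (is.null(regions)) {
    return(Biostrings::DNAStringSet(genome$seq))
  }
  if (nrow(regions) == 0L) stop("empty region set")
  seqs <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    seqs[i] <- genome_slice(genome, regions$chrom[i], regions$start[i], regions$end[i])
  }
  Biostrings::DNAStringSet(seqs)
}

#' Estimate a zero-order (independent-base) background model
#'
#' Counts bases over both strands of the covered sequence (so q(A) = q(T) and
#' q(C) = q(G) by construction) and normalises with a pseudocount per base.
#' N bases are excluded from the counts.
#'
#' @param genome A `genome_seq`.
#' @param regions A `region_set`, or `NULL` for the whole genome.
#' @param pseudocount Pseudocount added to each base count.
#' @return A `bg_zero` object with `q` (named probabilities) and `counts`.
#' @export
estimate_zero_order <- function(genome, regions = NULL, pseudocount = 1) {
  ss <- region_seqs(genome, regions)
  cnt <- colSums(Biostrings::alphabetFrequency(ss)[, BASES, drop = FALSE])
  # both strands: add complement counts
  both <- cnt + cnt[c("T", "G", "C", "A")]
  names(both) <- BASES
  if (sum(both) == 0) stop("regions cover zero non-N bases")
  q <- (both + pseudocount) / sum(both + pseudocount)
  structure(list(q = q, counts = both, pseudocount = pseudocount),
    class = "bg_zero"
  )
}

#' Estimate a first-order (dimer) background model
#'
#' Counts overlapping dimers within each contiguous covered block on both
#' strands (each dimer and its reverse complement counted symmetrically);
#' dimers are never counted across region boundaries, and windows containing
#' N are skipped. Returns the joint dimer distribution together with its row
#' marginal and the derived conditional q(b | a).
#'
#' The row marginal is the zero-order model under which the first-order
#' chain emits its first base; constructing the zero-order background from
#' this marginal makes the dimer-track decomposition exact (see
#' [background_bundle()]).
#'
#' @inheritParams estimate_zero_order
#' @param pseudocount Pseudocount added to each of the 16 dimer counts.
#' @return A `bg_first` object with `joint` (4 x 4 matrix, rows = first
#'   base), `marginal`, `conditional` and `counts`.
#' @export
estimate_first_order <- function(genome, regions = NULL, pseudocount = 1) {
  ss <- region_seqs(genome, regions)
  cnt <- colSums(Biostrings::dinucleotideFrequency(ss, step = 1))
  m <- matrix(cnt, 4L, 4L, byrow = TRUE, dimnames = list(BASES, BASES))
  # reverse-complement symmetrisation = counting both strands
  both <- m + rc_dimer_counts(m)
  if (sum(both) == 0) stop("regions cover zero non-N dimers")
  joint <- (both + pseudocount) / sum(both + pseudocount)
  marg <- rowSums(joint)
  cond <- joint / marg
  structure(
    list(
      joint = joint, marginal = marg, conditional = cond,
      counts = both, pseudocount = pseudocount
    ),
    class = "bg_first"
  )
}

# count matrix of reverse-complement dimers: rc of (a,b) is (comp b, comp a)
rc_dimer_counts <- function(m) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- m
  for (a in BASES) {
    for (b in BASES) {
      out[a, b] <- m[comp[b], comp[a]]
    }
  }
  out
}

#' Estimate per-context background methylation probabilities
#'
#' The background methylation probability of a context (CG, CHG, CHH) is the
#' mean merged methylation level over all methylation-table entries inside
#' the regions whose context classifies to it, both strands pooled. Estimates
#' are clamped into `[eps, 1 - eps]` so that binary relative entropy stays
#' finite under saturated methylation.
#'
#' @param methyl A `methyl_table`.
#' @param genome A `genome_seq` (for context classification).
#' @param regions A `region_set`, or `NULL` for the whole genome.
#' @param eps Clamping width.
#' @return A `bg_methyl` object with `m` (named CG/CHG/CHH probabilities),
#'   `n` (contributing cytosine counts) and `eps`.
#' @export
estimate_methyl_background <- function(methyl, genome, regions = NULL,
                                       eps = 1e-4) {
  stopifnot(inherits(methyl, "methyl_table"))
  mt <- methyl
  if (!is.null(regions)) {
    if (nrow(regions) == 0L) stop("empty region set")
    gr <- GenomicRanges::GRanges(
      mt$chrom, IRanges::IRanges(mt$pos + 1L, mt$pos + 1L)
    )
    hit <- GenomicRanges::countOverlaps(gr, regions_as_granges(regions),
      ignore.strand = TRUE
    ) > 0L
    mt <- mt[hit, , drop = FALSE]
  }
  if (nrow(mt) == 0L) stop("methylation table empty over the regions")
  # sites at chromosome ends can have UNDEFINED context; exclude them
  ctx <- classify_context(genome, mt$chrom, mt$pos, mt$strand)
  keep <- ctx != "UNDEFINED"
  mlev <- tapply(mt$level[keep], factor(ctx[keep], levels = c("CG", "CHG", "CHH")), mean)
  ncnt <- tapply(rep(1L, sum(keep)), factor(ctx[keep], levels = c("CG", "CHG", "CHH")), sum)
  if (any(is.na(mlev))) {
    stop(
      "no covered cytosines in context ",
      paste(names(mlev)[is.na(mlev)], collapse = ", "),
      "; supply larger regions or a prior"
    )
  }
  m <- pmin(pmax(as.numeric(mlev), eps), 1 - eps)
  names(m) <- names(mlev)
  ncnt <- as.integer(ncnt)
  names(ncnt) <- names(mlev)
  structure(list(m = m, n = ncnt, eps = eps), class = "bg_methyl")
}

#' Bundle the three background models for one region set
#'
#' Estimates the first-order dimer model and per-context methylation model
#' over a region set (or the whole genome), and derives the zero-order model
#' from the dimer model's strand-symmetrised marginal. Deriving both models
#' from the same dimer counts makes the dimer-track decomposition of the
#' first-order-minus-zero-order relative entropy exact up to region-edge
#' effects, while the symmetrisation keeps q(A)=q(T) and q(C)=q(G) exactly,
#' so all tracks mirror exactly under reverse complementation of the sites.
#'
#' @inheritParams estimate_methyl_background
#' @param pseudocount Pseudocount for dimer counts.
#' @param label Short label for figure annotation (e.g. `"WG"` or `"PR"`).
#' @return A `background_bundle` with components `bg0`, `bg1`, `mbg`,
#'   `label`.
#' @export
background_bundle <- function(genome, methyl, regions = NULL,
                              pseudocount = 1, label = if (is.null(regions)) "WG" else "PR") {
  bg1 <- estimate_first_order(genome, regions, pseudocount)
  # strand-symmetrised marginal of the dimer joint: q(a) = q(comp a) exactly,
  # and within one region-edge base of the raw row marginal
  qsym <- (rowSums(bg1$joint) + colSums(bg1$joint)) / 2
  bg0 <- structure(
    list(q = qsym, counts = rowSums(bg1$counts), pseudocount = pseudocount),
    class = "bg_zero"
  )
  mbg <- estimate_methyl_background(methyl, genome, regions)
  structure(
    list(bg0 = bg0, bg1 = bg1, mbg = mbg, label = label),
    class = "background_bundle"
  )
}

#' @export
print.background_bundle <- function(x, ...) {
  cat("<background_bundle> label:", x$label, "\n")
  cat("  q:", paste(sprintf("%s=%.4f", BASES, x$bg0$q), collapse = " "), "\n")
  cat(
    "  methylation:",
    paste(sprintf("%s=%.4f", names(x$mbg$m), x$mbg$m), collapse = " "), "\n"
  )
  invisible(x)
}

#' Serialize a background bundle to JSON
#'
#' Writes base frequencies, the dimer matrix, context methylation
#' probabilities and provenance so backgrounds can be precomputed once and
#' reused across runs.
#'
#' @param bundle A `background_bundle`.
#' @param path Output path.
#' @param provenance Optional named list recorded verbatim.
#' @export
write_background <- function(bundle, path, provenance = list()) {
  obj <- list(
    format = "methylogo-background",
    version = 1L,
    label = bundle$label,
    base_freq = as.list(bundle$bg0$q),
    dimer_joint = unname(apply(bundle$bg1$joint, 1L, as.list, simplify = FALSE)),
    dimer_bases = BASES,
    methylation = as.list(bundle$mbg$m),
    methylation_n = as.list(bundle$mbg$n),
    eps = bundle$mbg$eps,
    provenance = provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a background bundle from JSON
#' @param path Path written by [write_background()].
#' @return A `background_bundle`.
#' @export
read_background <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "methylogo-background")) {
    stop("not a methylogo background file: ", path)
  }
  joint <- do.call(rbind, lapply(obj$dimer_joint, unlist))
  dimnames(joint) <- list(BASES, BASES)
  marg <- rowSums(joint)
  q <- unlist(obj$base_freq)[BASES]
  m <- unlist(obj$methylation)[c("CG", "CHG", "CHH")]
  ncnt <- as.integer(unlist(obj$methylation_n)[c("CG", "CHG", "CHH")])
  names(ncnt) <- c("CG", "CHG", "CHH")
  structure(
    list(
      bg0 = structure(list(q = q, counts = NULL, pseudocount = NA_real_),
        class = "bg_zero"
      ),
      bg1 = structure(
        list(
          joint = joint, marginal = marg, conditional = joint / marg,
          counts = NULL, pseudocount = NA_real_
        ),
        class = "bg_first"
      ),
      mbg = structure(list(m = m, n = ncnt, eps = obj$eps), class = "bg_methyl"),
      label = obj$label
    ),
    class = "background_bundle"
  )
}
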