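#' Construct a set of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)`; strand is `"+"`, `"-"` or
#' `"."` (unstranded).
#'
#' @param chrom,start,end,strand Vectors of equal length (recycled).
#' @param name Optional interval names.
#' @return A `region_set` data frame.
#' @export
region_set <- function(chrom, start, end, strand = ".", name = NULL) {
  n <- max(length(chrom), length(start), length(end), length(strand))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(name)) df$name <- rep_len(as.character(name), n)
  if (any(df$start < 0L)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) stop("intervals must satisfy start < end")
  if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  class(df) <- c("region_set", "data.frame")
  df
}

#' Read a BED6 file of binding-site intervals
#'
#' @param path Path to a BED file (0-based half-open); six columns expected,
#'   strand required.
#' @return A `region_set`.
#' @export
read_bed6 <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- utils::read.table(path,
    sep = "\t", header = FALSE,
    stringsAsFactors = FALSE, quote = "", comment.char = "#"
  )
  if (ncol(raw) < 6L) stop("BED6 requires 6 columns; found ", ncol(raw))
  region_set(raw[[1L]], raw[[2L]], raw[[3L]], raw[[6L]], name = raw[[4L]])
}

#' Write a region set as BED6
#' @param regions A `region_set`.
#' @param path Output path.
#' @export
write_bed6 <- function(regions, path) {
  nm <- if ("name" %in% names(regions)) regions$name else seq_len(nrow(regions))
  out <- data.frame(regions$chrom, regions$start, regions$end, nm, 0L, regions$strand)
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a transcription start site table
#'
#' Tab-separated chrom / position / strand. Positions in the file are 1-based
#' (the common dialect of TSS annotation dumps) and converted to 0-based here.
#'
#' @param path Path to the TSV file.
#' @param one_based Set `FALSE` if the file is already 0-based.
#' @return Data frame with columns `chrom`, `pos` (0-based), `strand`.
#' @export
read_tss <- function(path, one_based = TRUE) {
  raw <- utils::read.table(path,
    sep = "\t", header = FALSE,
    stringsAsFactors = FALSE, quote = "", comment.char = "#"
  )
  if (ncol(raw) < 3L) stop("TSS table requires 3 columns")
  df <- data.frame(
    chrom = raw[[1L]],
    pos = as.integer(raw[[2L]]) - if (one_based) 1L else 0L,
    strand = raw[[3L]], stringsAsFactors = FALSE
  )
  if (!all(df$strand %in% c("+", "-"))) stop("TSS strand must be + or -")
  df
}

#' Build promoter regions around transcription start sites
#'
#' A promoter is the window from `upstream` bp upstream to `downstream` bp
#' downstream of the TSS (default 1000 bp upstream to 200 bp downstream). On
#' the plus strand a TSS at t gives `[t - upstream, t + downstream)`; on the
#' minus strand the mirror-image window on the genome,
#' `[t - downstream + 1, t + upstream + 1)`, covering the same strand-relative
#' bases. Windows are clamped to the chromosome and dropped if empty after
#' clamping.
#'
#' @param tss Data frame with `chrom`, `pos` (0-based), `strand`.
#' @param upstream,downstream Window extent in bp.
#' @param sizes Named vector of chromosome lengths (see [chrom_sizes()]).
#' @return A `region_set` of promoter windows.
#' @export
promoter_regions <- function(tss, upstream = 1000L, downstream = 200L, sizes) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(tss)))
  if (nrow(tss) == 0L) stop("empty TSS table")
  len <- sizes[tss$chrom]
  if (any(is.na(len))) stop("unknown chromosome in TSS table: ", tss$chrom[is.na(len)][1L])
  if (any(tss$pos < 0L | tss$pos >= len)) {
    bad <- which(tss$pos < 0L | tss$pos >= len)[1L]
    stop("TSS beyond chromosome end: ", tss$chrom[bad], ":", tss$pos[bad])
  }
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$pos - upstream, tss$pos - downstream + 1L)
  end <- ifelse(plus, tss$pos + downstream, tss$pos + upstream + 1L)
  start <- pmax(start, 0L)
  end <- pmin(end, as.integer(len))
  keep <- start < end
  region_set(tss$chrom[keep], start[keep], end[keep], tss$strand[keep])
}

#' Filter intervals by overlap with another interval set
#'
#' Keeps the intervals of `a` that overlap by at least one base
#' (`mode = "overlap-any"`) or are fully contained in (`mode = "contained"`)
#' some interval of `b`, under half-open coordinates. Records of `a` are
#' returned unmodified, in their original order; strand is ignored.
#'
#' @param a,b `region_set` objects.
#' @param mode `"overlap-any"` or `"contained"`.
#' @return The filtered `region_set`.
#' @export
intersect_regions <- function(a, b, mode = c("overlap-any", "contained")) {
  mode <- match.arg(mode)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(a[integer(0L), , drop = FALSE])
  }
  gra <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1L, a$end))
  grb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1L, b$end))
  type <- if (mode == "contained") "within" else "any"
  hit <- GenomicRanges::countOverlaps(gra, grb, type = type, ignore.strand = TRUE) > 0L
  a[hit, , drop = FALSE]
}

#' Convert a region set to GRanges
#' @param regions A `region_set`.
#' @return A `GRanges` object (1-based closed coordinates).
#' @export
regions_as_granges <- function(regions) {
  GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(regions$start + 1L, regions$end),
    strand = ifelse(regions$strand == ".", "*", regions$strand)
  )
}
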