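#' Load a genome from a FASTA file
#'
#' Reads every sequence in a FASTA file into an in-memory genome object.
#' Sequence names are the first whitespace-delimited word of each header.
#' Lowercase bases are normalised to uppercase; only A, C, G, T and N are
#' accepted.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_seq` object: a list with `seq` (named character vector,
#'   one string per chromosome) and `lengths` (named integer vector).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' g <- read_genome(fa)
#' genome_slice(g, "chr1", 0, 4)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1L])
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L) {
      stop(
        "non-ACGTN character '", substring(seqs[[i]], bad, bad),
        "' in sequence ", nm[i], " at position ", bad - 1L, " (0-based)"
      )
    }
  }
  genome_seq(seqs)
}

#' Construct a genome object from named sequences
#'
#' @param seqs Named character vector of chromosome sequences (A/C/G/T/N).
#' @return A `genome_seq` object.
#' @export
genome_seq <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  seqs <- toupper(seqs)
  structure(
    list(seq = seqs, lengths = vapply(seqs, nchar, integer(1L))),
    class = "genome_seq"
  )
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(
    "<genome_seq> ", length(x$seq), " sequence(s), ",
    format(sum(as.numeric(x$lengths)), big.mark = ","), " bp total\n",
    sep = ""
  )
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome A `genome_seq` object.
#' @return Named integer vector of sequence lengths.
#' @export
chrom_sizes <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  genome$lengths
}

#' Extract a genomic subsequence
#'
#' Coordinates are 0-based half-open; any access outside the chromosome is an
#' error rather than a silent truncation.
#'
#' @param genome A `genome_seq` object.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Character scalar of length `end - start`.
#' @export
genome_slice <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_seq"))
  if (!chrom %in% names(genome$seq)) {
    stop("unknown chromosome: ", chrom)
  }
  len <- genome$lengths[[chrom]]
  if (start < 0L || end > len || start > end) {
    stop(
      "slice [", start, ", ", end, ") out of range for ", chrom,
      " (length ", len, ")"
    )
  }
  substring(genome$seq[[chrom]], start + 1L, end)
}

#' Reverse complement of a DNA string
#' @param x Character vector of A/C/G/T/N strings.
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(
    x,
    function(s) {
      paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = ""
      )
    },
    character(1L),
    USE.NAMES = FALSE
  )
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Classify the trinucleotide context of a cytosine
#'
#' A cytosine's methylation propensity depends on its one or two
#' strand-relative downstream bases: CG if the next base is G, CHG if the next
#' base is A/C/T and the one after is G, CHH otherwise (H = A, C or T).
#' Positions whose required downstream bases fall off the chromosome or are N
#' are labelled UNDEFINED. For a minus-strand query, `pos` indexes the genome
#' plus strand (where the base must read G) and downstream bases are read as
#' complements of the preceding plus-strand bases.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param genome A `genome_seq` object.
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s) of the cytosine on the plus strand.
#' @param strand `"+"` or `"-"`.
#' @return Character vector over `{"CG","CHG","CHH","UNDEFINED"}`.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  stopifnot(inherits(genome, "genome_seq"))
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  out <- character(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (!ch %in% names(genome$seq)) stop("unknown chromosome: ", ch)
    s <- genome$seq[[ch]]
    len <- genome$lengths[[ch]]
    p <- pos[idx]
    if (any(p < 0L | p >= len)) stop("position out of range on ", ch)
    st <- strand[idx]
    plus <- st == "+"
    base <- substring(s, p + 1L, p + 1L)
    bad <- (plus & base != "C") | (!plus & base != "G")
    if (any(bad)) {
      j <- which(bad)[1L]
      stop(
        "no strand-relative cytosine at ", ch, ":", p[j], ":", st[j],
        " (plus-strand base is '", base[j], "')"
      )
    }
    d1p <- ifelse(plus, p + 1L, p - 1L)
    d2p <- ifelse(plus, p + 2L, p - 2L)
    getb <- function(pp, pl) {
      b <- rep(NA_character_, length(pp))
      ok <- pp >= 0L & pp < len
      if (!any(ok)) {
        return(b)
      }
      b[ok] <- substring(s, pp[ok] + 1L, pp[ok] + 1L)
      # strand-relative reading on the minus strand complements the base
      b[ok & !pl] <- comp_base(b[ok & !pl])
      b[b %in% "N"] <- NA_character_
      b
    }
    d1 <- getb(d1p, plus)
    d2 <- getb(d2p, plus)
    ctx <- rep("UNDEFINED", length(p))
    ctx[!is.na(d1) & d1 == "G"] <- "CG"
    h1 <- !is.na(d1) & d1 != "G"
    ctx[h1 & !is.na(d2) & d2 == "G"] <- "CHG"
    ctx[h1 & !is.na(d2) & d2 != "G"] <- "CHH"
    out[idx] <- ctx
  }
  out
}

#' Positions of all cytosines in a genome
#'
#' Finds every strand-relative cytosine (C on the plus strand, G on the plus
#' strand for the minus strand) over all chromosomes.
#'
#' @param genome A `genome_seq` object.
#' @return Data frame with columns `chrom`, `pos` (0-based), `strand`.
#' @export
genome_cytosines <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  res <- lapply(names(genome$seq), function(ch) {
    s <- genome$seq[[ch]]
    cpos <- gregexpr("C", s, fixed = TRUE)[[1L]]
    gpos <- gregexpr("G", s, fixed = TRUE)[[1L]]
    cpos <- cpos[cpos > 0L]
    gpos <- gpos[gpos > 0L]
    data.frame(
      chrom = ch,
      pos = c(cpos, gpos) - 1L,
      strand = rep(c("+", "-"), c(length(cpos), length(gpos))),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}
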