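#' Column mapping for a WGBS methylation-call file
#'
#' Methylation BED flavours differ in which columns hold the position, strand,
#' level and depth, whether the level is a percent or a fraction, and whether
#' positions are 0- or 1-based. Three named dialects are built in:
#'
#' * `"bedmethyl"` — ENCODE bedMethyl: 11 columns, strand in column 6,
#'   read coverage in column 10, percent methylation in column 11; 0-based.
#' * `"bismark"` — Bismark coverage: chrom, start, end, percent methylation,
#'   count methylated, count unmethylated; 1-based; no strand column (strand
#'   is reported as `"."` unless supplied separately).
#' * `"generic"` — chrom, start, end, strand, level (fraction in \[0,1\]),
#'   depth; 0-based. This is the dialect the simulator writes.
#'
#' @param chrom,pos,strand,level,depth 1-based column indices (`strand` and
#'   `depth` may be `NA`; `depth` may be a length-2 vector whose columns are
#'   summed, as in Bismark coverage files).
#' @param percent Logical: divide levels by 100.
#' @param one_based Logical: subtract 1 from positions on read.
#' @return A `wgbs_columns` mapping object.
#' @export
wgbs_columns <- function(chrom = 1L, pos = 2L, strand = 4L, level = 5L,
                         depth = 6L, percent = FALSE, one_based = FALSE) {
  structure(
    list(
      chrom = chrom, pos = pos, strand = strand, level = level,
      depth = depth, percent = percent, one_based = one_based
    ),
    class = "wgbs_columns"
  )
}

wgbs_dialect <- function(dialect) {
  switch(dialect,
    bedmethyl = wgbs_columns(1L, 2L, 6L, 11L, 10L, percent = TRUE),
    bismark = wgbs_columns(1L, 2L, NA_integer_, 4L, c(5L, 6L),
      percent = TRUE, one_based = TRUE
    ),
    generic = wgbs_columns(),
    stop("unknown WGBS dialect: ", dialect)
  )
}

#' Read per-cytosine methylation calls
#'
#' Parses a tab-separated methylation-call file into one record per cytosine:
#' chromosome, 0-based position, strand, methylation level in \[0,1\] and read
#' depth. The file layout is described by a dialect name or a custom
#' [wgbs_columns()] mapping.
#'
#' @param path Path to a tab-separated file (no header).
#' @param dialect `"generic"`, `"bedmethyl"`, `"bismark"`, or a
#'   `wgbs_columns` object.
#' @return Data frame of class `wgbs_calls` with columns `chrom`, `pos`,
#'   `strand`, `level`, `depth`.
#' @export
read_wgbs <- function(path, dialect = "generic") {
  map <- if (inherits(dialect, "wgbs_columns")) dialect else wgbs_dialect(dialect)
  if (!file.exists(path)) stop("WGBS file not found: ", path)
  if (file.size(path) == 0L) {
    return(empty_wgbs())
  }
  raw <- utils::read.table(path,
    sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    colClasses = "character", quote = "", comment.char = "#"
  )
  if (nrow(raw) == 0L) {
    return(empty_wgbs())
  }
  need <- max(c(map$chrom, map$pos, map$strand, map$level, map$depth), na.rm = TRUE)
  if (ncol(raw) < need) {
    stop("WGBS file has ", ncol(raw), " columns; mapping needs ", need)
  }
  pos <- as.integer(raw[[map$pos]]) - if (map$one_based) 1L else 0L
  strand <- if (is.na(map$strand[1L])) rep(".", nrow(raw)) else raw[[map$strand]]
  bad_strand <- !strand %in% c("+", "-", ".")
  if (any(bad_strand)) {
    stop(
      "unknown strand symbol '", strand[bad_strand][1L], "' at line ",
      which(bad_strand)[1L]
    )
  }
  level <- as.numeric(raw[[map$level[1L]]])
  if (map$percent) level <- level / 100
  bad <- is.na(level) | level < 0 | level > 1
  if (any(bad)) {
    stop(
      "methylation level out of [0,1] after scaling at line ",
      which(bad)[1L], " (value ", raw[[map$level[1L]]][which(bad)[1L]], ")"
    )
  }
  depth <- if (length(map$depth) == 2L) {
    as.integer(raw[[map$depth[1L]]]) + as.integer(raw[[map$depth[2L]]])
  } else if (is.na(map$depth)) {
    rep(NA_integer_, nrow(raw))
  } else {
    as.integer(raw[[map$depth]])
  }
  if (any(!is.na(depth) & depth < 0L)) stop("negative read depth")
  calls <- data.frame(
    chrom = raw[[map$chrom]], pos = pos, strand = strand,
    level = level, depth = depth, stringsAsFactors = FALSE
  )
  key <- paste(calls$chrom, calls$pos, calls$strand)
  if (anyDuplicated(key)) {
    stop("duplicate cytosine record: ", key[duplicated(key)][1L])
  }
  class(calls) <- c("wgbs_calls", "data.frame")
  calls
}

empty_wgbs <- function() {
  structure(
    data.frame(
      chrom = character(), pos = integer(), strand = character(),
      level = numeric(), depth = integer(), stringsAsFactors = FALSE
    ),
    class = c("wgbs_calls", "data.frame")
  )
}

#' Write methylation calls in the generic WGBS dialect
#'
#' @param calls A `wgbs_calls` data frame.
#' @param path Output path (tab-separated, no header).
#' @export
write_wgbs <- function(calls, path) {
  out <- data.frame(
    chrom = calls$chrom, start = calls$pos, end = calls$pos + 1L,
    strand = calls$strand, level = calls$level, depth = calls$depth
  )
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Merge replicate methylation-call sets into a methylation table
#'
#' A cytosine passes the depth filter in a replicate when its read depth is at
#' least `min_depth` (the default keeps sites with depth greater than four).
#' The merged level of a site is the unweighted mean of its level in every
#' replicate in which it passed; sites passing in no replicate are absent from
#' the result. With `require_all = TRUE` a site must pass in every replicate
#' instead.
#'
#' @param replicates A list of `wgbs_calls` data frames (one per replicate).
#' @param min_depth Minimum read depth for a site to count in a replicate.
#' @param require_all Require the site to pass the filter in all replicates.
#' @return A `methyl_table` object.
#' @export
merge_replicates <- function(replicates, min_depth = 5L, require_all = FALSE) {
  if (inherits(replicates, "data.frame")) replicates <- list(replicates)
  if (length(replicates) == 0L) stop("at least one replicate is required")
  kept <- lapply(replicates, function(r) r[!is.na(r$depth) & r$depth >= min_depth, , drop = FALSE])
  all <- do.call(rbind, lapply(kept, function(r) {
    data.frame(
      key = paste(r$chrom, r$pos, r$strand, sep = "\r"),
      chrom = r$chrom, pos = r$pos, strand = r$strand, level = r$level,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(all) || nrow(all) == 0L) {
    return(methyl_table(empty_wgbs()[, c("chrom", "pos", "strand", "level")]))
  }
  lv <- tapply(all$level, all$key, mean)
  if (require_all) {
    cnt <- tapply(all$level, all$key, length)
    lv <- lv[cnt == length(replicates)]
  }
  first <- all[!duplicated(all$key), , drop = FALSE]
  rownames(first) <- first$key
  first <- first[names(lv), , drop = FALSE]
  methyl_table(data.frame(
    chrom = first$chrom, pos = first$pos, strand = first$strand,
    level = as.numeric(lv), stringsAsFactors = FALSE
  ))
}

#' Construct a methylation table
#'
#' A methylation table maps (chrom, 0-based position, strand) to a merged
#' methylation level in \[0,1\]; it contains only sites that passed the read
#' depth filter.
#'
#' @param df Data frame with columns `chrom`, `pos`, `strand`, `level`.
#' @return A `methyl_table` object.
#' @export
methyl_table <- function(df) {
  stopifnot(all(c("chrom", "pos", "strand", "level") %in% names(df)))
  if (nrow(df) && (any(df$level < 0) || any(df$level > 1))) {
    stop("methylation levels must lie in [0,1]")
  }
  o <- order(df$chrom, df$pos, df$strand)
  df <- df[o, c("chrom", "pos", "strand", "level"), drop = FALSE]
  rownames(df) <- NULL
  attr(df, "key") <- paste(df$chrom, df$pos, df$strand, sep = "\r")
  class(df) <- c("methyl_table", "data.frame")
  df
}

#' Look up merged methylation levels
#'
#' @param mt A `methyl_table`.
#' @param chrom,pos,strand Vectors identifying cytosines (genome strand).
#' @return Numeric vector of levels; `NA` where the site is absent (filtered).
#' @export
methyl_lookup <- function(mt, chrom, pos, strand) {
  stopifnot(inherits(mt, "methyl_table"))
  i <- match(paste(chrom, pos, strand, sep = "\r"), attr(mt, "key"))
  mt$level[i]
}

#' @export
print.methyl_table <- function(x, ...) {
  cat("<methyl_table> ", nrow(x), " cytosines\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
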