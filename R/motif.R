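CONTEXTS <- c("CG", "CHG", "CHH")
STRANDS <- c("+", "-")

#' Build the motif model from an aligned site matrix
#'
#' Estimates, over the `L` core motif columns of a [extract_site_matrix()]
#' result:
#'
#' * per-position base probabilities `p[i, b]` (the position weight matrix),
#' * adjacent-pair joint probabilities `pairs[[j]][a, b]` for columns
#'   `j, j+1`,
#' * per position, strand and context: the probability `ctx_prob` that a site
#'   carries a strand-relative cytosine of that context there (sites whose
#'   cytosine has UNDEFINED context are excluded from numerator and
#'   denominator), and the mean methylation `m` of the available merged
#'   levels in that class (`NA` when no site in the class passed the depth
#'   filter),
#' * per position and strand: the overall mean observed methylation
#'   (`observed`, used for glyph shading).
#'
#' Strand is motif-relative throughout: `"+"` is the motif-forward strand.
#'
#' @param sm A `site_matrix`.
#' @param pseudocount Pseudocount added per base cell (and per dimer cell)
#'   of the count matrices.
#' @return A `motif_model` object.
#' @export
build_motif_model <- function(sm, pseudocount = 0.5) {
  stopifnot(inherits(sm, "site_matrix"))
  if (sm$n < 1L) stop("empty site matrix")
  L <- sm$L
  n <- sm$n
  cc <- core_columns(sm)
  p <- matrix(0, L, 4L, dimnames = list(NULL, BASES))
  for (i in seq_len(L)) {
    cnt <- table(factor(sm$base[, cc[i]], levels = BASES))
    p[i, ] <- (as.numeric(cnt) + pseudocount) / (sum(cnt) + 4 * pseudocount)
  }
  pairs <- vector("list", max(L - 1L, 0L))
  if (L >= 2L) {
    for (j in seq_len(L - 1L)) {
      cnt <- table(
        factor(sm$base[, cc[j]], levels = BASES),
        factor(sm$base[, cc[j + 1L]], levels = BASES)
      )
      pairs[[j]] <- (unclass(cnt) + pseudocount) / (sum(cnt) + 16 * pseudocount)
      dimnames(pairs[[j]]) <- list(BASES, BASES)
    }
  }
  ctx_prob <- array(0, c(L, 3L, 2L), dimnames = list(NULL, CONTEXTS, STRANDS))
  m <- array(NA_real_, c(L, 3L, 2L), dimnames = list(NULL, CONTEXTS, STRANDS))
  observed <- matrix(NA_real_, L, 2L, dimnames = list(NULL, STRANDS))
  for (i in seq_len(L)) {
    for (s in STRANDS) {
      ctx <- if (s == "+") sm$ctx_fwd[, cc[i]] else sm$ctx_rev[, cc[i]]
      lev <- if (s == "+") sm$meth_fwd[, cc[i]] else sm$meth_rev[, cc[i]]
      undef <- sum(!is.na(ctx) & ctx == "UNDEFINED")
      denom <- n - undef
      for (cx in CONTEXTS) {
        in_class <- !is.na(ctx) & ctx == cx
        if (denom > 0L) ctx_prob[i, cx, s] <- sum(in_class) / denom
        obs <- lev[in_class & !is.na(lev)]
        if (length(obs)) m[i, cx, s] <- mean(obs)
      }
      allobs <- lev[!is.na(ctx) & ctx != "UNDEFINED" & !is.na(lev)]
      if (length(allobs)) observed[i, s] <- mean(allobs)
    }
  }
  structure(
    list(
      L = L, n = n, p = p, pairs = pairs,
      ctx_prob = ctx_prob, m = m, observed = observed,
      pseudocount = pseudocount
    ),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> L =", x$L, ", n =", x$n, "sites\n")
  cons <- BASES[apply(x$p, 1L, which.max)]
  cat("  consensus:", paste(cons, collapse = ""), "\n")
  invisible(x)
}
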