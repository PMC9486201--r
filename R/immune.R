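# Stage 3: single-sample gene-set enrichment (ssGSEA) for arbitrary
# signature panels, unity normalization across samples, an ESTIMATE-style
# immune score, and Spearman correlation.

# per-sample ssGSEA enrichment score for one gene set, given the sample's
# expression vector. Genes are walked in decreasing-expression order; the
# in-set ECDF is weighted by rank magnitude^alpha (rank 1 = lowest
# expression, N = highest, average ranks for ties), the out-set ECDF is
# unweighted, and the score is the sum of their differences over all steps.
ssgseaOne <- function(x, in_set, alpha) {
  N <- length(x)
  r <- rank(x, ties.method = "average")       # magnitude: N = highest
  ord <- order(x, decreasing = TRUE)
  ins <- in_set[ord]
  rw <- r[ord]^alpha
  p_in <- cumsum(rw * ins) / sum(rw[ins])
  p_out <- cumsum(!ins) / (N - sum(ins))
  sum(p_in - p_out)
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' For each sample and gene set, ranks the sample's genes by decreasing
#' expression (average ranks for ties) and accumulates the difference
#' between the rank-weighted in-set empirical CDF (weights `rank^alpha`) and
#' the unweighted out-of-set CDF over the whole list; the enrichment score
#' is that running-sum total. The score depends on ranks only, so it is
#' invariant under any strictly monotone transform of a sample's profile.
#'
#' @param expr genes-by-samples numeric matrix (at least 2 genes).
#' @param gene_sets a [GeneSetList-class] (or named list of gene id
#'   vectors).
#' @param alpha rank-weighting exponent, `>= 0`; 0.25 (default) is the
#'   exponent of the original single-sample formulation.
#' @return sets-by-samples numeric matrix of raw enrichment scores, with
#'   attribute `normalized = FALSE`. A set with no gene in `expr` yields a
#'   row of `NA` (with a message); a set covering the whole expression
#'   universe is an error (the out-of-set CDF is undefined).
#' @export
ssgsea <- function(expr, gene_sets, alpha = 0.25) {
  expr <- as.matrix(expr)
  stopifnot(nrow(expr) >= 2L, alpha >= 0)
  sets <- if (is(gene_sets, "GeneSetList")) as.list(gene_sets) else gene_sets
  stopifnot(is.list(sets), !is.null(names(sets)))
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  genes <- rownames(expr)
  for (s in names(sets)) {
    in_set <- genes %in% sets[[s]]
    if (!any(in_set)) {
      message(sprintf("ssgsea: set '%s' shares no gene with the matrix", s))
      next
    }
    if (all(in_set))
      stop(sprintf("set '%s' equals the whole gene universe", s))
    out[s, ] <- apply(expr, 2L, ssgseaOne, in_set = in_set, alpha = alpha)
  }
  attr(out, "normalized") <- FALSE
  out
}

#' Normalize enrichment scores to unity per set
#'
#' Rescales every row (gene set) of an enrichment matrix to `[0, 1]` by
#' `(x - min) / (max - min)` across samples, so 0 is the minimal and 1 the
#' maximal score of each set. A constant row is mapped to all zeros with a
#' warning.
#'
#' @param es sets-by-samples enrichment matrix (from [ssgsea()]).
#' @return the rescaled matrix with attribute `normalized = TRUE`.
#' @export
normalizeUnity <- function(es) {
  stopifnot(is.matrix(es), ncol(es) >= 2L)
  out <- es
  for (i in seq_len(nrow(es))) {
    rng <- range(es[i, ], na.rm = TRUE)
    if (!all(is.finite(rng))) next
    if (rng[1L] == rng[2L]) {
      warning(sprintf("normalizeUnity: constant row '%s' set to 0",
                      rownames(es)[i]))
      out[i, ] <- 0
    } else {
      out[i, ] <- (es[i, ] - rng[1L]) / (rng[2L] - rng[1L])
    }
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Signature-based immune score
#'
#' Raw ssGSEA enrichment of a single immune gene-expression signature per
#' sample — a proxy for the immune-cell fraction in bulk tumor tissue. The
#' signature genes are data supplied by the user, not shipped constants.
#'
#' @param expr genes-by-samples matrix.
#' @param signature character vector of signature gene ids, or a
#'   single-set [GeneSetList-class].
#' @param alpha rank-weighting exponent (see [ssgsea()]).
#' @return named numeric vector of per-sample scores.
#' @export
immuneScore <- function(expr, signature, alpha = 0.25) {
  if (is(signature, "GeneSetList")) {
    stopifnot(length(signature) == 1L)
    signature <- signature[[1L]]
  }
  es <- ssgsea(expr, list(immune = signature), alpha = alpha)
  stats::setNames(es[1L, ], colnames(es))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-distribution approximation (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return list: `rho`, `p`, `n`.
#' @export
spearmanCor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
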