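# Internal helpers shared across modules.

# One global seed expands to per-component child seeds: seeding a local RNG
# stream with the parent seed and drawing the k-th of a fixed block of
# integers. Deterministic, order-independent across components.
childSeed <- function(seed, k) {
  stopifnot(length(seed) == 1L, is.finite(seed), k >= 1L, k <= 64L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, 64L)[k]
}

# run `expr` under a fixed seed without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Nonsynonymous variant classifications counted toward TMB
#'
#' The whitelist of MAF `Variant_Classification` strings treated as
#' nonsynonymous when computing tumor mutational burden. Matching is
#' case-insensitive.
#'
#' @return character vector of classification strings.
#' @examples
#' nonsynonymousClasses()
#' @export
nonsynonymousClasses <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Splice_Site",
    "Translation_Start_Site", "Nonstop_Mutation")
}

# z-score rows of a matrix across columns; returns list(z, dropped) where
# dropped names zero-variance rows (excluded from z)
zscoreRows <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  keep <- is.finite(sdv) & sdv > 0
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  list(z = z, dropped = rownames(m)[!keep])
}
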