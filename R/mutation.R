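# Stage 4: tumor mutational burden, top-mutated-gene landscape by score
# group, and per-gene group-difference tests.

#' Tumor mutational burden per sample
#'
#' Counts each sample's MAF records whose `Variant_Classification` matches
#' the nonsynonymous whitelist ([nonsynonymousClasses()], case-insensitive)
#' and divides by the exome window: `tmb = count / window_mb`. Every record
#' counts (multiple hits of one gene all contribute). Samples listed in
#' `samples` but absent from the table get count 0 and are flagged.
#'
#' @param maf data.frame with `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#'   `Variant_Classification` (see [readMAF()]).
#' @param samples sample ids to report (default: those in the table).
#' @param window_mb sequencing window in megabases; 38 Mb is the
#'   whole-exome convention.
#' @return data.frame: `sample_id`, `n_nonsynonymous`, `tmb`, `in_maf`.
#' @export
computeTmb <- function(maf, samples = NULL, window_mb = 38) {
  stopifnot(window_mb > 0)
  if (is.null(samples)) samples <- sort(unique(maf$Tumor_Sample_Barcode))
  wl <- tolower(nonsynonymousClasses())
  hit <- tolower(maf$Variant_Classification) %in% wl
  counts <- table(factor(maf$Tumor_Sample_Barcode[hit], levels = samples))
  data.frame(sample_id = samples,
             n_nonsynonymous = as.integer(counts),
             tmb = as.numeric(counts) / window_mb,
             in_maf = samples %in% maf$Tumor_Sample_Barcode,
             stringsAsFactors = FALSE)
}

#' Top mutated genes by score group
#'
#' A gene counts as mutated in a sample if at least one record exists for
#' the pair, regardless of classification (duplicate records collapse).
#' Genes are ranked by the fraction of grouped samples carrying a mutation,
#' alphabetical tie-break, and the top `n_top` are reported with per-group
#' fractions.
#'
#' @param maf mutation table (see [readMAF()]).
#' @param groups named character vector, sample id -> group label
#'   (typically `"high"`/`"low"`).
#' @param n_top number of genes to report (all if fewer exist).
#' @return data.frame: `gene`, `freq_overall`, then one `freq_<group>`
#'   column per group level, ordered by decreasing overall frequency.
#' @export
topMutatedGenes <- function(maf, groups, n_top = 15L) {
  stopifnot(!is.null(names(groups)), length(groups) >= 1L)
  lev <- sort(unique(groups))
  if (length(lev) < 1L) stop("no groups")
  maf <- maf[maf$Tumor_Sample_Barcode %in% names(groups), , drop = FALSE]
  if (nrow(maf) == 0L)
    return(data.frame(gene = character(), freq_overall = numeric()))
  pairs <- unique(maf[c("Hugo_Symbol", "Tumor_Sample_Barcode")])
  pairs$group <- groups[pairs$Tumor_Sample_Barcode]
  n_by_group <- table(factor(groups, levels = lev))
  genes <- sort(unique(pairs$Hugo_Symbol))
  tab <- table(factor(pairs$Hugo_Symbol, levels = genes),
               factor(pairs$group, levels = lev))
  freq_overall <- rowSums(tab) / length(groups)
  out <- data.frame(gene = genes, freq_overall = as.numeric(freq_overall),
                    stringsAsFactors = FALSE)
  for (g in lev) out[[paste0("freq_", g)]] <- as.numeric(tab[, g]) /
      as.numeric(n_by_group[[g]])
  out <- out[order(-out$freq_overall, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n_top)
}

#' Test a gene's mutation frequency between two groups
#'
#' Forms the 2x2 table (mutated yes/no) x (group) — a sample is mutated if
#' it has at least one record for the gene — and reports the two-sided
#' Fisher exact p-value (point-mass summation) together with the sample
#' odds ratio, Haldane-corrected (+0.5 to every cell) when any cell is 0.
#'
#' @param gene gene id.
#' @param maf mutation table.
#' @param groups named two-level group vector (sample id -> label).
#' @return list: `odds_ratio`, `p`, `table` (2x2 counts).
#' @export
groupMutationTest <- function(gene, maf, groups) {
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups required")
  if (any(table(factor(groups, levels = lev)) == 0L))
    stop("a group has no samples")
  mutated_samples <- unique(maf$Tumor_Sample_Barcode[maf$Hugo_Symbol == gene])
  mut <- names(groups) %in% mutated_samples
  tab <- table(mutated = factor(mut, levels = c(TRUE, FALSE)),
               group = factor(groups, levels = lev))
  p <- stats::fisher.test(tab)$p.value
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  if (any(tab == 0)) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  list(odds_ratio = (a * d) / (b * c_), p = p, table = tab)
}
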