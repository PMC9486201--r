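# Stage 1: per-cohort median-dichotomized univariate Cox per gene,
# inverse-variance meta-analytic pooling across cohorts, and threshold-based
# gene selection.

survFields <- function(cohort, endpoint = c("OS", "RFS")) {
  endpoint <- match.arg(endpoint)
  cd <- clinicalData(cohort)
  if (endpoint == "OS") {
    list(time = cd$os_time, event = cd$os_event)
  } else {
    if (!all(c("rfs_time", "rfs_event") %in% colnames(cd)))
      stop(sprintf("cohort '%s' has no RFS fields", cohortName(cohort)))
    keep <- !is.na(cd$rfs_time) & !is.na(cd$rfs_event)
    list(time = cd$rfs_time[keep], event = cd$rfs_event[keep], keep = keep)
  }
}

#' Screen one gene in one cohort (median-dichotomized univariate Cox)
#'
#' Splits the cohort at the gene's within-cohort median — samples strictly
#' above the median form the high group (ties at the median go to the low
#' group) — and fits a univariate Cox model on the high/low indicator. The
#' returned log hazard ratio is high versus low expression.
#'
#' @param cohort a [Cohort-class].
#' @param gene gene id present in the cohort's expression matrix.
#' @param endpoint `"OS"` (default) or `"RFS"`.
#' @param min_events minimum number of events required; below it the gene is
#'   recorded as missing with a reason rather than fitted.
#' @return one-row data.frame: `gene`, `cohort`, `log_hr`, `se_log_hr`, `p`,
#'   `n_samples`, `n_events`, `reason` (`NA` for a clean fit; otherwise the
#'   estimates are `NA` and `reason` explains why).
#' @export
screenGene <- function(cohort, gene, endpoint = c("OS", "RFS"),
                       min_events = 10L) {
  endpoint <- match.arg(endpoint)
  expr <- exprMatrix(cohort)
  if (!gene %in% rownames(expr)) stop(sprintf("gene '%s' not in cohort", gene))
  sf <- survFields(cohort, endpoint)
  x <- expr[gene, ]
  if (!is.null(sf$keep)) x <- x[sf$keep]
  r <- screenVector(x, sf$time, sf$event, min_events)
  data.frame(gene = gene, cohort = cohortName(cohort), log_hr = r$log_hr,
             se_log_hr = r$se_log_hr, p = r$p, n_samples = length(sf$time),
             n_events = sum(sf$event), reason = r$reason,
             stringsAsFactors = FALSE)
}

#' Screen a gene panel across several cohorts
#'
#' @param cohorts list of [Cohort-class] objects.
#' @param genes gene ids to screen; default is the union of all cohorts'
#'   genes. Genes absent from a cohort are recorded as missing for that
#'   cohort (panels never fully overlap across platforms).
#' @inheritParams screenGene
#' @return data.frame with one row per gene x cohort (see [screenGene()]).
#' @export
screenCohorts <- function(cohorts, genes = NULL, endpoint = c("OS", "RFS"),
                          min_events = 10L) {
  endpoint <- match.arg(endpoint)
  stopifnot(length(cohorts) >= 1L)
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(cohorts, function(co)
      rownames(exprMatrix(co))))))
  res <- lapply(cohorts, function(co) {
    expr <- exprMatrix(co)
    sf <- survFields(co, endpoint)
    present <- genes %in% rownames(expr)
    n <- length(genes)
    out <- data.frame(gene = genes, cohort = cohortName(co),
                      log_hr = NA_real_, se_log_hr = NA_real_, p = NA_real_,
                      n_samples = length(sf$time), n_events = sum(sf$event),
                      reason = NA_character_, stringsAsFactors = FALSE)
    out$reason[!present] <- "gene absent"
    prep <- prepCoxBinary(sf$time, sf$event)
    b <- se <- pv <- rep(NA_real_, n)
    rs <- out$reason
    for (i in which(present)) {
      x <- expr[genes[i], ]
      if (!is.null(sf$keep)) x <- x[sf$keep]
      r <- screenVector(x, sf$time, sf$event, min_events, prep = prep)
      b[i] <- r$log_hr; se[i] <- r$se_log_hr; pv[i] <- r$p; rs[i] <- r$reason
    }
    out$log_hr <- b; out$se_log_hr <- se; out$p <- pv; out$reason <- rs
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# median-split + univariate Cox on a bare expression vector; `prep` (from
# prepCoxBinary) lets one cohort's sort/tie structure be reused per gene
screenVector <- function(x, time, event, min_events = 10L, prep = NULL) {
  miss <- function(reason) list(log_hr = NA_real_, se_log_hr = NA_real_,
                                p = NA_real_, reason = reason)
  if (length(unique(x)) == 1L) return(miss("degenerate"))
  if (sum(event) < min_events) return(miss("too few events"))
  ind <- as.numeric(x > stats::median(x))
  if (length(unique(ind)) == 1L) return(miss("degenerate"))
  if (is.null(prep)) prep <- prepCoxBinary(time, event)
  fit <- tryCatch(coxBinaryFast(prep, ind), error = function(e) NULL)
  if (is.null(fit)) return(miss("fit error"))
  if (!fit$converged) return(miss("not converged"))
  list(log_hr = fit$coef, se_log_hr = fit$se, p = fit$p,
       reason = NA_character_)
}

#' Inverse-variance meta-analytic pooling of per-cohort gene effects
#'
#' Pools the per-cohort log hazard ratios of each gene by inverse-variance
#' weighting on the log scale. Under the fixed-effects model the pooled
#' estimate is `sum(w * b) / sum(w)` with `w = 1/se^2` and pooled standard
#' error `1/sqrt(sum(w))`; the random-effects model adds the
#' DerSimonian-Laird between-cohort variance `tau^2` to every cohort
#' variance before re-weighting. Cochran's Q and `I^2` quantify
#' heterogeneity. Missing per-cohort effects are pooled over the remaining
#' cohorts with `n_cohorts_used` recorded; genes with no usable cohort are
#' dropped with a message.
#'
#' @param effects data.frame from [screenCohorts()] (or rows shaped like
#'   [screenGene()] output).
#' @param model `"fixed"` (default) or `"random"`.
#' @return data.frame with one row per gene: `gene`, `pooled_log_hr`,
#'   `pooled_se`, `hr`, `ci95_low`, `ci95_high` (on the HR scale), `p`
#'   (two-sided normal), `q` (Benjamini-Hochberg across genes),
#'   `n_cohorts_used`, `Q`, `I2`, `tau2`, `direction` (`"poor"` for HR > 1,
#'   `"good"` for HR < 1).
#' @export
poolEffects <- function(effects, model = c("fixed", "random")) {
  model <- match.arg(model)
  need <- c("gene", "log_hr", "se_log_hr")
  stopifnot(all(need %in% colnames(effects)))
  rows <- lapply(split(effects, effects$gene), function(df) {
    ok <- is.finite(df$log_hr) & is.finite(df$se_log_hr) & df$se_log_hr > 0
    if (!any(ok)) return(NULL)
    b <- df$log_hr[ok]; se <- df$se_log_hr[ok]
    w <- 1 / se^2
    bf <- sum(w * b) / sum(w)
    k <- length(b)
    Q <- sum(w * (b - bf)^2)
    I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0
    tau2 <- 0
    if (model == "random" && k > 1L) {
      denom <- sum(w) - sum(w^2) / sum(w)
      tau2 <- if (denom > 0) max(0, (Q - (k - 1)) / denom) else 0
    }
    ws <- 1 / (se^2 + tau2)
    pooled <- sum(ws * b) / sum(ws)
    pse <- 1 / sqrt(sum(ws))
    data.frame(gene = df$gene[1L], pooled_log_hr = pooled, pooled_se = pse,
               hr = exp(pooled), ci95_low = exp(pooled - 1.96 * pse),
               ci95_high = exp(pooled + 1.96 * pse),
               p = 2 * stats::pnorm(-abs(pooled / pse)), q = NA_real_,
               n_cohorts_used = k, Q = Q, I2 = I2, tau2 = tau2,
               direction = if (exp(pooled) > 1) "poor" else "good",
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1L)))
  if (dropped > 0)
    message(sprintf("poolEffects: %d gene(s) dropped (no usable cohort effect)",
                    dropped))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) stop("no gene had a usable effect in any cohort")
  rownames(out) <- NULL
  out$q <- bhAdjust(out$p)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegating to
#' [stats::p.adjust()]), with input validation; element order is preserved.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values outside [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Select prognosis-associated genes from pooled effects
#'
#' @param pooled data.frame from [poolEffects()].
#' @param p_threshold,fdr_threshold selection thresholds in `(0, 1]`; a gene
#'   is kept when `p < p_threshold` and `q < fdr_threshold`.
#' @return the selected rows, with attributes `n_poor` / `n_good` counting
#'   risk (HR > 1) and protective (HR < 1) genes. An empty selection is
#'   valid and reported with a message.
#' @export
selectGenes <- function(pooled, p_threshold = 0.001, fdr_threshold = 0.001) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            fdr_threshold > 0, fdr_threshold <= 1)
  sel <- pooled[pooled$p < p_threshold & pooled$q < fdr_threshold, ,
                drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "n_poor") <- sum(sel$direction == "poor")
  attr(sel, "n_good") <- sum(sel$direction == "good")
  if (nrow(sel) == 0L)
    message("selectGenes: no gene passed the thresholds")
  sel
}

#' Write a forest-style screening summary
#'
#' One row per gene: per-cohort log-HR/SE/p columns side by side, then the
#' pooled HR with CI, p, q and direction.
#'
#' @param effects per-cohort effects from [screenCohorts()].
#' @param pooled pooled effects from [poolEffects()].
#' @param path output TSV path.
#' @return the assembled data.frame, invisibly.
#' @export
writeForestTable <- function(effects, pooled, path) {
  wide <- NULL
  for (co in unique(effects$cohort)) {
    sub <- effects[effects$cohort == co, c("gene", "log_hr", "se_log_hr", "p")]
    colnames(sub)[-1L] <- paste0(co, c(".log_hr", ".se", ".p"))
    wide <- if (is.null(wide)) sub else merge(wide, sub, by = "gene",
                                              all = TRUE)
  }
  out <- merge(wide, pooled, by = "gene", all.y = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(out)
}
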