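# Stage 2: signature weights from pooled effects, per-sample IEGPI score,
# survival-optimal cutoff, and high/low group assignment.

#' Signature weights from pooled gene effects
#'
#' The weight of gene *i* is `(HR_i - 1) / SE_i`, where `HR_i` is the pooled
#' hazard ratio and `SE_i` its standard error on the HR scale obtained from
#' the log-scale pooled SE by the delta method (`SE_HR = HR * SE_log`). Risk
#' genes (HR > 1) thus get positive weights, protective genes (HR < 1)
#' negative ones, and HR = 1 gives weight 0 exactly. Setting
#' `se_scale = "log"` instead divides by the log-scale SE directly.
#'
#' @param pooled data.frame of selected genes from [poolEffects()] /
#'   [selectGenes()] (needs `gene`, `pooled_log_hr`, `pooled_se`).
#' @param se_scale `"hr"` (delta method, default) or `"log"`.
#' @return data.frame of class `"signatureWeights"`: `gene`, `weight`, plus
#'   provenance columns `hr`, `se_used` and, when present in the input, `p`,
#'   `q`, `direction`.
#' @examples
#' pooled <- data.frame(gene = "g1", pooled_log_hr = log(2), pooled_se = 0.1)
#' computeWeights(pooled)  # SE_HR = 0.2, weight = (2 - 1) / 0.2 = 5
#' @export
computeWeights <- function(pooled, se_scale = c("hr", "log")) {
  se_scale <- match.arg(se_scale)
  stopifnot(nrow(pooled) >= 1L,
            all(c("gene", "pooled_log_hr", "pooled_se") %in% colnames(pooled)))
  if (any(pooled$pooled_se <= 0)) stop("nonpositive pooled SE")
  hr <- exp(pooled$pooled_log_hr)
  se_used <- if (se_scale == "hr") hr * pooled$pooled_se else pooled$pooled_se
  out <- data.frame(gene = pooled$gene, weight = (hr - 1) / se_used,
                    hr = hr, se_used = se_used, stringsAsFactors = FALSE)
  for (col in c("p", "q", "direction"))
    if (col %in% colnames(pooled)) out[[col]] <- pooled[[col]]
  class(out) <- c("signatureWeights", "data.frame")
  out
}

#' Score samples with a weighted z-score signature
#'
#' Each signature gene is z-scored across the samples of the matrix (mean 0,
#' SD 1), and a sample's score is the weighted sum `sum_i w_i * z_i` over
#' the signature genes. Signature genes absent from the matrix, or with zero
#' variance, are dropped with a warning; scoring fails if none remain. The
#' same operation applies unchanged to any expression matrix — a bulk
#' cohort, a merged pan-cancer matrix, or a cells-by-genes single-cell
#' matrix transposed to genes-by-cells.
#'
#' @param x a [Cohort-class] or a genes-by-samples numeric matrix.
#' @param weights a `signatureWeights` data.frame from [computeWeights()],
#'   or any data.frame with `gene` and `weight` columns.
#' @return data.frame: `sample_id`, `score`; attribute `genes_used` lists
#'   the signature genes actually scored.
#' @export
scoreSamples <- function(x, weights) {
  stopifnot(all(c("gene", "weight") %in% colnames(weights)))
  expr <- if (is(x, "Cohort")) exprMatrix(x) else as.matrix(x)
  present <- weights$gene %in% rownames(expr)
  if (!any(present)) stop("no signature gene present in the expression matrix")
  if (any(!present))
    warning(sprintf("%d signature gene(s) absent from the matrix: %s",
                    sum(!present),
                    paste(utils::head(weights$gene[!present], 5L),
                          collapse = ", ")))
  w <- weights[present, , drop = FALSE]
  sub <- expr[w$gene, , drop = FALSE]
  zs <- zscoreRows(sub)
  if (length(zs$dropped))
    warning(sprintf("%d zero-variance signature gene(s) dropped: %s",
                    length(zs$dropped),
                    paste(utils::head(zs$dropped, 5L), collapse = ", ")))
  w <- w[w$gene %in% rownames(zs$z), , drop = FALSE]
  if (nrow(w) == 0L) stop("no usable signature gene (all constant)")
  score <- drop(crossprod(zs$z[w$gene, , drop = FALSE], w$weight))
  out <- data.frame(sample_id = colnames(expr), score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "genes_used") <- w$gene
  out
}

#' Survival-optimal score cutoff
#'
#' `method = "maxrank"` (default) evaluates every observed score value that
#' leaves both groups at least `min_group_fraction` of the samples, computes
#' the two-group log-rank chi-square for the split "score > cutoff", and
#' returns the maximizing cutoff (the maximally selected rank statistic).
#' `method = "youden_at_horizon"` instead maximizes IPCW-weighted
#' sensitivity + specificity - 1 for the binary outcome "event by
#' `horizon`", with case/control weights as in [tdRocAuc()].
#'
#' @param scores numeric scores, aligned with `time`/`event`.
#' @param time,event survival data.
#' @param method cutoff criterion.
#' @param min_group_fraction minimum fraction of samples per group.
#' @param horizon months, used by `"youden_at_horizon"` only.
#' @return list: `cutoff`, `statistic` (maximized log-rank chi-square or
#'   Youden index), `method`, `n_candidates`.
#' @export
findCutoff <- function(scores, time, event,
                       method = c("maxrank", "youden_at_horizon"),
                       min_group_fraction = 0.1, horizon = 36) {
  method <- match.arg(method)
  checkSurv(time, event)
  stopifnot(length(scores) == length(time))
  if (sum(event) == 0L) stop("no events")
  n <- length(scores)
  cand <- sort(unique(scores))
  nhigh <- vapply(cand, function(c) sum(scores > c), numeric(1L))
  ok <- nhigh >= ceiling(min_group_fraction * n) &
    (n - nhigh) >= ceiling(min_group_fraction * n)
  cand <- cand[ok]
  if (length(cand) == 0L) stop("no admissible cutoff")
  if (method == "maxrank") {
    stat <- vapply(cand, function(c) {
      g <- scores > c
      lr <- tryCatch(logrankTest(time, event, g), error = function(e) NULL)
      if (is.null(lr)) -Inf else lr$chisq
    }, numeric(1L))
  } else {
    case <- time <= horizon & event == 1
    ctrl <- time > horizon
    if (!any(case) || !any(ctrl))
      stop("horizon leaves no cases or no controls")
    wcase <- 1 / censoringSurvival(time, event, time[case], minus = TRUE)
    wctrl <- 1 / censoringSurvival(time, event, horizon)
    stat <- vapply(cand, function(c) {
      sens <- sum(wcase * (scores[case] > c)) / sum(wcase)
      spec <- sum(scores[ctrl] <= c) * wctrl / (sum(ctrl) * wctrl)
      sens + spec - 1
    }, numeric(1L))
  }
  best <- which.max(stat)
  list(cutoff = cand[best], statistic = stat[best], method = method,
       n_candidates = length(cand))
}

#' Assign high/low groups at a cutoff
#'
#' A sample is `"high"` iff its score is strictly above the cutoff.
#' Applying a training-derived cutoff to a freshly scored validation cohort
#' is the supported external-validation path.
#'
#' @param scores a data.frame from [scoreSamples()] (or any with
#'   `sample_id` and `score`).
#' @param cutoff finite numeric cutoff.
#' @param cutoff_method provenance tag stored alongside.
#' @return the input data.frame with `group` (`"high"`/`"low"`), `cutoff`
#'   and `cutoff_method` columns appended.
#' @export
assignGroups <- function(scores, cutoff, cutoff_method = "supplied") {
  stopifnot(is.finite(cutoff), all(c("sample_id", "score") %in%
                                     colnames(scores)))
  scores$group <- ifelse(scores$score > cutoff, "high", "low")
  scores$cutoff <- cutoff
  scores$cutoff_method <- cutoff_method
  scores
}
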