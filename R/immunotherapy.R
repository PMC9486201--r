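# Stage 5: the score as an immunotherapy-response predictor — AUROC for
# responders (CR/PR) vs non-responders (SD/PD), score-distribution
# comparison, and survival by score group in treated cohorts.

#' Binarize RECIST response labels
#' @param response character vector of `CR`/`PR`/`SD`/`PD` (or already
#'   `responder`/`non-responder`).
#' @return logical vector, `TRUE` for responders (CR/PR).
#' @export
isResponder <- function(response) {
  r <- toupper(as.character(response))
  if (!all(r %in% c("CR", "PR", "SD", "PD", "RESPONDER", "NON-RESPONDER")))
    stop("unknown response label(s)")
  r %in% c("CR", "PR", "RESPONDER")
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a random positive outscores a random negative, with 0.5
#' credit for ties — identical to the trapezoidal area under the empirical
#' ROC curve. Computed from average ranks, so it is invariant under any
#' strictly increasing transform of the scores.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels logical (or 0/1) class labels; both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(labels)))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare score distributions between responders and non-responders
#'
#' Two-sided Wilcoxon rank-sum test of the score between CR/PR and SD/PD
#' patients: exact when both groups are small and tie-free, otherwise the
#' normal approximation with tie correction (via [stats::wilcox.test()]
#' without continuity correction). Group medians and the direction of the
#' difference are reported alongside.
#'
#' @param scores numeric scores.
#' @param response RECIST labels (see [isResponder()]).
#' @return list: `statistic` (rank-sum W), `p`, `median_responder`,
#'   `median_nonresponder`, `direction`.
#' @export
compareResponseGroups <- function(scores, response) {
  resp <- isResponder(response)
  if (sum(resp) == 0L || sum(!resp) == 0L) stop("a response group is empty")
  wt <- suppressWarnings(stats::wilcox.test(scores[resp], scores[!resp],
                                            correct = FALSE))
  m1 <- stats::median(scores[resp]); m0 <- stats::median(scores[!resp])
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_responder = m1, median_nonresponder = m0,
       direction = if (m1 > m0) "responders higher" else if (m1 < m0)
         "responders lower" else "equal")
}

#' Survival by score group in a (treated) cohort
#'
#' Dichotomizes the score at a cutoff (`"median"` or a number), then reports
#' the Kaplan-Meier fits per group, the log-rank test, and the Cox hazard
#' ratio of high versus low. The direction of the association is reported
#' explicitly — in treated cohorts a high score may track *better* survival,
#' the opposite of the untreated prognostic setting.
#'
#' @param scores numeric scores.
#' @param time,event survival data aligned with `scores`.
#' @param cutoff `"median"` or a finite number; groups are
#'   `score > cutoff`.
#' @return list: `cutoff`, `groups`, `km` (list of per-group
#'   [kmEstimate()]), `logrank` (see [logrankTest()]), `hr` with `ci95` and
#'   `p` from [coxFit()], and `direction`.
#' @export
survivalByScore <- function(scores, time, event, cutoff = "median") {
  checkSurv(time, event)
  stopifnot(length(scores) == length(time))
  cut_val <- if (identical(cutoff, "median")) stats::median(scores)
    else as.numeric(cutoff)
  g <- ifelse(scores > cut_val, "high", "low")
  if (length(unique(g)) != 2L) stop("cutoff puts all samples in one group")
  lr <- logrankTest(time, event, g)
  fit <- coxFit(time, event, as.numeric(g == "high"))
  hr <- exp(unname(fit$coef))
  list(cutoff = cut_val, groups = table(g),
       km = lapply(split(seq_along(g), g), function(ix)
         kmEstimate(time[ix], event[ix])),
       logrank = lr,
       hr = hr,
       hr_ci95 = exp(unname(fit$coef) + c(-1.96, 1.96) * unname(fit$se)),
       hr_p = unname(fit$p),
       direction = if (hr > 1) "high group at higher hazard"
         else "high group at lower hazard")
}
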