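# End-to-end orchestration: screening -> pooling -> selection -> weights ->
# scoring -> cutoff -> stratification -> per-cohort survival summaries,
# with optional immune, mutation and immunotherapy stages, file outputs and
# a run manifest. Training/validation separation is enforced here: weights
# and the cutoff are derived from the training cohorts only and applied
# frozen to any validation cohort.

#' Run the full signature pipeline
#'
#' Sequences the stages over a list of cohorts: (1) median-dichotomized
#' univariate Cox screening of every gene in every *training* cohort;
#' (2) inverse-variance meta-analytic pooling; (3) threshold selection;
#' (4) `(HR-1)/SE` weights; (5) per-cohort z-scored signature scores;
#' (6) survival-optimal cutoff on the pooled training scores; (7) high/low
#' stratification of every cohort (validation cohorts are scored with the
#' frozen training weights and cutoff — no validation survival information
#' enters steps 1-6); (8) per-cohort log-rank, Cox HR and time-dependent
#' AUC summaries. Optional stages: ssGSEA enrichment + immune-score
#' correlation (when `gene_sets` / `immune_signature` are given), TMB +
#' mutation landscape (when `maf` is given), and immunotherapy-response
#' metrics (when `response` is given).
#'
#' @param cohorts named list of [Cohort-class] objects.
#' @param validation character vector of cohort names held out for external
#'   validation (default none).
#' @param endpoint `"OS"` or `"RFS"` for screening and stratification.
#' @param model meta-analysis model, `"fixed"` or `"random"`.
#' @param p_threshold,fdr_threshold selection thresholds.
#' @param min_events per-cohort minimum event count for screening.
#' @param cutoff_method,min_group_fraction,horizon see [findCutoff()];
#'   `horizon` (months) is also the time-dependent AUC horizon.
#' @param gene_sets optional [GeneSetList-class] for ssGSEA enrichment.
#' @param ssgsea_alpha rank-weighting exponent for [ssgsea()].
#' @param immune_signature optional gene id vector for [immuneScore()].
#' @param maf optional mutation table (see [readMAF()]).
#' @param tmb_window_mb exome window for [computeTmb()].
#' @param response optional response cohort data.frame (`sample_id`,
#'   `score`, `response`, optional `os_time`/`os_event`).
#' @param out_dir optional directory; when given, all result tables are
#'   written there (weights.tsv, scores.tsv, forest_table.tsv,
#'   km_summary.tsv, cox_summary.tsv, enrichment.tsv, tmb.tsv,
#'   response_metrics.json, manifest.json).
#' @param seed recorded in the manifest; the pipeline itself is
#'   deterministic given its inputs.
#' @return list of class `"iegpiRun"` with elements `effects`, `pooled`,
#'   `selected`, `weights`, `scores` (per-sample with cohort, group,
#'   cutoff), `cutoff`, `survival_summary` (per cohort), `enrichment`,
#'   `immune_correlation`, `tmb`, `tmb_correlation`, `mutation_landscape`,
#'   `response_metrics`, `manifest`.
#' @export
runPipeline <- function(cohorts, validation = character(),
                        endpoint = c("OS", "RFS"),
                        model = c("fixed", "random"),
                        p_threshold = 0.001, fdr_threshold = 0.001,
                        min_events = 10L,
                        cutoff_method = c("maxrank", "youden_at_horizon"),
                        min_group_fraction = 0.1, horizon = 36,
                        gene_sets = NULL, ssgsea_alpha = 0.25,
                        immune_signature = NULL,
                        maf = NULL, tmb_window_mb = 38,
                        response = NULL,
                        out_dir = NULL, seed = 1L) {
  endpoint <- match.arg(endpoint)
  model <- match.arg(model)
  cutoff_method <- match.arg(cutoff_method)
  stopifnot(length(cohorts) >= 1L, !is.null(names(cohorts)),
            all(vapply(cohorts, is, logical(1L), "Cohort")))
  if (!all(validation %in% names(cohorts)))
    stop("unknown validation cohort name(s)")
  train <- setdiff(names(cohorts), validation)
  if (length(train) == 0L) stop("no training cohort left")
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))

  effects <- stage("screening",
                   screenCohorts(cohorts[train], endpoint = endpoint,
                                 min_events = min_events))
  pooled <- stage("pooling", poolEffects(effects, model = model))
  selected <- stage("selection",
                    selectGenes(pooled, p_threshold, fdr_threshold))
  manifest <- list(
    package_version = as.character(utils::packageVersion("iegpi")),
    config = list(endpoint = endpoint, model = model,
                  p_threshold = p_threshold, fdr_threshold = fdr_threshold,
                  min_events = min_events, cutoff_method = cutoff_method,
                  min_group_fraction = min_group_fraction, horizon = horizon,
                  ssgsea_alpha = ssgsea_alpha, tmb_window_mb = tmb_window_mb,
                  seed = seed,
                  train_cohorts = train, validation_cohorts = validation),
    n_samples = vapply(cohorts, ncol, integer(1L)),
    n_genes_screened = length(unique(effects$gene)),
    n_genes_pooled = nrow(pooled),
    n_genes_selected = nrow(selected),
    n_poor = attr(selected, "n_poor"), n_good = attr(selected, "n_good"))
  res <- list(effects = effects, pooled = pooled, selected = selected,
              weights = NULL, scores = NULL, cutoff = NULL,
              survival_summary = NULL, enrichment = NULL,
              immune_correlation = NULL, tmb = NULL, tmb_correlation = NULL,
              mutation_landscape = NULL, response_metrics = NULL,
              manifest = manifest)
  class(res) <- "iegpiRun"
  if (nrow(selected) == 0L) {
    message("runPipeline: empty gene selection; downstream stages skipped")
    res$manifest$stopped_after <- "selection"
    if (!is.null(out_dir)) writeRunOutputs(res, out_dir)
    return(res)
  }

  res$weights <- stage("weights", computeWeights(selected))
  scores <- stage("scoring", {
    do.call(rbind, lapply(names(cohorts), function(nm) {
      s <- scoreSamples(cohorts[[nm]], res$weights)
      s$cohort <- nm
      s
    }))
  })
  train_sc <- do.call(rbind, lapply(train, function(nm) {
    sf <- survFields(cohorts[[nm]], endpoint)
    sc <- scores$score[scores$cohort == nm]
    if (!is.null(sf$keep)) sc <- sc[sf$keep]
    data.frame(score = sc, time = sf$time, event = sf$event)
  }))
  cut <- stage("cutoff",
               findCutoff(train_sc$score, train_sc$time,
                          train_sc$event, method = cutoff_method,
                          min_group_fraction = min_group_fraction,
                          horizon = horizon))
  res$cutoff <- cut
  scores <- assignGroups(scores, cut$cutoff, cut$method)
  res$scores <- scores
  res$manifest$cutoff <- cut$cutoff
  res$manifest$cutoff_provenance <- list(
    derived_from = train, method = cut$method,
    applied_to = names(cohorts))

  res$survival_summary <- stage("survival_summary", {
    do.call(rbind, lapply(names(cohorts), function(nm) {
      sf <- survFields(cohorts[[nm]], endpoint)
      sc <- scores[scores$cohort == nm, , drop = FALSE]
      if (!is.null(sf$keep)) sc <- sc[sf$keep, , drop = FALSE]
      g <- sc$group
      row <- data.frame(cohort = nm, role = if (nm %in% train) "training"
                        else "validation",
                        n = length(sf$time), n_events = sum(sf$event),
                        n_high = sum(g == "high"), n_low = sum(g == "low"),
                        logrank_chisq = NA_real_, logrank_p = NA_real_,
                        hr_high_vs_low = NA_real_, hr_ci_low = NA_real_,
                        hr_ci_high = NA_real_, hr_p = NA_real_,
                        td_auc = NA_real_, stringsAsFactors = FALSE)
      if (length(unique(g)) == 2L) {
        lr <- tryCatch(logrankTest(sf$time, sf$event, g),
                       error = function(e) NULL)
        if (!is.null(lr)) {
          row$logrank_chisq <- lr$chisq; row$logrank_p <- lr$p
        }
        fit <- tryCatch(coxFit(sf$time, sf$event,
                               as.numeric(g == "high")),
                        error = function(e) NULL)
        if (!is.null(fit) && fit$converged) {
          row$hr_high_vs_low <- exp(unname(fit$coef))
          row$hr_ci_low <- exp(unname(fit$coef) - 1.96 * unname(fit$se))
          row$hr_ci_high <- exp(unname(fit$coef) + 1.96 * unname(fit$se))
          row$hr_p <- unname(fit$p)
        }
      }
      row$td_auc <- tryCatch(tdRocAuc(sc$score, sf$time, sf$event, horizon),
                             error = function(e) NA_real_)
      row
    }))
  })

  if (!is.null(gene_sets)) {
    res$enrichment <- stage("immune_enrichment", {
      do.call(cbind, lapply(names(cohorts), function(nm)
        normalizeUnity(ssgsea(exprMatrix(cohorts[[nm]]), gene_sets,
                              alpha = ssgsea_alpha))))
    })
  }
  if (!is.null(immune_signature)) {
    res$immune_correlation <- stage("immune_score", {
      do.call(rbind, lapply(names(cohorts), function(nm) {
        isc <- immuneScore(exprMatrix(cohorts[[nm]]), immune_signature,
                           alpha = ssgsea_alpha)
        sc <- scores[scores$cohort == nm, , drop = FALSE]
        ct <- spearmanCor(sc$score, isc[sc$sample_id])
        data.frame(cohort = nm, rho = ct$rho, p = ct$p, n = ct$n,
                   stringsAsFactors = FALSE)
      }))
    })
  }
  if (!is.null(maf)) {
    res$tmb <- stage("tmb", computeTmb(maf, samples = scores$sample_id,
                                       window_mb = tmb_window_mb))
    res$tmb_correlation <- stage("tmb_correlation", {
      m <- merge(scores, res$tmb, by = "sample_id")
      ct <- spearmanCor(m$score, m$tmb)
      data.frame(rho = ct$rho, p = ct$p, n = ct$n)
    })
    grp <- stats::setNames(scores$group, scores$sample_id)
    res$mutation_landscape <- stage("mutation_landscape",
                                    topMutatedGenes(maf, grp, n_top = 15L))
  }
  if (!is.null(response)) {
    res$response_metrics <- stage("response", {
      out <- list(auc = auroc(response$score, isResponder(response$response)),
                  wilcoxon = compareResponseGroups(response$score,
                                                   response$response))
      if (all(c("os_time", "os_event") %in% colnames(response)))
        out$survival <- survivalByScore(response$score, response$os_time,
                                        response$os_event)
      out
    })
  }
  if (!is.null(out_dir)) writeRunOutputs(res, out_dir)
  res
}

#' @export
print.iegpiRun <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("iegpi pipeline run: %d cohort(s) (%d training, %d validation)\n",
              length(m$n_samples), length(m$config$train_cohorts),
              length(m$config$validation_cohorts)))
  cat(sprintf("  genes screened %d, pooled %d, selected %d (%d poor / %d good)\n",
              m$n_genes_screened, m$n_genes_pooled, m$n_genes_selected,
              m$n_poor, m$n_good))
  if (!is.null(x$cutoff))
    cat(sprintf("  cutoff %.4f (%s)\n", x$cutoff$cutoff, x$cutoff$method))
  invisible(x)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

#' Write the result bundle of a pipeline run to a directory
#'
#' @param res an `"iegpiRun"` from [runPipeline()].
#' @param out_dir output directory (created if missing).
#' @return character vector of the files written, invisibly; the same list
#'   is recorded in `manifest.json`.
#' @export
writeRunOutputs <- function(res, out_dir) {
  stopifnot(inherits(res, "iegpiRun"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  p <- function(f) file.path(out_dir, f)
  writeForestTable(res$effects, res$pooled, p("forest_table.tsv"))
  files <- c(files, p("forest_table.tsv"))
  if (!is.null(res$weights))
    files <- c(files, writeTsv(res$weights, p("weights.tsv")))
  if (!is.null(res$scores))
    files <- c(files, writeTsv(res$scores, p("scores.tsv")))
  if (!is.null(res$survival_summary)) {
    files <- c(files, writeTsv(res$survival_summary, p("cox_summary.tsv")))
    km <- res$survival_summary[c("cohort", "role", "n", "n_events",
                                 "n_high", "n_low", "logrank_chisq",
                                 "logrank_p")]
    files <- c(files, writeTsv(km, p("km_summary.tsv")))
  }
  if (!is.null(res$enrichment)) {
    em <- data.frame(set = rownames(res$enrichment), res$enrichment,
                     check.names = FALSE)
    files <- c(files, writeTsv(em, p("enrichment.tsv")))
  }
  if (!is.null(res$tmb))
    files <- c(files, writeTsv(res$tmb, p("tmb.tsv")))
  if (!is.null(res$response_metrics)) {
    jsonlite::write_json(res$response_metrics, p("response_metrics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    files <- c(files, p("response_metrics.json"))
  }
  res$manifest$outputs <- basename(files)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  files <- c(files, p("manifest.json"))
  invisible(files)
}
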