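# Multi-cohort survival/expression simulator with known ground truth, plus
# generators for gene sets, mutation tables and immunotherapy-response
# cohorts. Everything is deterministic under a fixed seed: the global seed
# expands to per-component child seeds (see childSeed), so generating one
# component never perturbs another.

#' Simulation configuration for multi-cohort survival data
#'
#' Validated parameter bundle for [simulateCohorts()]. The defaults emulate
#' a seven-cohort pancreatic-cancer panel study: seven independent cohorts
#' with the sample sizes of typical public series (total 1137), a 182-gene
#' panel of which 27 carry true prognostic effects, effect magnitudes
#' |log HR| in [0.4, 0.8] acting through above/below-median expression
#' indicators, an exponential baseline hazard of 0.03 per month (median
#' survival around two years) and 30% right-censoring.
#'
#' @param n_cohorts number of independent cohorts.
#' @param n_samples_per_cohort scalar or vector (recycled/truncated to
#'   `n_cohorts`) of per-cohort sample counts.
#' @param n_genes panel size.
#' @param n_prognostic number of genes with nonzero true log hazard ratio
#'   (`<= n_genes`).
#' @param log_hr_range interval of |log HR| magnitudes for prognostic genes.
#' @param baseline_hazard exponential baseline hazard per cohort (1/month);
#'   scalar or per-cohort vector.
#' @param censoring_rate target fraction of censored observations in
#'   `[0, 1]`.
#' @param prognostic_direction `"mixed"` (random signs), `"risk"` (all
#'   log HR > 0) or `"protective"` (all < 0).
#' @param rfs also generate a recurrence-free-survival endpoint (same
#'   effects, 1.25x baseline hazard).
#' @param seed integer master seed.
#' @return list of class `"simulationConfig"`.
#' @export
simulationConfig <- function(n_cohorts = 7L,
                             n_samples_per_cohort = c(146L, 267L, 288L,
                                                      125L, 63L, 66L, 182L),
                             n_genes = 182L,
                             n_prognostic = 27L,
                             log_hr_range = c(0.4, 0.8),
                             baseline_hazard = 0.03,
                             censoring_rate = 0.3,
                             prognostic_direction = c("mixed", "risk",
                                                      "protective"),
                             rfs = FALSE,
                             seed = 1L) {
  prognostic_direction <- match.arg(prognostic_direction)
  if (n_cohorts < 1L) stop("n_cohorts must be positive")
  if (n_genes < 1L) stop("n_genes must be positive")
  if (any(n_samples_per_cohort < 1L)) stop("sample counts must be positive")
  if (n_prognostic < 0L || n_prognostic > n_genes)
    stop("n_prognostic must be in [0, n_genes]")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  if (length(log_hr_range) != 2L || any(log_hr_range < 0) ||
      log_hr_range[1L] > log_hr_range[2L])
    stop("log_hr_range must be a nondecreasing nonnegative interval")
  if (any(baseline_hazard <= 0)) stop("baseline_hazard must be positive")
  n_samples_per_cohort <- rep_len(as.integer(n_samples_per_cohort), n_cohorts)
  baseline_hazard <- rep_len(baseline_hazard, n_cohorts)
  structure(list(n_cohorts = as.integer(n_cohorts),
                 n_samples_per_cohort = n_samples_per_cohort,
                 n_genes = as.integer(n_genes),
                 n_prognostic = as.integer(n_prognostic),
                 log_hr_range = as.numeric(log_hr_range),
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 prognostic_direction = prognostic_direction,
                 rfs = rfs, seed = as.integer(seed)),
            class = "simulationConfig")
}

# censoring rate c such that mean_i c/(c+h_i) = target, by uniroot
calibrateCensoring <- function(hazards, target) {
  if (target <= 0) return(0)
  f <- function(cc) mean(cc / (cc + hazards)) - target
  stats::uniroot(f, lower = min(hazards) * 1e-6,
                 upper = max(hazards) * 1e6, tol = 1e-12)$root
}

#' Simulate multi-cohort survival/expression data with known ground truth
#'
#' Per cohort, gene expression is standard normal on the analysis scale
#' (genes independent). Survival times are exponential with hazard
#' `baseline * exp(sum_g beta_g * 1[expr_g > cohort median of expr_g])`, so
#' the estimand of median-dichotomized Cox screening equals the generating
#' `beta_g` by construction. Censoring is independent exponential with rate
#' solved numerically so the expected censoring fraction matches the
#' target. The same `beta` vector applies in every cohort; which genes are
#' prognostic, and their signs/magnitudes, are drawn once from the master
#' seed.
#'
#' @param config a [simulationConfig()].
#' @return list with elements `cohorts` (list of [Cohort-class]) and
#'   `truth` (list: `beta` — named per-gene true log HR, zero for null
#'   genes; `prognostic` — the nonzero gene ids; `medians` — per-cohort
#'   named vectors of the generation-time medians; `censoring_rate_realized`
#'   per cohort).
#' @export
simulateCohorts <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulationConfig"))
  genes <- sprintf("gene_%03d", seq_len(config$n_genes))
  beta <- stats::setNames(numeric(config$n_genes), genes)
  prog <- character()
  if (config$n_prognostic > 0L) {
    withSeed(childSeed(config$seed, 1L), {
      prog <- sort(sample(genes, config$n_prognostic))
      mag <- stats::runif(config$n_prognostic, config$log_hr_range[1L],
                          config$log_hr_range[2L])
      sgn <- switch(config$prognostic_direction,
                    mixed = sample(c(-1, 1), config$n_prognostic,
                                   replace = TRUE),
                    risk = rep(1, config$n_prognostic),
                    protective = rep(-1, config$n_prognostic))
      beta[prog] <- mag * sgn
    })
  }
  cohorts <- vector("list", config$n_cohorts)
  medians <- vector("list", config$n_cohorts)
  realized <- numeric(config$n_cohorts)
  for (k in seq_len(config$n_cohorts)) {
    nm <- sprintf("sim%02d", k)
    n <- config$n_samples_per_cohort[k]
    withSeed(childSeed(config$seed, 1L + k), {
      expr <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
                     dimnames = list(genes, sprintf("%s_s%04d", nm,
                                                    seq_len(n))))
      med <- apply(expr, 1L, stats::median)
      eta <- if (length(prog))
        drop(crossprod(expr[prog, , drop = FALSE] > med[prog], beta[prog]))
      else numeric(n)
      h <- config$baseline_hazard[k] * exp(eta)
      tt <- stats::rexp(n) / h
      if (config$censoring_rate > 0) {
        cr <- calibrateCensoring(h, config$censoring_rate)
        cc <- stats::rexp(n) / cr
      } else cc <- rep(Inf, n)
      os_time <- pmin(tt, cc)
      os_event <- as.numeric(tt <= cc)
      clin <- data.frame(sample_id = colnames(expr), os_time = os_time,
                         os_event = os_event, stringsAsFactors = FALSE)
      if (config$rfs) {
        h2 <- h * 1.25
        t2 <- stats::rexp(n) / h2
        c2 <- if (config$censoring_rate > 0)
          stats::rexp(n) / calibrateCensoring(h2, config$censoring_rate)
        else rep(Inf, n)
        clin$rfs_time <- pmin(t2, c2)
        clin$rfs_event <- as.numeric(t2 <= c2)
      }
      medians[[k]] <- med
      realized[k] <- mean(os_event == 0)
      cohorts[[k]] <- Cohort(expr, clin, name = nm)
    })
  }
  names(cohorts) <- names(medians) <- sprintf("sim%02d",
                                              seq_len(config$n_cohorts))
  list(cohorts = cohorts,
       truth = list(beta = beta, prognostic = prog, medians = medians,
                    censoring_rate_realized = realized))
}

#' Simulate named gene sets
#'
#' Draws `n_sets` gene sets of `set_size` genes each, sampled without
#' replacement within each set from the universe `gene_001 ...`, matching
#' the gene naming of [simulateCohorts()].
#'
#' @param n_sets,set_size,n_genes counts; `set_size <= n_genes`.
#' @param seed integer seed.
#' @return a [GeneSetList-class].
#' @export
simulateGeneSets <- function(n_sets = 28L, set_size = 30L, n_genes = 182L,
                             seed = 1L) {
  if (set_size > n_genes) stop("set_size exceeds n_genes")
  stopifnot(n_sets >= 1L, set_size >= 1L)
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  withSeed(childSeed(seed, 20L), {
    sets <- lapply(seq_len(n_sets), function(i) sample(genes, set_size))
    names(sets) <- sprintf("set_%02d", seq_len(n_sets))
    GeneSetList(sets, rep("simulated", n_sets))
  })
}

#' Simulate a minimal MAF mutation table
#'
#' Per sample, the number of background records is Poisson with the given
#' mean; genes are drawn uniformly (with replacement) from the pool and a
#' variant classification is drawn from a fixed mix of nonsynonymous and
#' silent classes (about 74% nonsynonymous). Optionally, named genes are
#' enriched per group: for each enriched gene, each sample gains one
#' missense record with the group-specific probability.
#'
#' @param samples sample ids (non-empty).
#' @param gene_pool gene ids to mutate.
#' @param mean_mutations positive mean background record count per sample.
#' @param groups optional named vector sample id -> group label, required
#'   when `enrichment` is given.
#' @param enrichment optional named list: gene -> named numeric vector of
#'   per-group mutation probabilities, e.g.
#'   `list(TP53 = c(high = 0.7, low = 0.3))`.
#' @param seed integer seed.
#' @return data.frame with `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#'   `Variant_Classification`.
#' @export
simulateMutations <- function(samples, gene_pool, mean_mutations = 60,
                              groups = NULL, enrichment = NULL, seed = 1L) {
  if (length(samples) == 0L) stop("empty sample list")
  if (mean_mutations <= 0) stop("mean_mutations must be positive")
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
               "Frame_Shift_Ins", "In_Frame_Del", "Splice_Site",
               "Silent", "3'UTR", "Intron")
  probs <- c(0.50, 0.06, 0.05, 0.04, 0.03, 0.06, 0.16, 0.06, 0.04)
  withSeed(childSeed(seed, 30L), {
    counts <- stats::rpois(length(samples), mean_mutations)
    total <- sum(counts)
    df <- data.frame(
      Hugo_Symbol = if (total) sample(gene_pool, total, replace = TRUE)
        else character(),
      Tumor_Sample_Barcode = rep(samples, counts),
      Variant_Classification = if (total)
        sample(classes, total, replace = TRUE, prob = probs) else character(),
      stringsAsFactors = FALSE)
    if (!is.null(enrichment)) {
      if (is.null(groups)) stop("enrichment requires 'groups'")
      extra <- list()
      for (g in names(enrichment)) {
        pr <- enrichment[[g]][groups[samples]]
        pr[is.na(pr)] <- 0
        hit <- stats::runif(length(samples)) < pr
        if (any(hit))
          extra[[g]] <- data.frame(Hugo_Symbol = g,
                                   Tumor_Sample_Barcode = samples[hit],
                                   Variant_Classification =
                                     "Missense_Mutation",
                                   stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, c(list(df), extra))
    }
    rownames(df) <- NULL
    df
  })
}

#' Couple immune-signature expression to the simulated risk level
#'
#' Rebuilds a simulated cohort so that the expression of the named
#' immune-signature genes is suppressed in proportion to each sample's true
#' risk: the standardized generating linear predictor (the sum of
#' `beta_g * 1[expr_g > median_g]` over prognostic genes, using the
#' generation-time medians) is subtracted, scaled by `strength`, from every
#' signature gene's expression row. High-risk samples therefore carry low
#' immune-signature expression by construction — the generative analogue of
#' an immune-excluded tumor — which makes the expected correlation between
#' a risk score and a signature-based immune score negative. Deterministic:
#' no new random numbers are drawn.
#'
#' @param cohort a [Cohort-class] from [simulateCohorts()].
#' @param truth the matching `truth` element (needs `beta` and the cohort's
#'   entry in `medians`).
#' @param signature_genes genes whose expression is coupled; they should be
#'   null genes, so the coupling does not feed back into the risk score.
#' @param strength suppression per SD of risk (expression units).
#' @return a new [Cohort-class] with modified expression.
#' @export
suppressImmuneSignature <- function(cohort, truth, signature_genes,
                                    strength = 0.8) {
  stopifnot(is(cohort, "Cohort"),
            cohortName(cohort) %in% names(truth$medians))
  expr <- exprMatrix(cohort)
  stopifnot(all(signature_genes %in% rownames(expr)))
  med <- truth$medians[[cohortName(cohort)]]
  prog <- truth$prognostic
  if (length(prog) == 0L) stop("no prognostic gene in the ground truth")
  eta <- drop(crossprod(expr[prog, , drop = FALSE] > med[prog],
                        truth$beta[prog]))
  z <- as.numeric(scale(eta))
  expr[signature_genes, ] <- expr[signature_genes, , drop = FALSE] -
    strength * rep(z, each = length(signature_genes))
  Cohort(expr, clinicalData(cohort), name = cohortName(cohort))
}

#' Simulate an immunotherapy-response cohort with calibrated AUROC
#'
#' Scores follow the binormal model: non-responders ~ N(0, 1), responders
#' ~ N(shift, 1) with `shift = sqrt(2) * qnorm(auc_target)`, so the
#' expected AUROC equals `auc_target` (`Phi(shift / sqrt(2))`). Responders
#' are split CR/PR and non-responders SD/PD at random. Survival times are
#' exponential with hazard `baseline_hazard * exp(score_loghr * score)` —
#' negative `score_loghr` (default) makes a higher score protective, the
#' treated-cohort pattern; set it positive for the untreated prognostic
#' pattern.
#'
#' @param n cohort size.
#' @param auc_target target AUROC, strictly inside (0.5, 1).
#' @param responder_fraction expected fraction of CR/PR patients.
#' @param score_loghr log hazard ratio per score unit.
#' @param baseline_hazard exponential baseline (1/month).
#' @param censoring_rate target censored fraction.
#' @param seed integer seed.
#' @return data.frame: `sample_id`, `score`, `response`, `os_time`,
#'   `os_event`.
#' @export
simulateResponseCohort <- function(n, auc_target = 0.8,
                                   responder_fraction = 0.3,
                                   score_loghr = -0.5,
                                   baseline_hazard = 0.05,
                                   censoring_rate = 0.2, seed = 1L) {
  if (auc_target <= 0.5 || auc_target >= 1)
    stop("auc_target must be strictly inside (0.5, 1)")
  stopifnot(n >= 2L, responder_fraction > 0, responder_fraction < 1)
  shift <- sqrt(2) * stats::qnorm(auc_target)
  withSeed(childSeed(seed, 40L), {
    resp <- stats::runif(n) < responder_fraction
    if (!any(resp)) resp[1L] <- TRUE
    if (all(resp)) resp[1L] <- FALSE
    score <- stats::rnorm(n) + shift * resp
    response <- ifelse(resp,
                       sample(c("CR", "PR"), n, replace = TRUE),
                       sample(c("SD", "PD"), n, replace = TRUE))
    h <- baseline_hazard * exp(score_loghr * score)
    tt <- stats::rexp(n) / h
    cc <- if (censoring_rate > 0)
      stats::rexp(n) / calibrateCensoring(h, censoring_rate)
    else rep(Inf, n)
    data.frame(sample_id = sprintf("pt_%04d", seq_len(n)),
               score = score, response = response,
               os_time = pmin(tt, cc), os_event = as.numeric(tt <= cc),
               stringsAsFactors = FALSE)
  })
}
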