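# Signature weights, sample scoring, cutpoint search and group assignment.

test_that("weights follow (HR-1)/SE_HR with the delta-method SE", {
  # HR = 2, log-scale SE 0.1 -> SE_HR = 0.2 -> w = 5
  pooled <- data.frame(gene = "g1", pooled_log_hr = log(2), pooled_se = 0.1)
  w <- computeWeights(pooled)
  expect_equal(w$weight, (2 - 1) / (2 * 0.1), tolerance = 1e-12)
  expect_equal(w$weight, 5, tolerance = 1e-12)
  # HR = 1 gives weight 0 for any SE
  expect_equal(computeWeights(data.frame(gene = "g", pooled_log_hr = 0,
                                         pooled_se = 0.42))$weight, 0)
  # protective gene: negative weight
  expect_lt(computeWeights(data.frame(gene = "g", pooled_log_hr = log(0.5),
                                      pooled_se = 0.2))$weight, 0)
  # log-scale SE variant
  wl <- computeWeights(pooled, se_scale = "log")
  expect_equal(wl$weight, (2 - 1) / 0.1, tolerance = 1e-12)
  expect_error(computeWeights(data.frame(gene = "g", pooled_log_hr = 1,
                                         pooled_se = 0)), "nonpositive")
})

test_that("weight signs always match the prognosis direction", {
  set.seed(4)
  pooled <- data.frame(gene = paste0("g", 1:30),
                       pooled_log_hr = rnorm(30), pooled_se = runif(30, 0.05, 0.4))
  w <- computeWeights(pooled)
  expect_equal(sign(w$weight), sign(exp(pooled$pooled_log_hr) - 1))
})

test_that("scores are the weighted sum of per-gene z-scores", {
  expr <- matrix(c(1, 2, 6, 4, 10, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  w <- data.frame(gene = c("gA", "gB"), weight = c(2, -1))
  sc <- scoreSamples(expr, w)
  # hand evaluation
  zA <- (expr["gA", ] - mean(expr["gA", ])) / sd(expr["gA", ])
  zB <- (expr["gB", ] - mean(expr["gB", ])) / sd(expr["gB", ])
  expect_equal(sc$score, unname(2 * zA - 1 * zB), tolerance = 1e-12)
  # single gene with weight 1: the z-score itself
  sc1 <- scoreSamples(expr, data.frame(gene = "gA", weight = 1))
  expect_equal(sc1$score, unname(zA), tolerance = 1e-12)
  # all-zero weights: all-zero scores
  sc0 <- scoreSamples(expr, data.frame(gene = c("gA", "gB"), weight = 0))
  expect_equal(sc0$score, c(0, 0, 0))
})

test_that("scoring is invariant to per-gene affine rescaling of expression", {
  set.seed(6)
  expr <- matrix(rnorm(50), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  w <- data.frame(gene = paste0("g", 1:5), weight = rnorm(5))
  sc1 <- scoreSamples(expr, w)
  expr2 <- expr * runif(5, 0.5, 4) + rnorm(5)   # row-wise affine
  sc2 <- scoreSamples(expr2, w)
  expect_equal(sc1$score, sc2$score, tolerance = 1e-10)
})

test_that("absent and constant signature genes are dropped with warnings", {
  expr <- matrix(c(1, 2, 3, 5, 5, 5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("gA", "flat"), paste0("s", 1:3)))
  w <- data.frame(gene = c("gA", "flat", "ghost"), weight = c(1, 1, 1))
  msgs <- capture_warnings(sc <- scoreSamples(expr, w))
  expect_match(msgs, "absent", all = FALSE)
  expect_match(msgs, "zero-variance", all = FALSE)
  expect_identical(attr(sc, "genes_used"), "gA")
  expect_error(suppressWarnings(
    scoreSamples(expr[1, , drop = FALSE] * 0 + 1,
                 data.frame(gene = "gA", weight = 1))),
    "no usable")
  expect_error(scoreSamples(expr, data.frame(gene = "ghost", weight = 1)),
               "no signature gene")
})

test_that("maxrank cutoff equals the exhaustive candidate maximum", {
  for (s in 1:6) {
    set.seed(200 + s)
    n <- 60
    score <- rnorm(n)
    t <- rexp(n, 0.05 * exp(0.8 * score))
    cens <- rexp(n, 0.03)
    time <- pmin(t, cens); event <- as.numeric(t <= cens)
    cut <- findCutoff(score, time, event, min_group_fraction = 0.1)
    # brute force over every admissible observed value
    cands <- sort(unique(score))
    stats <- sapply(cands, function(cc) {
      g <- score > cc
      if (sum(g) < ceiling(0.1 * n) || sum(!g) < ceiling(0.1 * n))
        return(NA_real_)
      logrankTest(time, event, g)$chisq
    })
    expect_equal(cut$statistic, max(stats, na.rm = TRUE), tolerance = 1e-10)
    g <- score > cut$cutoff
    expect_equal(logrankTest(time, event, g)$chisq, cut$statistic,
                 tolerance = 1e-10)
  }
})

test_that("cutoff falls between two well-separated survival clusters", {
  set.seed(55)
  n <- 50
  score <- c(rnorm(n, -4), rnorm(n, 4))
  time <- c(rexp(n, 0.02), rexp(n, 0.3)) + 0.01
  event <- rep(1, 2 * n)
  cut <- findCutoff(score, time, event)
  expect_gt(cut$cutoff, max(score[1:n]) - 1e-9)
  expect_lt(cut$cutoff, min(score[(n + 1):(2 * n)]))
})

test_that("youden cutoff maximizes IPCW sensitivity+specificity at the horizon", {
  set.seed(66)
  n <- 120
  score <- rnorm(n)
  t <- rexp(n, 0.04 * exp(score))
  cens <- rexp(n, 0.02)
  time <- pmin(t, cens); event <- as.numeric(t <= cens)
  cut <- findCutoff(score, time, event, method = "youden_at_horizon",
                    horizon = 12)
  expect_true(is.finite(cut$cutoff))
  expect_gt(cut$statistic, 0)   # informative score: positive Youden index
})

test_that("group assignment is a strict-threshold count, reusable on new cohorts", {
  sc <- data.frame(sample_id = paste0("s", 1:5),
                   score = c(-1, 0, 0.5, 2, 3))
  g <- assignGroups(sc, cutoff = 0.5)
  expect_identical(g$group, c("low", "low", "low", "high", "high"))
  expect_true(all(g$group == ifelse(g$score > 0.5, "high", "low")))
  # extremes
  expect_true(all(assignGroups(sc, max(sc$score))$group == "low"))
  expect_true(all(assignGroups(sc, min(sc$score) - 1)$group == "high"))
  # training-derived cutoff applied to a fresh cohort: plain counting
  set.seed(7)
  fresh <- data.frame(sample_id = paste0("v", 1:100), score = rnorm(100))
  gv <- assignGroups(fresh, cutoff = 0.3)
  expect_equal(sum(gv$group == "high"), sum(fresh$score > 0.3))
})

test_that("risk-dominated signatures stratify survival in the right direction", {
  # all signature genes harmful: high group must do worse
  cfg <- simulationConfig(n_cohorts = 1, n_samples_per_cohort = 500,
                          n_genes = 40, n_prognostic = 10,
                          log_hr_range = c(0.5, 0.8),
                          prognostic_direction = "risk",
                          censoring_rate = 0.3, seed = 303)
  sim <- simulateCohorts(cfg)
  eff <- screenCohorts(sim$cohorts)
  pooled <- poolEffects(eff)
  sel <- selectGenes(pooled, 0.05, 0.05)
  w <- computeWeights(sel)
  expect_true(all(w$weight[w$gene %in% sim$truth$prognostic] > 0))
  sc <- scoreSamples(sim$cohorts[[1]], w)
  cd <- clinicalData(sim$cohorts[[1]])
  cut <- findCutoff(sc$score, cd$os_time, cd$os_event)
  g <- assignGroups(sc, cut$cutoff)
  fit <- coxFit(cd$os_time, cd$os_event, as.numeric(g$group == "high"))
  expect_gt(exp(unname(fit$coef)), 1)
})
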