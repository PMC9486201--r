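# Median-dichotomized screening, inverse-variance pooling, BH adjustment
# and threshold selection.

test_that("median split puts exactly half of an even cohort in each group and ties go low", {
  expr <- matrix(c(1:8, c(2, 2, 2, 2, 9, 9, 9, 9)), nrow = 2, byrow = TRUE,
                 dimnames = list(c("gA", "gC"), paste0("s", 1:8)))
  med <- median(expr["gA", ])
  expect_equal(sum(expr["gA", ] > med), 4)
  # gC has ties at the median: they are assigned to the low group
  expect_equal(sum(expr["gC", ] > median(expr["gC", ])), 4)
  x <- c(1, 2, 2, 3)  # median 2; only the 3 is "high"
  expect_equal(sum(x > median(x)), 1)
})

test_that("screenGene composes median split and coxFit exactly", {
  co <- toyCohort()
  cd <- clinicalData(co)
  eff <- screenGene(co, "gA", min_events = 1)
  ind <- as.numeric(exprMatrix(co)["gA", ] > median(exprMatrix(co)["gA", ]))
  ref <- coxFit(cd$os_time, cd$os_event, ind)
  expect_equal(eff$log_hr, unname(ref$coef), tolerance = 1e-8)
  expect_equal(eff$se_log_hr, unname(ref$se), tolerance = 1e-8)
  expect_equal(eff$p, unname(ref$p), tolerance = 1e-8)
  expect_equal(eff$n_events, sum(cd$os_event))
})

test_that("constant genes and low-event cohorts are recorded as missing with reasons", {
  expr <- matrix(c(rep(5, 6), rnorm(6)), nrow = 2, byrow = TRUE,
                 dimnames = list(c("flat", "ok"), paste0("s", 1:6)))
  clin <- data.frame(sample_id = paste0("s", 1:6),
                     os_time = c(3, 6, 9, 12, 15, 18),
                     os_event = c(1, 1, 0, 1, 0, 1))
  co <- Cohort(expr, clin, "t")
  expect_identical(screenGene(co, "flat", min_events = 1)$reason,
                   "degenerate")
  expect_identical(screenGene(co, "ok", min_events = 10)$reason,
                   "too few events")
  expect_error(screenGene(co, "nope"), "not in cohort")
})

test_that("screenCohorts marks genes absent from a cohort and pools over the rest", {
  co1 <- toyCohort("c1")
  expr2 <- matrix(rnorm(16), 2, 8,
                  dimnames = list(c("gA", "gD"), paste0("s", 1:8)))
  co2 <- Cohort(expr2, clinicalData(co1), "c2")
  eff <- screenCohorts(list(c1 = co1, c2 = co2), min_events = 1)
  expect_setequal(unique(eff$gene), c("gA", "gB", "gC", "gD"))
  expect_identical(eff$reason[eff$gene == "gD" & eff$cohort == "c1"],
                   "gene absent")
  pooled <- poolEffects(eff)
  expect_equal(pooled$n_cohorts_used[pooled$gene == "gA"], 2)
  expect_equal(pooled$n_cohorts_used[pooled$gene == "gD"], 1)
})

test_that("fixed-effects pooling reproduces the closed forms", {
  # hand evaluation of sum(w b)/sum(w), 1/sqrt(sum(w)) for two studies
  eff <- data.frame(gene = "g", cohort = c("a", "b"),
                    log_hr = c(0.5, 0.1), se_log_hr = c(0.2, 0.4))
  pooled <- poolEffects(eff)
  w <- c(1 / 0.04, 1 / 0.16)
  expect_equal(pooled$pooled_log_hr, sum(w * c(0.5, 0.1)) / sum(w),
               tolerance = 1e-12)
  expect_equal(pooled$pooled_se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  # three studies
  eff3 <- data.frame(gene = "g", cohort = c("a", "b", "c"),
                     log_hr = c(0.3, -0.2, 0.6),
                     se_log_hr = c(0.1, 0.25, 0.3))
  p3 <- poolEffects(eff3)
  w3 <- 1 / c(0.1, 0.25, 0.3)^2
  expect_equal(p3$pooled_log_hr, sum(w3 * c(0.3, -0.2, 0.6)) / sum(w3),
               tolerance = 1e-12)
  expect_equal(p3$pooled_se, 1 / sqrt(sum(w3)), tolerance = 1e-12)
  # equal SEs: arithmetic mean, se/sqrt(k)
  eq <- data.frame(gene = "g", cohort = letters[1:4],
                   log_hr = c(0.1, 0.4, 0.2, 0.3), se_log_hr = 0.25)
  pe <- poolEffects(eq)
  expect_equal(pe$pooled_log_hr, 0.25, tolerance = 1e-12)
  expect_equal(pe$pooled_se, 0.25 / 2, tolerance = 1e-12)
  # a single cohort passes through unchanged
  one <- poolEffects(eff[1, ])
  expect_equal(one$pooled_log_hr, 0.5)
  expect_equal(one$pooled_se, 0.2)
})

test_that("pooling matches metafor and respects heterogeneity identities", {
  eff <- data.frame(gene = "g", cohort = letters[1:3],
                    log_hr = c(0.8, 0.2, -0.1),
                    se_log_hr = c(0.15, 0.3, 0.2))
  pf <- poolEffects(eff, model = "fixed")
  rf <- metafor::rma(yi = eff$log_hr, sei = eff$se_log_hr, method = "FE")
  expect_equal(pf$pooled_log_hr, as.numeric(rf$beta), tolerance = 1e-10)
  expect_equal(pf$pooled_se, rf$se, tolerance = 1e-10)
  expect_equal(pf$Q, rf$QE, tolerance = 1e-10)
  pr <- poolEffects(eff, model = "random")
  rr <- metafor::rma(yi = eff$log_hr, sei = eff$se_log_hr, method = "DL")
  expect_equal(pr$pooled_log_hr, as.numeric(rr$beta), tolerance = 1e-10)
  expect_equal(pr$tau2, rr$tau2, tolerance = 1e-10)
  # identical effects: I2 = 0 and random = fixed
  same <- data.frame(gene = "g", cohort = letters[1:3], log_hr = 0.3,
                     se_log_hr = c(0.1, 0.2, 0.3))
  expect_equal(poolEffects(same)$I2, 0)
  expect_equal(poolEffects(same, "random")$pooled_log_hr,
               poolEffects(same, "fixed")$pooled_log_hr)
  # pooled SE never exceeds the best single cohort
  expect_lte(pf$pooled_se, min(eff$se_log_hr))
  # CI brackets the HR
  expect_true(pf$ci95_low <= pf$hr && pf$hr <= pf$ci95_high)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bhAdjust(p), rep(0.04, 4), tolerance = 1e-12)
  # brute force: q_i = min over j>=i of p_(j) * n / j, mapped back
  set.seed(31)
  pr <- runif(25)
  n <- length(pr)
  ord <- order(pr)
  qs <- sapply(seq_len(n), function(i)
    min(sapply(i:n, function(j) pr[ord[j]] * n / j)))
  brute <- numeric(n); brute[ord] <- pmin(qs, 1)
  expect_equal(bhAdjust(pr), brute, tolerance = 1e-12)
  expect_equal(bhAdjust(0.37), 0.37)
  # permutation equivariance
  perm <- sample(n)
  expect_equal(bhAdjust(pr[perm]), bhAdjust(pr)[perm])
  expect_error(bhAdjust(c(0.5, 1.2)), "outside")
})

test_that("selectGenes applies both thresholds and counts directions", {
  pooled <- data.frame(gene = paste0("g", 1:4),
                       pooled_log_hr = c(0.5, -0.4, 0.2, 0.1),
                       pooled_se = 0.1,
                       p = c(1e-5, 1e-4, 0.2, 0.5),
                       q = c(4e-5, 2e-4, 0.3, 0.5),
                       direction = c("poor", "good", "poor", "poor"))
  sel <- selectGenes(pooled, 0.001, 0.001)
  expect_identical(sel$gene, c("g1", "g2"))
  expect_equal(attr(sel, "n_poor"), 1)
  expect_equal(attr(sel, "n_good"), 1)
  all_ <- selectGenes(pooled, 1, 1)
  expect_equal(nrow(all_), 4)
  expect_message(none <- selectGenes(pooled, 1e-9, 1e-9), "no gene")
  expect_equal(nrow(none), 0)
})

test_that("null genes yield approximately uniform screening p-values", {
  cfg <- simulationConfig(n_cohorts = 1, n_samples_per_cohort = 400,
                          n_genes = 150, n_prognostic = 0,
                          censoring_rate = 0.2, seed = 77)
  sim <- simulateCohorts(cfg)
  eff <- screenCohorts(sim$cohorts, min_events = 5)
  p <- eff$p[!is.na(eff$p)]
  # fraction below 0.05 within 3 binomial SD of 0.05
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / length(p)))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
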