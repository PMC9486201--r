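# The synthetic-data generators: determinism, calibration and ground truth.

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- simulationConfig(n_cohorts = 2, n_samples_per_cohort = 50,
                          n_genes = 20, n_prognostic = 4, seed = 123)
  s1 <- simulateCohorts(cfg)
  s2 <- simulateCohorts(cfg)
  expect_identical(lapply(s1$cohorts, exprMatrix),
                   lapply(s2$cohorts, exprMatrix))
  expect_identical(lapply(s1$cohorts, clinicalData),
                   lapply(s2$cohorts, clinicalData))
  expect_identical(s1$truth, s2$truth)
  # a different seed changes the data
  cfg2 <- simulationConfig(n_cohorts = 2, n_samples_per_cohort = 50,
                           n_genes = 20, n_prognostic = 4, seed = 124)
  expect_false(identical(exprMatrix(simulateCohorts(cfg2)$cohorts[[1]]),
                         exprMatrix(s1$cohorts[[1]])))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(runif(1))
  invisible(simulateCohorts(simulationConfig(n_cohorts = 1,
                                             n_samples_per_cohort = 30,
                                             n_genes = 5, n_prognostic = 1,
                                             seed = 9)))
  after <- runif(2)
  expect_identical(before, c(before[1], after))
})

test_that("config validation rejects impossible settings", {
  expect_error(simulationConfig(n_cohorts = 0), "positive")
  expect_error(simulationConfig(n_genes = 0), "positive")
  expect_error(simulationConfig(n_samples_per_cohort = -5), "positive")
  expect_error(simulationConfig(n_prognostic = 500, n_genes = 100),
               "n_prognostic")
  expect_error(simulationConfig(censoring_rate = 1.2), "censoring_rate")
  expect_error(simulationConfig(log_hr_range = c(0.8, 0.4)), "interval")
})

test_that("ground truth has exactly n_prognostic nonzero effects of the requested sign", {
  cfg <- simulationConfig(n_cohorts = 1, n_samples_per_cohort = 40,
                          n_genes = 50, n_prognostic = 8,
                          prognostic_direction = "risk", seed = 2)
  tr <- simulateCohorts(cfg)$truth
  expect_equal(sum(tr$beta != 0), 8)
  expect_true(all(tr$beta[tr$prognostic] >= 0.4 &
                    tr$beta[tr$prognostic] <= 0.8))
  cfg0 <- simulationConfig(n_cohorts = 1, n_samples_per_cohort = 40,
                           n_genes = 50, n_prognostic = 0, seed = 2)
  expect_true(all(simulateCohorts(cfg0)$truth$beta == 0))
})

test_that("realized censoring approximates the target", {
  cfg <- simulationConfig(n_cohorts = 2, n_samples_per_cohort = 800,
                          n_genes = 10, n_prognostic = 2,
                          censoring_rate = 0.3, seed = 5)
  sim <- simulateCohorts(cfg)
  expect_true(all(abs(sim$truth$censoring_rate_realized - 0.3) < 0.07))
  cfg0 <- simulationConfig(n_cohorts = 1, n_samples_per_cohort = 100,
                           n_genes = 5, n_prognostic = 0,
                           censoring_rate = 0, seed = 5)
  expect_true(all(clinicalData(simulateCohorts(cfg0)$cohorts[[1]])$os_event
                  == 1))
})

test_that("screening recovers a single strong effect at large n", {
  # one gene with beta = log(2), n = 2000, no censoring: the estimate must
  # land within 3 SE of the generating parameter
  cfg <- simulationConfig(n_cohorts = 1, n_samples_per_cohort = 2000,
                          n_genes = 1, n_prognostic = 1,
                          log_hr_range = c(log(2), log(2)),
                          prognostic_direction = "risk",
                          censoring_rate = 0, seed = 11)
  sim <- simulateCohorts(cfg)
  eff <- screenCohorts(sim$cohorts)
  expect_lt(abs(eff$log_hr - log(2)), 3 * eff$se_log_hr)
})

test_that("gene sets honor size contracts and determinism", {
  gs <- simulateGeneSets(n_sets = 28, set_size = 30, n_genes = 182,
                         seed = 3)
  expect_length(gs, 28)
  expect_true(all(lengths(as.list(gs)) == 30))
  expect_true(all(sapply(as.list(gs), anyDuplicated) == 0))
  expect_identical(as.list(simulateGeneSets(28, 30, 182, seed = 3)),
                   as.list(gs))
  # set_size = n_genes: every set is the whole universe
  gs2 <- simulateGeneSets(n_sets = 3, set_size = 10, n_genes = 10, seed = 1)
  expect_true(all(sapply(as.list(gs2), function(s)
    setequal(s, sprintf("gene_%03d", 1:10)))))
  expect_error(simulateGeneSets(set_size = 50, n_genes = 10), "exceeds")
})

test_that("mutation tables are deterministic, Poisson-sized and enrichable", {
  samples <- paste0("s", 1:400)
  m1 <- simulateMutations(samples, paste0("g", 1:100), mean_mutations = 8,
                          seed = 6)
  expect_identical(simulateMutations(samples, paste0("g", 1:100),
                                     mean_mutations = 8, seed = 6), m1)
  counts <- table(factor(m1$Tumor_Sample_Barcode, levels = samples))
  expect_lt(abs(mean(counts) - 8), 3 * sqrt(8 / 400))
  # near-zero mean: near-empty table
  m0 <- simulateMutations(samples, "g1", mean_mutations = 1e-4, seed = 6)
  expect_lt(nrow(m0), 5)
  expect_error(simulateMutations(character(), "g1", 5), "empty")
  expect_error(simulateMutations("s1", "g1", 0), "positive")
  # group enrichment hits the stated probabilities within binomial error
  groups <- setNames(rep(c("high", "low"), each = 200), samples)
  me <- simulateMutations(samples, paste0("g", 1:100), mean_mutations = 0.01,
                          groups = groups,
                          enrichment = list(TP53 = c(high = 0.7, low = 0.3)),
                          seed = 8)
  tp <- me[me$Hugo_Symbol == "TP53", ]
  f_high <- length(unique(tp$Tumor_Sample_Barcode[
    groups[tp$Tumor_Sample_Barcode] == "high"])) / 200
  f_low <- length(unique(tp$Tumor_Sample_Barcode[
    groups[tp$Tumor_Sample_Barcode] == "low"])) / 200
  expect_lt(abs(f_high - 0.7), 3 * sqrt(0.7 * 0.3 / 200))
  expect_lt(abs(f_low - 0.3), 3 * sqrt(0.3 * 0.7 / 200))
})

test_that("response cohorts hit the binormal AUROC calibration", {
  rc <- simulateResponseCohort(5000, auc_target = 0.8, seed = 12)
  expect_identical(simulateResponseCohort(5000, auc_target = 0.8, seed = 12),
                   rc)
  auc <- auroc(rc$score, isResponder(rc$response))
  expect_gt(auc, 0.77); expect_lt(auc, 0.83)
  expect_error(simulateResponseCohort(100, auc_target = 0.5), "strictly")
  expect_error(simulateResponseCohort(100, auc_target = 1), "strictly")
})

test_that("null screening p-values stay calibrated across replicates", {
  # all beta = 0: fraction with p < 0.05 within 3 binomial SD of 0.05
  fracs <- numeric(5)
  for (r in 1:5) {
    cfg <- simulationConfig(n_cohorts = 1, n_samples_per_cohort = 200,
                            n_genes = 100, n_prognostic = 0,
                            censoring_rate = 0.2, seed = 500 + r)
    eff <- screenCohorts(simulateCohorts(cfg)$cohorts, min_events = 5)
    fracs[r] <- mean(eff$p < 0.05, na.rm = TRUE)
  }
  n_tot <- 5 * 100
  expect_lt(abs(mean(fracs) - 0.05), 3 * sqrt(0.05 * 0.95 / n_tot))
})
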