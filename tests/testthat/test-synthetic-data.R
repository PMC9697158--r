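test_that("simulated cohorts are deterministic and match their marginals", {
  c1 <- simulateCohort(191, seed = 11)
  c2 <- simulateCohort(191, seed = 11)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulateCohort(191, seed = 12)
  expect_false(identical(c1$clinical, c3$clinical))

  # class split by the survival median is near-balanced
  expect_lte(abs(sum(c1$truth == 1L) - sum(c1$truth == 0L)), 1L)

  # observed frequencies within 3 binomial sd of the target marginals
  m <- defaultCohortMarginals()
  n <- 191
  for (f in names(m$categorical)) {
    probs <- m$categorical[[f]]$probs
    nObs <- sum(!is.na(c1$clinical[[f]]))
    for (cat in names(probs)) {
      got <- sum(c1$clinical[[f]] == cat, na.rm = TRUE)
      want <- nObs * probs[[cat]]
      tol <- 3 * sqrt(nObs * probs[[cat]] * (1 - probs[[cat]])) + 1
      expect_lte(abs(got - want), tol)
    }
    missRate <- m$categorical[[f]]$missing
    expect_lte(abs(sum(is.na(c1$clinical[[f]])) - n * missRate),
               3 * sqrt(n * max(missRate, 1e-9) * (1 - missRate)) + 1)
  }
})

test_that("zero missing rates yield a complete table", {
  m <- defaultCohortMarginals()
  for (f in names(m$categorical)) m$categorical[[f]]$missing <- 0
  for (f in names(m$numeric)) m$numeric[[f]]$missing <- 0
  coh <- simulateCohort(80, m, seed = 2)
  expect_false(anyNA(coh$clinical[clinicalFeatures()]))
})

test_that("invalid marginals are rejected", {
  m <- defaultCohortMarginals()
  m$categorical$sex$probs <- c(male = 0.7, female = 0.6)
  expect_error(simulateCohort(50, m), "sum to 1")
  m2 <- defaultCohortMarginals()
  m2$numeric$age$median <- 200
  expect_error(simulateCohort(50, m2), "min < median < max")
})

test_that("cohort summaries use full-cohort denominators and sum below 100%", {
  coh <- simulateCohort(150, seed = 21)
  summ <- summarizeCohort(coh$clinical)
  for (f in unique(summ$feature)) {
    expect_lte(sum(summ$percent[summ$feature == f]), 100 + 1e-9)
    expect_equal(sum(summ$count[summ$feature == f]), 150)
  }
  # uniform two-category feature splits 50/50
  tab <- coh$clinical[1:10, ]
  tab$sex <- rep(c("male", "female"), 5L)
  summ10 <- summarizeCohort(tab)
  expect_equal(summaryPercent(summ10, "sex", "male"), 50)
  expect_equal(summaryPercent(summ10, "sex", "female"), 50)
})

test_that("a perfect-accuracy spec reproduces the truth exactly", {
  ids <- sprintf("p%02d", 1:20)
  truth <- stats::setNames(rep(c(0L, 1L), 10L), ids)
  tab <- simulatePredictions(
    list(syntheticModelSpec("m", "clinical", target_accuracy = 1,
                            difficulty_weight = 0)),
    truth, folds = 2L, seed = 3)
  r <- predictionRecords(tab)
  expect_identical(r$predicted_label, unname(truth[r$patient_id]))
  cc <- confusionCounts(r$predicted_label, truth[r$patient_id])
  expect_equal(recallScore(cc), 1)
})

test_that("equal-accuracy flip-group members make identical errors (K = 0)", {
  ids <- sprintf("p%03d", 1:60)
  set.seed(4)
  truth <- stats::setNames(sample(0:1, 60, TRUE), ids)
  tab <- simulatePredictions(
    list(syntheticModelSpec("a", "imaging", granularity = "patient",
                            target_accuracy = 0.7, flip_group = "g"),
         syntheticModelSpec("b", "imaging", granularity = "patient",
                            target_accuracy = 0.7, flip_group = "g")),
    truth, folds = 1L, seed = 5)
  r <- predictionRecords(tab)
  pa <- r$predicted_label[r$model_id == "a"][order(r$sample_id[r$model_id == "a"])]
  pb <- r$predicted_label[r$model_id == "b"][order(r$sample_id[r$model_id == "b"])]
  expect_identical(pa, pb)
  tt <- truth[sort(r$sample_id[r$model_id == "a"])]
  expect_equal(kappaDiversity(pairContingency(pa, pb, tt)), 0)
})

test_that("marginal accuracies are calibrated within binomial tolerance", {
  ids <- sprintf("p%04d", 1:1000)
  set.seed(6)
  truth <- stats::setNames(sample(0:1, 1000, TRUE), ids)
  targets <- c(0.6, 0.75, 0.9)
  specs <- lapply(seq_along(targets), function(i)
    syntheticModelSpec(paste0("m", i), "clinical", target_accuracy = targets[i],
                       difficulty_weight = i - 1))
  tab <- simulatePredictions(specs, truth, folds = 1L, seed = 7)
  r <- predictionRecords(tab)
  for (i in seq_along(targets)) {
    rr <- r[r$model_id == paste0("m", i), ]
    acc <- mean(rr$predicted_label == truth[rr$patient_id])
    tol <- 3 * sqrt(targets[i] * (1 - targets[i]) / nrow(rr))
    expect_lte(abs(acc - targets[i]), tol)
  }
})

test_that("stronger difficulty coupling never increases expected pairwise diversity", {
  ids <- sprintf("p%04d", 1:2000)
  set.seed(8)
  truth <- stats::setNames(sample(0:1, 2000, TRUE), ids)
  ks <- vapply(c(0, 0.5, 1.5, 3), function(w) {
    specs <- list(
      syntheticModelSpec("a", "clinical", target_accuracy = 0.75,
                         difficulty_weight = w),
      syntheticModelSpec("b", "clinical", target_accuracy = 0.75,
                         difficulty_weight = w))
    tab <- simulatePredictions(specs, truth, folds = 1L, seed = 9)
    r <- predictionRecords(tab)
    pa <- r$predicted_label[r$model_id == "a"]
    pb <- r$predicted_label[r$model_id == "b"]
    tt <- unname(truth[r$patient_id[r$model_id == "a"]])
    kappaDiversity(pairContingency(pa, pb, tt))
  }, numeric(1L))
  # allow small sampling slack between adjacent grid points
  expect_true(all(diff(ks) < 0.03))
  expect_gt(ks[1L], ks[length(ks)] + 0.1)
})

test_that("degenerate targets with positive coupling warn and go deterministic", {
  ids <- sprintf("p%02d", 1:12)
  truth <- stats::setNames(rep(c(1L, 0L), 6L), ids)
  expect_warning(
    tab <- simulatePredictions(
      list(syntheticModelSpec("m", "clinical", target_accuracy = 1,
                              difficulty_weight = 2)),
      truth, folds = 1L, seed = 1),
    "unreachable")
  r <- predictionRecords(tab)
  expect_identical(r$predicted_label, unname(truth[r$patient_id]))
})

test_that("the planted scenario is deterministic and structured as designed", {
  s1 <- plantedOptimumScenario(60, seed = 31, nFolds = 2L)
  s2 <- plantedOptimumScenario(60, seed = 31, nFolds = 2L)
  expect_identical(predictionRecords(s1$table), predictionRecords(s2$table))
  expect_identical(s1$planted, c("cl1", "im1", "im2"))

  # duplicates predict identically, so their pairwise diversity collapses
  r <- predictionRecords(s1$table)
  val <- r[r$split == "val" & r$fold_id == 0L, ]
  p1 <- val$predicted_label[val$model_id == "im1"][order(val$sample_id[val$model_id == "im1"])]
  p3 <- val$predicted_label[val$model_id == "im3"][order(val$sample_id[val$model_id == "im3"])]
  expect_identical(p1, p3)

  # at the scenario's designed scale the planted trio strictly beats trios
  # containing a duplicated pair (diversity collapse) and trios swapping in
  # the degraded clinical copy (pathwise recall loss)
  sFull <- plantedOptimumScenario(100, seed = 31)
  ct <- candidateTable(selectOptimal(sFull$registry, sFull$table))
  planted <- ct[ct$members == "cl1;im1;im2", ]
  dupPair <- ct[ct$members == "cl1;im1;im3", ]
  expect_lt(dupPair$k_bar, planted$k_bar)
  expect_lt(planted$objective, dupPair$objective)
  weak <- ct[ct$members == "cl2;im1;im2", ]
  expect_lte(weak$r_bar, planted$r_bar)
  expect_lt(planted$objective, weak$objective)
})
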