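test_that("feasible enumeration honours size, parity and modality floors", {
  reg1 <- ModelRegistry(c("c1", "i1", "i2"), c("clinical", "imaging", "imaging"))
  expect_identical(enumerateFeasible(reg1, 3L), list(c("c1", "i1", "i2")))

  reg2 <- ModelRegistry(c("c1", "c2", "i1", "i2"),
                        c("clinical", "clinical", "imaging", "imaging"))
  cands <- enumerateFeasible(reg2, 3L)
  expect_length(cands, 4L)
  expect_true(all(vapply(cands, length, integer(1L)) == 3L))

  regNoClin <- ModelRegistry(c("i1", "i2", "i3"), "imaging")
  expect_error(enumerateFeasible(regNoClin, 3L), "per modality")
  expect_length(enumerateFeasible(regNoClin, 3L, requireMultimodal = FALSE),
                1L)
  expect_error(enumerateFeasible(reg2, 4L), "odd")
})

test_that("feasible-set cardinality matches the closed-form count", {
  set.seed(17)
  for (rep in 1:10) {
    nCl <- sample(1:4, 1L); nIm <- sample(1:5, 1L)
    if (nCl + nIm < 3L) nIm <- nIm + 2L
    reg <- ModelRegistry(c(sprintf("c%d", seq_len(nCl)),
                           sprintf("i%d", seq_len(nIm))),
                         c(rep("clinical", nCl), rep("imaging", nIm)))
    maxSize <- sample(c(3L, 5L), 1L)
    M <- nCl + nIm
    expected <- 0L
    for (s in seq(3L, min(maxSize, M), by = 2L))
      expected <- expected + choose(M, s) - choose(nCl, s) - choose(nIm, s)
    expect_length(enumerateFeasible(reg, maxSize), expected)
  }
})

test_that("the objective is the squared distance from the ideal point", {
  expect_equal(selectionObjective(1, 1), 0)
  expect_equal(selectionObjective(0.8, 0.9), 0.05)
  expect_equal(selectionObjective(0, 0), 2)
  # monotone: improving either coordinate towards 1 never hurts
  set.seed(3)
  for (rep in 1:50) {
    r <- stats::runif(1); k <- stats::runif(1)
    expect_lte(selectionObjective(min(r + 0.1, 1), k),
               selectionObjective(r, k))
    expect_lte(selectionObjective(r, min(k + 0.1, 1)),
               selectionObjective(r, k))
  }
})

test_that("candidate scores average fold recall and diversity", {
  ids <- sprintf("p%02d", 1:10)
  truth <- stats::setNames(rep(c(1L, 0L), 5L), ids)
  hit4of5 <- truth; hit4of5[[1L]] <- 0L      # recall 0.8 in fold 0
  hit3of5 <- truth; hit3of5[[1L]] <- 0L; hit3of5[[3L]] <- 0L  # 0.6 in fold 1
  preds <- list(`0` = unname(hit4of5), `1` = unname(hit3of5))
  tab <- fixedPredictionTable(list(m1 = preds, m2 = preds, m3 = preds), truth)
  sc <- scoreCandidate(c("m1", "m2", "m3"), tab)
  expect_equal(sc[["r_bar"]], 0.7)
  expect_equal(sc[["k_bar"]], 0)          # identical members
  expect_error(scoreCandidate("m1", tab), "at least two")
})

test_that("candidate scoring matches the independent fold-by-pair oracle", {
  for (seed in c(101, 202)) {
    inst <- randomSelectionInstance(seed)
    ids <- modelIds(inst$registry)
    set.seed(seed)
    for (rep in 1:3) {
      mem <- sort(sample(ids, 3L))
      got <- scoreCandidate(mem, inst$table, inst$foldIds)
      want <- oracleScore(predictionRecords(inst$table),
                          patientTruth(inst$table), mem, inst$foldIds)
      expect_equal(unname(got), unname(want))
    }
  }
})

test_that("the exhaustive search returns the brute-force argmin with its tie-break", {
  inst <- randomSelectionInstance(7)
  res <- selectOptimal(inst$registry, inst$table, maxSize = inst$maxSize)
  want <- oracleSelect(predictionRecords(inst$table),
                       patientTruth(inst$table),
                       modelIds(inst$registry),
                       clinicalModels(inst$registry),
                       inst$foldIds, inst$maxSize)
  expect_identical(memberIds(optimalEnsemble(res)), want)
  # E* attains the minimum objective among the scored candidates
  ct <- candidateTable(res)
  expect_equal(objectiveValue(optimalEnsemble(res)), min(ct$objective))
})

test_that("duplicate-score candidates fall to the smallest-then-lexicographic tie-break", {
  # im3/im4 duplicate im1/im2 exactly, so several trios tie with the
  # lexicographically smallest one
  sc <- plantedOptimumScenario(60, seed = 5, nFolds = 2L)
  res <- selectOptimal(sc$registry, sc$table)
  ct <- candidateTable(res)
  best <- ct$members[abs(ct$objective - min(ct$objective)) < 1e-12]
  expect_gt(length(best), 1L)
  expect_identical(keyOf(memberIds(optimalEnsemble(res))), min(best))
})

test_that("single-objective selections maximise their score and never beat E*'s objective", {
  for (seed in c(31, 32, 33)) {
    inst <- randomSelectionInstance(seed)
    rec <- predictionRecords(inst$table)
    tt <- patientTruth(inst$table)
    eR <- selectSingleObjective("R", inst$registry, inst$table,
                                maxSize = inst$maxSize)
    eK <- selectSingleObjective("K", inst$registry, inst$table,
                                maxSize = inst$maxSize)
    expect_identical(memberIds(eR),
                     oracleSelect(rec, tt, modelIds(inst$registry),
                                  clinicalModels(inst$registry),
                                  inst$foldIds, inst$maxSize,
                                  objective = "R"))
    expect_identical(memberIds(eK),
                     oracleSelect(rec, tt, modelIds(inst$registry),
                                  clinicalModels(inst$registry),
                                  inst$foldIds, inst$maxSize,
                                  objective = "K"))
    eStar <- optimalEnsemble(selectOptimal(inst$registry, inst$table,
                                           maxSize = inst$maxSize))
    expect_gte(objectiveValue(eR), objectiveValue(eStar))
  }
})

test_that("relaxing the modality floors can only improve the objective", {
  for (seed in c(41, 42, 43)) {
    inst <- randomSelectionInstance(seed)
    relaxed <- selectRelaxed(inst$registry, inst$table,
                             maxSize = inst$maxSize)
    constrained <- optimalEnsemble(selectOptimal(inst$registry, inst$table,
                                                 maxSize = inst$maxSize))
    expect_lte(objectiveValue(relaxed), objectiveValue(constrained))
    expect_identical(memberIds(relaxed),
                     oracleSelect(predictionRecords(inst$table),
                                  patientTruth(inst$table),
                                  modelIds(inst$registry),
                                  clinicalModels(inst$registry),
                                  inst$foldIds, inst$maxSize,
                                  multimodal = FALSE))
  }
})

test_that("an all-clinical trio is reachable only without the modality floors", {
  # three clinical models with perfect recall and one distinct negative
  # error each; the imaging model predicts the negative class throughout.
  # The all-clinical trio scores best but violates the modality floors.
  ids <- sprintf("p%d", 1:6)
  truth <- stats::setNames(c(1L, 1L, 1L, 0L, 0L, 0L), ids)
  errAt <- function(i) { x <- unname(truth); x[i] <- 1L; x }
  preds <- list(cl1 = list(`0` = errAt(4)),
                cl2 = list(`0` = errAt(5)),
                cl3 = list(`0` = errAt(6)),
                im1 = list(`0` = rep(0L, 6)))
  tab <- fixedPredictionTable(preds, truth)
  reg <- ModelRegistry(c("cl1", "cl2", "cl3", "im1"),
                       c(rep("clinical", 3L), "imaging"))
  relaxed <- selectRelaxed(reg, tab)
  constrained <- optimalEnsemble(selectOptimal(reg, tab))
  expect_identical(memberIds(relaxed), c("cl1", "cl2", "cl3"))
  expect_true("im1" %in% memberIds(constrained))
  expect_lt(objectiveValue(relaxed), objectiveValue(constrained))
})

test_that("the Pareto front keeps exactly the non-dominated candidates", {
  one <- data.frame(members = "a;b;c", size = 3L, n_clinical = 1L,
                    n_imaging = 2L, r_bar = 0.5, k_bar = 0.5,
                    objective = selectionObjective(0.5, 0.5))
  expect_identical(paretoFront(one), one)

  two <- rbind(one, one)
  two$members <- c("x", "y")
  two$r_bar <- c(0.9, 0.8); two$k_bar <- c(0.2, 0.9)
  expect_identical(nrow(paretoFront(two)), 2L)

  dom <- two
  dom$r_bar <- c(0.9, 0.8); dom$k_bar <- c(0.9, 0.8)
  expect_identical(paretoFront(dom)$members, "x")
  expect_error(paretoFront(one[0L, ]), "empty")
})

test_that("the selected optimum always lies on the Pareto front", {
  for (seed in c(51, 52, 53, 54)) {
    inst <- randomSelectionInstance(seed)
    res <- selectOptimal(inst$registry, inst$table, maxSize = inst$maxSize)
    front <- paretoFront(res)
    expect_true(keyOf(memberIds(optimalEnsemble(res))) %in% front$members)
    # stored front equals recomputation from the candidate table
    expect_identical(front, paretoFront(candidateTable(res)))
  }
})

test_that("the all-ensembles baseline averages candidate test metrics", {
  inst <- randomSelectionInstance(61)
  cands <- enumerateFeasible(inst$registry, 3L)
  got <- baselineMeanAll(cands, inst$table)
  per <- vapply(cands, function(mem) {
    folds <- inst$foldIds
    m <- vapply(folds, function(b) {
      pred <- ensemblePredict(inst$table, mem, b, "test")
      tt <- patientTruth(inst$table)[names(pred)]
      cc <- confusionCounts(pred, tt)
      c(accuracyScore(cc), fScore(cc), recallScore(cc))
    }, numeric(3L))
    rowMeans(m) * 100
  }, numeric(3L))
  expect_equal(got$mean, unname(apply(per, 1L, mean)))
  expect_equal(got$sd, unname(apply(per, 1L, stats::sd)))
  # a single candidate reports its own metrics with zero spread
  single <- baselineMeanAll(cands[1L], inst$table)
  expect_equal(single$mean, unname(per[, 1L]))
  expect_equal(single$sd, rep(0, 3L))
})

test_that("the a-posteriori top-k ensemble picks the largest test recalls", {
  ids <- sprintf("p%02d", 1:10)
  truth <- stats::setNames(rep(c(1L, 0L), 5L), ids)
  flip <- function(x, i) { x[i] <- 1L - x[i]; x }
  preds <- list(
    cl1 = list(`0` = unname(truth)),                      # recall 1.0
    cl2 = list(`0` = unname(flip(truth, 1))),             # recall 0.8
    im1 = list(`0` = unname(flip(truth, c(1, 3)))),       # recall 0.6
    im2 = list(`0` = unname(flip(truth, c(1, 3, 5, 7)))))  # recall 0.2
  tab <- fixedPredictionTable(preds, truth)
  reg <- ModelRegistry(c("cl1", "cl2", "im1", "im2"),
                       c("clinical", "clinical", "imaging", "imaging"))
  top3 <- baselinePosthocTopK(tab, k = 3L, registry = reg)
  expect_identical(memberIds(top3), c("cl1", "cl2", "im1"))
  # three-model pool returns the whole pool
  reg3 <- ModelRegistry(c("cl1", "cl2", "im1"),
                        c("clinical", "clinical", "imaging"))
  tab3 <- fixedPredictionTable(preds[1:3], truth)
  expect_identical(memberIds(baselinePosthocTopK(tab3, k = 3L,
                                                 registry = reg3)),
                   c("cl1", "cl2", "im1"))
  expect_error(baselinePosthocTopK(tab3, k = 4L, registry = reg3),
               "at least 4")
})

test_that("anchored-pair averaging equals filter-then-average", {
  inst <- randomSelectionInstance(71)
  cands <- enumerateFeasible(inst$registry, inst$maxSize)
  anchors <- sort(cands[[1L]])[1:2]
  keep <- Filter(function(x) all(anchors %in% x), cands)
  got <- baselinePosthocPairAverage(anchors, cands, inst$table)
  want <- baselineMeanAll(keep, inst$table)
  expect_equal(got, want)
  expect_error(baselinePosthocPairAverage(c("zz1", "zz2"), cands, inst$table),
               "no feasible candidate")
})

test_that("selection results serialise to a structured report", {
  inst <- randomSelectionInstance(81)
  res <- selectOptimal(inst$registry, inst$table)
  path <- file.path(tempdir(), "selection.json")
  writeSelectionResult(res, path)
  doc <- jsonlite::fromJSON(path)
  expect_identical(doc$optimal$members, memberIds(optimalEnsemble(res)))
  expect_identical(nrow(doc$candidates), nrow(candidateTable(res)))
  expect_named(doc$baselines, c("E_R", "E_K", "E_relaxed"))
})
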