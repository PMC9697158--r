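# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

# Fully random prediction table (mixed granularities, arbitrary splits) for
# I/O and subset contracts.
randomPredictionTable <- function(seed, nModels = 3L, nFolds = 2L,
                                  nPatients = 8L) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(nPatients))
  truth <- stats::setNames(sample(0:1, nPatients, replace = TRUE), ids)
  pieces <- list()
  for (m in seq_len(nModels)) {
    slice <- m %% 2L == 0L
    for (b in seq_len(nFolds) - 1L) {
      spl <- sample(c("train", "val", "test"), nPatients, replace = TRUE)
      if (slice) {
        ns <- sample(1:3, nPatients, replace = TRUE)
        pieces[[length(pieces) + 1L]] <- data.frame(
          model_id = paste0("m", m), fold_id = b,
          split = rep(spl, ns),
          sample_id = paste0(rep(ids, ns), "_s", sequence(ns)),
          patient_id = rep(ids, ns),
          predicted_label = sample(0:1, sum(ns), replace = TRUE),
          stringsAsFactors = FALSE)
      } else {
        pieces[[length(pieces) + 1L]] <- data.frame(
          model_id = paste0("m", m), fold_id = b, split = spl,
          sample_id = ids, patient_id = ids,
          predicted_label = sample(0:1, nPatients, replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  PredictionTable(do.call(rbind, pieces), truth)
}

# Patient-level table in which every model predicts a prescribed label
# vector in every requested fold/split; used to pin scores exactly.
fixedPredictionTable <- function(predsByModelFold, truth,
                                 splits = c("train", "val", "test")) {
  ids <- names(truth)
  pieces <- list()
  for (m in names(predsByModelFold)) {
    for (b in names(predsByModelFold[[m]])) {
      for (sp in splits) {
        pieces[[length(pieces) + 1L]] <- data.frame(
          model_id = m, fold_id = as.integer(b), split = sp,
          sample_id = ids, patient_id = ids,
          predicted_label = as.integer(predsByModelFold[[m]][[b]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  PredictionTable(do.call(rbind, pieces), truth)
}

# Clinical cohort reproducing the printed characteristics table of the
# 191-patient NSCLC cohort exactly (counts per category, missing counts,
# median-split counts for the numeric features).
printedCohortTable <- function() {
  n <- 191L
  cat_vec <- function(counts, nMissing = 0L)
    c(rep(names(counts), counts), rep(NA_character_, nMissing))
  data.frame(
    patient_id = sprintf("p%03d", seq_len(n)),
    age = c(rep(60, 82), rep(80, 83), rep(NA_real_, 26)),
    ctv = c(rep(100, 77), rep(200, 77), rep(NA_real_, 37)),
    sex = cat_vec(c(male = 133, female = 58)),
    histology = cat_vec(c(adenocarcinoma = 95, squamous = 59, other = 11,
                          unknown = 26)),
    stage = cat_vec(c(II = 4, III = 160, IV = 27)),
    t_stage = cat_vec(c(T0 = 1, T1 = 9, T2 = 32, T3 = 65, T4 = 48), 36L),
    n_stage = cat_vec(c(N0 = 15, N1 = 33, N2 = 93, N2_recurrence = 6,
                        N3 = 18), 26L),
    stringsAsFactors = FALSE)
}

summaryPercent <- function(summ, feature, category) {
  row <- summ[summ$feature == feature & summ$category == category, ]
  stopifnot(nrow(row) == 1L)
  row$percent
}

# Small random selection instance for oracle-equivalence checks: pool of
# nCl clinical + nIm imaging synthetic models with mixed redundancy.
randomSelectionInstance <- function(seed, nPatients = 50L, nFolds = 2L) {
  set.seed(seed)
  nCl <- sample(1:3, 1L)
  nIm <- sample(1:5, 1L)
  if (nCl + nIm < 3L) nIm <- 3L - nCl + nIm
  ids <- sprintf("pt%03d", seq_len(nPatients))
  truth <- stats::setNames(sample(rep_len(0:1, nPatients)), ids)
  mkSpec <- function(id, modality) {
    grp <- if (stats::runif(1) < 0.25) sample(c("g1", "g2"), 1L)
           else NA_character_
    syntheticModelSpec(id, modality,
                       granularity = if (modality == "clinical") "patient"
                                     else sample(c("patient", "slice"), 1L),
                       target_accuracy = stats::runif(1, 0.55, 0.9),
                       difficulty_weight = stats::runif(1, 0, 1),
                       flip_group = grp)
  }
  specs <- c(lapply(sprintf("cl%d", seq_len(nCl)), mkSpec,
                    modality = "clinical"),
             lapply(sprintf("im%d", seq_len(nIm)), mkSpec,
                    modality = "imaging"))
  # flip groups must not mix granularities; regroup by granularity label
  for (i in seq_along(specs)) {
    if (!is.na(specs[[i]]$flip_group))
      specs[[i]]$flip_group <- paste0(specs[[i]]$flip_group, "_",
                                      specs[[i]]$granularity)
  }
  table <- simulatePredictions(specs, truth, folds = nFolds,
                               slicesPerPatient = c(1L, 3L),
                               seed = seed + 1L)
  registry <- ModelRegistry(
    vapply(specs, `[[`, character(1L), "model_id"),
    vapply(specs, `[[`, character(1L), "modality"),
    vapply(specs, `[[`, character(1L), "granularity"))
  maxSize <- if (nCl + nIm >= 5L && stats::runif(1) < 0.3) 5L else 3L
  list(table = table, registry = registry, maxSize = maxSize,
       foldIds = seq_len(nFolds) - 1L)
}

keyOf <- function(ids) paste(sort(ids), collapse = ";")
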