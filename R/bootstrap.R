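#' @include selector.R
NULL

# Split sizes for one stratum by cumulative flooring: train gets
# floor(f_train * n), later splits absorb the rounding remainders so that
# every split stays within one patient of its exact proportion.
.splitSizes <- function(n, fractions) {
  cuts <- floor(cumsum(fractions) * n + 1e-9)
  sizes <- diff(c(0L, cuts))
  names(sizes) <- names(fractions)
  sizes
}

#' Generate repeated random patient-grouped splits
#'
#' The evaluation protocol: `nReps` independent random partitions of the
#' patients into train/validation/test at the given proportions (default
#' 80/10/10). Partitions are drawn by subsampling without replacement —
#' repeated Monte-Carlo splitting, the resampling scheme compatible with
#' disjoint fixed proportions. When `stratify` is on (default), the split is
#' drawn within each prognosis class, preserving the class ratio of the
#' near-balanced cohort within one patient per split. Splits operate on
#' patients only; slice-level predictions inherit their patient's split, so
#' slices of one patient never straddle sets.
#'
#' @param patientIds character vector of patient identifiers.
#' @param patientLabels 0/1 labels aligned with `patientIds` (required when
#'   `stratify = TRUE`).
#' @param nReps number of random extractions (default 5).
#' @param fractions train/val/test proportions summing to 1.
#' @param seed integer seed; the same seed reproduces the same assignments.
#' @param stratify draw within prognosis classes (default `TRUE`).
#' @return list of `nReps` [FoldAssignment-class] objects with fold ids
#'   `0 .. nReps - 1`.
#' @examples
#' folds <- makeBootstrapSplits(sprintf("p%02d", 1:100),
#'                              rep(c(0, 1), 50), nReps = 2, seed = 7)
#' table(splitAssignment(folds[[1]]))
#' @export
makeBootstrapSplits <- function(patientIds, patientLabels = NULL, nReps = 5L,
                                fractions = c(train = 0.8, val = 0.1,
                                              test = 0.1),
                                seed = 1L, stratify = TRUE) {
  if (anyDuplicated(patientIds)) stop("patientIds must be unique")
  if (length(fractions) != 3L || !isTRUE(all.equal(sum(fractions), 1)))
    stop("fractions must be three proportions summing to 1")
  names(fractions) <- .SPLITS
  if (stratify) {
    if (is.null(patientLabels) || length(patientLabels) != length(patientIds))
      stop("stratified splits need one label per patient")
    strata <- split(as.character(patientIds), patientLabels)
  } else {
    strata <- list(all = as.character(patientIds))
  }
  nonzero <- sum(fractions > 0)
  for (s in names(strata))
    if (length(strata[[s]]) < nonzero)
      stop(sprintf("stratum '%s' has too few patients (%d) for %d splits",
                   s, length(strata[[s]]), nonzero))
  withSeed(seed, {
    lapply(seq_len(nReps) - 1L, function(b) {
      assignment <- character(0)
      for (s in names(strata)) {
        ids <- sample(strata[[s]])
        sizes <- .splitSizes(length(ids), fractions)
        lab <- rep(names(sizes), sizes)
        assignment <- c(assignment, stats::setNames(lab, ids))
      }
      FoldAssignment(b, assignment[order(names(assignment))], seed = seed)
    })
  })
}

#' Test-set performance of a model or ensemble
#'
#' Evaluates a subject — a single model id or a member set — on the test
#' split of every fold at patient level (slice predictions are first
#' reduced by per-patient majority vote, ensembles then vote across
#' members), and reports accuracy, F-score and recall as across-fold mean
#' and sample standard deviation, in percent.
#'
#' @param subject single model id or character vector of member ids.
#' @param table a [PredictionTable-class].
#' @param foldIds folds to evaluate on; defaults to all folds in `table`.
#' @param config a [VoteConfig-class].
#' @return data.frame with columns `metric`, `mean`, `sd` (percent scale).
#' @export
evaluateOnTests <- function(subject, table, foldIds = NULL,
                            config = VoteConfig()) {
  foldIds <- foldIds %||% foldIds(table)
  if (!length(foldIds)) stop("no folds to evaluate on")
  per <- vapply(foldIds, function(b)
    .testMetricsFold(table, subject, b, config), numeric(3L))
  per <- per * 100
  data.frame(metric = rownames(per),
             mean = apply(per, 1L, mean),
             sd = apply(per, 1L, sdOrZero),
             row.names = NULL, stringsAsFactors = FALSE)
}

.reportRow <- function(name, modality, members, metrics) {
  g <- function(m, col) metrics[[col]][metrics$metric == m]
  data.frame(name = name, modality = modality, members = members,
             accuracy_mean = g("accuracy", "mean"),
             accuracy_sd = g("accuracy", "sd"),
             f_score_mean = g("f_score", "mean"),
             f_score_sd = g("f_score", "sd"),
             recall_mean = g("recall", "mean"),
             recall_sd = g("recall", "sd"),
             stringsAsFactors = FALSE)
}

#' Build the full evaluation report
#'
#' Renders the standard results layout: one row per unimodal model, then the
#' selected optimum `E_star`, the single-objective baselines `E_R` and
#' `E_K`, the all-ensembles average `E_mean_all`, the a-posteriori top-3
#' recall ensemble `E_post3`, the anchored-pair average `E_post2_star_mean`
#' (ensembles containing the per-modality a-posteriori recall leaders) and
#' the relaxed-constraint optimum `E_relaxed`. All metrics are test-set
#' mean +/- sd in percent, rounded to two decimals (half-up); the best
#' unimodal row of each modality (by mean accuracy) is flagged.
#'
#' @param registry a [ModelRegistry-class].
#' @param table a [PredictionTable-class].
#' @param foldIds folds; defaults to all folds in `table`.
#' @param selection a [SelectionResult-class] from [selectOptimal()];
#'   computed on the fly when `NULL`.
#' @param config a [VoteConfig-class].
#' @param maxSize search cap used for the averaged baselines (and for the
#'   on-the-fly selection).
#' @return data.frame (one row per model/ensemble) with attributes
#'   `n_folds` and `tie_policy`.
#' @export
buildReport <- function(registry, table, foldIds = NULL, selection = NULL,
                        config = VoteConfig(), maxSize = 3L) {
  foldIds <- foldIds %||% foldIds(table)
  if (is.null(selection))
    selection <- selectOptimal(registry, table, foldIds, maxSize, config)
  ids <- sort(modelIds(registry))
  clin <- clinicalModels(registry)
  rows <- lapply(ids, function(m)
    .reportRow(m, if (m %in% clin) "clinical" else "imaging", m,
               evaluateOnTests(m, table, foldIds, config)))
  ensembleRow <- function(name, cand)
    .reportRow(name, "multimodal", memberKey(cand@memberIds),
               evaluateOnTests(cand@memberIds, table, foldIds, config))
  bl <- baselineEnsembles(selection)
  rows <- c(rows, list(
    ensembleRow("E_star", optimalEnsemble(selection)),
    ensembleRow("E_R", bl$E_R),
    ensembleRow("E_K", bl$E_K)))
  candSets <- lapply(candidateTable(selection)$members,
                     function(s) strsplit(s, ";", fixed = TRUE)[[1L]])
  avg <- baselineMeanAll(candSets, table, foldIds, config)
  rows <- c(rows, list(.reportRow("E_mean_all", "multimodal", "*", avg)))
  post3 <- baselinePosthocTopK(table, foldIds, 3L, config, registry)
  rows <- c(rows, list(ensembleRow("E_post3", post3)))
  # anchors: the a-posteriori recall leader of each modality
  recallOf <- function(m) .testMetricsMean(table, m, foldIds, config)[["recall"]]
  bestBy <- function(pool) pool[order(-vapply(pool, recallOf, numeric(1L)),
                                      pool)][1L]
  anchors <- c(bestBy(sort(clin)), bestBy(sort(imagingModels(registry))))
  pairAvg <- tryCatch(
    baselinePosthocPairAverage(anchors, candSets, table, foldIds, config),
    error = function(e) NULL)
  if (!is.null(pairAvg))
    rows <- c(rows, list(.reportRow("E_post2_star_mean", "multimodal",
                                    paste0(memberKey(anchors), ";*"), pairAvg)))
  rows <- c(rows, list(ensembleRow("E_relaxed", bl$E_relaxed)))
  out <- do.call(rbind, rows)
  num <- grep("_(mean|sd)$", names(out))
  out[num] <- lapply(out[num], roundHalfUp, digits = 2L)
  out$best_in_modality <- FALSE
  for (mod in c("clinical", "imaging")) {
    i <- which(out$modality == mod)
    if (length(i))
      out$best_in_modality[i[which.max(out$accuracy_mean[i])]] <- TRUE
  }
  rownames(out) <- NULL
  attr(out, "n_folds") <- length(foldIds)
  attr(out, "tie_policy") <- config@tiePolicy
  out
}

#' Read and write evaluation reports
#'
#' The report round-trips through a structured-record JSON file preserving
#' the `n_folds` and `tie_policy` attributes; `writeEvaluationReport` can
#' also emit plain CSV (by `.csv` extension) for spreadsheet use.
#'
#' @param report data.frame from [buildReport()].
#' @param path output path (`.json` or `.csv`).
#' @return `readEvaluationReport` returns the report data.frame with its
#'   attributes restored.
#' @export
writeEvaluationReport <- function(report, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(report, path, row.names = FALSE)
  } else {
    doc <- list(n_folds = attr(report, "n_folds"),
                tie_policy = attr(report, "tie_policy"),
                rows = report)
    jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname writeEvaluationReport
#' @export
readEvaluationReport <- function(path) {
  doc <- jsonlite::fromJSON(path)
  out <- as.data.frame(doc$rows, stringsAsFactors = FALSE)
  attr(out, "n_folds") <- doc$n_folds
  attr(out, "tie_policy") <- doc$tie_policy
  out
}
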