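#' @include voting.R
NULL

#' Enumerate feasible candidate ensembles
#'
#' Lists every model subset satisfying the selection constraints: more than
#' one member, an odd member count (so the across-model majority vote can
#' never tie), at most `maxSize` members and — unless
#' `requireMultimodal = FALSE` — at least one clinical and one imaging
#' member. The enumeration is deterministic: subsets are ordered by size,
#' then lexicographically by their sorted member tuple.
#'
#' `maxSize` caps the exhaustive search. The default of 3 reflects the
#' practical regime of late-fusion pools with tens of models, where full
#' exhaustion over all odd subsets is combinatorially explosive while the
#' selected ensembles are small; with a small pool the cap can be raised to
#' perform true exhaustion.
#'
#' @param registry a [ModelRegistry-class].
#' @param maxSize odd integer >= 3, the largest ensemble size searched.
#' @param requireMultimodal enforce the one-model-per-modality floors
#'   (default `TRUE`).
#' @return list of character vectors (sorted member ids).
#' @examples
#' reg <- ModelRegistry(c("c1", "i1", "i2"), c("clinical", "imaging", "imaging"))
#' enumerateFeasible(reg)
#' @export
enumerateFeasible <- function(registry, maxSize = 3L,
                              requireMultimodal = TRUE) {
  stopifnot(methods::is(registry, "ModelRegistry"))
  maxSize <- as.integer(maxSize)
  if (maxSize < 3L || maxSize %% 2L == 0L)
    stop("maxSize must be an odd integer >= 3")
  clin <- clinicalModels(registry)
  imag <- imagingModels(registry)
  if (requireMultimodal && (!length(clin) || !length(imag)))
    stop("multimodal selection needs at least one model per modality")
  ids <- sort(modelIds(registry))
  out <- list()
  for (s in seq(3L, min(maxSize, length(ids)), by = 2L)) {
    sets <- utils::combn(ids, s, simplify = FALSE)
    if (requireMultimodal)
      sets <- Filter(function(x) any(x %in% clin) && any(x %in% imag), sets)
    out <- c(out, sets)
  }
  out
}

#' The two-term selection objective
#'
#' `(1 - rBar)^2 + (1 - kBar)^2`: squared distance of an ensemble's
#' fold-averaged recall and diversity from the ideal point (1, 1). Smaller
#' is better; 0 means a perfectly sensitive and perfectly diverse ensemble.
#' Because the pairwise kappa diversity can exceed 1 (anti-correlated
#' members), the diversity term also penalises over-diverse ensembles — a
#' direct consequence of the squared form.
#'
#' @param rBar,kBar fold-averaged recall and diversity.
#' @return the objective value.
#' @examples
#' selectionObjective(0.8, 0.9)
#' @export
selectionObjective <- function(rBar, kBar) (1 - rBar)^2 + (1 - kBar)^2

# Per-fold recall and ensemble diversity of a member subset given the
# patient-level validation matrix `mat` (patients x members) and aligned
# truth. Odd member counts cannot tie, so the vote reduces to a row-sum
# threshold.
.scoreFromMatrix <- function(mat, truth, config) {
  size <- ncol(mat)
  pred <- as.integer(2L * rowSums(mat) > size)
  pos <- truth == config@positiveLabel
  if (!any(pos))
    stop("recall is undefined: no positive patients in the validation split")
  r <- sum(pred == truth & pos) / sum(pos)
  correct <- mat == truth
  ks <- numeric(0)
  for (i in seq_len(size - 1L)) {
    for (j in seq.int(i + 1L, size)) {
      a <- correct[, i]; b <- correct[, j]
      ct <- c(n11 = sum(a & b), n10 = sum(a & !b),
              n01 = sum(!a & b), n00 = sum(!a & !b))
      ks <- c(ks, kappaDiversity(ct))
    }
  }
  c(r = r, k = mean(ks))
}

#' Score a candidate ensemble on the validation folds
#'
#' For every fold, the ensemble's majority-vote recall and its mean pairwise
#' kappa diversity are computed on the patient-level validation predictions;
#' the across-fold means (`r_bar`, `k_bar`) are returned. These are the two
#' quantities the selection objective combines. A fold whose validation
#' split holds no positive patient makes recall undefined and raises an
#' error.
#'
#' @param memberIds at least two member model ids.
#' @param table a [PredictionTable-class].
#' @param foldIds folds to average over; defaults to all folds in `table`.
#' @param config a [VoteConfig-class].
#' @return named numeric `c(r_bar, k_bar)`.
#' @export
scoreCandidate <- function(memberIds, table, foldIds = NULL,
                           config = VoteConfig()) {
  if (length(memberIds) < 2L)
    stop("a candidate ensemble needs at least two members")
  foldIds <- foldIds %||% foldIds(table)
  truth <- patientTruth(table)
  per <- vapply(foldIds, function(b) {
    mat <- patientLevelMatrix(table, sort(memberIds), b, "val", config)
    .scoreFromMatrix(mat, truth[rownames(mat)], config)
  }, numeric(2L))
  c(r_bar = mean(per["r", ]), k_bar = mean(per["k", ]))
}

# Score every candidate in `candidates` (list of member-id sets) over the
# validation folds, reusing one patient-level matrix per fold.
.scoreAllCandidates <- function(registry, table, foldIds, config, candidates) {
  truth <- patientTruth(table)
  ids <- sort(modelIds(registry))
  mats <- lapply(foldIds, function(b) {
    mat <- patientLevelMatrix(table, ids, b, "val", config)
    list(mat = mat, truth = truth[rownames(mat)])
  })
  clin <- clinicalModels(registry)
  n <- length(candidates)
  rbar <- kbar <- numeric(n)
  ncl <- nim <- integer(n)
  keys <- character(n)
  for (i in seq_len(n)) {
    mem <- candidates[[i]]
    per <- vapply(mats, function(fm)
      .scoreFromMatrix(fm$mat[, mem, drop = FALSE], fm$truth, config),
      numeric(2L))
    rbar[i] <- mean(per["r", ])
    kbar[i] <- mean(per["k", ])
    ncl[i] <- sum(mem %in% clin)
    nim[i] <- length(mem) - ncl[i]
    keys[i] <- memberKey(mem)
  }
  data.frame(members = keys,
             size = lengths(candidates),
             n_clinical = ncl, n_imaging = nim,
             r_bar = rbar, k_bar = kbar,
             objective = selectionObjective(rbar, kbar),
             stringsAsFactors = FALSE)
}

# Deterministic tie-break ordering: best score first, then smaller size,
# then lexicographic member tuple. The score is rounded to 10 significant
# digits first so that mathematically equal scores reached through
# different floating-point paths still fall to the documented tie-break.
.rankCandidates <- function(df, score)
  order(signif(score, 10L), df$size, df$members)

.candidateFromRow <- function(df, i) {
  methods::new("EnsembleCandidate",
               memberIds = strsplit(df$members[i], ";", fixed = TRUE)[[1L]],
               nClinical = as.integer(df$n_clinical[i]),
               nImaging = as.integer(df$n_imaging[i]),
               rBar = df$r_bar[i], kBar = df$k_bar[i],
               objectiveValue = df$objective[i])
}

#' Pareto front of scored candidates
#'
#' Returns the candidates not dominated in the two selection scores.
#' Dominance is measured towards the ideal point (1, 1): candidate A
#' dominates B when A is at least as close to 1 in both `|1 - r_bar|` and
#' `|1 - k_bar|` and strictly closer in one. For diversities below 1 this
#' coincides with plain maximisation of (r_bar, k_bar); phrasing it through
#' the ideal point keeps the front consistent with the squared-distance
#' objective when kappa diversity exceeds 1, so the selected optimum always
#' lies on the front.
#'
#' @param object a data.frame with columns `r_bar` and `k_bar` (e.g. the
#'   candidate table of a [SelectionResult-class]), or a
#'   [SelectionResult-class] whose stored front is returned.
#' @return the non-dominated rows of the candidate table.
#' @export
setMethod("paretoFront", "data.frame", function(object) {
  if (!nrow(object)) stop("empty candidate list")
  dr <- abs(1 - object$r_bar)
  dk <- abs(1 - object$k_bar)
  n <- nrow(object)
  keep <- vapply(seq_len(n), function(i) {
    dom <- dr <= dr[i] & dk <= dk[i] & (dr < dr[i] | dk < dk[i])
    !any(dom)
  }, logical(1L))
  object[keep, , drop = FALSE]
})

#' @rdname paretoFront
#' @export
setMethod("paretoFront", "SelectionResult", function(object) object@paretoFront)

#' Exhaustive multimodal ensemble selection
#'
#' The core search: every feasible candidate ensemble (odd size between 3
#' and `maxSize`, at least one model per modality) is scored by its
#' fold-averaged validation recall `r_bar` and kappa diversity `k_bar`, and
#' the ensemble minimising [selectionObjective()] is returned as the
#' optimum. Ties are broken deterministically: smaller ensembles first, then
#' the lexicographically smallest member tuple. The result also carries the
#' full scored candidate table, the Pareto front, and the validation-based
#' baselines: the single-objective maximisers `E_R` and `E_K` and the
#' optimum `E_relaxed` obtained when the multimodality floors are dropped.
#'
#' @param registry a [ModelRegistry-class].
#' @param table a [PredictionTable-class] with validation predictions for
#'   every model and fold.
#' @param foldIds folds to average over; defaults to all folds in `table`.
#' @param maxSize odd integer >= 3; see [enumerateFeasible()].
#' @param config a [VoteConfig-class].
#' @return a [SelectionResult-class].
#' @examples
#' sc <- plantedOptimumScenario(60, seed = 1, nFolds = 2)
#' res <- selectOptimal(sc$registry, sc$table)
#' memberIds(optimalEnsemble(res))
#' @export
selectOptimal <- function(registry, table, foldIds = NULL, maxSize = 3L,
                          config = VoteConfig()) {
  foldIds <- foldIds %||% foldIds(table)
  relaxedSets <- enumerateFeasible(registry, maxSize, requireMultimodal = FALSE)
  # enforce floors on the superset afterwards, so the relaxed baseline
  # reuses the same scored table
  clin <- clinicalModels(registry)
  imag <- imagingModels(registry)
  if (!length(clin) || !length(imag))
    stop("multimodal selection needs at least one model per modality")
  scored <- .scoreAllCandidates(registry, table, foldIds, config, relaxedSets)
  multimodal <- scored$n_clinical >= 1L & scored$n_imaging >= 1L
  feas <- scored[multimodal, , drop = FALSE]
  if (!nrow(feas)) stop("no feasible multimodal candidate")
  rownames(feas) <- NULL
  ordObj <- .rankCandidates(feas, feas$objective)
  optimal <- .candidateFromRow(feas, ordObj[1L])
  baselines <- list(
    E_R = .candidateFromRow(feas, .rankCandidates(feas, -feas$r_bar)[1L]),
    E_K = .candidateFromRow(feas, .rankCandidates(feas, -feas$k_bar)[1L]),
    E_relaxed = .candidateFromRow(scored,
                                  .rankCandidates(scored, scored$objective)[1L]))
  methods::new("SelectionResult",
               optimal = optimal,
               candidates = feas,
               paretoFront = paretoFront(feas),
               baselines = baselines,
               searchConfig = list(maxSize = as.integer(maxSize),
                                   foldIds = foldIds,
                                   tiePolicy = config@tiePolicy,
                                   positiveLabel = config@positiveLabel,
                                   requireMultimodal = TRUE))
}

#' Single-objective and relaxed baseline selections
#'
#' `selectSingleObjective` returns the feasible candidate maximising the
#' fold-averaged recall alone (`which = "R"`) or the diversity alone
#' (`which = "K"`), with the same deterministic tie-break as
#' [selectOptimal()]. `selectRelaxed` minimises the full objective but drops
#' the one-model-per-modality floors, keeping only the odd-size constraint —
#' the ensemble obtained when multimodality is not enforced.
#'
#' @param which `"R"` or `"K"`.
#' @inheritParams selectOptimal
#' @return an [EnsembleCandidate-class].
#' @export
selectSingleObjective <- function(which = c("R", "K"), registry, table,
                                  foldIds = NULL, maxSize = 3L,
                                  config = VoteConfig()) {
  which <- match.arg(which)
  foldIds <- foldIds %||% foldIds(table)
  sets <- enumerateFeasible(registry, maxSize, requireMultimodal = TRUE)
  scored <- .scoreAllCandidates(registry, table, foldIds, config, sets)
  score <- if (which == "R") -scored$r_bar else -scored$k_bar
  .candidateFromRow(scored, .rankCandidates(scored, score)[1L])
}

#' @rdname selectSingleObjective
#' @export
selectRelaxed <- function(registry, table, foldIds = NULL, maxSize = 3L,
                          config = VoteConfig()) {
  foldIds <- foldIds %||% foldIds(table)
  sets <- enumerateFeasible(registry, maxSize, requireMultimodal = FALSE)
  scored <- .scoreAllCandidates(registry, table, foldIds, config, sets)
  .candidateFromRow(scored, .rankCandidates(scored, scored$objective)[1L])
}

# Accuracy / F-score / recall of a member set on the test split of one fold.
.testMetricsFold <- function(table, memberIds, foldId, config) {
  pred <- ensemblePredict(table, memberIds, foldId, "test", config)
  truth <- patientTruth(table)[names(pred)]
  cc <- confusionCounts(pred, truth, config@positiveLabel)
  c(accuracy = accuracyScore(cc), f_score = fScore(cc),
    recall = recallScore(cc))
}

# Fold-mean test metrics of one subject (model id or member set), percent.
.testMetricsMean <- function(table, memberIds, foldIds, config) {
  per <- vapply(foldIds, function(b)
    .testMetricsFold(table, memberIds, b, config), numeric(3L))
  rowMeans(per) * 100
}

#' Average test performance over all feasible ensembles
#'
#' Evaluates every candidate ensemble on the test splits of all folds and
#' reports, for accuracy, F-score and recall, the mean and sample standard
#' deviation across candidates of the per-candidate fold-mean metric (in
#' percent). This is the all-ensembles average baseline against which the
#' selected optimum is compared.
#'
#' @param candidates list of member-id sets; defaults to
#'   [enumerateFeasible()] on `registry`.
#' @param table a [PredictionTable-class].
#' @param foldIds folds to evaluate on; defaults to all.
#' @param config a [VoteConfig-class].
#' @param registry used only to enumerate when `candidates` is `NULL`.
#' @param maxSize passed to the default enumeration.
#' @return data.frame with columns `metric`, `mean`, `sd` (percent).
#' @export
baselineMeanAll <- function(candidates = NULL, table, foldIds = NULL,
                            config = VoteConfig(), registry = NULL,
                            maxSize = 3L) {
  foldIds <- foldIds %||% foldIds(table)
  if (is.null(candidates)) {
    if (is.null(registry))
      stop("either candidates or a registry must be supplied")
    candidates <- enumerateFeasible(registry, maxSize)
  }
  if (!length(candidates)) stop("no candidates to average over")
  per <- vapply(candidates, function(mem)
    .testMetricsMean(table, mem, foldIds, config), numeric(3L))
  data.frame(metric = rownames(per),
             mean = apply(per, 1L, mean),
             sd = apply(per, 1L, sdOrZero),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' A-posteriori top-k recall ensemble
#'
#' Builds the ensemble of the `k` unimodal models with the largest mean
#' *test* recall at patient level — an a-posteriori construction that peeks
#' at the test sets, used as a comparison point for the validation-driven
#' selection. Ties at rank `k` are broken towards the lexicographically
#' smaller model id. The returned candidate carries the usual validation
#' scores so it can sit in the same report as the selected optimum.
#'
#' @param table a [PredictionTable-class].
#' @param foldIds folds; defaults to all.
#' @param k ensemble size (default 3).
#' @param config a [VoteConfig-class].
#' @param registry a [ModelRegistry-class] (modality bookkeeping).
#' @return an [EnsembleCandidate-class].
#' @export
baselinePosthocTopK <- function(table, foldIds = NULL, k = 3L,
                                config = VoteConfig(), registry) {
  foldIds <- foldIds %||% foldIds(table)
  ids <- sort(modelIds(registry))
  if (length(ids) < k)
    stop(sprintf("need at least %d models, registry has %d", k, length(ids)))
  rec <- vapply(ids, function(m)
    .testMetricsMean(table, m, foldIds, config)[["recall"]], numeric(1L))
  top <- ids[order(-rec, ids)][seq_len(k)]
  sc <- scoreCandidate(top, table, foldIds, config)
  clin <- clinicalModels(registry)
  methods::new("EnsembleCandidate", memberIds = sort(top),
               nClinical = sum(top %in% clin),
               nImaging = sum(!top %in% clin),
               rBar = sc[["r_bar"]], kBar = sc[["k_bar"]],
               objectiveValue = selectionObjective(sc[["r_bar"]], sc[["k_bar"]]))
}

#' Average test performance of ensembles anchored on two models
#'
#' Averages the test metrics of every feasible candidate that contains both
#' anchor models (typically the two unimodal classifiers with the largest
#' a-posteriori recall), varying the remaining members. Reported like
#' [baselineMeanAll()].
#'
#' @param anchors two model ids that every averaged ensemble must contain.
#' @param candidates list of member-id sets to filter; defaults to
#'   [enumerateFeasible()] on `registry`.
#' @inheritParams baselineMeanAll
#' @return data.frame with columns `metric`, `mean`, `sd` (percent).
#' @export
baselinePosthocPairAverage <- function(anchors, candidates = NULL, table,
                                       foldIds = NULL, config = VoteConfig(),
                                       registry = NULL, maxSize = 3L) {
  if (length(anchors) != 2L) stop("exactly two anchor models are required")
  if (is.null(candidates)) {
    if (is.null(registry))
      stop("either candidates or a registry must be supplied")
    candidates <- enumerateFeasible(registry, maxSize)
  }
  keep <- Filter(function(mem) all(anchors %in% mem), candidates)
  if (!length(keep))
    stop(sprintf("no feasible candidate contains both anchors: %s",
                 paste(anchors, collapse = ", ")))
  baselineMeanAll(keep, table, foldIds, config)
}

#' @rdname accessors
#' @export
setMethod("memberIds", "EnsembleCandidate", function(object) object@memberIds)

#' @rdname accessors
#' @export
setMethod("rBar", "EnsembleCandidate", function(object) object@rBar)

#' @rdname accessors
#' @export
setMethod("kBar", "EnsembleCandidate", function(object) object@kBar)

#' @rdname accessors
#' @export
setMethod("objectiveValue", "EnsembleCandidate",
          function(object) object@objectiveValue)

#' @rdname accessors
#' @export
setMethod("optimalEnsemble", "SelectionResult", function(object) object@optimal)

#' @rdname accessors
#' @export
setMethod("candidateTable", "SelectionResult", function(object) object@candidates)

#' @rdname accessors
#' @export
setMethod("baselineEnsembles", "SelectionResult",
          function(object) object@baselines)

setMethod("show", "EnsembleCandidate", function(object) {
  cat(sprintf("EnsembleCandidate {%s} | %d clinical + %d imaging\n",
              paste(object@memberIds, collapse = ", "),
              object@nClinical, object@nImaging))
  cat(sprintf("  r_bar = %.4f, k_bar = %.4f, objective = %.4f\n",
              object@rBar, object@kBar, object@objectiveValue))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d feasible candidates (max size %d), %d on the Pareto front\n",
              nrow(object@candidates), object@searchConfig$maxSize,
              nrow(object@paretoFront)))
  cat("Optimal ensemble E*:\n")
  methods::show(object@optimal)
})

#' Serialise a selection result
#'
#' Writes the selection report (optimal ensemble, full candidate table,
#' Pareto front, validation baselines, search configuration) as a single
#' structured-record JSON document.
#'
#' @param result a [SelectionResult-class].
#' @param path output JSON path.
#' @return `invisible(path)`.
#' @export
writeSelectionResult <- function(result, path) {
  stopifnot(methods::is(result, "SelectionResult"))
  candList <- function(x)
    list(members = x@memberIds, n_clinical = x@nClinical,
         n_imaging = x@nImaging, r_bar = x@rBar, k_bar = x@kBar,
         objective = x@objectiveValue)
  doc <- list(optimal = candList(result@optimal),
              baselines = lapply(result@baselines, candList),
              candidates = result@candidates,
              pareto_front = result@paretoFront,
              search_config = result@searchConfig)
  jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
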