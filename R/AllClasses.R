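#' @import methods
NULL

.MODALITIES <- c("clinical", "imaging")
.GRANULARITIES <- c("patient", "slice")
.SPLITS <- c("train", "val", "test")
.TIE_POLICIES <- c("positive", "negative", "error")

#' Catalogue of unimodal models
#'
#' A `ModelRegistry` lists the pool of trained unimodal models from which
#' ensembles are built. Each entry carries a unique `model_id`, the modality
#' the model consumes (`clinical` tabular data or `imaging` CT slices) and
#' its prediction granularity: clinical learners emit one label per patient,
#' imaging networks one label per CT slice (later reduced to patient level
#' by majority vote).
#'
#' @slot entries data.frame with columns `model_id`, `modality`,
#'   `granularity`.
#'
#' @seealso [ModelRegistry()] for construction, [enumerateFeasible()] for the
#'   candidate ensembles a registry induces.
#' @export
setClass("ModelRegistry", representation(entries = "data.frame"))

setValidity("ModelRegistry", function(object) {
  e <- object@entries
  msgs <- character()
  need <- c("model_id", "modality", "granularity")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (nrow(e) == 0L) msgs <- c(msgs, "registry must contain at least one model")
  if (anyDuplicated(e$model_id))
    msgs <- c(msgs, "model_id values must be unique")
  if (!all(e$modality %in% .MODALITIES))
    msgs <- c(msgs, sprintf("modality must be one of: %s",
                            paste(.MODALITIES, collapse = ", ")))
  if (!all(e$granularity %in% .GRANULARITIES))
    msgs <- c(msgs, sprintf("granularity must be one of: %s",
                            paste(.GRANULARITIES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Binary predictions of many models over bootstrap folds
#'
#' A `PredictionTable` stores one binary predicted label per
#' (model, fold, split, sample). Samples of a patient-granularity model are
#' patients (`sample_id == patient_id`); samples of a slice-granularity model
#' are CT slices carrying their patient's identifier. The ground-truth
#' prognosis class is stored once per patient: slices inherit their patient's
#' label, since the task is a patient-level overall-survival class.
#'
#' @slot records data.frame with columns `model_id` (character), `fold_id`
#'   (integer, 0-based), `split` (`train`/`val`/`test`), `sample_id`
#'   (character), `patient_id` (character), `predicted_label` (0/1 integer).
#' @slot truth named integer vector of 0/1 patient labels; 1 marks the
#'   positive (short-survival) class.
#'
#' @seealso [PredictionTable()], [readPredictionTable()],
#'   [subsetPredictions()].
#' @export
setClass("PredictionTable",
         representation(records = "data.frame", truth = "integer"))

setValidity("PredictionTable", function(object) {
  r <- object@records
  tr <- object@truth
  msgs <- character()
  need <- c("model_id", "fold_id", "split", "sample_id", "patient_id",
            "predicted_label")
  if (!all(need %in% names(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (nrow(r)) {
    if (!all(r$predicted_label %in% c(0L, 1L)))
      msgs <- c(msgs, "predicted_label must be strictly binary (0/1)")
    if (!all(r$split %in% .SPLITS))
      msgs <- c(msgs, sprintf("split must be one of: %s",
                              paste(.SPLITS, collapse = ", ")))
    key <- paste(r$model_id, r$fold_id, r$split, r$sample_id, sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, "(model_id, fold_id, split, sample_id) must be unique")
    miss <- setdiff(unique(r$patient_id), names(tr))
    if (length(miss))
      msgs <- c(msgs, sprintf("patients without ground truth: %s",
                              paste(utils::head(miss, 5L), collapse = ", ")))
  }
  if (length(tr)) {
    if (is.null(names(tr)) || anyDuplicated(names(tr)) || any(names(tr) == ""))
      msgs <- c(msgs, "truth must be uniquely named by patient_id")
    if (!all(tr %in% c(0L, 1L)))
      msgs <- c(msgs, "truth labels must be strictly binary (0/1)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Patient-to-split assignment of one bootstrap fold
#'
#' One replicate of the repeated random patient-grouped split protocol:
#' every patient is assigned to exactly one of train/validation/test; all CT
#' slices of a patient follow the patient, so no information leaks across
#' splits.
#'
#' @slot foldId integer fold index (0-based).
#' @slot assignment named character vector patient_id -> split.
#' @slot seed integer seed the assignment was drawn from.
#'
#' @seealso [makeBootstrapSplits()].
#' @export
setClass("FoldAssignment",
         representation(foldId = "integer", assignment = "character",
                        seed = "integer"))

setValidity("FoldAssignment", function(object) {
  a <- object@assignment
  msgs <- character()
  if (length(object@foldId) != 1L || is.na(object@foldId) || object@foldId < 0L)
    msgs <- c(msgs, "foldId must be a single non-negative integer")
  if (!length(a) || is.null(names(a)) || anyDuplicated(names(a)))
    msgs <- c(msgs, "assignment must be uniquely named by patient_id")
  if (!all(a %in% .SPLITS))
    msgs <- c(msgs, sprintf("splits must be one of: %s",
                            paste(.SPLITS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Majority-vote configuration
#'
#' Fixes how exact ties are resolved when an even number of votes is split
#' half-and-half, and which label is the positive (short-survival) class.
#' Across-model votes never tie because candidate ensembles are constrained
#' to odd sizes, but the slice counts of a patient may be even; the default
#' resolves slice ties in favour of the positive class, consistent with the
#' recall-driven selection objective.
#'
#' @slot tiePolicy one of `"positive"`, `"negative"`, `"error"`.
#' @slot positiveLabel integer 0 or 1; label of the positive class.
#'
#' @seealso [VoteConfig()], [majorityVote()].
#' @export
setClass("VoteConfig",
         representation(tiePolicy = "character", positiveLabel = "integer"))

setValidity("VoteConfig", function(object) {
  msgs <- character()
  if (length(object@tiePolicy) != 1L || !object@tiePolicy %in% .TIE_POLICIES)
    msgs <- c(msgs, sprintf("tiePolicy must be one of: %s",
                            paste(.TIE_POLICIES, collapse = ", ")))
  if (length(object@positiveLabel) != 1L ||
      !object@positiveLabel %in% c(0L, 1L))
    msgs <- c(msgs, "positiveLabel must be 0 or 1")
  if (length(msgs)) msgs else TRUE
})

#' A scored candidate ensemble
#'
#' One subset of the model pool together with its validation scores: the
#' fold-averaged majority-vote recall `rBar`, the fold-averaged ensemble
#' kappa diversity `kBar`, and the objective value
#' `(1 - rBar)^2 + (1 - kBar)^2` that the selector minimises.
#'
#' @slot memberIds character vector of member model ids (sorted).
#' @slot nClinical,nImaging integer per-modality member counts.
#' @slot rBar,kBar,objectiveValue numeric scores.
#'
#' @seealso [selectOptimal()], [scoreCandidate()], [selectionObjective()].
#' @export
setClass("EnsembleCandidate",
         representation(memberIds = "character", nClinical = "integer",
                        nImaging = "integer", rBar = "numeric",
                        kBar = "numeric", objectiveValue = "numeric"))

setValidity("EnsembleCandidate", function(object) {
  msgs <- character()
  if (!length(object@memberIds) || anyDuplicated(object@memberIds))
    msgs <- c(msgs, "memberIds must be non-empty and unique")
  if (length(object@memberIds) != object@nClinical + object@nImaging)
    msgs <- c(msgs, "|E| must equal |E|_Cl + |E|_Im")
  expected <- (1 - object@rBar)^2 + (1 - object@kBar)^2
  if (!isTRUE(all.equal(object@objectiveValue, expected, tolerance = 1e-8)))
    msgs <- c(msgs, "objectiveValue must equal (1 - rBar)^2 + (1 - kBar)^2")
  if (length(msgs)) msgs else TRUE
})

#' Result of an exhaustive ensemble search
#'
#' Holds the optimal ensemble (the argmin of the two-term objective over all
#' feasible candidates), the full scored candidate table, the Pareto front in
#' (recall, diversity), the validation-based baseline ensembles, and the
#' search configuration.
#'
#' @slot optimal [EnsembleCandidate-class], the selected ensemble E*.
#' @slot candidates data.frame with one row per feasible candidate: `members`
#'   (ids joined by `";"`), `size`, `n_clinical`, `n_imaging`, `r_bar`,
#'   `k_bar`, `objective`.
#' @slot paretoFront data.frame, the non-dominated subset of `candidates`.
#' @slot baselines named list of [EnsembleCandidate-class] objects; contains
#'   `E_R` and `E_K` (single-objective maximisers) and `E_relaxed` (the
#'   optimum with the multimodality constraint dropped).
#' @slot searchConfig named list (max size, folds, tie policy, positive
#'   label, whether the modality constraint was enforced).
#'
#' @seealso [selectOptimal()], [paretoFront()].
#' @export
setClass("SelectionResult",
         representation(optimal = "EnsembleCandidate",
                        candidates = "data.frame",
                        paretoFront = "data.frame",
                        baselines = "list",
                        searchConfig = "list"))

setValidity("SelectionResult", function(object) {
  msgs <- character()
  cand <- object@candidates
  need <- c("members", "size", "n_clinical", "n_imaging", "r_bar", "k_bar",
            "objective")
  if (!all(need %in% names(cand)))
    return(paste("candidates must have columns", paste(need, collapse = ", ")))
  if (nrow(cand)) {
    if (min(cand$objective) < object@optimal@objectiveValue - 1e-10)
      msgs <- c(msgs, "optimal must attain the minimum objective")
  }
  if (length(msgs)) msgs else TRUE
})
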