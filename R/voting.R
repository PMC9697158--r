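#' @include metrics.R
NULL

#' Create a vote configuration
#'
#' @param tiePolicy how an exact tie among an even number of votes is
#'   resolved: `"positive"` (default; favours sensitivity, consistent with
#'   the recall-driven selection objective), `"negative"`, or `"error"`.
#' @param positiveLabel the positive-class label, 0 or 1 (default 1, the
#'   short-survival class).
#' @return a [VoteConfig-class].
#' @export
VoteConfig <- function(tiePolicy = c("positive", "negative", "error"),
                       positiveLabel = 1L) {
  tiePolicy <- match.arg(tiePolicy)
  methods::new("VoteConfig", tiePolicy = tiePolicy,
               positiveLabel = as.integer(positiveLabel))
}

setMethod("show", "VoteConfig", function(object) {
  cat(sprintf("VoteConfig: tiePolicy = %s, positiveLabel = %d\n",
              object@tiePolicy, object@positiveLabel))
})

#' Majority vote over binary labels
#'
#' Returns the strict-majority label of a vote vector; an exact tie (only
#' possible for an even number of votes) is resolved by the configured tie
#' policy.
#'
#' @param votes non-empty 0/1 vector.
#' @param config a [VoteConfig-class].
#' @return a single 0/1 label.
#' @examples
#' majorityVote(c(1, 0, 1))
#' majorityVote(c(1, 0), VoteConfig("negative"))
#' @export
majorityVote <- function(votes, config = VoteConfig()) {
  if (!length(votes)) stop("cannot vote over an empty vote list")
  stopIfNot01(votes, "votes")
  pos <- config@positiveLabel
  neg <- 1L - pos
  nPos <- sum(votes == pos)
  nNeg <- length(votes) - nPos
  if (nPos > nNeg) return(pos)
  if (nNeg > nPos) return(neg)
  switch(config@tiePolicy,
         positive = pos,
         negative = neg,
         error = stop("exact tie in majority vote (tiePolicy = 'error')"))
}

#' Reduce one model's slice predictions to patient level
#'
#' For a slice-granularity imaging model, each patient's final label is the
#' majority vote over the labels of that patient's CT slices in the
#' requested fold and split. Patient-granularity models (one record per
#' patient) pass through unchanged, so the operation is safe to apply
#' uniformly across the model pool.
#'
#' @param table a [PredictionTable-class].
#' @param modelId single model id.
#' @param foldId single fold id.
#' @param split `"train"`, `"val"` or `"test"`.
#' @param config a [VoteConfig-class]; its tie policy resolves even slice
#'   counts.
#' @return named 0/1 integer vector, one label per patient (sorted by
#'   patient id).
#' @export
aggregateSlicesToPatient <- function(table, modelId, foldId, split,
                                     config = VoteConfig()) {
  stopifnot(methods::is(table, "PredictionTable"))
  r <- table@records
  sel <- r$model_id == modelId & r$fold_id == foldId & r$split == split
  if (!any(sel))
    stop(sprintf("no predictions for model '%s' in fold %s split '%s'",
                 modelId, foldId, split))
  rr <- r[sel, c("patient_id", "predicted_label")]
  grp <- split(rr$predicted_label, rr$patient_id)
  out <- vapply(grp, majorityVote, integer(1L), config = config)
  out[order(names(out))]
}

#' Late-fusion ensemble prediction
#'
#' Predicts patient labels for an ensemble: each member is first reduced to
#' patient level ([aggregateSlicesToPatient()]), then the members' labels
#' are combined per patient by majority vote. Every member must cover the
#' same patients in the requested fold/split. With an odd member count the
#' across-model vote can never tie, which is why candidate ensembles are
#' restricted to odd sizes.
#'
#' @param table a [PredictionTable-class].
#' @param memberIds character vector of member model ids (at least one).
#' @param foldId single fold id.
#' @param split `"train"`, `"val"` or `"test"`.
#' @param config a [VoteConfig-class].
#' @return named 0/1 integer vector of patient labels.
#' @export
ensemblePredict <- function(table, memberIds, foldId, split,
                            config = VoteConfig()) {
  if (!length(memberIds)) stop("ensemble needs at least one member")
  mat <- patientLevelMatrix(table, memberIds, foldId, split, config)
  apply(mat, 1L, majorityVote, config = config)
}

#' Patient-level prediction matrix of several models
#'
#' Convenience around [aggregateSlicesToPatient()]: one column per model,
#' one row per patient, aligned on a common sorted patient set. An error is
#' raised if the models do not cover the same patients in the requested
#' fold/split.
#'
#' @inheritParams ensemblePredict
#' @param modelIds model ids (columns).
#' @return integer matrix (patients x models) of 0/1 labels.
#' @export
patientLevelMatrix <- function(table, modelIds, foldId, split,
                               config = VoteConfig()) {
  cols <- lapply(modelIds, function(m)
    aggregateSlicesToPatient(table, m, foldId, split, config))
  pats <- names(cols[[1L]])
  for (i in seq_along(cols)) {
    if (!identical(names(cols[[i]]), pats))
      stop(sprintf("model '%s' does not cover the same patients as '%s' in fold %s split '%s'",
                   modelIds[i], modelIds[1L], foldId, split))
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- modelIds
  mat
}

#' Export patient-level labels as delimited text
#'
#' @param labels named 0/1 vector as returned by [ensemblePredict()].
#' @param path output CSV path (columns `patient_id`, `predicted_label`).
#' @return `invisible(path)`.
#' @export
writePatientLabels <- function(labels, path) {
  utils::write.csv(data.frame(patient_id = names(labels),
                              predicted_label = as.integer(labels)),
                   path, row.names = FALSE)
  invisible(path)
}
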