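#' @include registry.R
NULL

#' Build a prediction table
#'
#' @param records data.frame with columns `model_id`, `fold_id`, `split`,
#'   `sample_id`, `patient_id`, `predicted_label`. For patient-level models
#'   `sample_id` equals `patient_id`; for slice-level models each CT slice is
#'   one row carrying its patient's id.
#' @param truth named 0/1 vector of ground-truth patient labels (1 = positive
#'   short-survival class). Every patient referenced by `records` must be
#'   present.
#' @return a [PredictionTable-class].
#' @examples
#' rec <- data.frame(model_id = "m1", fold_id = 0L, split = "val",
#'                   sample_id = c("p1", "p2"), patient_id = c("p1", "p2"),
#'                   predicted_label = c(1L, 0L))
#' tab <- PredictionTable(rec, truth = c(p1 = 1L, p2 = 0L))
#' patientTruth(tab)
#' @export
PredictionTable <- function(records, truth) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("model_id", "fold_id", "split", "sample_id", "patient_id",
            "predicted_label")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop(sprintf("records is missing columns: %s", paste(miss, collapse = ", ")))
  records <- records[, need]
  records$model_id <- as.character(records$model_id)
  records$fold_id <- as.integer(records$fold_id)
  records$split <- as.character(records$split)
  records$sample_id <- as.character(records$sample_id)
  records$patient_id <- as.character(records$patient_id)
  records$predicted_label <- as.integer(records$predicted_label)
  rownames(records) <- NULL
  tr <- stats::setNames(as.integer(truth), names(truth))
  methods::new("PredictionTable", records = records, truth = tr)
}

#' @rdname accessors
#' @export
setMethod("predictionRecords", "PredictionTable",
          function(object) object@records)

#' @rdname accessors
#' @export
setMethod("patientTruth", "PredictionTable", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("modelIds", "PredictionTable",
          function(object) sort(unique(object@records$model_id)))

#' @rdname accessors
#' @export
setMethod("foldIds", "PredictionTable",
          function(object) sort(unique(object@records$fold_id)))

setMethod("show", "PredictionTable", function(object) {
  r <- object@records
  cat(sprintf(paste0("PredictionTable: %d records | %d models | %d folds | ",
                     "%d patients (%d positive)\n"),
              nrow(r), length(unique(r$model_id)),
              length(unique(r$fold_id)), length(object@truth),
              sum(object@truth == 1L)))
})

# Per-row contract checks with row numbers, used by the loaders so that a
# malformed file is reported by offending line rather than a generic
# validity failure.
.checkRecordRows <- function(records, where) {
  bad <- which(!records$predicted_label %in% c(0, 1) |
                 is.na(records$predicted_label))
  if (length(bad))
    stop(sprintf("%s: non-binary predicted_label at row(s) %s", where,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  bad <- which(!records$split %in% .SPLITS)
  if (length(bad))
    stop(sprintf("%s: unknown split token at row(s) %s", where,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  key <- paste(records$model_id, records$fold_id, records$split,
               records$sample_id, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad))
    stop(sprintf("%s: duplicate (model_id, fold_id, split, sample_id) at row(s) %s",
                 where, paste(utils::head(bad, 5L), collapse = ", ")))
  invisible(TRUE)
}

.truthSidecar <- function(path) sub("(\\.[^.]+)?$", "_truth.csv", path)

#' Read and write prediction tables
#'
#' Two lossless serialisations are supported. The delimited form
#' (`format = "csv"`) is a CSV with header
#' `model_id,fold_id,split,sample_id,patient_id,predicted_label` plus a
#' sidecar CSV (`<path>_truth.csv`, or `truthPath`) with columns
#' `patient_id,label` holding the per-patient ground truth. The
#' structured-record form (`format = "json"`) is a single JSON document with
#' `records` and `truth` members. Malformed input (missing column,
#' non-binary label, unknown split token, duplicate key) is rejected with an
#' error naming the offending row.
#'
#' @param path file to read or write.
#' @param format `"csv"` or `"json"`; defaults from the file extension.
#' @param table a [PredictionTable-class] (for writing).
#' @param truthPath sidecar truth CSV path for the delimited form; defaults
#'   to `<path stem>_truth.csv`.
#' @return `readPredictionTable` returns a [PredictionTable-class];
#'   `writePredictionTable` returns `invisible(path)`.
#' @export
readPredictionTable <- function(path,
                                format = c("auto", "csv", "json"),
                                truthPath = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop(sprintf("prediction file not found: %s", path))
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(doc$records) || is.null(doc$truth))
      stop(sprintf("%s: JSON prediction table needs 'records' and 'truth'", path))
    records <- as.data.frame(doc$records, stringsAsFactors = FALSE)
    if (!nrow(records))
      records <- data.frame(model_id = character(), fold_id = integer(),
                            split = character(), sample_id = character(),
                            patient_id = character(),
                            predicted_label = integer())
    truth <- unlist(doc$truth)
  } else {
    records <- utils::read.csv(path, stringsAsFactors = FALSE)
    for (cc in c("model_id", "sample_id", "patient_id"))
      if (cc %in% names(records)) records[[cc]] <- as.character(records[[cc]])
    truthPath <- truthPath %||% .truthSidecar(path)
    if (!file.exists(truthPath))
      stop(sprintf("truth sidecar not found: %s", truthPath))
    td <- utils::read.csv(truthPath, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
    if (!all(c("patient_id", "label") %in% names(td)))
      stop(sprintf("%s: truth file needs columns patient_id, label", truthPath))
    truth <- stats::setNames(as.integer(td$label), td$patient_id)
  }
  need <- c("model_id", "fold_id", "split", "sample_id", "patient_id",
            "predicted_label")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  .checkRecordRows(records, path)
  PredictionTable(records, truth)
}

#' @rdname readPredictionTable
#' @export
writePredictionTable <- function(table, path,
                                 format = c("auto", "csv", "json"),
                                 truthPath = NULL) {
  stopifnot(methods::is(table, "PredictionTable"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    doc <- list(records = table@records,
                truth = as.list(table@truth))
    jsonlite::write_json(doc, path, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(table@records, path, row.names = FALSE)
    truthPath <- truthPath %||% .truthSidecar(path)
    utils::write.csv(data.frame(patient_id = names(table@truth),
                                label = as.integer(table@truth)),
                     truthPath, row.names = FALSE)
  }
  invisible(path)
}

#' Subset a prediction table
#'
#' Restricts a table to selected models, folds and/or splits; the truth
#' mapping is restricted to the patients still referenced. `NULL` keeps a
#' dimension untouched. Requesting an unknown model or fold is an error
#' rather than a silent empty result.
#'
#' @param table a [PredictionTable-class].
#' @param modelIds,foldIds,splits values to keep, or `NULL` for all. An
#'   empty character/integer vector selects nothing (empty table).
#' @return a [PredictionTable-class].
#' @export
subsetPredictions <- function(table, modelIds = NULL, foldIds = NULL,
                              splits = NULL) {
  stopifnot(methods::is(table, "PredictionTable"))
  r <- table@records
  keep <- rep(TRUE, nrow(r))
  if (!is.null(modelIds)) {
    unknown <- setdiff(modelIds, unique(r$model_id))
    if (length(unknown))
      stop(sprintf("unknown model_id: %s", paste(unknown, collapse = ", ")))
    keep <- keep & r$model_id %in% modelIds
  }
  if (!is.null(foldIds)) {
    unknown <- setdiff(foldIds, unique(r$fold_id))
    if (length(unknown))
      stop(sprintf("unknown fold_id: %s", paste(unknown, collapse = ", ")))
    keep <- keep & r$fold_id %in% foldIds
  }
  if (!is.null(splits)) {
    unknown <- setdiff(splits, .SPLITS)
    if (length(unknown))
      stop(sprintf("unknown split: %s", paste(unknown, collapse = ", ")))
    keep <- keep & r$split %in% splits
  }
  out <- r[keep, , drop = FALSE]
  truth <- table@truth[names(table@truth) %in% unique(out$patient_id)]
  PredictionTable(out, truth)
}

#' Build a fold assignment
#'
#' @param foldId 0-based fold index.
#' @param assignment named character vector patient_id -> split
#'   (`train`/`val`/`test`).
#' @param seed integer seed recorded for provenance.
#' @return a [FoldAssignment-class].
#' @seealso [makeBootstrapSplits()]
#' @export
FoldAssignment <- function(foldId, assignment, seed = NA_integer_) {
  methods::new("FoldAssignment", foldId = as.integer(foldId),
               assignment = assignment, seed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("foldIds", "FoldAssignment", function(object) object@foldId)

#' Patient split assignment of a fold
#'
#' @param fold a [FoldAssignment-class].
#' @return named character vector patient_id -> split.
#' @export
splitAssignment <- function(fold) {
  stopifnot(methods::is(fold, "FoldAssignment"))
  fold@assignment
}

setMethod("show", "FoldAssignment", function(object) {
  tab <- table(factor(object@assignment, levels = .SPLITS))
  cat(sprintf("FoldAssignment %d (seed %s): train %d | val %d | test %d\n",
              object@foldId, object@seed, tab["train"], tab["val"],
              tab["test"]))
})
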