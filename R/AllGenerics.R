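#' @include AllClasses.R
NULL

#' Accessors for registry, prediction and selection objects
#'
#' Small generics exposing the slots of the package's S4 classes without
#' direct slot access: model catalogue views (`modelIds`, `nModels`,
#' `clinicalModels`, `imagingModels`, `granularityOf`), prediction-table
#' views (`predictionRecords`, `patientTruth`, `foldIds`), and
#' selection-result views (`memberIds`, `rBar`, `kBar`, `objectiveValue`,
#' `optimalEnsemble`, `candidateTable`, `baselineEnsembles`).
#'
#' @param object an object of the documented class.
#' @param modelId single model id (for `granularityOf`).
#' @return `modelIds`, `clinicalModels`, `imagingModels`, `memberIds`:
#'   character vectors; `nModels`: integer; `granularityOf`: `"patient"` or
#'   `"slice"`; `predictionRecords`, `candidateTable`: data.frames;
#'   `patientTruth`: named 0/1 integer vector; `foldIds`: sorted integer
#'   vector; `rBar`, `kBar`, `objectiveValue`: numerics; `optimalEnsemble`:
#'   an [EnsembleCandidate-class]; `baselineEnsembles`: a named list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelIds", function(object) standardGeneric("modelIds"))

#' @rdname accessors
#' @export
setGeneric("nModels", function(object) standardGeneric("nModels"))

#' @rdname accessors
#' @export
setGeneric("clinicalModels", function(object) standardGeneric("clinicalModels"))

#' @rdname accessors
#' @export
setGeneric("imagingModels", function(object) standardGeneric("imagingModels"))

#' @rdname accessors
#' @export
setGeneric("granularityOf",
           function(object, modelId) standardGeneric("granularityOf"))

#' @rdname accessors
#' @export
setGeneric("predictionRecords",
           function(object) standardGeneric("predictionRecords"))

#' @rdname accessors
#' @export
setGeneric("patientTruth", function(object) standardGeneric("patientTruth"))

#' @rdname accessors
#' @export
setGeneric("foldIds", function(object) standardGeneric("foldIds"))

#' @rdname accessors
#' @export
setGeneric("memberIds", function(object) standardGeneric("memberIds"))

#' @rdname accessors
#' @export
setGeneric("rBar", function(object) standardGeneric("rBar"))

#' @rdname accessors
#' @export
setGeneric("kBar", function(object) standardGeneric("kBar"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setGeneric("optimalEnsemble", function(object) standardGeneric("optimalEnsemble"))

#' @rdname accessors
#' @export
setGeneric("candidateTable", function(object) standardGeneric("candidateTable"))

#' @rdname accessors
#' @export
setGeneric("baselineEnsembles",
           function(object) standardGeneric("baselineEnsembles"))

#' @rdname paretoFront
#' @export
setGeneric("paretoFront", function(object) standardGeneric("paretoFront"))
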