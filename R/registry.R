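#' @include utils.R
NULL

#' Build a model registry
#'
#' @param model_id character vector of unique model identifiers.
#' @param modality character vector, `"clinical"` or `"imaging"`, recycled
#'   if length 1.
#' @param granularity character vector, `"patient"` or `"slice"`. Defaults to
#'   `"patient"` for clinical models and `"slice"` for imaging models, the
#'   usual granularities of tabular learners and slice-level CNNs.
#' @return a [ModelRegistry-class].
#' @examples
#' reg <- ModelRegistry(c("adaboost", "resnet34", "vgg11bn"),
#'                      c("clinical", "imaging", "imaging"))
#' nModels(reg)
#' imagingModels(reg)
#' @export
ModelRegistry <- function(model_id, modality,
                          granularity = ifelse(modality == "clinical",
                                               "patient", "slice")) {
  entries <- data.frame(model_id = as.character(model_id),
                        modality = rep_len(as.character(modality),
                                           length(model_id)),
                        granularity = rep_len(as.character(granularity),
                                              length(model_id)),
                        stringsAsFactors = FALSE)
  methods::new("ModelRegistry", entries = entries)
}

#' @rdname accessors
#' @export
setMethod("modelIds", "ModelRegistry",
          function(object) object@entries$model_id)

#' @rdname accessors
#' @export
setMethod("nModels", "ModelRegistry", function(object) nrow(object@entries))

#' @rdname accessors
#' @export
setMethod("clinicalModels", "ModelRegistry", function(object)
  object@entries$model_id[object@entries$modality == "clinical"])

#' @rdname accessors
#' @export
setMethod("imagingModels", "ModelRegistry", function(object)
  object@entries$model_id[object@entries$modality == "imaging"])

#' @rdname accessors
#' @export
setMethod("granularityOf", "ModelRegistry", function(object, modelId) {
  i <- match(modelId, object@entries$model_id)
  if (anyNA(i))
    stop(sprintf("unknown model_id: %s",
                 paste(modelId[is.na(i)], collapse = ", ")))
  object@entries$granularity[i]
})

setMethod("show", "ModelRegistry", function(object) {
  cat(sprintf("ModelRegistry with %d models (%d clinical, %d imaging)\n",
              nModels(object), length(clinicalModels(object)),
              length(imagingModels(object))))
  print(utils::head(object@entries, 10L), row.names = FALSE)
  if (nModels(object) > 10L) cat(sprintf("... and %d more\n", nModels(object) - 10L))
})

#' Read or write a model registry file
#'
#' The registry is a small configuration file listing `model_id`, `modality`
#' and `granularity` for every model in the pool, as delimited text (CSV with
#' header) or JSON, chosen by file extension.
#'
#' @param path file path; `.json` selects the structured-record form,
#'   anything else is read/written as CSV.
#' @param registry a [ModelRegistry-class] (for writing).
#' @return `readModelRegistry` returns a [ModelRegistry-class];
#'   `writeModelRegistry` returns `invisible(path)`.
#' @export
readModelRegistry <- function(path) {
  if (!file.exists(path)) stop(sprintf("registry file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    d <- jsonlite::fromJSON(path)
    d <- as.data.frame(d, stringsAsFactors = FALSE)
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  }
  need <- c("model_id", "modality", "granularity")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("registry file %s is missing columns: %s", path,
                 paste(miss, collapse = ", ")))
  ModelRegistry(d$model_id, d$modality, d$granularity)
}

#' @rdname readModelRegistry
#' @export
writeModelRegistry <- function(registry, path) {
  stopifnot(methods::is(registry, "ModelRegistry"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(registry@entries, path, dataframe = "rows",
                         pretty = TRUE)
  } else {
    utils::write.csv(registry@entries, path, row.names = FALSE)
  }
  invisible(path)
}
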