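#' @include predictions.R
NULL

.NUMERIC_FEATURES <- c("age", "ctv")
.CATEGORICAL_FEATURES <- c("sex", "histology", "stage", "t_stage", "n_stage")

#' The fixed clinical feature schema
#'
#' The clinical modality carries seven descriptors per patient: two numeric
#' (`age` in years, `ctv` — the delineated clinical target volume — in cm^3)
#' and five categorical (`sex`, `histology`, `stage`, `t_stage`, `n_stage`).
#' `clinicalFeatures()` returns their names; `defaultClinicalSchema()` the
#' default ordered category lists used for one-hot encoding, including the
#' virtual `"unknown"` histology category assigned to patients without a
#' histopathological examination. The schema is configurable: stage
#' sub-divisions (e.g. IIIa/IIIb) can be declared by supplying a richer
#' category list to [oneHotEncode()].
#'
#' @return `clinicalFeatures()`: character vector of the 7 feature names;
#'   `defaultClinicalSchema()`: named list mapping each categorical feature
#'   to its ordered category vector.
#' @export
clinicalFeatures <- function() c(.NUMERIC_FEATURES, .CATEGORICAL_FEATURES)

#' @rdname clinicalFeatures
#' @export
defaultClinicalSchema <- function() {
  list(sex = c("male", "female"),
       histology = c("adenocarcinoma", "squamous", "other", "unknown"),
       stage = c("II", "III", "IV"),
       t_stage = c("T0", "T1", "T2", "T3", "T4"),
       n_stage = c("N0", "N1", "N2", "N2_recurrence", "N3"))
}

.checkClinical <- function(table, what = "clinical table") {
  if (!is.data.frame(table)) stop(sprintf("%s must be a data.frame", what))
  need <- c("patient_id", clinicalFeatures())
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop(sprintf("%s is missing columns: %s", what,
                 paste(miss, collapse = ", ")))
  invisible(table)
}

#' Read or write a clinical table
#'
#' Delimited text with header; one row per patient, columns `patient_id`
#' plus the seven features of [clinicalFeatures()]. Missing values are empty
#' fields or `NA`.
#'
#' @param path file path.
#' @param table clinical data.frame (for writing).
#' @return `readClinicalTable` returns the validated data.frame.
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("clinical file not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  d$patient_id <- as.character(d$patient_id)
  for (f in .CATEGORICAL_FEATURES)
    if (f %in% names(d)) d[[f]] <- as.character(d[[f]])
  for (f in .NUMERIC_FEATURES)
    if (f %in% names(d)) d[[f]] <- as.numeric(d[[f]])
  .checkClinical(d, path)
}

#' @rdname readClinicalTable
#' @export
writeClinicalTable <- function(table, path) {
  .checkClinical(table)
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

# Mode with deterministic lexicographic tie-break.
.modeOf <- function(x) {
  x <- x[!is.na(x)]
  tab <- table(x)               # names sorted lexicographically
  names(tab)[which.max(tab)]    # first maximum = smallest category on ties
}

#' Impute missing clinical values from a training split
#'
#' Missing numeric values are replaced by the training-split median, missing
#' categorical values by the training-split mode (ties broken towards the
#' lexicographically smallest category). Histology is the exception: a
#' missing histology is never guessed but assigned the literal category
#' `"unknown"`, because patients without a histopathological examination are
#' a meaningful group of their own. Imputation statistics depend only on the
#' training split, so validation/test rows never leak into them.
#'
#' @param train clinical data.frame (training split) the statistics are
#'   learned from.
#' @param target clinical data.frame to impute; defaults to `train`.
#' @return `target` with no remaining missing values.
#' @examples
#' tr <- data.frame(patient_id = c("a", "b", "c"), age = c(60, 70, 80),
#'                  ctv = c(50, 100, 150), sex = c("male", "male", "female"),
#'                  histology = c("squamous", NA, "other"),
#'                  stage = "III", t_stage = "T2", n_stage = "N1")
#' imputeMissing(tr)$histology
#' @export
imputeMissing <- function(train, target = train) {
  .checkClinical(train, "train")
  .checkClinical(target, "target")
  if (!nrow(train)) stop("training split is empty")
  out <- target
  for (f in .NUMERIC_FEATURES) {
    vals <- train[[f]]
    if (all(is.na(vals)))
      stop(sprintf("cannot impute '%s': entirely missing in the training split", f))
    med <- stats::median(vals, na.rm = TRUE)
    out[[f]][is.na(out[[f]])] <- med
  }
  for (f in .CATEGORICAL_FEATURES) {
    if (f == "histology") {
      out[[f]][is.na(out[[f]])] <- "unknown"
      next
    }
    if (any(is.na(out[[f]]))) {
      vals <- train[[f]]
      if (all(is.na(vals)))
        stop(sprintf("cannot impute '%s': entirely missing in the training split", f))
      out[[f]][is.na(out[[f]])] <- .modeOf(vals)
    }
  }
  out
}

#' One-hot encode a clinical table
#'
#' Expands each categorical feature into one indicator column per declared
#' category (named `<feature>.<category>`, in schema order); numeric
#' features pass through unchanged as one column each. Rows are ordered and
#' named by `patient_id`. The table must already be imputation-complete; a
#' categorical value outside the declared schema is an error naming the
#' feature and value.
#'
#' @param table imputed clinical data.frame.
#' @param schema named list mapping each categorical feature to its ordered
#'   category vector; see [defaultClinicalSchema()].
#' @return numeric matrix with attribute `numeric_columns` naming the
#'   passthrough columns (used by [minMaxNormalize()]).
#' @export
oneHotEncode <- function(table, schema = defaultClinicalSchema()) {
  .checkClinical(table)
  feats <- table[, clinicalFeatures(), drop = FALSE]
  if (any(is.na(feats)))
    stop("table contains missing values; run imputeMissing() first")
  miss <- setdiff(.CATEGORICAL_FEATURES, names(schema))
  if (length(miss))
    stop(sprintf("schema lacks categorical feature(s): %s",
                 paste(miss, collapse = ", ")))
  blocks <- list()
  for (f in .NUMERIC_FEATURES) {
    m <- matrix(as.numeric(table[[f]]), ncol = 1L,
                dimnames = list(NULL, f))
    blocks[[f]] <- m
  }
  for (f in .CATEGORICAL_FEATURES) {
    cats <- schema[[f]]
    vals <- table[[f]]
    bad <- setdiff(unique(vals), cats)
    if (length(bad))
      stop(sprintf("feature '%s': value(s) outside declared schema: %s", f,
                   paste(bad, collapse = ", ")))
    m <- outer(vals, cats, `==`) * 1
    colnames(m) <- paste(f, cats, sep = ".")
    blocks[[f]] <- m
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- table$patient_id
  attr(out, "numeric_columns") <- .NUMERIC_FEATURES
  out
}

#' Min-max normalise numeric columns to the unit interval
#'
#' Scales every numeric column of an encoded matrix to `[0, 1]` with bounds
#' learned from the training split: `(x - min_train) / (max_train -
#' min_train)`. Target values outside the training range are clipped to the
#' interval, preserving the stated range guarantee on unseen splits.
#' Indicator columns produced by [oneHotEncode()] are already 0/1 and are
#' left untouched.
#'
#' @param train encoded matrix the bounds are learned from.
#' @param target encoded matrix to scale; defaults to `train`.
#' @param numericColumns columns to scale; defaults to the
#'   `numeric_columns` attribute of `train`, or all columns when absent.
#' @return `target` with scaled columns and a `bounds` attribute (matrix
#'   with rows `min`, `max`).
#' @export
minMaxNormalize <- function(train, target = train,
                            numericColumns = NULL) {
  stopifnot(is.matrix(train), is.matrix(target))
  numericColumns <- numericColumns %||%
    (attr(train, "numeric_columns") %||% colnames(train))
  miss <- setdiff(numericColumns, colnames(train))
  if (length(miss))
    stop(sprintf("unknown column(s): %s", paste(miss, collapse = ", ")))
  bounds <- sapply(numericColumns, function(cc) {
    rng <- range(train[, cc])
    if (rng[1] == rng[2])
      stop(sprintf("column '%s' is constant in the training split; scale is degenerate", cc))
    rng
  })
  rownames(bounds) <- c("min", "max")
  out <- target
  for (cc in numericColumns) {
    x <- (target[, cc] - bounds["min", cc]) /
      (bounds["max", cc] - bounds["min", cc])
    out[, cc] <- pmin(pmax(x, 0), 1)
  }
  attr(out, "numeric_columns") <- attr(train, "numeric_columns")
  attr(out, "bounds") <- bounds
  out
}
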