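#' @include bootstrap.R
NULL

#' Describe a synthetic classifier
#'
#' A synthetic model emits binary predictions whose marginal accuracy and
#' error correlation are controllable, standing in for a trained unimodal
#' learner when exercising the ensemble selector. Correlation is induced by
#' a two-level mechanism: all models see a shared per-patient latent
#' difficulty (coupling strength `difficulty_weight`), and models in one
#' `flip_group` additionally reuse the same error draw, making their
#' mistakes maximally redundant (two group members with equal target
#' accuracy produce identical predictions, pairwise kappa diversity 0).
#'
#' @param model_id unique model id.
#' @param modality `"clinical"` or `"imaging"`.
#' @param granularity `"patient"` or `"slice"`; slice models emit one label
#'   per CT slice with independent per-slice noise.
#' @param target_accuracy desired marginal accuracy in `[0, 1]` at the
#'   emitted-sample level.
#' @param difficulty_weight non-negative coupling to the shared per-patient
#'   difficulty; 0 decouples the model, larger values correlate its errors
#'   with other coupled models.
#' @param flip_group optional label; models sharing a label (and
#'   granularity) share one error source.
#' @return a list of class `SyntheticModelSpec`.
#' @seealso [simulatePredictions()], [plantedOptimumScenario()]
#' @export
syntheticModelSpec <- function(model_id, modality,
                               granularity = ifelse(modality == "clinical",
                                                    "patient", "slice"),
                               target_accuracy = 0.75,
                               difficulty_weight = 1,
                               flip_group = NA_character_) {
  if (target_accuracy < 0 || target_accuracy > 1)
    stop("target_accuracy must lie in [0, 1]")
  if (difficulty_weight < 0) stop("difficulty_weight must be non-negative")
  structure(list(model_id = as.character(model_id),
                 modality = match.arg(modality, .MODALITIES),
                 granularity = match.arg(granularity, .GRANULARITIES),
                 target_accuracy = target_accuracy,
                 difficulty_weight = difficulty_weight,
                 flip_group = as.character(flip_group)),
            class = "SyntheticModelSpec")
}

.specsToFrame <- function(specs) {
  if (is.data.frame(specs)) {
    df <- specs
  } else {
    if (inherits(specs, "SyntheticModelSpec")) specs <- list(specs)
    df <- do.call(rbind, lapply(specs, function(s)
      data.frame(model_id = s$model_id, modality = s$modality,
                 granularity = s$granularity,
                 target_accuracy = s$target_accuracy,
                 difficulty_weight = s$difficulty_weight,
                 flip_group = s$flip_group, stringsAsFactors = FALSE)))
  }
  if (!nrow(df)) stop("at least one model spec is required")
  if (anyDuplicated(df$model_id)) stop("model_id values must be unique")
  grp <- stats::na.omit(unique(df$flip_group))
  for (g in grp) {
    gran <- unique(df$granularity[!is.na(df$flip_group) & df$flip_group == g])
    if (length(gran) > 1L)
      stop(sprintf("flip_group '%s' mixes granularities", g))
  }
  df
}

#' Default cohort marginals
#'
#' The per-feature category probabilities, missing-value rates and bounded
#' numeric ranges used by [simulateCohort()], chosen to match the published
#' characteristics of a 191-patient locally-advanced NSCLC cohort: a
#' two-thirds male population, adenocarcinoma/squamous-dominated histology
#' with a 13.6% share of patients lacking a histopathological examination
#' (the virtual `"unknown"` category), predominantly stage III disease, and
#' median overall survival of 15.64 months. Numeric features are described
#' by bounded ranges with their medians (age median 71 years, clinical
#' target volume median 114.88 cm^3).
#'
#' @return nested list with members `categorical` (per feature: `probs`,
#'   `missing`), `numeric` (per feature: `min`, `median`, `max`, `missing`)
#'   and `survival` (`median_months`, `sdlog`).
#' @export
defaultCohortMarginals <- function() {
  list(
    categorical = list(
      sex = list(probs = c(male = 133, female = 58) / 191, missing = 0),
      histology = list(probs = c(adenocarcinoma = 95, squamous = 59,
                                 other = 11, unknown = 26) / 191,
                       missing = 0),
      stage = list(probs = c(II = 4, III = 160, IV = 27) / 191, missing = 0),
      t_stage = list(probs = c(T0 = 1, T1 = 9, T2 = 32, T3 = 65,
                               T4 = 48) / 155,
                     missing = 36 / 191),
      n_stage = list(probs = c(N0 = 15, N1 = 33, N2 = 93, N2_recurrence = 6,
                               N3 = 18) / 165,
                     missing = 26 / 191)),
    numeric = list(
      age = list(min = 40, median = 71, max = 92, missing = 26 / 191),
      ctv = list(min = 2, median = 114.88, max = 600, missing = 37 / 191)),
    survival = list(median_months = 15.64, sdlog = 0.8))
}

.checkMarginals <- function(marginals) {
  for (f in names(marginals$categorical)) {
    m <- marginals$categorical[[f]]
    if (!isTRUE(all.equal(sum(m$probs), 1)))
      stop(sprintf("category probabilities of '%s' must sum to 1", f))
    if (m$missing < 0 || m$missing >= 1)
      stop(sprintf("missing rate of '%s' must lie in [0, 1)", f))
  }
  for (f in names(marginals$numeric)) {
    m <- marginals$numeric[[f]]
    if (!(m$min < m$median && m$median < m$max))
      stop(sprintf("numeric feature '%s' needs min < median < max", f))
  }
  invisible(marginals)
}

#' Simulate a clinical cohort
#'
#' Draws `n` patients independently from the given marginals: categorical
#' values from the per-feature category probabilities, numeric values
#' uniformly from either side of the declared median (so the sampled median
#' sits at the target), and missing values injected at the stated rates. A
#' log-normal overall-survival time is sampled per patient and the binary
#' prognosis class is assigned by the median split of the sampled times,
#' yielding a near-balanced cohort; label 1 marks the short-survival
#' (positive) class.
#'
#' @param n number of patients (>= 2).
#' @param marginals see [defaultCohortMarginals()].
#' @param seed integer seed; the same seed reproduces the cohort.
#' @return list with `clinical` (data.frame: `patient_id` + the 7
#'   features), `truth` (named 0/1 vector) and `os_months` (named numeric).
#' @export
simulateCohort <- function(n = 191L, marginals = defaultCohortMarginals(),
                           seed = 1L) {
  if (n < 2L) stop("need at least two patients")
  .checkMarginals(marginals)
  withSeed(seed, {
    ids <- sprintf("pt%04d", seq_len(n))
    tab <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
    for (f in .NUMERIC_FEATURES) {
      m <- marginals$numeric[[f]]
      upper <- stats::runif(n) < 0.5
      x <- ifelse(upper, stats::runif(n, m$median, m$max),
                  stats::runif(n, m$min, m$median))
      x[stats::runif(n) < m$missing] <- NA_real_
      tab[[f]] <- x
    }
    for (f in .CATEGORICAL_FEATURES) {
      m <- marginals$categorical[[f]]
      x <- sample(names(m$probs), n, replace = TRUE, prob = m$probs)
      x[stats::runif(n) < m$missing] <- NA_character_
      tab[[f]] <- x
    }
    os <- stats::rlnorm(n, meanlog = log(marginals$survival$median_months),
                        sdlog = marginals$survival$sdlog)
    truth <- stats::setNames(as.integer(os < stats::median(os)), ids)
    list(clinical = tab, truth = truth,
         os_months = stats::setNames(os, ids))
  })
}

#' Summarise a cohort table
#'
#' Per-feature category counts and percentages in the printed-table
#' convention: the denominator is always the full cohort (missing values
#' included), percentages are rounded half-up to two decimals, and the two
#' continuous features are summarised by splitting at their observed median.
#' Rows for missing values are labelled `(missing)`.
#'
#' @param table clinical data.frame (see [readClinicalTable()]).
#' @return data.frame with columns `feature`, `category`, `count`,
#'   `percent`.
#' @examples
#' coh <- simulateCohort(100, seed = 3)
#' head(summarizeCohort(coh$clinical))
#' @export
summarizeCohort <- function(table) {
  .checkClinical(table)
  if (!nrow(table)) stop("cannot summarise an empty cohort")
  n <- nrow(table)
  schema <- defaultClinicalSchema()
  rows <- list()
  addRow <- function(feature, category, count)
    rows[[length(rows) + 1L]] <<- data.frame(
      feature = feature, category = category, count = count,
      percent = roundHalfUp(100 * count / n, 2L), stringsAsFactors = FALSE)
  for (f in .NUMERIC_FEATURES) {
    x <- table[[f]]
    med <- stats::median(x, na.rm = TRUE)
    addRow(f, paste0("<", format(med)), sum(x < med, na.rm = TRUE))
    addRow(f, paste0(">=", format(med)), sum(x >= med, na.rm = TRUE))
    if (anyNA(x)) addRow(f, "(missing)", sum(is.na(x)))
  }
  for (f in .CATEGORICAL_FEATURES) {
    x <- table[[f]]
    cats <- unique(x[!is.na(x)])
    declared <- intersect(schema[[f]], cats)
    cats <- c(declared, sort(setdiff(cats, declared)))
    for (cc in cats) addRow(f, cc, sum(x == cc, na.rm = TRUE))
    if (anyNA(x)) addRow(f, "(missing)", sum(is.na(x)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Calibrate the link intercept a so that mean(plogis(a - w * d)) == target
# over the realised difficulty draws d.
.calibrateIntercept <- function(target, w, d) {
  if (w == 0) return(stats::qlogis(min(max(target, 1e-12), 1 - 1e-12)))
  stats::uniroot(function(a) mean(stats::plogis(a - w * d)) - target,
                 lower = -50, upper = 50, tol = 1e-10)$root
}

#' Simulate correlated classifier predictions
#'
#' Generates a [PredictionTable-class] from synthetic model specs. Each
#' patient carries a latent difficulty `d ~ N(0, 1)`; model `m` classifies a
#' sample correctly with probability `plogis(a_m - w_m * d)`, where the
#' intercept `a_m` is calibrated so the marginal accuracy matches the spec's
#' `target_accuracy` over the realised difficulties. Models sharing a
#' `flip_group` reuse a single uniform error draw per sample, so equal-
#' accuracy group members make identical errors and a lower-accuracy member
#' errs on a superset of its partner's mistakes. Slice-granularity models
#' emit one label per CT slice (slice counts drawn uniformly from
#' `slicesPerPatient`, shared across models) with independent per-slice
#' noise around the patient's difficulty. A target accuracy of exactly 0 or
#' 1 with a positive difficulty weight cannot be reached by the link; a
#' warning is emitted and exact deterministic labels are used.
#'
#' @param specs list of [syntheticModelSpec()] entries (or an equivalent
#'   data.frame).
#' @param truth named 0/1 vector of patient labels.
#' @param folds number of folds (splits are then drawn internally with the
#'   derived seed) or a list of [FoldAssignment-class] covering all
#'   patients.
#' @param slicesPerPatient integer range `c(min, max)` of CT slices per
#'   patient.
#' @param seed integer seed.
#' @return a [PredictionTable-class] holding predictions of every model for
#'   every fold and split.
#' @export
simulatePredictions <- function(specs, truth, folds = 5L,
                                slicesPerPatient = c(3L, 7L), seed = 1L) {
  df <- .specsToFrame(specs)
  if (is.null(names(truth)) || !length(truth))
    stop("truth must be a named 0/1 vector")
  stopIfNot01(truth, "truth")
  patients <- names(truth)
  if (is.numeric(folds) && length(folds) == 1L)
    folds <- makeBootstrapSplits(patients, truth, nReps = folds,
                                 seed = seed + 1L)
  for (fa in folds) {
    miss <- setdiff(patients, names(splitAssignment(fa)))
    if (length(miss))
      stop(sprintf("fold %d does not assign patient(s): %s", foldIds(fa),
                   paste(utils::head(miss, 5L), collapse = ", ")))
  }
  nP <- length(patients)
  keys <- ifelse(is.na(df$flip_group), df$model_id, df$flip_group)
  needSlice <- tapply(df$granularity == "slice", keys, any)
  withSeed(seed, {
    d <- stats::setNames(stats::rnorm(nP), patients)
    lo <- as.integer(slicesPerPatient[1L])
    hi <- as.integer(slicesPerPatient[length(slicesPerPatient)])
    if (lo < 1L || hi < lo) stop("slicesPerPatient must be a positive range")
    nSlices <- stats::setNames(sample(seq.int(lo, hi), nP, replace = TRUE),
                               patients)
    totalSlices <- sum(nSlices)
    draws <- lapply(folds, function(fa) {
      perKey <- lapply(sort(unique(keys)), function(k) {
        list(u_pat = stats::runif(nP),
             u_slice = if (needSlice[[k]]) stats::runif(totalSlices) else NULL)
      })
      names(perKey) <- sort(unique(keys))
      perKey
    })
    pieces <- list()
    for (mi in seq_len(nrow(df))) {
      target <- df$target_accuracy[mi]
      w <- df$difficulty_weight[mi]
      degenerate <- target %in% c(0, 1)
      if (degenerate && w > 0)
        warning(sprintf("model '%s': target accuracy %g is unreachable with a positive difficulty weight; using exact deterministic labels",
                        df$model_id[mi], target))
      p <- if (degenerate) rep(target, nP)
      else stats::plogis(.calibrateIntercept(target, w, d) - w * d)
      key <- keys[mi]
      isSlice <- df$granularity[mi] == "slice"
      for (fi in seq_along(folds)) {
        fa <- folds[[fi]]
        splitVec <- splitAssignment(fa)[patients]
        if (isSlice) {
          u <- draws[[fi]][[key]]$u_slice
          pSlice <- rep(p, nSlices)
          correct <- u < pSlice
          truthSlice <- rep(as.integer(truth), nSlices)
          pred <- ifelse(correct, truthSlice, 1L - truthSlice)
          pieces[[length(pieces) + 1L]] <- data.frame(
            model_id = df$model_id[mi], fold_id = foldIds(fa),
            split = rep(unname(splitVec), nSlices),
            sample_id = paste0(rep(patients, nSlices), "_s",
                               sequence(nSlices)),
            patient_id = rep(patients, nSlices),
            predicted_label = pred, stringsAsFactors = FALSE)
        } else {
          u <- draws[[fi]][[key]]$u_pat
          correct <- u < p
          pred <- ifelse(correct, as.integer(truth), 1L - as.integer(truth))
          pieces[[length(pieces) + 1L]] <- data.frame(
            model_id = df$model_id[mi], fold_id = foldIds(fa),
            split = unname(splitVec), sample_id = patients,
            patient_id = patients, predicted_label = pred,
            stringsAsFactors = FALSE)
        }
      }
    }
    PredictionTable(do.call(rbind, pieces), truth)
  })
}

#' A pool with a planted optimal trio
#'
#' Constructs a synthetic selection instance whose intended optimum is known
#' by design: one accurate clinical model (`cl1`, patient-level accuracy
#' 0.70) and two accurate, mutually error-decorrelated imaging models
#' (`im1`, `im2`, slice-level accuracy 0.62, about 0.70 at patient level
#' after slice-majority aggregation) form the planted trio — strengths in
#' the band real unimodal prognosis models occupy — while every decoy is
#' redundant with a planted member through a shared error source: `im3` and
#' `im4` are exact duplicates of `im1` and `im2`, and `cl2` is a degraded
#' chance-level copy of `cl1` (accuracy 0.50, errors a superset of
#' `cl1`'s). A trio that
#' swaps in the degraded clinical copy can only lose recall; a trio pairing
#' a model with its own copy loses on diversity (their pairwise kappa
#' diversity collapses); trios swapping in an exact duplicate for its twin
#' tie exactly and fall to the deterministic tie-break.
#'
#' Splits are patient-grouped and class-stratified with a 40/40/20
#' train/validation/test partition rather than the production 80/10/10
#' protocol, for statistical power: the selection scores are estimated per
#' fold on the validation patients, and with only ten of them the sampling
#' noise of the pairwise kappa estimate (sd about `1/sqrt(n)`) and of the
#' vote-recall estimate would exceed the planted score margins no matter
#' how the search is implemented; likewise ten test patients quantise
#' per-fold recall in 20-point steps, too coarse to compare selection
#' strategies. Forty validation and twenty test patients keep both the
#' planted structure and the evaluation resolvable; the train share is
#' inert here because the generator emits predictions directly rather than
#' fitting models.
#'
#' @param nPatients cohort size (>= 50).
#' @param seed integer seed.
#' @param nFolds number of bootstrap folds (default 5).
#' @param slicesPerPatient CT slices per patient, uniform range.
#' @return list with `table` ([PredictionTable-class]), `registry`
#'   ([ModelRegistry-class]), `planted` (the intended optimal member ids)
#'   and `folds` (list of [FoldAssignment-class]).
#' @export
plantedOptimumScenario <- function(nPatients = 100L, seed = 1L, nFolds = 5L,
                                   slicesPerPatient = c(3L, 7L)) {
  if (nPatients < 50L) stop("planted scenario needs at least 50 patients")
  ids <- sprintf("pt%04d", seq_len(nPatients))
  truth <- withSeed(seed, stats::setNames(
    sample(rep_len(c(0L, 1L), nPatients)), ids))
  folds <- makeBootstrapSplits(ids, truth, nReps = nFolds,
                               fractions = c(train = 0.4, val = 0.4,
                                             test = 0.2),
                               seed = seed + 1L)
  specs <- list(
    syntheticModelSpec("cl1", "clinical", target_accuracy = 0.70,
                       difficulty_weight = 0, flip_group = "dupC"),
    syntheticModelSpec("cl2", "clinical", target_accuracy = 0.50,
                       difficulty_weight = 0, flip_group = "dupC"),
    syntheticModelSpec("im1", "imaging", target_accuracy = 0.62,
                       difficulty_weight = 0, flip_group = "dupA"),
    syntheticModelSpec("im2", "imaging", target_accuracy = 0.62,
                       difficulty_weight = 0, flip_group = "dupB"),
    syntheticModelSpec("im3", "imaging", target_accuracy = 0.62,
                       difficulty_weight = 0, flip_group = "dupA"),
    syntheticModelSpec("im4", "imaging", target_accuracy = 0.62,
                       difficulty_weight = 0, flip_group = "dupB"))
  table <- simulatePredictions(specs, truth, folds, slicesPerPatient,
                               seed = seed + 2L)
  registry <- ModelRegistry(c("cl1", "cl2", "im1", "im2", "im3", "im4"),
                            c("clinical", "clinical", rep("imaging", 4L)))
  list(table = table, registry = registry,
       planted = c("cl1", "im1", "im2"), folds = folds)
}
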