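#' @include clinical.R
NULL

#' Confusion counts of a binary prediction
#'
#' Tallies the 2x2 confusion table of a binary prediction against the ground
#' truth. The positive class defaults to label 1, the short-survival
#' prognosis class — the class whose recall the selection objective protects,
#' so that no poor-prognosis patient is missed before treatment.
#'
#' @param pred,truth equal-length 0/1 vectors.
#' @param positiveLabel label counted as positive (0 or 1).
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionCounts <- function(pred, truth, positiveLabel = 1L) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  stopIfNot01(pred, "pred"); stopIfNot01(truth, "truth")
  pos <- truth == positiveLabel
  hit <- pred == truth
  c(tp = sum(pos & hit), fp = sum(!pos & !hit),
    tn = sum(!pos & hit), fn = sum(pos & !hit))
}

.countTotal <- function(counts) sum(counts[c("tp", "fp", "tn", "fn")])

#' Recall, accuracy and F-score from confusion counts
#'
#' `recallScore` is TP / P, the sensitivity on the positive class;
#' `accuracyScore` is (TP + TN) / N; `fScore` is the F1 harmonic mean of
#' precision and recall on the positive class. Recall over an evaluation set
#' with no positive instances is undefined and raises an error. The fully
#' degenerate F-score case — no positive instances and no positive
#' predictions — is defined as 0 with a warning.
#'
#' @param counts named vector from [confusionCounts()].
#' @return a fraction in `[0, 1]`.
#' @examples
#' cc <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' recallScore(cc); accuracyScore(cc); fScore(cc)
#' @export
recallScore <- function(counts) {
  p <- counts[["tp"]] + counts[["fn"]]
  if (p == 0) stop("recall is undefined: no positive instances")
  counts[["tp"]] / p
}

#' @rdname recallScore
#' @export
accuracyScore <- function(counts) {
  n <- .countTotal(counts)
  if (n == 0) stop("accuracy is undefined on an empty sample")
  (counts[["tp"]] + counts[["tn"]]) / n
}

#' @rdname recallScore
#' @export
fScore <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (.countTotal(counts) == 0) stop("F-score is undefined on an empty sample")
  if (tp == 0) {
    if (fp == 0 && fn == 0)
      warning("no positive instances and no positive predictions; F-score defined as 0")
    return(0)
  }
  2 * tp / (2 * tp + fp + fn)
}

#' Joint-correctness contingency of two classifiers
#'
#' Counts, over an evaluation set, how often two classifiers are jointly
#' right or wrong: `n11` both correct, `n10` only the first correct, `n01`
#' only the second, `n00` both wrong. These four cells feed the pairwise
#' kappa diversity.
#'
#' @param predA,predB,truth equal-length 0/1 vectors.
#' @return named integer vector `c(n11, n10, n01, n00)`.
#' @examples
#' pairContingency(c(1, 1, 0, 0), c(1, 0, 0, 1), c(1, 1, 0, 1))
#' @export
pairContingency <- function(predA, predB, truth) {
  if (length(predA) != length(truth) || length(predB) != length(truth))
    stop("predA, predB and truth must have the same length")
  stopIfNot01(predA, "predA"); stopIfNot01(predB, "predB")
  stopIfNot01(truth, "truth")
  a <- predA == truth
  b <- predB == truth
  c(n11 = sum(a & b), n10 = sum(a & !b), n01 = sum(!a & b), n00 = sum(!a & !b))
}

#' Pairwise kappa diversity
#'
#' One minus the inter-rater kappa of the joint correct/incorrect
#' contingency of two classifiers:
#' `K = 1 - 2 (n11 n00 - n01 n10) / [(n11 + n10)(n01 + n00) + (n11 + n01)(n10 + n00)]`.
#' K is 0 for classifiers that always agree (kappa 1), about 1 for
#' independent errors (kappa 0) and reaches 2 for exactly complementary
#' classifiers (kappa -1); it always lies in `[0, 2]`. The value is not
#' clipped to `[0, 1]`. When the denominator is zero the formula is
#' undefined and the limit values are used: 0 if the two prediction vectors
#' are identical (`n10 = n01 = 0`), 2 if they are exactly complementary
#' (`n11 = n00 = 0`).
#'
#' @param contingency named vector from [pairContingency()].
#' @return a value in `[0, 2]`; larger means more complementary errors.
#' @examples
#' kappaDiversity(c(n11 = 2, n10 = 1, n01 = 1, n00 = 0))
#' @export
kappaDiversity <- function(contingency) {
  n11 <- contingency[["n11"]]; n10 <- contingency[["n10"]]
  n01 <- contingency[["n01"]]; n00 <- contingency[["n00"]]
  n <- n11 + n10 + n01 + n00
  if (n == 0) stop("kappa diversity is undefined on an empty contingency")
  den <- (n11 + n10) * (n01 + n00) + (n11 + n01) * (n10 + n00)
  if (den == 0) {
    if (n10 + n01 == 0) return(0)   # identical predictions, kappa = 1
    return(2)                       # complementary, kappa = -1
  }
  1 - 2 * (n11 * n00 - n01 * n10) / den
}

#' Ensemble kappa diversity
#'
#' The mean pairwise [kappaDiversity()] over all unordered pairs of ensemble
#' members: `2 / (|E| (|E| - 1)) * sum_{i<j} K_ij`. Higher values mean the
#' members err on different samples and so complement each other under
#' majority voting.
#'
#' @param memberPreds list of at least two equal-length 0/1 label vectors.
#' @param truth 0/1 vector of the same length.
#' @return non-negative mean pairwise diversity.
#' @export
ensembleDiversity <- function(memberPreds, truth) {
  m <- length(memberPreds)
  if (m < 2L) stop("ensemble diversity needs at least two members")
  ks <- numeric(0)
  for (i in seq_len(m - 1L))
    for (j in seq.int(i + 1L, m))
      ks <- c(ks, kappaDiversity(pairContingency(memberPreds[[i]],
                                                 memberPreds[[j]], truth)))
  mean(ks)
}
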