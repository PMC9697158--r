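# Independent brute-force oracle for the ensemble search, written as plain
# element-by-element loops over the raw records so that it shares no code
# path with the package implementation.

oracleKappaFromCorrectness <- function(corrA, corrB) {
  n11 <- n10 <- n01 <- n00 <- 0L
  for (i in seq_along(corrA)) {
    if (corrA[i] && corrB[i]) n11 <- n11 + 1L
    else if (corrA[i]) n10 <- n10 + 1L
    else if (corrB[i]) n01 <- n01 + 1L
    else n00 <- n00 + 1L
  }
  den <- (n11 + n10) * (n01 + n00) + (n11 + n01) * (n10 + n00)
  if (den == 0) {
    if (n10 + n01 == 0L) return(0)
    return(2)
  }
  1 - 2 * (n11 * n00 - n01 * n10) / den
}

oracleKappaFromCells <- function(n11, n10, n01, n00) {
  den <- (n11 + n10) * (n01 + n00) + (n11 + n01) * (n10 + n00)
  if (den == 0) return(if (n10 + n01 == 0) 0 else 2)
  1 - 2 * (n11 * n00 - n01 * n10) / den
}

# Patient-level labels of one model by explicit per-patient counting.
oraclePatientLabels <- function(records, model, fold, split, tieLabel = 1L) {
  rr <- records[records$model_id == model & records$fold_id == fold &
                  records$split == split, ]
  pats <- sort(unique(rr$patient_id))
  out <- integer(length(pats))
  names(out) <- pats
  for (p in pats) {
    v <- rr$predicted_label[rr$patient_id == p]
    ones <- sum(v == 1L)
    zeros <- length(v) - ones
    out[p] <- if (ones > zeros) 1L else if (zeros > ones) 0L else tieLabel
  }
  out
}

# Fold-averaged (recall, diversity) of a member set, two explicit loops
# (folds x pairs).
oracleScore <- function(records, truth, members, foldIds, split = "val") {
  rs <- ks <- numeric(0)
  for (b in foldIds) {
    labs <- lapply(members, function(m)
      oraclePatientLabels(records, m, b, split))
    pats <- names(labs[[1L]])
    tt <- truth[pats]
    votes <- vapply(labs, function(x) x[pats], integer(length(pats)))
    votes <- matrix(votes, nrow = length(pats))
    pred <- integer(length(pats))
    for (i in seq_along(pats))
      pred[i] <- if (sum(votes[i, ] == 1L) * 2L > ncol(votes)) 1L else 0L
    tp <- sum(pred == 1L & tt == 1L)
    rs <- c(rs, tp / sum(tt == 1L))
    kk <- numeric(0)
    for (i in seq_len(length(members) - 1L))
      for (j in seq.int(i + 1L, length(members)))
        kk <- c(kk, oracleKappaFromCorrectness(labs[[i]][pats] == tt,
                                               labs[[j]][pats] == tt))
    ks <- c(ks, mean(kk))
  }
  c(r = mean(rs), k = mean(ks))
}

oracleEnumerate <- function(ids, clinicalIds, maxSize, multimodal = TRUE) {
  out <- list()
  for (s in seq(3L, min(maxSize, length(ids)), by = 2L)) {
    for (x in utils::combn(sort(ids), s, simplify = FALSE)) {
      if (!multimodal ||
          (any(x %in% clinicalIds) && any(!x %in% clinicalIds)))
        out[[length(out) + 1L]] <- x
    }
  }
  out
}

# Argmin/argmax with the documented tie-break: score, then size, then
# lexicographic member tuple.
oracleSelect <- function(records, truth, ids, clinicalIds, foldIds,
                         maxSize = 3L, multimodal = TRUE,
                         objective = c("multi", "R", "K")) {
  objective <- match.arg(objective)
  cands <- oracleEnumerate(ids, clinicalIds, maxSize, multimodal)
  best <- NULL
  bestKey <- NULL
  for (x in cands) {
    sc <- oracleScore(records, truth, x, foldIds)
    val <- switch(objective,
                  multi = (1 - sc[["r"]])^2 + (1 - sc[["k"]])^2,
                  R = -sc[["r"]],
                  K = -sc[["k"]])
    val <- signif(val, 10L)   # same rounded-tie convention as the package
    key <- list(val = val, size = length(x),
                tuple = paste(sort(x), collapse = ";"))
    better <- is.null(bestKey) ||
      val < bestKey$val ||
      (val == bestKey$val &&
         (key$size < bestKey$size ||
            (key$size == bestKey$size && key$tuple < bestKey$tuple)))
    if (better) {
      best <- sort(x)
      bestKey <- key
    }
  }
  best
}
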