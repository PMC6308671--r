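# Metrics: confusion counts, sensitivity/specificity/accuracy, ROC/AUC,
# and the agreement-partition bookkeeping for decision fusion. The
# positive class throughout is bruised (the detection target): TP is a
# correctly detected bruised sample, so sensitivity = bruised recall and
# specificity = healthy recall.

#' Score hard predictions against the truth
#'
#' @param pred predicted labels (`"healthy"`/`"bruised"`).
#' @param truth true labels, both classes present.
#' @return an `evaluation_report` list: `TP`, `TN`, `FP`, `FN`,
#'   `sensitivity`, `specificity`, `accuracy`, `n`.
#' @export
score_predictions <- function(pred, truth) {
  if (length(pred) == 0L) stop("score_predictions: empty input")
  if (length(pred) != length(truth)) {
    stop("score_predictions: length mismatch")
  }
  pred <- as.character(pred); truth <- as.character(truth)
  TP <- sum(pred == "bruised" & truth == "bruised")
  TN <- sum(pred == "healthy" & truth == "healthy")
  FP <- sum(pred == "bruised" & truth == "healthy")
  FN <- sum(pred == "healthy" & truth == "bruised")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 sensitivity = TP / (TP + FN),
                 specificity = TN / (TN + FP),
                 accuracy = (TP + TN) / length(pred),
                 n = length(pred)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> n=%d  sens=%.3f  spec=%.3f  acc=%.3f\n",
    x$n, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Scores must orient so that larger means more bruised (e.g.
#' `p_bruised` or a fused bruised score). AUC is the normalized
#' Mann-Whitney U statistic with half credit for ties, so it is invariant
#' under strictly monotone score transforms.
#'
#' @param scores continuous scores, larger = more bruised.
#' @param truth true labels, both classes present.
#' @return a list: `roc` (data frame of fpr/tpr points) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.character(truth)
  nb <- sum(truth == "bruised"); nh <- sum(truth == "healthy")
  if (nb == 0L || nh == 0L) stop("roc_auc: both classes required in truth")
  r <- rank(scores)  # average ranks give tie credit 0.5
  auc <- (sum(r[truth == "bruised"]) - nb * (nb + 1) / 2) / (nb * nh)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores >= t & truth == "bruised") / nb,
                 numeric(1)),
    fpr = vapply(thr, function(t) sum(scores >= t & truth == "healthy") / nh,
                 numeric(1)))
  list(roc = roc, auc = auc)
}

#' Agreement partition of a decision fusion run
#'
#' Splits the samples into those where the two base classifiers agreed
#' and those where they conflicted, and counts how many of each were
#' fused to the correct label -- the bookkeeping used to show that
#' decision fusion resolves most conflicts correctly.
#'
#' @param labelsA,labelsB the two base classifiers' hard labels.
#' @param fused the fused labels.
#' @param truth the true labels.
#' @return a list: `n_agree`, `n_agree_correct`, `n_conflict`,
#'   `n_conflict_correct`, `n`.
#' @export
agreement_partition <- function(labelsA, labelsB, fused, truth) {
  n <- length(truth)
  if (length(labelsA) != n || length(labelsB) != n || length(fused) != n) {
    stop("agreement_partition: length mismatch")
  }
  agree <- as.character(labelsA) == as.character(labelsB)
  correct <- as.character(fused) == as.character(truth)
  list(n_agree = sum(agree),
       n_agree_correct = sum(agree & correct),
       n_conflict = sum(!agree),
       n_conflict_correct = sum(!agree & correct),
       n = n)
}

#' Write an evaluation report (plus optional ROC points) to disk
#'
#' @param report an `evaluation_report` (or any named list of scalars).
#' @param path output path stem; writes `<path>.json` and `<path>.csv`,
#'   plus `<path>_roc.csv` when `roc` is given.
#' @param roc optional ROC data frame from [roc_auc()].
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, roc = NULL) {
  jsonlite::write_json(unclass(report), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(unclass(report)), paste0(path, ".csv"),
                   row.names = FALSE)
  if (!is.null(roc)) {
    utils::write.csv(roc, paste0(path, "_roc.csv"), row.names = FALSE)
  }
  invisible(path)
}
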