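#' Molecular disease-activity score (I_MDS)
#'
#' Each sample's score is the sum of its enrichment scores over the selected
#' set of disease-associated upregulated signatures, centered so that the
#' healthy-volunteer (NHV) reference averages exactly zero:
#'
#'   score_j = sum_{s in S} ES_sj - mean_{h in NHV} sum_{s in S} ES_sh
#'
#' Zero is therefore "molecular health" and the score reads as total
#' molecular dysregulation at equal signature weight — an assumption
#' justified when the signatures share few genes (see [overlap_summary()]).
#'
#' @param es signatures x samples ES matrix.
#' @param signature_set character ids of the selected signatures (rows of
#'   `es`); typically the shared upregulated set from [run_baseline()].
#' @param nhv_ids sample ids of the healthy reference used for centering.
#'   NHV samples are themselves scored; centering uses them as reference.
#' @param offset optional pre-computed centering offset (the uncentered NHV
#'   mean sum) carried over from a training cohort when the scored cohort
#'   has no healthy samples of its own. Overrides `nhv_ids`.
#' @return object of class `imds_result`: list with `scores` (named numeric,
#'   one per sample), `offset`, `signature_set`, `nhv_ids`.
#' @export
compute_imds <- function(es, signature_set, nhv_ids = NULL, offset = NULL) {
  stopifnot(is.matrix(es))
  signature_set <- unique(as.character(signature_set))
  if (!length(signature_set)) stop("signature_set is empty")
  miss <- setdiff(signature_set, rownames(es))
  if (length(miss))
    stop("signature(s) missing from ES matrix: ", paste(miss, collapse = ", "))
  sums <- colSums(es[signature_set, , drop = FALSE])
  if (is.null(offset)) {
    if (is.null(nhv_ids) || !length(nhv_ids))
      stop("provide nhv_ids for centering, or a carried-over offset")
    missh <- setdiff(nhv_ids, colnames(es))
    if (length(missh))
      stop("NHV sample(s) missing from ES matrix: ",
           paste(missh, collapse = ", "))
    offset <- mean(sums[nhv_ids])
  }
  structure(list(scores = sums - offset, offset = offset,
                 signature_set = signature_set,
                 nhv_ids = nhv_ids %||% character(0)),
            class = "imds_result")
}

#' @export
print.imds_result <- function(x, ...) {
  cat(sprintf("imds_result: %d sample(s), %d signature(s), offset %.3f\n",
              length(x$scores), length(x$signature_set), x$offset))
  print(summary(x$scores))
  invisible(x)
}

#' Classify samples by score threshold
#'
#' A sample strictly below the cutoff is called responder-like (treatment
#' recommendation); a score at or above the cutoff is nonresponder-like.
#' The published operating point on the training cohort is 32.
#'
#' @param result an `imds_result`, or a named numeric score vector.
#' @param threshold classification cutoff (default 32).
#' @param boundary class assigned at a score exactly equal to the cutoff
#'   (default `"nonresponder-like"`, the stated rule).
#' @return named character vector of predicted classes.
#' @export
classify_imds <- function(result, threshold = 32,
                          boundary = c("nonresponder-like",
                                       "responder-like")) {
  boundary <- match.arg(boundary)
  scores <- if (inherits(result, "imds_result")) result$scores else result
  cls <- ifelse(scores < threshold, "responder-like", "nonresponder-like")
  if (boundary == "responder-like")
    cls[scores == threshold] <- "responder-like"
  stats::setNames(cls, names(scores))
}

#' Confusion metrics against clinical response labels
#'
#' Sensitivity is the fraction of clinical responders called
#' responder-like; specificity the fraction of clinical non-responders
#' called nonresponder-like. The full confusion table is returned so either
#' orientation convention can be checked.
#'
#' @param predicted character vector of classes from [classify_imds()].
#' @param labels clinical labels, "R" or "NR", parallel to `predicted`
#'   (or named by the same sample ids).
#' @return list with `sensitivity`, `specificity`, and `table` (2x2 counts,
#'   predicted x clinical).
#' @export
confusion_metrics <- function(predicted, labels) {
  if (!is.null(names(predicted)) && !is.null(names(labels)))
    labels <- labels[names(predicted)]
  labels <- as.character(labels)
  if (!all(labels %in% c("R", "NR")))
    stop("clinical labels must be 'R' or 'NR'")
  if (length(predicted) != length(labels))
    stop("predicted and labels differ in length")
  tab <- table(factor(predicted, c("responder-like", "nonresponder-like")),
               factor(labels, c("R", "NR")), dnn = c("predicted", "clinical"))
  sens <- tab["responder-like", "R"] / sum(tab[, "R"])
  spec <- tab["nonresponder-like", "NR"] / sum(tab[, "NR"])
  list(sensitivity = unname(sens), specificity = unname(spec), table = tab)
}

#' Scan score thresholds against clinical labels
#'
#' Candidate cutoffs are the midpoints between consecutive sorted unique
#' scores (plus one below the minimum and one above the maximum). Two
#' selection rules: `"max_specificity_first"` maximizes sensitivity subject
#' to specificity = 1 (the operating philosophy behind the published
#' cutoff: never recommend anti-TNF to a molecular non-responder);
#' `"youden"` maximizes sensitivity + specificity - 1. Ties break to the
#' lowest qualifying threshold.
#'
#' @param scores named numeric score vector (baseline patient samples).
#' @param labels clinical labels "R"/"NR" parallel to (or named like)
#'   `scores`.
#' @param criterion threshold-selection rule.
#' @return list with `threshold`, `sensitivity`, `specificity` at that
#'   threshold, and `scan`, the full data.frame of candidates.
#' @export
choose_threshold <- function(scores, labels,
                             criterion = c("max_specificity_first",
                                           "youden")) {
  criterion <- match.arg(criterion)
  if (!is.null(names(scores)) && !is.null(names(labels)))
    labels <- labels[names(scores)]
  labels <- as.character(labels)
  if (!all(c("R", "NR") %in% labels))
    stop("both clinical classes R and NR must be present")
  u <- sort(unique(scores))
  cand <- c(u[1L] - 1, (u[-1L] + u[-length(u)]) / 2, u[length(u)] + 1)
  scan <- do.call(rbind, lapply(cand, function(th) {
    pred <- ifelse(scores < th, "responder-like", "nonresponder-like")
    m <- confusion_metrics(pred, labels)
    data.frame(threshold = th, sensitivity = m$sensitivity,
               specificity = m$specificity)
  }))
  pick <- switch(criterion,
    max_specificity_first = {
      ok <- which(scan$specificity == 1)
      ok[which.max(scan$sensitivity[ok])]  # which.max: first (lowest) tie
    },
    youden = which.max(scan$sensitivity + scan$specificity - 1))
  list(threshold = scan$threshold[pick],
       sensitivity = scan$sensitivity[pick],
       specificity = scan$specificity[pick],
       scan = scan)
}
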