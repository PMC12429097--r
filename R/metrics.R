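# Evaluation of binary pathogenicity predictions against harmonized
# germline categories: the binary-grouped accuracy rule, label-flip-
# invariant score metrics (AUROC_sym, balanced accuracy, MCC_sym), and
# per-category redistribution bookkeeping.

#' Binary-grouped prediction accuracy
#'
#' The original eight germline categories are collapsed into a benign group
#' (default: benign, benign/likely benign, likely benign) versus everything
#' else. A prediction of `"benign"` is correct only for variants in the
#' benign group; a prediction of `"pathogenic"` is correct for every other
#' variant. Note this rule systematically favours predictors that force
#' ambiguous categories into pathogenic.
#'
#' @param predictions Named character vector: variant ->
#'   `"benign"`/`"pathogenic"`.
#' @param categories Named character vector: variant -> germline category.
#'   Every variant in `categories` must be covered by `predictions`.
#' @param grouping Character vector of categories forming the benign group.
#' @return Fraction of correct predictions in `[0, 1]`.
#' @export
grouped_accuracy <- function(predictions, categories,
                             grouping = benign_group()) {
  uncovered <- setdiff(names(categories), names(predictions))
  if (length(uncovered) > 0) {
    stop("predictions do not cover variant(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  pred <- predictions[names(categories)]
  in_benign <- categories %in% grouping
  correct <- (pred == "benign" & in_benign) |
    (pred == "pathogenic" & !in_benign)
  mean(correct)
}

mcc_from_confusion <- function(tp, tn, fp, fn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Label-flip-invariant classifier metrics
#'
#' Scores a continuous statistic against binary labels with metrics that
#' are invariant under globally complementing the labels:
#' `auroc_sym = max(AUROC, 1 - AUROC)` (mid-rank tie treatment, via
#' \pkg{pROC}), `mcc_sym = |MCC|` at the operating threshold, and balanced
#' accuracy (mean of class-conditional recalls) at the same threshold.
#' AUROC_sym and MCC_sym are minimal flip-invariant symmetrizations of the
#' usual metrics and are implementation-defined choices.
#'
#' The operating threshold defaults to the midpoint between the extrema of
#' the two classes (the classifier's single operating point); the class
#' with the higher mean score is predicted on the high side of the
#' threshold, so all three metrics are unchanged by a label complement.
#'
#' @param scores Numeric statistic values.
#' @param labels Binary labels aligned with `scores` (any two values).
#' @param threshold Optional explicit operating threshold.
#' @return List with `auroc_sym`, `balanced_accuracy`, `mcc_sym`,
#'   `threshold`, `confusion` (named counts `tp`, `tn`, `fp`, `fn` with the
#'   high-scoring class as positive).
#' @export
symmetric_metrics <- function(scores, labels, threshold = NULL) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2) {
    stop("labels must contain exactly two classes", call. = FALSE)
  }
  if (any(is.na(scores))) stop("missing scores", call. = FALSE)

  means <- tapply(scores, labels, mean)
  positive <- names(means)[which.max(means)]   # high-score class
  negative <- setdiff(classes, positive)

  roc <- pROC::roc(response = factor(labels, levels = c(negative, positive)),
                   predictor = scores, quiet = TRUE, direction = "<")
  auroc <- as.numeric(pROC::auc(roc))
  auroc_sym <- max(auroc, 1 - auroc)

  if (is.null(threshold)) {
    threshold <- (max(scores[labels == negative]) +
                    min(scores[labels == positive])) / 2
  }
  pred_pos <- scores > threshold
  is_pos <- labels == positive
  tp <- sum(pred_pos & is_pos)
  tn <- sum(!pred_pos & !is_pos)
  fp <- sum(pred_pos & !is_pos)
  fn <- sum(!pred_pos & is_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_

  list(
    auroc_sym = auroc_sym,
    balanced_accuracy = mean(c(sens, spec)),
    mcc_sym = abs(mcc_from_confusion(tp, tn, fp, fn)),
    threshold = threshold,
    confusion = c(tp = tp, tn = tn, fp = fp, fn = fn)
  )
}

#' Per-category redistribution by predictor
#'
#' For each tool, cross-tabulates the original germline category against
#' the tool's binary call, mirroring stacked redistribution bar charts.
#' Marginals over calls equal the original category counts.
#'
#' @param predictions Tibble with columns `variant`, `tool`, `call`.
#' @param categories Named character vector: variant -> germline category.
#' @return Tibble with columns `tool`, `category`, `benign`, `pathogenic`.
#' @export
redistribution_by_predictor <- function(predictions, categories) {
  if (nrow(predictions) == 0) {
    return(tibble(tool = character(), category = character(),
                  benign = integer(), pathogenic = integer()))
  }
  predictions |>
    dplyr::group_split(.data$tool) |>
    purrr::map(function(p) {
      tool <- p$tool[1]
      calls <- setNames(p$call, p$variant)
      out <- redistribute(categories[names(calls)], calls)
      out$tool <- tool
      out
    }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("tool")
}
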