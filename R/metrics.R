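#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, sensitivity (accuracy on actives) and specificity
#' (accuracy on inactives) as exact fractions from confusion counts; no
#' rounding is applied internally.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts; both classes must be
#'   represented (`tp + fn >= 1`, `tn + fp >= 1`).
#' @param auc Optional AUC to carry along (default `NA`).
#' @return A one-row tibble of class `model_metrics` with columns `acc`,
#'   `se`, `sp`, `auc`, `tp`, `fn`, `tn`, `fp`.
#' @examples
#' confusion_metrics(tp = 117, fn = 18, tn = 38, fp = 5)
#' @export
confusion_metrics <- function(tp, fn, tn, fp, auc = NA_real_) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts))) {
    hs_config_error("confusion counts must be non-negative integers")
  }
  if (tp + fn < 1) hs_data_error("no positive samples: sensitivity undefined")
  if (tn + fp < 1) hs_data_error("no negative samples: specificity undefined")
  out <- tibble::tibble(
    acc = (tp + tn) / (tp + tn + fp + fn),
    se = tp / (tp + fn),
    sp = tn / (tn + fp),
    auc = auc,
    tp = as.integer(tp), fn = as.integer(fn),
    tn = as.integer(tn), fp = as.integer(fp)
  )
  class(out) <- c("model_metrics", class(out))
  out
}

#' Area under the ROC curve (Mann-Whitney pair statistic)
#'
#' AUC computed as the fraction of (active, inactive) pairs in which the
#' active sample scores strictly higher, counting ties as one half - the
#' exact Mann-Whitney U formulation, invariant under any strictly monotone
#' transform of the scores.
#'
#' @param scores Numeric score per sample (higher = more active-like).
#' @param labels Binary labels aligned with `scores`; the level named
#'   `"active"` (or logical `TRUE`) is the positive class.
#' @return A single number in \[0, 1\].
#' @examples
#' auc_score(c(0.9, 0.4, 0.6, 0.1), c("active", "active", "inactive", "inactive"))
#' @export
auc_score <- function(scores, labels) {
  pos <- as_active(labels)
  if (!any(pos) || all(pos)) {
    hs_data_error("both classes must be present to compute AUC")
  }
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Coerce assorted label encodings to logical "is active".
as_active <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- tolower(as.character(labels))
  if (all(l %in% c("active", "inactive"))) return(l == "active")
  if (all(l %in% c("1", "0"))) return(l == "1")
  if (all(l %in% c("true", "false"))) return(l == "true")
  hs_data_error("cannot interpret labels as binary active/inactive")
}
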