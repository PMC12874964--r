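#' Evaluation metrics for presence/absence scores
#'
#' Computes the two evaluation statistics used for single-model screening:
#' ROC AUC, defined as the fraction of concordant (presence, absence) score
#' pairs with ties counted one half, and the maximum True Skill Statistic
#' (sensitivity + specificity - 1) over the threshold grid
#' `0.00, 0.01, ..., 1.00`, where a row is classified presence when its score
#' is at least the threshold. The smallest maximizing threshold is reported.
#'
#' @param scores numeric scores in `[0, 1]`, higher meaning more
#'   presence-like.
#' @param labels presence/absence labels (logical, or 0/1).
#' @return a one-row tibble: `roc_auc`, `tss`, `best_threshold`,
#'   `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length", call. = FALSE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present", call. = FALSE)
  # rank-sum form of the concordant-pair count (ties get 1/2)
  r <- rank(scores)
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- seq(0, 1, by = 0.01)
  sens <- vapply(thresholds, function(t) sum(scores[labels] >= t) / n_pos, numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores[!labels] < t) / n_neg, numeric(1))
  tss <- sens + spec - 1
  best <- which.max(tss) # which.max returns the first (smallest) maximizer
  tibble::tibble(
    roc_auc = auc,
    tss = tss[best],
    best_threshold = thresholds[best],
    sensitivity = sens[best],
    specificity = spec[best]
  )
}
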