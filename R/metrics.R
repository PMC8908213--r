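#' Annotation and retrieval metrics
#'
#' `precision_recall_f` scores a predicted ontology-class set against a gold
#' set: precision is the fraction of predictions that are correct, recall
#' the fraction of gold classes found, and the F-measure their harmonic
#' mean, `2PR/(P+R)` (0 when `P + R = 0`).
#'
#' `average_precision_at_k` is truncated average precision: the mean of the
#' precision values at the ranks of relevant items found in the top `k`,
#' normalized by `min(|relevant|, k)`; `map_at_k` averages it over queries
#' (mAP@k).
#'
#' `auc_pr` is the trapezoidal area under a precision-recall curve obtained
#' by sweeping the association threshold, computed over recall-sorted points
#' and clipped to `[0, 1]`.
#'
#' @param predicted Character vector of predicted classes (may be empty).
#' @param gold Non-empty character vector of gold classes.
#' @return `precision_recall_f` returns a named numeric vector
#'   `c(precision, recall, f_measure)`.
#' @export
precision_recall_f <- function(predicted, gold) {
  predicted <- unique(predicted)
  gold <- unique(gold)
  correct <- length(intersect(predicted, gold))
  p <- if (length(predicted)) correct / length(predicted) else 0
  r <- if (length(gold)) correct / length(gold) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f_measure = f)
}

#' @rdname precision_recall_f
#' @param ranked Duplicate-free ranked result list (best first).
#' @param relevant Set of relevant items.
#' @param k Truncation rank (`>= 1`).
#' @export
average_precision_at_k <- function(ranked, relevant, k = 10L) {
  stopifnot(k >= 1L)
  relevant <- unique(relevant)
  if (!length(relevant)) return(0)
  if (anyDuplicated(ranked)) stop("ranked list contains duplicates", call. = FALSE)
  top <- utils::head(ranked, k)
  hits <- which(top %in% relevant)
  if (!length(hits)) return(0)
  prec_at <- vapply(seq_along(hits), function(i) i / hits[i], numeric(1))
  sum(prec_at) / min(length(relevant), k)
}

#' @rdname precision_recall_f
#' @param ranked_lists List of ranked result vectors, one per query.
#' @param relevant_sets List of relevant sets, parallel to `ranked_lists`.
#' @export
map_at_k <- function(ranked_lists, relevant_sets, k = 10L) {
  stopifnot(length(ranked_lists) == length(relevant_sets))
  if (!length(ranked_lists)) return(NA_real_)
  mean(mapply(average_precision_at_k, ranked_lists, relevant_sets,
              MoreArgs = list(k = k)))
}

#' @rdname precision_recall_f
#' @param points A data.frame or matrix with columns `recall` and
#'   `precision` (at least two rows).
#' @export
auc_pr <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("recall", "precision") %in% names(points)))
  if (nrow(points) < 2L) {
    stop("auc_pr needs at least two (recall, precision) points", call. = FALSE)
  }
  ord <- order(points$recall, points$precision)
  r <- points$recall[ord]
  p <- points$precision[ord]
  area <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  min(max(area, 0), 1)
}
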