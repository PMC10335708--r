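#' Area under the precision-recall curve
#'
#' Unseen cells are the positives and the uncertainty score is the ranking
#' statistic. The area is computed by step integration of the PR curve
#' (average precision over distinct score thresholds, descending), with no
#' trapezoidal interpolation. A constant score gives the positive
#' prevalence, the random-classifier baseline.
#'
#' @param scores numeric vector, higher = more likely positive.
#' @param positive logical vector marking true positives.
#' @return Scalar AUPRC.
#' @export
auprc <- function(scores, positive) {
  if (length(scores) != length(positive)) {
    stop("scores and mask lengths differ", call. = FALSE)
  }
  positive <- as.logical(positive)
  n_pos <- sum(positive)
  if (n_pos == 0 || n_pos == length(positive)) {
    stop("need at least one positive and one negative", call. = FALSE)
  }
  o <- order(-scores)
  s <- scores[o]
  y <- positive[o]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- c(s[-1] != s[-length(s)], TRUE) # last index per distinct score
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' F1 score for "unassigned" calls against the true unseen mask
#'
#' `"unassigned"` is the positive call. Conventions for degenerate cases:
#' nothing flagged and nothing truly unseen gives 1; nothing flagged with
#' unseen cells present gives 0.
#'
#' @param pred_labels character vector of final labels (possibly containing
#'   `"unassigned"`).
#' @param unseen logical vector marking truly unseen cells.
#' @return Scalar F1.
#' @export
f1_unassigned <- function(pred_labels, unseen) {
  if (length(pred_labels) != length(unseen)) {
    stop("labels and mask lengths differ", call. = FALSE)
  }
  called <- pred_labels == "unassigned"
  unseen <- as.logical(unseen)
  tp <- sum(called & unseen)
  if (!any(called)) return(if (!any(unseen)) 1 else 0)
  if (tp == 0) return(0)
  precision <- tp / sum(called)
  recall <- tp / sum(unseen)
  2 * precision * recall / (precision + recall)
}

#' Annotation accuracy with unseen cells scored via "unassigned"
#'
#' A cell counts as correct when it is a shared-type cell predicted with
#' its true label, or an unseen-type cell predicted `"unassigned"`.
#'
#' @param pred_labels character vector of final labels.
#' @param true_labels character vector of true labels.
#' @param unseen logical vector marking truly unseen cells.
#' @return Fraction of correctly annotated cells.
#' @export
annotation_accuracy <- function(pred_labels, true_labels, unseen) {
  n <- length(pred_labels)
  if (length(true_labels) != n || length(unseen) != n) {
    stop("input lengths differ", call. = FALSE)
  }
  unseen <- as.logical(unseen)
  correct <- ifelse(unseen, pred_labels == "unassigned",
                    pred_labels == true_labels)
  mean(correct)
}

#' Accuracy-ratio index between two paired score vectors
#'
#' The ratio of the number of paired tests in which A outperforms B to the
#' number in which it performs worse; ties are excluded from both counts.
#' Greater than 1 means A wins overall. Returns `Inf` when A never loses
#' but wins at least once, and `NA` when all pairs tie.
#'
#' @param a,b paired per-test scores.
#' @return Scalar ratio (possibly `Inf` or `NA`).
#' @export
ar_index <- function(a, b) {
  if (length(a) != length(b)) stop("paired scores required", call. = FALSE)
  wins <- sum(a > b)
  losses <- sum(a < b)
  if (wins == 0 && losses == 0) return(NA_real_)
  if (losses == 0) return(Inf)
  wins / losses
}

#' Oracle thresholding at the true unseen proportion
#'
#' Flags the cells above the `(1 - p) * 100`% quantile of the score, i.e.
#' the top `floor(p * n)` cells by nearest rank (so `p -> 0` flags
#' nothing). Ties at the cut are flagged inclusively, which can flag
#' slightly more than `floor(p * n)` cells.
#'
#' @param m per-cell uncertainty scores (higher = more uncertain).
#' @param p true unseen proportion, strictly between 0 and 1.
#' @return Logical mask of flagged cells.
#' @export
threshold_from_true_proportion <- function(m, p) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1) {
    stop("p must lie strictly between 0 and 1", call. = FALSE)
  }
  k <- floor(p * length(m))
  if (k == 0) return(rep(FALSE, length(m)))
  cut <- sort(m, decreasing = TRUE)[k]
  m >= cut
}

#' Build leave-one-cell-type-out benchmark tests
#'
#' One test per cell type shared by every reference and the query: in each
#' test that type's cells are removed from all references (the query is
#' untouched), simulating a query-only unseen type. The truth mask marks
#' query cells whose type is absent from every post-removal reference.
#'
#' @param references list of labeled [labeled_dataset()] objects.
#' @param query a [labeled_dataset()].
#' @param query_labels true query labels (defaults to `query$labels`).
#' @return List of `benchmark_test` objects with elements `references`,
#'   `query`, `held_out_type`, `unseen_mask`, `p`.
#' @export
make_benchmark_tests <- function(references, query,
                                 query_labels = query$labels) {
  if (is.null(query_labels)) {
    stop("query labels required to build benchmark tests", call. = FALSE)
  }
  ref_type_sets <- lapply(references, function(r) unique(r$labels))
  shared <- Reduce(intersect, c(ref_type_sets, list(unique(query_labels))))
  if (!length(shared)) {
    stop("no cell type is shared by every reference and the query",
         call. = FALSE)
  }
  lapply(sort(shared), function(held) {
    refs2 <- lapply(references, function(r) {
      keep <- r$labels != held
      labeled_dataset(r$matrix[keep, , drop = FALSE],
                      cells = r$cells[keep], labels = r$labels[keep],
                      stage = r$stage)
    })
    remaining <- unique(unlist(lapply(refs2, function(r) r$labels)))
    stopifnot(!held %in% remaining)
    unseen_mask <- !(query_labels %in% remaining)
    structure(
      list(references = refs2, query = query, held_out_type = held,
           unseen_mask = unseen_mask, p = mean(unseen_mask)),
      class = "benchmark_test")
  })
}

#' Per-model accuracies of the base classifiers
#'
#' Annotation accuracy of each base model's hard labels against the truth
#' (base models cannot abstain, so unseen cells always count wrong for
#' them). Used to verify that the ensemble beats its parts.
#'
#' @param stack a [prediction_stack()].
#' @param true_labels true query labels.
#' @param unseen logical unseen mask.
#' @return Numeric vector of per-model accuracies.
#' @export
base_model_accuracies <- function(stack, true_labels, unseen) {
  apply(stack$hard, 1, function(idx) {
    annotation_accuracy(stack$vocabulary[idx], true_labels, unseen)
  })
}
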