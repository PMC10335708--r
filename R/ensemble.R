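#' Assemble base-model predictions into a prediction stack
#'
#' Collects the per-model query probability matrices, their hard labels, and
#' the per-type subset counts `L` (the number of retained reference subsets
#' whose label set contains each type — the vote normalizer).
#'
#' @param probs list of probability matrices (cells x vocabulary), one per
#'   trained base model, identical dimensions and column order.
#' @param subsets the `reference_subset` list the models were trained on
#'   (same order), used to count `L`.
#' @param vocabulary global ordered cell-type vocabulary.
#' @return A `prediction_stack`: list with `probs`, `hard` (models x cells
#'   integer matrix of vocabulary indices), `L` (named integer vector) and
#'   `vocabulary`.
#' @export
prediction_stack <- function(probs, subsets, vocabulary) {
  if (!length(probs)) stop("empty prediction list", call. = FALSE)
  if (length(probs) != length(subsets)) {
    stop("probs and subsets lengths differ", call. = FALSE)
  }
  K <- length(vocabulary)
  n <- nrow(probs[[1]])
  for (P in probs) {
    if (nrow(P) != n || ncol(P) != K) {
      stop("inconsistent probability matrix dimensions", call. = FALSE)
    }
    if (any(abs(rowSums(P) - 1) > 1e-6) || any(P < 0)) {
      stop("probability rows must sum to 1", call. = FALSE)
    }
  }
  L <- subset_counts(subsets, vocabulary)
  hard <- t(vapply(probs, function(P) max.col(P, ties.method = "first"),
                   integer(n)))
  structure(list(probs = probs, hard = hard, L = L, vocabulary = vocabulary,
                 n_cells = n),
            class = "prediction_stack")
}

#' @export
print.prediction_stack <- function(x, ...) {
  cat("<prediction_stack> ", length(x$probs), " base models x ", x$n_cells,
      " cells x ", length(x$vocabulary), " types\n", sep = "")
  cat("  L:", paste0(x$vocabulary, "=", x$L, collapse = ", "), "\n")
  invisible(x)
}

#' Hard labels from a probability matrix
#'
#' Per-cell argmax over the vocabulary; ties resolve to the lowest
#' vocabulary index for reproducibility.
#'
#' @param probs probability matrix (cells x vocabulary), columns named.
#' @return Character vector of predicted labels.
#' @export
hard_labels <- function(probs) {
  if (is.null(colnames(probs))) {
    stop("probs must carry the vocabulary as column names", call. = FALSE)
  }
  colnames(probs)[max.col(probs, ties.method = "first")]
}

#' Count reference subsets carrying each cell type
#'
#' `L_k` is the number of usable (retained) reference subsets whose label
#' set contains type `k`. Subsets dropped at the gene-overlap floor are
#' excluded from both the vote numerator and this denominator.
#'
#' @param subsets list of `reference_subset` objects.
#' @param vocabulary global ordered cell-type vocabulary.
#' @return Named integer vector `L` over the vocabulary.
#' @export
subset_counts <- function(subsets, vocabulary) {
  L <- vapply(vocabulary, function(k) {
    sum(vapply(subsets, function(s) k %in% s$labels, logical(1)))
  }, integer(1))
  if (any(L == 0)) {
    stop("cell type(s) with no supporting subset: ",
         paste(vocabulary[L == 0], collapse = ", "),
         " (vocabulary must be built from the retained references)",
         call. = FALSE)
  }
  L
}

# Internal: n_cells x K matrix of vote counts divided by L.
.normalized_vote_matrix <- function(stack) {
  K <- length(stack$vocabulary)
  counts <- matrix(0, stack$n_cells, K)
  for (mdl in seq_len(nrow(stack$hard))) {
    idx <- cbind(seq_len(stack$n_cells), stack$hard[mdl, ])
    counts[idx] <- counts[idx] + 1
  }
  sweep(counts, 2, stack$L, "/")
}

#' Consensus annotation by normalized majority vote
#'
#' Per cell, each type's score is the number of base models voting for it
#' divided by `L_k`, the number of subsets carrying that type; the label is
#' the argmax (ties to the lowest vocabulary index). The normalization lets
#' a type present in only one reference win with proportionally fewer raw
#' votes, preserving single-reference-specific types. When every `L_k` is
#' equal this reduces exactly to a plain majority vote.
#'
#' @param stack a [prediction_stack()].
#' @return Character vector of consensus labels (the metaphase annotation).
#' @export
majority_vote <- function(stack) {
  stopifnot(inherits(stack, "prediction_stack"))
  scores <- .normalized_vote_matrix(stack)
  stack$vocabulary[max.col(scores, ties.method = "first")]
}
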