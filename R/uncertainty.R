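#' Shannon entropy (base 2) of a probability vector
#'
#' `0 * log2(0)` is taken as 0; the result lies in `[0, log2(length(p))]`.
#'
#' @param p nonnegative numeric vector summing to 1 (within 1e-6).
#' @return Scalar entropy in bits.
#' @export
entropy <- function(p) {
  if (any(p < 0)) stop("negative probabilities", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6) {
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  h <- p * log2(p)
  h[!is.finite(h)] <- 0
  -sum(h)
}

#' Intra-model uncertainty: mean per-model prediction entropy
#'
#' For each cell, the entropy of each base model's predicted probability
#' vector, averaged over all models. High when no single type dominates
#' within the individual classifiers.
#'
#' @param stack a [prediction_stack()].
#' @return Numeric vector, one value per query cell.
#' @export
intra_model_metric <- function(stack) {
  stopifnot(inherits(stack, "prediction_stack"))
  ent <- vapply(stack$probs, .row_entropy2, numeric(stack$n_cells))
  if (stack$n_cells == 1L) ent <- matrix(ent, nrow = 1)
  rowMeans(ent)
}

#' Inter-model uncertainty: entropy of the pooled probability profile
#'
#' Base-model probabilities are summed per type and divided by `L_k` (the
#' number of subsets carrying the type), the resulting profile is
#' row-normalized to a probability vector, and its entropy taken. High when
#' no type has high confidence in the model pool as a whole.
#'
#' @param stack a [prediction_stack()].
#' @return Numeric vector, one value per query cell.
#' @export
inter_model_metric <- function(stack) {
  stopifnot(inherits(stack, "prediction_stack"))
  Q <- Reduce(`+`, stack$probs)
  Q <- sweep(Q, 2, stack$L, "/")
  Qt <- Q / rowSums(Q)
  .row_entropy2(Qt)
}

#' Inter-prediction uncertainty: entropy of the vote distribution
#'
#' Like [inter_model_metric()] but pooling the hard-assignment labels
#' rather than the probabilities: the `L_k`-normalized vote counts are
#' row-normalized and their entropy taken. High when the base models
#' disagree on the label.
#'
#' @param stack a [prediction_stack()].
#' @return Numeric vector, one value per query cell.
#' @export
inter_prediction_metric <- function(stack) {
  stopifnot(inherits(stack, "prediction_stack"))
  Q <- .normalized_vote_matrix(stack)
  rs <- rowSums(Q)
  stopifnot(all(rs > 0)) # every model votes, so rows cannot be empty
  .row_entropy2(Q / rs)
}

#' Ensemble uncertainty score
#'
#' Each raw metric is min-max scaled to `[0, 1]` over the query cells
#' independently (a constant metric scales to all zeros), and the ensemble
#' score `m` is the mean of the three scaled metrics.
#'
#' @param m1,m2,m3 raw per-cell metrics from [intra_model_metric()],
#'   [inter_model_metric()], [inter_prediction_metric()].
#' @return An `uncertainty_scores` data.frame with columns `m1`, `m2`,
#'   `m3`, `m1s`, `m2s`, `m3s`, `m`.
#' @export
ensemble_metric <- function(m1, m2, m3) {
  n <- length(m1)
  if (length(m2) != n || length(m3) != n) {
    stop("metric vectors must have equal length", call. = FALSE)
  }
  m1s <- .minmax_scale(m1)
  m2s <- .minmax_scale(m2)
  m3s <- .minmax_scale(m3)
  out <- data.frame(m1 = m1, m2 = m2, m3 = m3,
                    m1s = m1s, m2s = m2s, m3s = m3s,
                    m = (m1s + m2s + m3s) / 3)
  class(out) <- c("uncertainty_scores", class(out))
  out
}

#' Compute all uncertainty metrics for a prediction stack
#'
#' Convenience wrapper running the three per-cell metrics and their
#' ensemble in one call.
#'
#' @param stack a [prediction_stack()].
#' @return An `uncertainty_scores` data.frame (see [ensemble_metric()]).
#' @export
uncertainty_scores <- function(stack) {
  ensemble_metric(intra_model_metric(stack),
                  inter_model_metric(stack),
                  inter_prediction_metric(stack))
}
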