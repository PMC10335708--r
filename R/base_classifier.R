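#' Cross-entropy classification loss
#'
#' Mean negative log predicted probability of the true class (natural log,
#' the standard training convention; the uncertainty module separately uses
#' base-2 entropy and the two are never mixed).
#'
#' @param probs numeric matrix of predicted probabilities, cells in rows,
#'   classes in columns (columns named by the class vocabulary); every row
#'   must sum to 1 (within 1e-6).
#' @param labels character vector of true labels, all present in
#'   `colnames(probs)` (or in `vocabulary` when given).
#' @param vocabulary optional class vocabulary overriding `colnames(probs)`.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(probs, labels, vocabulary = colnames(probs)) {
  if (is.null(vocabulary)) {
    stop("probs must have column names or a vocabulary must be given",
         call. = FALSE)
  }
  if (length(labels) != nrow(probs)) {
    stop("labels length must equal nrow(probs)", call. = FALSE)
  }
  if (any(abs(rowSums(probs) - 1) > 1e-6) || any(probs < 0)) {
    stop("probs rows must be probability vectors", call. = FALSE)
  }
  idx <- match(as.character(labels), vocabulary)
  if (anyNA(idx)) {
    stop("labels outside the class vocabulary: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  -mean(log(probs[cbind(seq_len(nrow(probs)), idx)]))
}

#' Autoencoder reconstruction loss
#'
#' Mean squared reconstruction error summed over the reference and query
#' matrices: `||Xr_hat - Xr||_F^2 / (n_ref * p) + ||Xq_hat - Xq||_F^2 /
#' (n_query * p)`.
#'
#' @param ref_hat,ref reconstructed and observed reference matrices.
#' @param query_hat,query reconstructed and observed query matrices.
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(ref_hat, ref, query_hat, query) {
  if (!identical(dim(ref_hat), dim(ref))) {
    stop("reference reconstruction shape mismatch", call. = FALSE)
  }
  if (!identical(dim(query_hat), dim(query))) {
    stop("query reconstruction shape mismatch", call. = FALSE)
  }
  sum((ref_hat - ref)^2) / length(ref) +
    sum((query_hat - query)^2) / length(query)
}

# ---- internal network machinery -------------------------------------------

# Parameters: encoder p -> hidden[1] -> hidden[2] (ReLU), linear classifier
# hidden[2] -> K, decoder mirroring the encoder with a linear output layer.
.nn_init <- function(p, hidden, K) {
  he <- function(n_in, n_out) {
    matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  }
  h1 <- hidden[1]; h2 <- hidden[2]
  list(
    W1 = he(p, h1),  b1 = rep(0, h1),
    W2 = he(h1, h2), b2 = rep(0, h2),
    Wc = he(h2, K),  bc = rep(0, K),
    W3 = he(h2, h1), b3 = rep(0, h1),
    W4 = he(h1, p),  b4 = rep(0, p)
  )
}

.relu <- function(x) x * (x > 0)

.softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

.nn_encode <- function(par, X) {
  Z1 <- .relu(sweep(X %*% par$W1, 2, par$b1, "+"))
  Z2 <- .relu(sweep(Z1 %*% par$W2, 2, par$b2, "+"))
  list(Z1 = Z1, Z2 = Z2)
}

.nn_forward <- function(par, X) {
  enc <- .nn_encode(par, X)
  logits <- sweep(enc$Z2 %*% par$Wc, 2, par$bc, "+")
  D1 <- .relu(sweep(enc$Z2 %*% par$W3, 2, par$b3, "+"))
  Xhat <- sweep(D1 %*% par$W4, 2, par$b4, "+")
  list(Z1 = enc$Z1, Z2 = enc$Z2, logits = logits,
       probs = .softmax_rows(logits), D1 = D1, Xhat = Xhat)
}

# Full objective on given data (used for the per-epoch training log).
.nn_objective <- function(par, Xr, y_idx, Xq, lambda) {
  fr <- .nn_forward(par, Xr)
  fq <- .nn_forward(par, Xq)
  ce <- -mean(log(pmax(fr$probs[cbind(seq_along(y_idx), y_idx)], 1e-300)))
  re <- sum((fr$Xhat - Xr)^2) / length(Xr) + sum((fq$Xhat - Xq)^2) / length(Xq)
  list(ce = ce, re = re, total = ce + lambda * re)
}

# One gradient step on a mixed batch. `is_ref` marks reference rows (which
# contribute cross-entropy); reconstruction weights differ by origin so the
# minibatch gradient is an unbiased estimate of the full objective gradient.
.nn_gradients <- function(par, X, is_ref, y_idx, lambda, p) {
  f <- .nn_forward(par, X)
  m_r <- sum(is_ref); m_q <- sum(!is_ref)

  dlogits <- matrix(0, nrow(X), ncol(par$Wc))
  if (m_r > 0) {
    P <- f$probs[is_ref, , drop = FALSE]
    P[cbind(seq_len(m_r), y_idx)] <- P[cbind(seq_len(m_r), y_idx)] - 1
    dlogits[is_ref, ] <- P / m_r
  }

  w <- numeric(nrow(X))
  if (m_r > 0) w[is_ref] <- 1 / (m_r * p)
  if (m_q > 0) w[!is_ref] <- 1 / (m_q * p)
  dXhat <- 2 * lambda * (f$Xhat - X) * w

  dW4 <- crossprod(f$D1, dXhat); db4 <- colSums(dXhat)
  dD1 <- (dXhat %*% t(par$W4)) * (f$D1 > 0)
  dW3 <- crossprod(f$Z2, dD1); db3 <- colSums(dD1)
  dWc <- crossprod(f$Z2, dlogits); dbc <- colSums(dlogits)
  dZ2 <- (dlogits %*% t(par$Wc) + dD1 %*% t(par$W3)) * (f$Z2 > 0)
  dW2 <- crossprod(f$Z1, dZ2); db2 <- colSums(dZ2)
  dZ1 <- (dZ2 %*% t(par$W2)) * (f$Z1 > 0)
  dW1 <- crossprod(X, dZ1); db1 <- colSums(dZ1)

  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wc = dWc, bc = dbc,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}

#' Train one autoencoder-regularized base classifier
#'
#' Trains a small neural network on one reference subset: a two-layer ReLU
#' encoder, a linear softmax classifier head over the global cell-type
#' vocabulary, and a mirrored decoder. The objective is
#' `L_ce + lambda * L_re`, where the reconstruction term covers both
#' reference and query cells, letting the embedding adapt to the query
#' batch without using pseudo-labels. Optimized by Adam on shuffled
#' minibatches mixing reference and query rows; fully deterministic given
#' `seed`.
#'
#' @param subset a `reference_subset` from [build_reference_subsets()].
#' @param vocabulary global ordered cell-type vocabulary; classifier output
#'   dimension is its length, including types absent from this reference.
#' @param lambda reconstruction weight (default 1).
#' @param epochs training epochs (default 30).
#' @param hidden encoder layer widths (default `c(256, 64)`).
#' @param batch_size minibatch size (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed RNG seed controlling initialization and shuffling.
#' @return A `trained_base_model`: parameters, `genes`, `vocabulary`,
#'   `seed`, and `log` (data.frame of per-epoch cross-entropy,
#'   reconstruction and total loss, epoch 0 = initialization).
#' @export
train_base_model <- function(subset, vocabulary, lambda = 1, epochs = 30,
                             hidden = c(256, 64), batch_size = 128,
                             learning_rate = 1e-3, seed = 1L) {
  stopifnot(inherits(subset, "reference_subset"))
  Xr <- subset$ref_matrix
  Xq <- subset$query_matrix
  if (min(Xr) < -1e-9 || max(Xr) > 1 + 1e-9) {
    stop("subset matrices must be min-max scaled to [0, 1]", call. = FALSE)
  }
  y_idx <- match(subset$labels, vocabulary)
  if (anyNA(y_idx)) {
    stop("subset labels outside the vocabulary", call. = FALSE)
  }
  if (length(unique(y_idx)) < 2) {
    stop("subset has a single cell type; cannot train a classifier",
         call. = FALSE)
  }
  p <- ncol(Xr); K <- length(vocabulary)
  nr <- nrow(Xr); nq <- nrow(Xq)

  withr::with_seed(as.integer(seed), {
    par <- .nn_init(p, hidden, K)
    mstate <- lapply(par, function(x) x * 0)
    vstate <- lapply(par, function(x) x * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L

    log0 <- .nn_objective(par, Xr, y_idx, Xq, lambda)
    loss_log <- data.frame(epoch = 0L, ce = log0$ce, re = log0$re,
                           total = log0$total)

    all_idx <- c(seq_len(nr), nr + seq_len(nq))
    is_ref_all <- c(rep(TRUE, nr), rep(FALSE, nq))
    X_all <- rbind(Xr, Xq)

    for (ep in seq_len(epochs)) {
      perm <- sample(length(all_idx))
      n_steps <- ceiling(length(perm) / batch_size)
      for (s in seq_len(n_steps)) {
        take <- perm[((s - 1) * batch_size + 1):min(s * batch_size, length(perm))]
        Xb <- X_all[take, , drop = FALSE]
        rb <- is_ref_all[take]
        yb <- y_idx[all_idx[take][rb]]
        g <- .nn_gradients(par, Xb, rb, yb, lambda, p)
        step <- step + 1L
        for (nm in names(par)) {
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g[[nm]]
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g[[nm]]^2
          mhat <- mstate[[nm]] / (1 - beta1^step)
          vhat <- vstate[[nm]] / (1 - beta2^step)
          par[[nm]] <- par[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      obj <- .nn_objective(par, Xr, y_idx, Xq, lambda)
      if (!is.finite(obj$total)) {
        stop("non-finite training loss at epoch ", ep, " (ce = ", obj$ce,
             ", re = ", obj$re, "); lower the learning rate", call. = FALSE)
      }
      loss_log <- rbind(loss_log,
                        data.frame(epoch = ep, ce = obj$ce, re = obj$re,
                                   total = obj$total))
    }
  })

  structure(
    list(par = par, genes = subset$gene_set, vocabulary = vocabulary,
         hidden = hidden, lambda = lambda, seed = as.integer(seed),
         ref_index = subset$ref_index, method = subset$method,
         log = loss_log),
    class = "trained_base_model")
}

#' @export
print.trained_base_model <- function(x, ...) {
  n <- nrow(x$log)
  cat("<trained_base_model> ref", x$ref_index, "/", x$method, ": ",
      length(x$genes), " genes -> ", paste(x$hidden, collapse = " -> "),
      " -> ", length(x$vocabulary), " classes; loss ",
      round(x$log$total[1], 4), " -> ", round(x$log$total[n], 4),
      " over ", n - 1, " epochs\n", sep = "")
  invisible(x)
}

#' Predict class probabilities for query cells
#'
#' Softmax output of the classifier head on the encoder embedding. The query
#' matrix must be restricted to the model's gene list in identical order.
#'
#' @param model a `trained_base_model`.
#' @param query_matrix numeric matrix, cells x genes, column names equal to
#'   `model$genes`.
#' @return Probability matrix (cells x vocabulary), rows summing to 1.
#' @export
predict_proba <- function(model, query_matrix) {
  stopifnot(inherits(model, "trained_base_model"))
  if (is.null(colnames(query_matrix)) ||
      !identical(colnames(query_matrix), model$genes)) {
    stop("query matrix genes do not match the model's gene list (same ",
         "genes, same order, required)", call. = FALSE)
  }
  enc <- .nn_encode(model$par, query_matrix)
  logits <- sweep(enc$Z2 %*% model$par$Wc, 2, model$par$bc, "+")
  probs <- .softmax_rows(logits)
  dimnames(probs) <- list(rownames(query_matrix), model$vocabulary)
  probs
}
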