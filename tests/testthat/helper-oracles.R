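# Independent brute-force oracles: explicit loops, no shared code with the
# package implementations they check.

oracle_entropy <- function(p) {
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log2(v)
  h
}

oracle_m1 <- function(stack) {
  n <- stack$n_cells
  out <- numeric(n)
  for (c in seq_len(n)) {
    tot <- 0
    for (P in stack$probs) tot <- tot + oracle_entropy(P[c, ])
    out[c] <- tot / length(stack$probs)
  }
  out
}

oracle_m2 <- function(stack) {
  n <- stack$n_cells
  K <- length(stack$vocabulary)
  out <- numeric(n)
  for (c in seq_len(n)) {
    q <- numeric(K)
    for (k in seq_len(K)) {
      s <- 0
      for (P in stack$probs) s <- s + P[c, k]
      q[k] <- s / stack$L[k]
    }
    out[c] <- oracle_entropy(q / sum(q))
  }
  out
}

oracle_m3 <- function(stack) {
  n <- stack$n_cells
  K <- length(stack$vocabulary)
  out <- numeric(n)
  for (c in seq_len(n)) {
    q <- numeric(K)
    for (k in seq_len(K)) {
      votes <- 0
      for (mdl in seq_len(nrow(stack$hard))) {
        if (stack$hard[mdl, c] == k) votes <- votes + 1
      }
      q[k] <- votes / stack$L[k]
    }
    out[c] <- oracle_entropy(q / sum(q))
  }
  out
}

oracle_vote <- function(stack) {
  n <- stack$n_cells
  K <- length(stack$vocabulary)
  out <- character(n)
  for (c in seq_len(n)) {
    score <- numeric(K)
    for (k in seq_len(K)) {
      votes <- 0
      for (mdl in seq_len(nrow(stack$hard))) {
        if (stack$hard[mdl, c] == k) votes <- votes + 1
      }
      score[k] <- votes / stack$L[k]
    }
    best <- 1
    for (k in seq_len(K)) if (score[k] > score[best]) best <- k
    out[c] <- stack$vocabulary[best]
  }
  out
}

oracle_cross_entropy <- function(probs, labels, vocab) {
  tot <- 0
  for (c in seq_len(nrow(probs))) {
    for (k in seq_along(vocab)) {
      if (labels[c] == vocab[k]) tot <- tot - log(unname(probs[c, k]))
    }
  }
  tot / nrow(probs)
}

oracle_reconstruction <- function(rh, r, qh, q) {
  s1 <- 0
  for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r)))
    s1 <- s1 + (rh[i, j] - r[i, j])^2
  s2 <- 0
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q)))
    s2 <- s2 + (qh[i, j] - q[i, j])^2
  s1 / (nrow(r) * ncol(r)) + s2 / (nrow(q) * ncol(q))
}

# All-thresholds PR curve from explicit confusion tables.
oracle_auprc <- function(scores, positive) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  rec <- prec <- numeric(length(thresholds))
  for (t in seq_along(thresholds)) {
    called <- scores >= thresholds[t]
    tp <- sum(called & positive)
    fp <- sum(called & !positive)
    fn <- sum(!called & positive)
    prec[t] <- tp / (tp + fp)
    rec[t] <- tp / (tp + fn)
  }
  ap <- 0
  prev_rec <- 0
  for (t in seq_along(thresholds)) {
    ap <- ap + (rec[t] - prev_rec) * prec[t]
    prev_rec <- rec[t]
  }
  ap
}

oracle_f1 <- function(pred_labels, unseen) {
  tp <- sum(pred_labels == "unassigned" & unseen)
  fp <- sum(pred_labels == "unassigned" & !unseen)
  fn <- sum(pred_labels != "unassigned" & unseen)
  if (tp + fp == 0) return(if (sum(unseen) == 0) 1 else 0)
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

oracle_accuracy <- function(pred, truth, unseen) {
  ok <- 0
  for (c in seq_along(pred)) {
    if (unseen[c]) {
      if (pred[c] == "unassigned") ok <- ok + 1
    } else if (pred[c] == truth[c]) ok <- ok + 1
  }
  ok / length(pred)
}

oracle_ar <- function(a, b) {
  w <- 0; l <- 0
  for (i in seq_along(a)) {
    if (a[i] > b[i]) w <- w + 1
    if (a[i] < b[i]) l <- l + 1
  }
  if (w == 0 && l == 0) return(NA_real_)
  if (l == 0) return(Inf)
  w / l
}

# Posterior-evaluation oracle for 1-D mixture component assignment.
oracle_assign <- function(fit, x) {
  out <- integer(length(x))
  for (i in seq_along(x)) {
    post <- fit$weights * dnorm(x[i], fit$means, sqrt(fit$vars))
    best <- which(post == max(post))
    out[i] <- best[length(best)] # tie -> larger mean (sorted by mean)
  }
  out
}

# A random but valid prediction stack: random label sets per subset (union
# covering the vocabulary) and random probability rows.
make_random_stack <- function(n_models = 8, n_cells = 40, K = 5, seed = 1) {
  withr::with_seed(seed, {
    vocab <- paste0("t", seq_len(K))
    subsets <- lapply(seq_len(n_models), function(i) {
      types <- sample(vocab, sample(2:K, 1))
      if (i == 1) types <- vocab # guarantee coverage
      structure(list(labels = types), class = "reference_subset")
    })
    probs <- lapply(seq_len(n_models), function(i) {
      P <- matrix(rgamma(n_cells * K, shape = 1), n_cells, K)
      P <- P / rowSums(P)
      colnames(P) <- vocab
      P
    })
    prediction_stack(probs, subsets, vocab)
  })
}
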