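# A linearly separable two-type subset for training sanity checks.
make_separable_subset <- function(n_per_type = 100, n_genes = 40, seed = 13) {
  withr::with_seed(seed, {
    labels <- rep(c("A", "B"), each = n_per_type)
    n <- 2 * n_per_type
    m <- matrix(runif(n * n_genes, 0, 0.2), n, n_genes)
    m[labels == "A", 1:10] <- m[labels == "A", 1:10] + 0.8
    m[labels == "B", 11:20] <- m[labels == "B", 11:20] + 0.8
    m <- pmin(m, 1)
    genes <- paste0("g", seq_len(n_genes))
    colnames(m) <- genes
    rownames(m) <- paste0("r", seq_len(n))
    q <- m[seq(1, n, by = 2), , drop = FALSE]
    rownames(q) <- paste0("q", seq_len(nrow(q)))
    structure(list(ref_index = 1L, method = "DE", gene_set = genes,
                   ref_matrix = m, labels = labels, query_matrix = q,
                   ref_cells = rownames(m), query_cells = rownames(q)),
              class = "reference_subset")
  })
}

test_that("cross-entropy loss matches closed forms and the loop oracle", {
  vocab <- c("A", "B", "C", "D")
  onehot <- diag(4)
  colnames(onehot) <- vocab
  expect_equal(cross_entropy_loss(onehot, vocab), 0)

  uniform <- matrix(1 / 4, 3, 4, dimnames = list(NULL, vocab))
  expect_equal(cross_entropy_loss(uniform, c("A", "C", "D")), log(4))

  withr::with_seed(14, {
    P <- matrix(rgamma(6 * 4, 1), 6, 4)
    P <- P / rowSums(P)
    colnames(P) <- vocab
    y <- sample(vocab, 6, replace = TRUE)
    expect_equal(cross_entropy_loss(P, y), oracle_cross_entropy(P, y, vocab),
                 tolerance = 1e-12)
  })

  expect_error(cross_entropy_loss(uniform, c("A", "Z", "B")), "vocabulary")
})

test_that("reconstruction loss matches hand arithmetic and the oracle", {
  X <- matrix(1:6, 2, 3)
  expect_equal(reconstruction_loss(X, X, X + 0, X), 0)

  expect_equal(reconstruction_loss(matrix(2), matrix(1),
                                   matrix(5), matrix(3)), 1 + 4)

  withr::with_seed(15, {
    r <- matrix(rnorm(12), 3, 4); rh <- matrix(rnorm(12), 3, 4)
    q <- matrix(rnorm(8), 2, 4); qh <- matrix(rnorm(8), 2, 4)
    expect_equal(reconstruction_loss(rh, r, qh, q),
                 oracle_reconstruction(rh, r, qh, q), tolerance = 1e-12)
  })
  expect_error(reconstruction_loss(matrix(1), matrix(1:2), matrix(1),
                                   matrix(1)), "mismatch")
})

test_that("training reduces the objective and separates clean types", {
  s <- make_separable_subset()
  mdl <- train_base_model(s, vocabulary = c("A", "B"), epochs = 25,
                          hidden = c(16, 8), learning_rate = 3e-3, seed = 3)
  expect_lte(tail(mdl$log$total, 1), mdl$log$total[1])
  P <- predict_proba(mdl, s$ref_matrix)
  expect_gte(mean(hard_labels(P) == s$labels), 0.95)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)
})

test_that("with lambda = 0 the objective reduces to the cross-entropy", {
  s <- make_separable_subset(n_per_type = 30, seed = 16)
  mdl <- train_base_model(s, vocabulary = c("A", "B"), lambda = 0,
                          epochs = 5, hidden = c(8, 4), seed = 4)
  expect_equal(mdl$log$total, mdl$log$ce, tolerance = 1e-12)
})

test_that("training is bitwise deterministic given the seed", {
  s <- make_separable_subset(n_per_type = 25, seed = 17)
  m1 <- train_base_model(s, c("A", "B"), epochs = 4, hidden = c(8, 4),
                         seed = 99)
  m2 <- train_base_model(s, c("A", "B"), epochs = 4, hidden = c(8, 4),
                         seed = 99)
  expect_identical(m1$par, m2$par)
  expect_identical(m1$log, m2$log)
  m3 <- train_base_model(s, c("A", "B"), epochs = 4, hidden = c(8, 4),
                         seed = 100)
  expect_false(identical(m1$par, m3$par))
})

test_that("degenerate subsets and mismatched queries are rejected", {
  s <- make_separable_subset(n_per_type = 20, seed = 18)
  s_one <- s
  s_one$labels <- rep("A", length(s$labels))
  expect_error(train_base_model(s_one, c("A", "B")), "single cell type")

  mdl <- train_base_model(s, c("A", "B"), epochs = 2, hidden = c(8, 4),
                          seed = 5)
  bad <- s$query_matrix[, rev(seq_len(ncol(s$query_matrix)))]
  expect_error(predict_proba(mdl, bad), "gene list")
})

test_that("softmax head behaves: zero logits are uniform, shifts cancel", {
  s <- make_separable_subset(n_per_type = 20, seed = 19)
  mdl <- train_base_model(s, c("A", "B"), epochs = 2, hidden = c(8, 4),
                          seed = 6)
  # zero classifier head -> uniform rows regardless of the embedding
  mdl0 <- mdl
  mdl0$par$Wc[] <- 0
  mdl0$par$bc[] <- 0
  P0 <- predict_proba(mdl0, s$query_matrix)
  expect_equal(unname(P0), matrix(0.5, nrow(P0), 2), tolerance = 1e-12)

  # per-row constant logit shifts leave probabilities unchanged
  mdl_shift <- mdl
  mdl_shift$par$bc <- mdl$par$bc + 7.3
  expect_equal(predict_proba(mdl_shift, s$query_matrix),
               predict_proba(mdl, s$query_matrix), tolerance = 1e-9)
})
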