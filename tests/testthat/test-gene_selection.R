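# A small labeled dataset at the log stage with a planted marker in gene 1
# (high mean in type A only, tiny variance) and background noise elsewhere.
make_marker_ds <- function(n_per_type = 20, n_genes = 50, seed = 5) {
  withr::with_seed(seed, {
    labels <- rep(c("A", "B", "C"), each = n_per_type)
    n <- length(labels)
    m <- matrix(rlnorm(n * n_genes, 0, 0.3), n, n_genes,
                dimnames = list(paste0("c", 1:n), paste0("g", 1:n_genes)))
    m[labels == "A", 1] <- 5 + rnorm(n_per_type, 0, 0.01)
    m[labels != "A", 1] <- abs(rnorm(2 * n_per_type, 0, 0.01))
    labeled_dataset(m, labels = labels, stage = "log")
  })
}

test_that("a planted clean marker ranks first under the DE score", {
  ds <- make_marker_ds()
  tbl <- score_genes(ds, "DE")
  expect_equal(tbl$gene[which.max(tbl$score)], "g1")
  expect_equal(select_top_genes(tbl, 1), "g1")
})

test_that("a gene identically distributed across types lands in the bottom decile of DD", {
  withr::with_seed(6, {
    labels <- rep(c("A", "B"), each = 30)
    m <- matrix(0, 60, 40, dimnames = list(paste0("c", 1:60),
                                           paste0("g", 1:40)))
    shift <- rep(c(0, 1), each = 30)
    for (j in 1:39) m[, j] <- rlnorm(60, shift * 0.8, 0.3) # genes with signal
    m[, 40] <- rep(rlnorm(30, 0.4, 0.3), 2) # exactly equal across groups
    ds <- labeled_dataset(m, labels = labels, stage = "log")
    tbl <- score_genes(ds, "DD")
    expect_lte(rank(tbl$score)[40], 4) # bottom decile of 40 genes
    expect_lt(tbl$score[40], 0.2)
  })
})

test_that("an all-or-nothing detection pattern maximizes the DP score", {
  withr::with_seed(7, {
    labels <- rep(c("A", "B"), each = 15)
    m <- matrix(rpois(30 * 20, 2), 30, 20,
                dimnames = list(paste0("c", 1:30), paste0("g", 1:20)))
    m[, 1] <- c(rep(3, 15), rep(0, 15)) # 100% in A, 0% elsewhere
    ds <- labeled_dataset(m, labels = labels, stage = "log")
    tbl <- score_genes(ds, "DP")
    expect_equal(which.max(tbl$score), 1L)
  })
})

test_that("vectorized DV/DD/DP statistics match the base-R tests", {
  withr::with_seed(8, {
    labels <- rep(c("A", "B"), times = c(12, 18))
    grp <- labels == "A"
    m <- matrix(rlnorm(30 * 6, 0, 0.5) + rep(runif(6), each = 30), 30, 6)
    # no ties for the KS comparison (continuous draws)
    bart <- ensembleAnnot:::.bartlett_stat(m, grp)
    ks <- ensembleAnnot:::.ks_stat_cols(m, grp)
    m_pois <- matrix(rpois(30 * 6, 1), 30, 6)
    chi <- ensembleAnnot:::.detection_chisq(m_pois, grp)
    for (j in 1:6) {
      expect_equal(bart[j],
                   unname(bartlett.test(m[, j], labels)$statistic),
                   tolerance = 1e-10)
      expect_equal(ks[j],
                   unname(suppressWarnings(
                     ks.test(m[grp, j], m[!grp, j])$statistic)),
                   tolerance = 1e-10)
      tab <- table(factor(m_pois[, j] > 0, levels = c(FALSE, TRUE)),
                   factor(grp, levels = c(FALSE, TRUE)))
      if (all(rowSums(tab) > 0)) {
        expect_equal(chi[j],
                     unname(suppressWarnings(
                       chisq.test(tab, correct = FALSE)$statistic)),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("the Gini score matches closed forms and the pairwise oracle", {
  n <- 10
  m <- matrix(1, 4, 3, dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  m[, 2] <- c(9, 0, 0, 0) # expressed in exactly 1 of 4 cells
  withr::with_seed(9, m[, 3] <- rgamma(4, 1))
  ds <- labeled_dataset(m, stage = "libnorm")
  tbl <- score_genes(ds, "GC")
  expect_equal(tbl$score[1], 0)            # constant gene: perfect equality
  expect_equal(tbl$score[2], (4 - 1) / 4)  # single-expressor closed form

  # mean-absolute-difference oracle: G = sum_ij |xi - xj| / (2 n^2 mu)
  v <- m[, 3]
  gini_oracle <- sum(abs(outer(v, v, "-"))) / (2 * length(v)^2 * mean(v))
  expect_equal(tbl$score[3], gini_oracle, tolerance = 1e-12)
})

test_that("dispersion increases with variance at fixed mean", {
  withr::with_seed(10, {
    base <- rep(c(4, 8), each = 10)
    m <- matrix(rlnorm(20 * 30, 1, 0.4), 20, 30)
    m[, 1] <- base + rnorm(20, 0, 0.5)
    m[, 2] <- base + rnorm(20, 0, 0.5) * 2 # same mean bin, double spread
    m[, 2] <- m[, 2] - mean(m[, 2]) + mean(m[, 1]) # equalize means exactly
    m <- abs(m)
    ds <- labeled_dataset(m, stage = "libnorm")
    tbl <- score_genes(ds, "Disp")
    expect_gt(tbl$score[2], tbl$score[1])
  })
})

test_that("all-zero genes score zero under every method", {
  withr::with_seed(11, {
    labels <- rep(c("A", "B"), each = 10)
    m <- matrix(rpois(20 * 10, 3) + 1, 20, 10,
                dimnames = list(paste0("c", 1:20), paste0("g", 1:10)))
    m[, 4] <- 0
    ds_log <- labeled_dataset(m, labels = labels, stage = "log")
    ds_ln <- labeled_dataset(m, labels = labels, stage = "libnorm")
    for (mth in c("DE", "DV", "DD", "DP", "BI")) {
      expect_equal(score_genes(ds_log, mth)$score[4], 0, info = mth)
    }
    for (mth in c("GC", "Disp", "Vst")) {
      expect_equal(score_genes(ds_ln, mth)$score[4], 0, info = mth)
    }
  })
})

test_that("scoring preconditions are enforced", {
  ds <- tiny_dataset(labels = rep("A", 6))
  ds$stage <- "log"
  expect_error(score_genes(ds, "DE"), ">= 2 cell types")
  ds2 <- tiny_dataset(labels = c("A", rep("B", 5)))
  ds2$stage <- "log"
  expect_error(score_genes(ds2, "DV"), ">= 2 cells")
  ds3 <- tiny_dataset()
  expect_error(score_genes(ds3, "GC"), "requires stage")  # raw, not libnorm
})

test_that("top-gene selection is deterministic with stable tie-breaks", {
  tbl <- data.frame(gene = c("a", "b", "c"), score = c(3, 1, 2))
  class(tbl) <- c("gene_score_table", class(tbl))
  expect_equal(select_top_genes(tbl, 2), c("a", "c"))
  expect_equal(sort(select_top_genes(tbl, 3)), c("a", "b", "c"))
  expect_warning(all4 <- select_top_genes(tbl, 4), "exceeds")
  expect_equal(length(all4), 3)

  ties <- data.frame(gene = c("a", "b", "c"), score = c(1, 2, 2))
  expect_equal(select_top_genes(ties, 1), "b") # earlier gene wins the tie
  ties2 <- data.frame(gene = c("a", "b", "c"), score = c(2, 1, 2))
  expect_equal(select_top_genes(ties2, 1), "a")

  expect_equal(select_top_genes(tbl, min_score = 2), c("a", "c"))
  expect_error(select_top_genes(tbl[0, ], 1), "empty")
})

test_that("every supervised method recovers planted markers in its regime", {
  # Mean-, variance- and distribution-based statistics see the markers in
  # shallow zero-inflated count data.
  coll <- cached("marker_recovery_coll", {
    cfg <- simulation_config(n_refs = 1, cells_per_type = 80,
                             n_genes = 2000, n_markers_per_type = 30,
                             seed = 42)
    simulate_collection(cfg)
  })
  ref <- library_size_normalize(coll$references[[1]])
  ref_log <- log_transform(ref)
  markers <- unlist(coll$truth$marker_genes)
  for (mth in c("DE", "DV", "DD")) {
    top <- select_top_genes(score_genes(ref_log, mth), 500)
    expect_gte(mean(markers %in% top), 0.8)
  }

  # The detection-proportion statistic needs detection contrasts that are
  # not masked by uniform dropout; markers sitting on already-saturated
  # baseline genes are invisible to it by construction.
  coll_nd <- cached("marker_recovery_nodrop", {
    simulate_collection(simulation_config(
      n_refs = 1, cells_per_type = 80, n_genes = 2000,
      n_markers_per_type = 30, dropout_rate = 0, seed = 42))
  })
  ref_nd <- log_transform(library_size_normalize(coll_nd$references[[1]]))
  top_dp <- select_top_genes(score_genes(ref_nd, "DP"), 500)
  expect_gte(mean(unlist(coll_nd$truth$marker_genes) %in% top_dp), 0.8)

  # The bimodality index needs bimodality to come from the cell types, not
  # from sampling zeros: in deeply sequenced data it ranks markers highly,
  # while in shallow counts the zeros-vs-detected split dominates every
  # gene. This complementarity is why the ensemble uses eight views.
  coll_deep <- cached("marker_recovery_deep", {
    simulate_collection(simulation_config(
      n_refs = 1, cells_per_type = 80, n_genes = 2000,
      n_markers_per_type = 30, baseline_log_mean = 3, dropout_rate = 0,
      seed = 42))
  })
  ref_deep <- log_transform(library_size_normalize(coll_deep$references[[1]]))
  top_bi <- select_top_genes(score_genes(ref_deep, "BI"), 500)
  expect_gte(mean(unlist(coll_deep$truth$marker_genes) %in% top_bi), 0.8)
  # determinism: identical input gives identical gene sets
  t1 <- select_top_genes(score_genes(ref_log, "DE"), 100)
  t2 <- select_top_genes(score_genes(ref_log, "DE"), 100)
  expect_identical(t1, t2)
  t3 <- select_top_genes(score_genes(ref, "Vst"), 100)
  t4 <- select_top_genes(score_genes(ref, "Vst"), 100)
  expect_identical(t3, t4)
})

test_that("reference subsets count |methods| x |references| and intersect with the query", {
  coll <- small_collection()
  subs <- build_reference_subsets(coll$references, coll$query, n_top = 100)
  expect_length(subs, 2 * 8)
  info <- table(vapply(subs, `[[`, integer(1), "ref_index"))
  expect_equal(unname(c(info)), c(8, 8))

  # a query missing half the genes: gene sets shrink to the intersection
  q <- coll$query
  keep <- q$genes[seq(1, length(q$genes), by = 2)]
  q_half <- labeled_dataset(q$matrix[, keep], cells = q$cells)
  subs_half <- build_reference_subsets(coll$references, q_half,
                                       methods = "DE", n_top = 100)
  for (s in subs_half) {
    expect_true(all(s$gene_set %in% keep))
    expect_identical(colnames(s$ref_matrix), s$gene_set)
    expect_identical(colnames(s$query_matrix), s$gene_set)
  }

  # two identical selections still yield two distinct subsets (diversity by
  # design), and matrices arrive min-max scaled
  subs_dup <- build_reference_subsets(coll$references[1], coll$query,
                                      gene_lists = list(A = keep[1:50],
                                                        B = keep[1:50]))
  expect_length(subs_dup, 2)
  expect_true(all(subs_dup[[1]]$ref_matrix >= 0 &
                  subs_dup[[1]]$ref_matrix <= 1))

  # gene floor drops undersized subsets with a warning
  expect_warning(
    expect_error(
      build_reference_subsets(coll$references[1], coll$query,
                              gene_lists = list(tiny = keep[1:3])),
      "dropped"),
    "only")
})
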