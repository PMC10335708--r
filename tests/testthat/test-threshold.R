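test_that("a single tight Gaussian selects one component and flags nothing", {
  x <- withr::with_seed(40, pmin(pmax(rnorm(500, 0.5, 0.05), 0), 1))
  fit <- fit_gmm_1d(x, seed = 1)
  expect_equal(fit$k, 1)
  groups <- assign_groups(fit, x)
  out <- identify_unassigned(fit, groups, x)
  expect_false(any(out$mask))
  expect_equal(out$diagnostics$chosen_k, 1)
  expect_true(is.na(out$diagnostics$implied_threshold))
})

test_that("a well-separated bimodal sample selects two components", {
  x <- withr::with_seed(41, c(rnorm(250, 0.2, 0.05), rnorm(250, 0.85, 0.05)))
  x <- pmin(pmax(x, 0), 1)
  fit <- fit_gmm_1d(x, seed = 2)
  expect_equal(fit$k, 2)
  expect_equal(fit$means, c(0.2, 0.85), tolerance = 0.05)
  groups <- assign_groups(fit, x)
  out <- identify_unassigned(fit, groups, x)
  truth_high <- c(rep(FALSE, 250), rep(TRUE, 250))
  expect_lte(mean(out$mask != truth_high), 0.02)
})

test_that("mixture fitting is deterministic given the seed", {
  x <- withr::with_seed(42, c(rnorm(100, 0.3, 0.1), rnorm(100, 0.8, 0.05)))
  f1 <- fit_gmm_1d(x, seed = 7)
  f2 <- fit_gmm_1d(x, seed = 7)
  expect_identical(f1$aic, f2$aic)
  expect_identical(f1$means, f2$means)
  expect_identical(assign_groups(f1, x), assign_groups(f2, x))
})

test_that("group assignment follows the posterior with larger-mean ties", {
  # exactly representable parameters so the midpoint tie is a true tie
  fit <- structure(list(k = 2L, weights = c(0.5, 0.5), means = c(0.25, 0.75),
                        vars = c(0.0625, 0.0625), loglik = 0,
                        aic = c(`1` = 1, `2` = 0)),
                   class = "gmm1d")
  expect_equal(assign_groups(fit, c(0.25, 0.75)), c(1L, 2L))
  # the exact midpoint of two identical components is a tie -> larger mean
  expect_equal(assign_groups(fit, 0.5), 2L)

  x <- withr::with_seed(43, runif(200))
  fit_r <- fit_gmm_1d(x, k_range = 2:3, seed = 3)
  expect_equal(assign_groups(fit_r, x), oracle_assign(fit_r, x))
})

test_that("uncertain groups combine the 0.6 cutoff with the top group", {
  mk_fit <- function(k) {
    structure(list(k = as.integer(k), weights = rep(1 / k, k),
                   means = seq_len(k) / (k + 1), vars = rep(0.01, k),
                   loglik = 0, aic = setNames(rep(0, k), seq_len(k))),
              class = "gmm1d")
  }
  # means 0.85 and 0.2: only the 0.85 group (cutoff and top coincide)
  fit2 <- mk_fit(2)
  m <- c(0.15, 0.25, 0.8, 0.9)
  groups <- c(1L, 1L, 2L, 2L)
  out <- identify_unassigned(fit2, groups, m)
  expect_equal(out$mask, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(out$diagnostics$group_means), c(0.2, 0.85))

  # means 0.3 and 0.5: nothing passes 0.6 but the top group is still flagged
  m2 <- c(0.25, 0.35, 0.45, 0.55)
  out2 <- identify_unassigned(fit2, groups, m2)
  expect_equal(out2$mask, c(FALSE, FALSE, TRUE, TRUE))

  # the strict switch drops the unconditional top-group rule
  out3 <- identify_unassigned(fit2, groups, m2, strict_cutoff_only = TRUE)
  expect_false(any(out3$mask))

  # multiple groups past the cutoff are all flagged
  fit3 <- mk_fit(3)
  m3 <- c(0.2, 0.2, 0.65, 0.7, 0.9, 0.95)
  groups3 <- c(1L, 1L, 2L, 2L, 3L, 3L)
  out4 <- identify_unassigned(fit3, groups3, m3)
  expect_equal(out4$mask, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))

  # every flagged cell sits at or above the implied threshold
  expect_true(all(m3[out4$mask] >= out4$diagnostics$implied_threshold))
  expect_equal(out4$diagnostics$implied_threshold, 0.65)
})

test_that("finalize_annotation merges labels with the mask", {
  labels <- c("A", "B", "C")
  expect_equal(finalize_annotation(labels, rep(FALSE, 3)), labels)
  expect_equal(finalize_annotation(labels, rep(TRUE, 3)),
               rep("unassigned", 3))
  expect_equal(finalize_annotation(labels, c(TRUE, FALSE, TRUE)),
               c("unassigned", "B", "unassigned"))
  expect_error(finalize_annotation(labels, TRUE), "lengths differ")
})

test_that("the EM fit agrees with mclust on separated data", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  x <- withr::with_seed(44, c(rnorm(200, 0.25, 0.06), rnorm(150, 0.8, 0.05)))
  fit <- fit_gmm_1d(x, k_range = 2, seed = 5)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4)
  my_groups <- assign_groups(fit, x)
  mc_groups <- mc$classification
  # component ids may be permuted; align by mean order
  if (mc$parameters$mean[1] > mc$parameters$mean[2]) {
    mc_groups <- 3L - mc_groups
  }
  expect_gte(mean(my_groups == mc_groups), 0.98)
})

test_that("unassigned fractions track the true unseen proportion", {
  # Benchmark-scale studies (3 references x 5 types) at small unseen
  # fractions; the cached p = 0.2 study runs are pooled in below.
  devs <- numeric(0)
  for (p in c(0.05, 0.1)) {
    for (s in c(510, 520)) {
      cfg <- simulation_config(unseen_type = "type4", unseen_fraction = p,
                               seed = s)
      coll <- simulate_collection(cfg)
      res <- annotate_query(coll$references, coll$query, n_top = 500,
                            epochs = 40, learning_rate = 3e-3,
                            hidden = c(64, 32), seed = s)
      devs <- c(devs, abs(mean(res$unassigned) - p))
    }
  }
  for (r in easy_runs()) {
    devs <- c(devs, abs(mean(r$res$unassigned) - 0.2))
  }
  expect_gte(mean(devs <= 0.1), 0.8)
})
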