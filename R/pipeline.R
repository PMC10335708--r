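#' Annotate a query dataset from multiple references
#'
#' Runs the full ensemble pipeline: library-size normalization, eight-way
#' gene selection per reference, training of one autoencoder-regularized
#' classifier per reference-by-method subset, normalized majority voting,
#' the three entropy-based uncertainty metrics and their ensemble score,
#' and the adaptive Gaussian-mixture threshold that labels putative
#' unseen-type cells `"unassigned"`.
#'
#' @param references list of labeled [labeled_dataset()] objects at stage
#'   `"raw"` (raw counts).
#' @param query an unlabeled [labeled_dataset()] at stage `"raw"` sharing
#'   the gene namespace (exact string match) with the references.
#' @param methods gene-selection methods (default all eight).
#' @param n_top genes per method per reference (default 500).
#' @param lambda reconstruction-loss weight (default 1).
#' @param epochs,hidden,batch_size,learning_rate base-classifier training
#'   controls; see [train_base_model()].
#' @param seed master seed; model `ij` trains with `seed + subset index`,
#'   and the mixture fit uses `seed`.
#' @param min_genes minimum intersected gene-set size per subset.
#' @param mean_cutoff,strict_cutoff_only unassigned-flagging controls; see
#'   [identify_unassigned()].
#' @param rename_map optional two-column label rename table applied to all
#'   references (see [apply_rename_map()]).
#' @param gene_lists optional pre-selected gene sets replacing computed
#'   selection (see [build_reference_subsets()]).
#' @param filter optional list of arguments to [filter_dataset()] applied
#'   to every reference (and, without the cell-type filter, to the query)
#'   before annotation; `NULL` (default) skips filtering, assuming curated
#'   inputs.
#' @param verbose print progress.
#' @return An `annotation_result`: list with `cells`, `labels` (final, with
#'   `"unassigned"`), `vote_labels`, `scores` (the `uncertainty_scores`
#'   data.frame), `unassigned` (logical mask), `diagnostics`
#'   (`threshold_diagnostics`), `vocabulary`, `L`, `stack`
#'   (the [prediction_stack()]), `subset_info` (data.frame of retained
#'   subsets), `seed`.
#' @export
annotate_query <- function(references, query,
                           methods = c("DE", "DV", "DD", "DP", "BI",
                                       "GC", "Disp", "Vst"),
                           n_top = 500, lambda = 1, epochs = 30,
                           hidden = c(256, 64), batch_size = 128,
                           learning_rate = 1e-3, seed = 1L,
                           min_genes = 10, mean_cutoff = 0.6,
                           strict_cutoff_only = FALSE, rename_map = NULL,
                           gene_lists = NULL, filter = NULL,
                           verbose = FALSE) {
  seed <- as.integer(seed)
  if (!is.null(rename_map)) {
    references <- lapply(references, apply_rename_map, rename_map = rename_map)
  }
  if (!is.null(filter)) {
    references <- lapply(references, function(r) {
      do.call(filter_dataset, c(list(ds = r), filter))
    })
    qfilter <- filter
    qfilter$min_cells_per_type <- 0
    query <- do.call(filter_dataset, c(list(ds = query), qfilter))
  }

  vocab <- cell_type_vocabulary(references)
  if (verbose) {
    message("vocabulary: ", paste(vocab$types, collapse = ", "))
  }

  subsets <- build_reference_subsets(references, query, methods = methods,
                                     n_top = n_top, min_genes = min_genes,
                                     gene_lists = gene_lists)
  if (verbose) {
    message(length(subsets), " reference subsets built (",
            length(references), " references x ", length(methods),
            " methods)")
  }

  probs <- vector("list", length(subsets))
  for (s in seq_along(subsets)) {
    model <- train_base_model(subsets[[s]], vocabulary = vocab$types,
                              lambda = lambda, epochs = epochs,
                              hidden = hidden, batch_size = batch_size,
                              learning_rate = learning_rate,
                              seed = seed + s)
    probs[[s]] <- predict_proba(model, subsets[[s]]$query_matrix)
    if (verbose) {
      message("  trained ", s, "/", length(subsets), " (ref",
              subsets[[s]]$ref_index, "/", subsets[[s]]$method, ")")
    }
  }

  stack <- prediction_stack(probs, subsets, vocab$types)
  vote <- majority_vote(stack)
  scores <- uncertainty_scores(stack)

  fit <- fit_gmm_1d(scores$m, seed = seed)
  groups <- assign_groups(fit, scores$m)
  flag <- identify_unassigned(fit, groups, scores$m,
                              mean_cutoff = mean_cutoff,
                              strict_cutoff_only = strict_cutoff_only)
  labels <- finalize_annotation(vote, flag$mask)

  subset_info <- data.frame(
    ref_index = vapply(subsets, `[[`, integer(1), "ref_index"),
    method = vapply(subsets, `[[`, character(1), "method"),
    n_genes = vapply(subsets, function(s) length(s$gene_set), integer(1)))

  structure(
    list(cells = query$cells, labels = labels, vote_labels = vote,
         scores = scores, unassigned = flag$mask,
         diagnostics = flag$diagnostics, vocabulary = vocab$types,
         L = stack$L, stack = stack, subset_info = subset_info,
         seed = seed),
    class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("<annotation_result> ", length(x$cells), " query cells, ",
      length(x$vocabulary), " reference cell types, ",
      length(x$stack$probs), " base models\n", sep = "")
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat("  labels: ", paste0(names(tab), " (", tab, ")", collapse = ", "),
      "\n", sep = "")
  cat("  unassigned fraction: ",
      round(mean(x$unassigned), 4), "\n", sep = "")
  cat("  mixture components: ", x$diagnostics$chosen_k, "; group means: ",
      paste(round(x$diagnostics$group_means, 3), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Write an annotation result to disk
#'
#' Writes `annotations.tsv` (cell id, predicted label, vote label, `m1`,
#' `m2`, `m3`, `m`, unassigned flag) and `report.json` (vocabulary, subset
#' counts `L`, retained subsets, threshold diagnostics, seed).
#'
#' @param result an `annotation_result`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two paths written.
#' @export
write_annotation_result <- function(result, dir) {
  stopifnot(inherits(result, "annotation_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "annotations.tsv")
  data.table::fwrite(
    data.frame(cell = result$cells, label = result$labels,
               vote_label = result$vote_labels,
               m1 = result$scores$m1, m2 = result$scores$m2,
               m3 = result$scores$m3, m = result$scores$m,
               unassigned = result$unassigned),
    tsv, sep = "\t")
  js <- file.path(dir, "report.json")
  report <- list(
    n_cells = length(result$cells),
    vocabulary = result$vocabulary,
    L = as.list(result$L),
    subsets = result$subset_info,
    unassigned_fraction = mean(result$unassigned),
    threshold = list(
      chosen_k = result$diagnostics$chosen_k,
      aic_per_k = as.list(result$diagnostics$aic_per_k),
      group_means = unname(result$diagnostics$group_means),
      uncertain_groups = result$diagnostics$uncertain_groups,
      implied_threshold = result$diagnostics$implied_threshold),
    seed = result$seed)
  jsonlite::write_json(report, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv, js))
}

#' Run the leave-one-cell-type-out benchmark
#'
#' Annotates the query once per [make_benchmark_tests()] test and scores
#' unseen-type identification (AUPRC of the ensemble score, F1 of the
#' unassigned call) and annotation accuracy.
#'
#' @param tests list of `benchmark_test` objects.
#' @param query_labels true query labels.
#' @param ... passed to [annotate_query()].
#' @return data.frame with one row per test: `held_out_type`, `p`,
#'   `auprc`, `f1`, `accuracy`, `unassigned_fraction`.
#' @export
run_benchmark <- function(tests, query_labels, ...) {
  rows <- lapply(tests, function(bt) {
    res <- annotate_query(bt$references, bt$query, ...)
    data.frame(
      held_out_type = bt$held_out_type,
      p = bt$p,
      auprc = auprc(res$scores$m, bt$unseen_mask),
      f1 = f1_unassigned(res$labels, bt$unseen_mask),
      accuracy = annotation_accuracy(res$labels, query_labels,
                                     bt$unseen_mask),
      unassigned_fraction = mean(res$unassigned))
  })
  do.call(rbind, rows)
}
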