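#' Build reference-by-method training subsets
#'
#' For each reference dataset and each gene-selection method, selects the
#' top-scoring genes, intersects them with the query's gene namespace, and
#' produces a training view: the reference and query matrices restricted to
#' that gene set (in identical order) and preprocessed for model training
#' (log2, per-gene z-score, per-gene min-max — each matrix scaled on its own
#' cells). With `M` references and 8 methods this yields `8M` subsets, the
#' diversity backbone of the ensemble. Subsets whose intersected gene set
#' falls below `min_genes` are dropped with a warning.
#'
#' @param references list of labeled [labeled_dataset()] objects at stage
#'   `"raw"` or `"libnorm"`.
#' @param query a [labeled_dataset()] at stage `"raw"` or `"libnorm"`.
#' @param methods gene-selection methods to use (default all eight).
#' @param n_top genes selected per method per reference (default 500).
#' @param min_genes minimum intersected gene-set size to keep a subset
#'   (default 10).
#' @param gene_lists optional named list of pre-selected gene sets replacing
#'   computed selection; names are used as method labels and each list
#'   element is applied to every reference.
#' @return List of `reference_subset` objects, each with elements
#'   `ref_index`, `method`, `gene_set`, `ref_matrix`, `labels`,
#'   `query_matrix`.
#' @export
build_reference_subsets <- function(references, query,
                                    methods = c("DE", "DV", "DD", "DP", "BI",
                                                "GC", "Disp", "Vst"),
                                    n_top = 500, min_genes = 10,
                                    gene_lists = NULL) {
  if (!length(references)) stop("no reference datasets", call. = FALSE)
  for (r in references) {
    if (is.null(r$labels)) {
      stop("every reference must carry labels", call. = FALSE)
    }
  }
  norm_one <- function(ds) if (ds$stage == "raw") library_size_normalize(ds) else ds
  refs_ln <- lapply(references, norm_one)
  query_ln <- norm_one(query)
  if (!all(vapply(refs_ln, function(d) d$stage, "") == "libnorm") ||
      query_ln$stage != "libnorm") {
    stop("references and query must be at stage raw or libnorm", call. = FALSE)
  }

  query_genes <- query_ln$genes
  subsets <- list()
  for (i in seq_along(refs_ln)) {
    ref <- refs_ln[[i]]
    ref_log <- log_transform(ref) # shared by the supervised scorers
    if (is.null(gene_lists)) {
      selections <- lapply(methods, function(mth) {
        ds_for <- if (mth %in% c("GC", "Disp", "Vst")) ref else ref_log
        select_top_genes(score_genes(ds_for, mth), n_top = n_top)
      })
      names(selections) <- methods
    } else {
      selections <- lapply(gene_lists, function(g) intersect(g, ref$genes))
    }
    for (mth in names(selections)) {
      gene_set <- intersect(selections[[mth]], query_genes)
      if (length(gene_set) < min_genes) {
        warning("dropping subset ref", i, "/", mth, ": only ",
                length(gene_set), " genes shared with the query",
                call. = FALSE)
        next
      }
      ref_view <- .preprocess_selected(restrict_genes(ref, gene_set))
      query_view <- .preprocess_selected(restrict_genes(query_ln, gene_set))
      subsets[[length(subsets) + 1L]] <- structure(
        list(ref_index = i, method = mth, gene_set = gene_set,
             ref_matrix = ref_view$matrix, labels = ref$labels,
             query_matrix = query_view$matrix,
             ref_cells = ref$cells, query_cells = query_ln$cells),
        class = "reference_subset")
    }
  }
  if (!length(subsets)) {
    stop("all reference subsets were dropped: no usable gene overlap ",
         "between references and query", call. = FALSE)
  }
  subsets
}

#' @export
print.reference_subset <- function(x, ...) {
  cat("<reference_subset> ref", x$ref_index, " / ", x$method, ": ",
      length(x$gene_set), " genes, ", nrow(x$ref_matrix),
      " reference cells, ", nrow(x$query_matrix), " query cells\n", sep = "")
  invisible(x)
}
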