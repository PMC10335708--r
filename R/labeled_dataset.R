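#' Labeled single-cell expression dataset
#'
#' The basic container used throughout the package: a dense cells-by-genes
#' expression matrix together with gene identifiers, cell identifiers, an
#' optional per-cell cell-type label vector, and a preprocessing `stage`
#' marker. The stage machine enforces the pipeline ordering: library-size
#' normalization is applied to raw counts, gene selection happens on
#' normalized data, and log transform, per-gene z-scoring and min-max
#' scaling are applied only after gene selection, in that order.
#'
#' @param matrix numeric matrix, cells in rows and genes in columns; all
#'   values must be finite. Raw-stage values must be nonnegative.
#' @param genes character vector of unique gene identifiers (defaults to
#'   `colnames(matrix)`).
#' @param cells character vector of unique cell identifiers (defaults to
#'   `rownames(matrix)`).
#' @param labels optional character vector of per-cell cell-type labels.
#' @param stage preprocessing stage, one of `"raw"`, `"libnorm"`,
#'   `"selected"`, `"log"`, `"zscore"`, `"minmax"`.
#'
#' @return An object of class `labeled_dataset`: a list with elements
#'   `matrix`, `genes`, `cells`, `labels` and `stage`.
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 3,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' ds <- labeled_dataset(m, labels = c("A", "A", "B"))
#' ds
#' @export
labeled_dataset <- function(matrix, genes = colnames(matrix),
                            cells = rownames(matrix), labels = NULL,
                            stage = "raw") {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix (cells x genes)", call. = FALSE)
  }
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(matrix)))
  if (is.null(cells)) cells <- paste0("cell", seq_len(nrow(matrix)))
  genes <- as.character(genes)
  cells <- as.character(cells)
  if (length(genes) != ncol(matrix)) {
    stop("length(genes) must equal ncol(matrix)", call. = FALSE)
  }
  if (length(cells) != nrow(matrix)) {
    stop("length(cells) must equal nrow(matrix)", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("gene identifiers must be unique (sum duplicates before building ",
         "a labeled_dataset; read_expression() does this automatically)",
         call. = FALSE)
  }
  if (anyDuplicated(cells)) {
    stop("cell identifiers must be unique", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(matrix)) {
      stop("labels length (", length(labels), ") does not match number of ",
           "cells (", nrow(matrix), ")", call. = FALSE)
    }
  }
  .stage_index(stage)
  if (any(!is.finite(matrix))) {
    stop("expression matrix contains non-finite values", call. = FALSE)
  }
  if (stage %in% c("raw", "libnorm", "selected", "log") && any(matrix < 0)) {
    stop("expression matrix contains negative values", call. = FALSE)
  }
  dimnames(matrix) <- list(cells, genes)
  structure(
    list(matrix = matrix, genes = genes, cells = cells, labels = labels,
         stage = stage),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", length(x$cells), " cells x ", length(x$genes),
      " genes, stage = ", x$stage, "\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- sort(table(x$labels), decreasing = TRUE)
    cat("  labels: ", paste0(names(tab), " (", tab, ")", collapse = ", "),
        "\n", sep = "")
  } else {
    cat("  labels: <none>\n")
  }
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$matrix)

# Internal: require a dataset at one of the allowed stages.
.assert_stage <- function(ds, allowed, op) {
  if (!inherits(ds, "labeled_dataset")) {
    stop(op, "() expects a labeled_dataset", call. = FALSE)
  }
  if (!ds$stage %in% allowed) {
    stop(op, "() requires stage in {", paste(allowed, collapse = ", "),
         "} but got '", ds$stage, "'; preprocessing steps must be applied ",
         "in order raw -> libnorm -> selected -> log -> zscore -> minmax",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Restrict a dataset to a gene subset
#'
#' Subsets the expression matrix to the given genes in the given order and
#' marks the dataset as `selected`. Used after gene selection and before
#' log / z-score / min-max scaling.
#'
#' @param ds a [labeled_dataset()] at stage `libnorm` (or `raw`).
#' @param genes character vector of genes to keep, all present in `ds$genes`.
#' @return A `labeled_dataset` at stage `selected`.
#' @export
restrict_genes <- function(ds, genes) {
  .assert_stage(ds, c("raw", "libnorm"), "restrict_genes")
  genes <- as.character(genes)
  missing <- setdiff(genes, ds$genes)
  if (length(missing)) {
    stop("genes not present in dataset: ", paste(utils::head(missing, 5),
         collapse = ", "), if (length(missing) > 5) ", ...", call. = FALSE)
  }
  if (!length(genes)) stop("empty gene subset", call. = FALSE)
  labeled_dataset(ds$matrix[, genes, drop = FALSE], genes = genes,
                  cells = ds$cells, labels = ds$labels, stage = "selected")
}

#' Apply a cell-type rename map to dataset labels
#'
#' Cell-type nomenclature often differs between reference atlases (for
#' example "PP" versus "gamma" for pancreatic gamma cells). Harmonization is
#' the user's responsibility; this helper applies a user-supplied two-column
#' rename table (`from`, `to`) to the labels of a dataset before the global
#' cell-type vocabulary is built.
#'
#' @param ds a labeled [labeled_dataset()].
#' @param rename_map data.frame (or two-column matrix) whose first column
#'   holds existing label strings and second column their replacements.
#' @return The dataset with renamed labels.
#' @export
apply_rename_map <- function(ds, rename_map) {
  if (is.null(ds$labels)) stop("dataset has no labels", call. = FALSE)
  rm <- as.data.frame(rename_map, stringsAsFactors = FALSE)
  if (ncol(rm) < 2) stop("rename_map needs two columns (from, to)", call. = FALSE)
  from <- as.character(rm[[1]]); to <- as.character(rm[[2]])
  idx <- match(ds$labels, from)
  hit <- !is.na(idx)
  ds$labels[hit] <- to[idx[hit]]
  ds
}

#' Build the global cell-type vocabulary across references
#'
#' The vocabulary is the union of the cell-type label sets of all reference
#' datasets, ordered lexicographically for determinism, together with a
#' reference-by-type presence table.
#'
#' @param references list of labeled [labeled_dataset()] objects.
#' @return An object of class `cell_type_vocabulary` with elements `types`
#'   (ordered character vector) and `presence` (logical matrix, references
#'   in rows, types in columns).
#' @export
cell_type_vocabulary <- function(references) {
  if (!length(references)) stop("no reference datasets supplied", call. = FALSE)
  label_sets <- lapply(references, function(r) {
    if (is.null(r$labels)) stop("every reference must carry labels", call. = FALSE)
    unique(r$labels)
  })
  types <- sort(unique(unlist(label_sets)))
  presence <- t(vapply(label_sets, function(s) types %in% s,
                       logical(length(types))))
  dimnames(presence) <- list(paste0("ref", seq_along(references)), types)
  structure(list(types = types, presence = presence),
            class = "cell_type_vocabulary")
}

#' @export
print.cell_type_vocabulary <- function(x, ...) {
  cat("<cell_type_vocabulary> ", length(x$types), " types across ",
      nrow(x$presence), " references\n", sep = "")
  print(x$presence)
  invisible(x)
}
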