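#' Filter a raw dataset by cell-type size, gene prevalence and cell coverage
#'
#' Applies, in order: (1) drop cell types with fewer than
#' `min_cells_per_type` cells (requires labels; skipped when the threshold
#' is 0), (2) drop genes expressed (value > 0) in fewer than
#' `min_cells_per_gene` cells, (3) drop cells expressing fewer than
#' `min_genes_per_cell` genes. The defaults match common curation practice
#' for multi-dataset reference collections. The operation is idempotent at
#' fixed thresholds.
#'
#' @param ds a [labeled_dataset()] at stage `"raw"`.
#' @param min_cells_per_type minimum cells per cell type (default 10).
#' @param min_cells_per_gene minimum cells in which a gene is detected
#'   (default 100).
#' @param min_genes_per_cell minimum genes detected per cell (default 100).
#' @return The filtered `labeled_dataset`, still at stage `"raw"`.
#' @export
filter_dataset <- function(ds, min_cells_per_type = 10,
                           min_cells_per_gene = 100,
                           min_genes_per_cell = 100) {
  .assert_stage(ds, "raw", "filter_dataset")
  m <- ds$matrix
  labels <- ds$labels
  cells <- ds$cells

  if (min_cells_per_type > 0) {
    if (is.null(labels)) {
      stop("cell-type filtering requested (min_cells_per_type > 0) but the ",
           "dataset has no labels", call. = FALSE)
    }
    tab <- table(labels)
    keep_types <- names(tab)[tab >= min_cells_per_type]
    keep <- labels %in% keep_types
    if (!any(keep)) {
      stop("all ", nrow(m), " cells removed: no cell type has >= ",
           min_cells_per_type, " cells", call. = FALSE)
    }
    m <- m[keep, , drop = FALSE]
    labels <- labels[keep]
    cells <- cells[keep]
  }

  detected_cells <- colSums(m > 0)
  keep_genes <- detected_cells >= min_cells_per_gene
  if (!any(keep_genes)) {
    stop("all ", ncol(m), " genes removed: no gene is detected in >= ",
         min_cells_per_gene, " cells", call. = FALSE)
  }
  m <- m[, keep_genes, drop = FALSE]

  genes_per_cell <- rowSums(m > 0)
  keep_cells <- genes_per_cell >= min_genes_per_cell
  if (!any(keep_cells)) {
    stop("all ", nrow(m), " cells removed: no cell expresses >= ",
         min_genes_per_cell, " genes", call. = FALSE)
  }
  m <- m[keep_cells, , drop = FALSE]
  cells <- cells[keep_cells]
  if (!is.null(labels)) labels <- labels[keep_cells]

  labeled_dataset(m, cells = cells, labels = labels, stage = "raw")
}

#' Library-size normalization to a fixed scale factor
#'
#' Divides each cell's expression values by the cell's total and multiplies
#' by `scale_factor`, so every cell's values sum to `scale_factor`
#' (10000 by default).
#'
#' @param ds a [labeled_dataset()] at stage `"raw"`.
#' @param scale_factor target total per cell (default 10000).
#' @return The dataset at stage `"libnorm"`.
#' @export
library_size_normalize <- function(ds, scale_factor = 1e4) {
  .assert_stage(ds, "raw", "library_size_normalize")
  totals <- rowSums(ds$matrix)
  zero <- totals <= 0
  if (any(zero)) {
    stop("cells with zero total expression cannot be normalized: ",
         paste(utils::head(ds$cells[zero], 5), collapse = ", "),
         if (sum(zero) > 5) ", ...", call. = FALSE)
  }
  m <- ds$matrix / totals * scale_factor
  labeled_dataset(m, cells = ds$cells, labels = ds$labels, stage = "libnorm")
}

#' Log2(x + 1) transform
#'
#' @param ds a [labeled_dataset()] at stage `"libnorm"` or `"selected"`.
#' @return The dataset at stage `"log"`.
#' @export
log_transform <- function(ds) {
  .assert_stage(ds, c("libnorm", "selected"), "log_transform")
  labeled_dataset(log2(ds$matrix + 1), cells = ds$cells, labels = ds$labels,
                  stage = "log")
}

#' Per-gene z-score standardization
#'
#' Centers every gene to mean 0 and scales to standard deviation 1 across
#' cells (population standard deviation). Genes constant across cells are
#' mapped to all zeros.
#'
#' @param ds a [labeled_dataset()] at stage `"log"`.
#' @return The dataset at stage `"zscore"`.
#' @export
zscore_genes <- function(ds) {
  .assert_stage(ds, "log", "zscore_genes")
  m <- ds$matrix
  mu <- colMeans(m)
  sd0 <- sqrt(.col_vars(m, means = mu, ddof = 0L))
  z <- sweep(m, 2, mu, "-")
  nz <- sd0 > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sd0[nz], "/")
  z[, !nz] <- 0
  ds_out <- labeled_dataset(z, cells = ds$cells, labels = ds$labels,
                            stage = "zscore")
  ds_out
}

#' Per-gene min-max scaling to [0, 1]
#'
#' Linearly maps every gene to the unit interval; constant genes map to all
#' zeros.
#'
#' @param ds a [labeled_dataset()] at stage `"zscore"`.
#' @return The dataset at stage `"minmax"`.
#' @export
minmax_genes <- function(ds) {
  .assert_stage(ds, "zscore", "minmax_genes")
  m <- ds$matrix
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  span <- hi - lo
  nz <- span > 0
  out <- sweep(m, 2, lo, "-")
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, span[nz], "/")
  out[, !nz] <- 0
  labeled_dataset(out, cells = ds$cells, labels = ds$labels, stage = "minmax")
}

# Internal: the post-selection preprocessing chain (log -> z-score -> min-max)
# applied to a gene-restricted libnorm dataset. Each matrix is scaled on its
# own cells.
.preprocess_selected <- function(ds) {
  minmax_genes(zscore_genes(log_transform(ds)))
}
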