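#' Read an expression matrix (with optional labels) from disk
#'
#' Supported formats:
#' * `csv` / `tsv` — dense table. By default genes are in columns: the header
#'   row carries gene identifiers and, when the first column is
#'   non-numeric, it is taken as cell identifiers. With
#'   `genes_in = "rows"` the table is transposed after reading (header =
#'   cell identifiers, first column = gene identifiers).
#' * `mtx` — MatrixMarket triplet file with sidecar files `genes.tsv` and
#'   `barcodes.tsv` next to it (one identifier per line). The matrix is
#'   stored genes-by-cells as in common single-cell tooling and is
#'   transposed to cells-by-genes on read.
#' * `h5` — not supported by this package; convert to MTX or CSV first.
#'
#' Duplicate gene identifiers are summed with a warning. Values must be
#' finite and nonnegative; the returned dataset is at stage `"raw"`.
#'
#' @param path path to the matrix file.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`, `"h5"`. Defaults to a
#'   guess from the file extension.
#' @param labels_path optional path to a one-column text file (optional
#'   header `label`) with one cell-type label per cell, in matrix cell order.
#' @param genes_in for `csv`/`tsv`: `"columns"` (default) or `"rows"`.
#' @param genes_path,cells_path for `mtx`: override the default sidecar
#'   locations (`genes.tsv` / `barcodes.tsv` in the matrix directory).
#' @return A [labeled_dataset()] at stage `"raw"`.
#' @export
read_expression <- function(path, format = NULL, labels_path = NULL,
                            genes_in = c("columns", "rows"),
                            genes_path = NULL, cells_path = NULL) {
  genes_in <- match.arg(genes_in)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     mtx = "mtx", h5 = "h5", h5ad = "h5",
                     stop("cannot guess format from extension '", ext,
                          "'; pass format=", call. = FALSE))
  }
  format <- match.arg(format, c("csv", "tsv", "mtx", "h5"))
  if (format == "h5") {
    stop("HDF5 input is not supported by this package; export the matrix ",
         "to MatrixMarket (matrix.mtx + genes.tsv + barcodes.tsv) or ",
         "CSV/TSV and re-run", call. = FALSE)
  }

  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE, check.names = FALSE)
    first_numeric <- is.numeric(dt[[1]])
    if (first_numeric) {
      ids <- NULL
      m <- as.matrix(dt)
    } else {
      ids <- as.character(dt[[1]])
      m <- as.matrix(dt[, -1, drop = FALSE])
      # data.frame column subsetting mangles duplicate names (make.unique);
      # restore the originals so duplicates can be summed below
      colnames(m) <- colnames(dt)[-1]
    }
    storage.mode(m) <- "double"
    if (genes_in == "columns") {
      genes <- colnames(m)
      cells <- ids %||% paste0("cell", seq_len(nrow(m)))
      rownames(m) <- cells
    } else {
      genes <- ids %||% paste0("gene", seq_len(nrow(m)))
      cells <- colnames(m)
      m <- t(m)
      rownames(m) <- cells
      colnames(m) <- genes
    }
  } else { # mtx
    dir <- dirname(path)
    genes_path <- genes_path %||% file.path(dir, "genes.tsv")
    cells_path <- cells_path %||% file.path(dir, "barcodes.tsv")
    if (!file.exists(genes_path)) {
      stop("MTX gene sidecar not found: ", genes_path, call. = FALSE)
    }
    if (!file.exists(cells_path)) {
      stop("MTX cell sidecar not found: ", cells_path, call. = FALSE)
    }
    mm <- Matrix::readMM(path)
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(mm) != length(genes)) {
      stop("MTX row count (", nrow(mm), ") does not match genes.tsv (",
           length(genes), " entries)", call. = FALSE)
    }
    if (ncol(mm) != length(cells)) {
      stop("MTX column count (", ncol(mm), ") does not match barcodes.tsv (",
           length(cells), " entries)", call. = FALSE)
    }
    m <- t(as.matrix(mm))
    dimnames(m) <- list(cells, genes)
  }

  .assert_finite_nonneg(m)

  # collapse duplicate gene identifiers by summation
  genes <- colnames(m)
  if (anyDuplicated(genes)) {
    warning("duplicate gene identifiers summed: ",
            paste(unique(genes[duplicated(genes)]), collapse = ", "),
            call. = FALSE)
    m <- t(rowsum(t(m), group = genes, reorder = FALSE))
  }

  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- read_labels(labels_path, n_expected = nrow(m))
  }
  labeled_dataset(m, labels = labels, stage = "raw")
}

#' Read a per-cell label file
#'
#' One label per line; a single optional header line named `label` (or
#' `cell_type`, `labels`) is skipped.
#'
#' @param path path to the label file.
#' @param n_expected optional expected number of labels; mismatch is an error.
#' @return Character vector of labels.
#' @export
read_labels <- function(path, n_expected = NULL) {
  if (!file.exists(path)) stop("labels file not found: ", path, call. = FALSE)
  lab <- readLines(path)
  lab <- lab[nzchar(lab)]
  if (length(lab) && tolower(lab[1]) %in% c("label", "labels", "cell_type",
                                            "celltype")) {
    lab <- lab[-1]
  }
  if (!is.null(n_expected) && length(lab) != n_expected) {
    stop("labels file has ", length(lab), " entries but the matrix has ",
         n_expected, " cells", call. = FALSE)
  }
  lab
}

#' Write an expression dataset to disk
#'
#' Inverse of [read_expression()] for the `csv`, `tsv` and `mtx` formats.
#' For `mtx`, `path` is a directory receiving `matrix.mtx`, `genes.tsv` and
#' `barcodes.tsv`. Labels, when present, are written next to the matrix as
#' `<stem>_labels.tsv` (or `labels.tsv` inside an MTX directory).
#'
#' @param ds a [labeled_dataset()].
#' @param path output file (csv/tsv) or directory (mtx).
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`.
#' @param write_labels whether to write the label sidecar when labels exist.
#' @return Invisibly, a character vector of the paths written.
#' @export
write_expression <- function(ds, path, format = c("csv", "tsv", "mtx"),
                             write_labels = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "labeled_dataset"))
  paths <- character(0)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell = ds$cells, ds$matrix, check.names = FALSE,
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = sep)
    paths <- path
    if (write_labels && !is.null(ds$labels)) {
      lp <- file.path(dirname(path),
                      paste0(tools::file_path_sans_ext(basename(path)),
                             "_labels.tsv"))
      writeLines(c("label", ds$labels), lp)
      paths <- c(paths, lp)
    }
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    mp <- file.path(path, "matrix.mtx")
    Matrix::writeMM(Matrix::Matrix(t(ds$matrix), sparse = TRUE), mp)
    writeLines(ds$genes, file.path(path, "genes.tsv"))
    writeLines(ds$cells, file.path(path, "barcodes.tsv"))
    paths <- c(mp, file.path(path, c("genes.tsv", "barcodes.tsv")))
    if (write_labels && !is.null(ds$labels)) {
      lp <- file.path(path, "labels.tsv")
      writeLines(c("label", ds$labels), lp)
      paths <- c(paths, lp)
    }
  }
  invisible(paths)
}
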