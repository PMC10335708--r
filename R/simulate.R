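#' Configuration for the synthetic multi-reference generator
#'
#' Describes a synthetic study: several reference batches and one query
#' batch drawn from a shared set of cell-type expression programs.
#' Counts follow a negative-binomial model (fixed dispersion, the standard
#' first-order description of scRNA-seq counts) with type-specific marker
#' genes elevated on the log scale, per-(reference, gene) log-normal
#' multiplicative batch factors mimicking technology differences, and
#' zero-inflation for dropout. When `unseen_type` is set, that type is
#' excluded from every reference but present in the query at fraction `p`
#' given by `unseen_fraction`.
#'
#' @param n_refs number of reference datasets (default 3).
#' @param global_types character vector of cell-type names (default 5
#'   types).
#' @param types_per_ref optional list (length `n_refs`) of type subsets per
#'   reference; default: every reference carries every (non-unseen) type.
#' @param cells_per_type reference cells per type (default 100).
#' @param query_cells_per_type query cells per shared type (default 60).
#' @param n_genes number of genes (default 2000).
#' @param n_markers_per_type planted marker genes per type (default 30,
#'   disjoint blocks).
#' @param marker_effect log-scale mean shift of markers in their own type
#'   (default 2, i.e. about 7.4-fold).
#' @param baseline_log_mean meanlog of the log-normal baseline gene means
#'   (default 0.5, a shallow droplet-like depth; raise it to emulate deeply
#'   sequenced data with few sampling zeros).
#' @param batch_shift_sd sd of the per-(batch, gene) log-normal factor
#'   (default 0.15).
#' @param dropout_rate zero-inflation probability (default 0.2).
#' @param dispersion negative-binomial dispersion, `size = 1/dispersion`
#'   (default 0.3).
#' @param unseen_type optional type withheld from all references.
#' @param unseen_fraction query fraction of the unseen type (default 0.2).
#' @param seed RNG seed; the collection is fully determined by it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_refs = 3,
                              global_types = paste0("type", 1:5),
                              types_per_ref = NULL,
                              cells_per_type = 100,
                              query_cells_per_type = 60,
                              n_genes = 2000,
                              n_markers_per_type = 30,
                              marker_effect = 2,
                              baseline_log_mean = 0.5,
                              batch_shift_sd = 0.15,
                              dropout_rate = 0.2,
                              dispersion = 0.3,
                              unseen_type = NULL,
                              unseen_fraction = 0.2,
                              seed = 1L) {
  if (n_markers_per_type * length(global_types) > n_genes) {
    stop("more marker genes requested than genes available", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate > 1 ||
      unseen_fraction <= 0 || unseen_fraction >= 1) {
    stop("rates must lie in [0, 1] (unseen_fraction strictly inside)",
         call. = FALSE)
  }
  if (!is.null(unseen_type) && !unseen_type %in% global_types) {
    stop("unseen_type must be one of global_types", call. = FALSE)
  }
  if (is.null(types_per_ref)) {
    types_per_ref <- rep(list(global_types), n_refs)
  }
  if (length(types_per_ref) != n_refs) {
    stop("types_per_ref must have one entry per reference", call. = FALSE)
  }
  structure(
    list(n_refs = n_refs, global_types = global_types,
         types_per_ref = types_per_ref, cells_per_type = cells_per_type,
         query_cells_per_type = query_cells_per_type, n_genes = n_genes,
         n_markers_per_type = n_markers_per_type,
         marker_effect = marker_effect, baseline_log_mean = baseline_log_mean,
         batch_shift_sd = batch_shift_sd,
         dropout_rate = dropout_rate, dispersion = dispersion,
         unseen_type = unseen_type, unseen_fraction = unseen_fraction,
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Simulate a multi-reference collection with a query batch
#'
#' Draws the references and the query described by a
#' [simulation_config()]. Every batch (each reference and the query) gets
#' its own gene-wise batch factors, so the query is a distinct "batch".
#'
#' @param cfg a [simulation_config()].
#' @return List with `references` (list of labeled [labeled_dataset()]),
#'   `query` (unlabeled `labeled_dataset`), and `truth` (list: `labels`,
#'   `unseen_mask`, `unseen_types`, `p`, `marker_genes` — a named list of
#'   the planted markers per type).
#' @export
simulate_collection <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, {
    genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
    baseline <- exp(stats::rnorm(cfg$n_genes, mean = cfg$baseline_log_mean, sd = 1))

    marker_idx <- split(seq_len(cfg$n_markers_per_type * length(cfg$global_types)),
                        rep(seq_along(cfg$global_types),
                            each = cfg$n_markers_per_type))
    names(marker_idx) <- cfg$global_types

    type_mean <- function(type) {
      mu <- baseline
      mu[marker_idx[[type]]] <- mu[marker_idx[[type]]] * exp(cfg$marker_effect)
      mu
    }

    draw_batch <- function(type_counts, batch_name) {
      bf <- exp(stats::rnorm(cfg$n_genes, 0, cfg$batch_shift_sd))
      labels <- rep(names(type_counts), times = type_counts)
      n <- length(labels)
      m <- matrix(0, n, cfg$n_genes)
      row <- 1L
      for (type in names(type_counts)) {
        nt <- type_counts[[type]]
        if (nt == 0) next
        mu <- type_mean(type) * bf
        block <- matrix(
          stats::rnbinom(nt * cfg$n_genes, mu = rep(mu, each = nt),
                         size = 1 / cfg$dispersion),
          nrow = nt)
        if (cfg$dropout_rate > 0) {
          keep <- matrix(stats::rbinom(nt * cfg$n_genes, 1,
                                       1 - cfg$dropout_rate), nrow = nt)
          block <- block * keep
        }
        m[row:(row + nt - 1L), ] <- block
        row <- row + nt
      }
      cells <- sprintf("%s_cell%04d", batch_name, seq_len(n))
      dimnames(m) <- list(cells, genes)
      list(matrix = m, labels = labels, cells = cells)
    }

    references <- vector("list", cfg$n_refs)
    for (i in seq_len(cfg$n_refs)) {
      types_i <- setdiff(cfg$types_per_ref[[i]], cfg$unseen_type)
      counts <- stats::setNames(rep(cfg$cells_per_type, length(types_i)),
                                types_i)
      b <- draw_batch(counts, paste0("ref", i))
      references[[i]] <- labeled_dataset(b$matrix, cells = b$cells,
                                         labels = b$labels, stage = "raw")
    }

    ref_types <- unique(unlist(lapply(references, function(r) r$labels)))
    shared_types <- intersect(cfg$global_types, ref_types)
    q_counts <- stats::setNames(rep(cfg$query_cells_per_type,
                                    length(shared_types)), shared_types)
    if (!is.null(cfg$unseen_type)) {
      n_shared <- sum(q_counts)
      n_unseen <- round(cfg$unseen_fraction / (1 - cfg$unseen_fraction) *
                          n_shared)
      q_counts[cfg$unseen_type] <- n_unseen
    }
    qb <- draw_batch(q_counts, "query")
    query <- labeled_dataset(qb$matrix, cells = qb$cells, labels = NULL,
                             stage = "raw")
    unseen_types <- setdiff(unique(qb$labels), ref_types)
    unseen_mask <- qb$labels %in% unseen_types

    list(references = references, query = query,
         truth = list(labels = qb$labels, unseen_mask = unseen_mask,
                      unseen_types = unseen_types, p = mean(unseen_mask),
                      marker_genes = lapply(marker_idx, function(i) genes[i])))
  })
}

#' Write a simulated collection to disk as plain-text fixtures
#'
#' References are written as `ref<i>.<ext>` with label sidecars, the query
#' as `query.<ext>`, and the truth table as `truth.tsv` (cell, label,
#' unseen flag). Round-trips exactly through [read_expression()].
#'
#' @param collection a [simulate_collection()] result.
#' @param dir output directory (created if needed).
#' @param format `"csv"`, `"tsv"` or `"mtx"` (MTX writes one subdirectory
#'   per matrix).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(collection, dir, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  ext <- format
  for (i in seq_along(collection$references)) {
    target <- if (format == "mtx") file.path(dir, paste0("ref", i))
              else file.path(dir, paste0("ref", i, ".", ext))
    paths <- c(paths, write_expression(collection$references[[i]], target,
                                       format = format))
  }
  qtarget <- if (format == "mtx") file.path(dir, "query")
             else file.path(dir, paste0("query.", ext))
  paths <- c(paths, write_expression(collection$query, qtarget,
                                     format = format))
  tp <- file.path(dir, "truth.tsv")
  data.table::fwrite(
    data.frame(cell = collection$query$cells,
               label = collection$truth$labels,
               unseen = collection$truth$unseen_mask),
    tp, sep = "\t")
  invisible(c(paths, tp))
}
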