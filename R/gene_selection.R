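#' Per-gene informativeness scores
#'
#' Eight gene-scoring methods, five supervised (one-vs-rest per cell type,
#' aggregated by the maximum over types, since markers are type-specific)
#' and three unsupervised highly-variable-gene recipes:
#'
#' * `DE` — moderated t-statistic (limma empirical-Bayes) on log data.
#' * `DV` — Bartlett variance-homogeneity statistic.
#' * `DD` — two-sample Kolmogorov-Smirnov statistic.
#' * `DP` — Pearson chi-squared statistic on detection (value > 0).
#' * `BI` — bimodality index `delta * sqrt(pi * (1 - pi))` from an exact
#'   one-dimensional two-means split of the gene's values.
#' * `GC` — Gini coefficient of the gene's expression across cells.
#' * `Disp` — dispersion (variance / mean), z-scored within 20 mean bins on
#'   the log scale.
#' * `Vst` — standardized variance after a loess variance-stabilizing
#'   mean-variance fit, standardized values clipped at `sqrt(n)`.
#'
#' Supervised scores are computed on log-transformed library-normalized
#' data (stage `"log"`), unsupervised scores on library-normalized data
#' (stage `"libnorm"`), matching the conventions of their source recipes.
#' All-zero genes score 0 under every method.
#'
#' @param ds a [labeled_dataset()] at the stage required by `method`.
#' @param method one of `"DE"`, `"DV"`, `"DD"`, `"DP"`, `"BI"`, `"GC"`,
#'   `"Disp"`, `"Vst"`.
#' @param labels per-cell labels for the supervised methods; defaults to
#'   `ds$labels`.
#' @return A `gene_score_table`: data.frame with columns `gene` and `score`
#'   (finite, higher = more informative) and attribute `method`.
#' @export
score_genes <- function(ds, method, labels = ds$labels) {
  method <- match.arg(method, c("DE", "DV", "DD", "DP", "BI",
                                "GC", "Disp", "Vst"))
  supervised <- method %in% c("DE", "DV", "DD", "DP", "BI")
  if (supervised) {
    .assert_stage(ds, "log", "score_genes")
    if (is.null(labels)) {
      stop("supervised method ", method, " requires labels", call. = FALSE)
    }
    labels <- as.character(labels)
    if (length(labels) != nrow(ds$matrix)) {
      stop("labels length does not match number of cells", call. = FALSE)
    }
    tab <- table(labels)
    if (length(tab) < 2) {
      stop("supervised gene scoring needs >= 2 cell types", call. = FALSE)
    }
    if (any(tab < 2)) {
      stop("every cell type needs >= 2 cells; too small: ",
           paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
    }
    scores <- switch(method,
      DE = .score_de(ds$matrix, labels),
      DV = .score_ovr(ds$matrix, labels, .bartlett_stat),
      DD = .score_ovr(ds$matrix, labels, .ks_stat_cols),
      DP = .score_ovr(ds$matrix, labels, .detection_chisq),
      BI = .score_bi(ds$matrix)
    )
  } else {
    .assert_stage(ds, "libnorm", "score_genes")
    if (nrow(ds$matrix) < 2) {
      stop("unsupervised gene scoring needs >= 2 cells", call. = FALSE)
    }
    scores <- switch(method,
      GC = .score_gini(ds$matrix),
      Disp = .score_dispersion(ds$matrix),
      Vst = .score_vst(ds$matrix)
    )
  }
  scores[!is.finite(scores)] <- 0
  scores[colSums(ds$matrix) == 0] <- 0
  out <- data.frame(gene = ds$genes, score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  class(out) <- c("gene_score_table", class(out))
  out
}

# ---- supervised statistics (vectorized over genes) -------------------------

# Apply a two-group column statistic one-vs-rest for every cell type and
# keep each gene's maximum.
.score_ovr <- function(m, labels, stat_fun) {
  types <- sort(unique(labels))
  s <- matrix(0, length(types), ncol(m))
  for (t in seq_along(types)) {
    grp <- labels == types[t]
    s[t, ] <- stat_fun(m, grp)
  }
  s[!is.finite(s)] <- 0
  apply(s, 2, max)
}

# limma moderated t, one column of the design per one-vs-rest contrast.
.score_de <- function(m, labels) {
  types <- sort(unique(labels))
  expr <- t(m) # genes x cells for limma
  best <- rep(0, ncol(m))
  for (t in types) {
    design <- cbind(Intercept = 1, grp = as.numeric(labels == t))
    # degenerate (constant / all-zero) genes trip limma's zero-variance
    # warning; their scores are forced to 0 below, so silence it
    fit <- suppressWarnings(limma::eBayes(limma::lmFit(expr, design)))
    tstat <- abs(fit$t[, "grp"])
    tstat[!is.finite(tstat)] <- 0
    best <- pmax(best, tstat)
  }
  best
}

# Bartlett's variance-homogeneity statistic for two groups, per column.
.bartlett_stat <- function(m, grp) {
  n1 <- sum(grp); n2 <- sum(!grp)
  if (n1 < 2 || n2 < 2) return(rep(0, ncol(m)))
  x1 <- m[grp, , drop = FALSE]; x2 <- m[!grp, , drop = FALSE]
  v1 <- .col_vars(x1); v2 <- .col_vars(x2)
  df1 <- n1 - 1; df2 <- n2 - 1; df <- df1 + df2
  sp <- (df1 * v1 + df2 * v2) / df
  correction <- 1 + (1 / df1 + 1 / df2 - 1 / df) / 3
  stat <- (df * log(sp) - df1 * log(v1) - df2 * log(v2)) / correction
  stat[!is.finite(stat)] <- 0
  pmax(stat, 0)
}

# Two-sample KS statistic per column, with tied values handled by
# evaluating the ECDF difference at the last occurrence of each distinct
# pooled value.
.ks_stat_cols <- function(m, grp) {
  n1 <- sum(grp); n2 <- sum(!grp)
  w <- ifelse(grp, 1 / n1, -1 / n2)
  apply(m, 2, function(v) {
    o <- order(v)
    z <- cumsum(w[o])
    vs <- v[o]
    last <- c(vs[-1] != vs[-length(vs)], TRUE)
    max(abs(z[last]))
  })
}

# Pearson chi-squared (no continuity correction) on the 2x2 detection table
# (expressed / not) x (in type / rest), per column.
.detection_chisq <- function(m, grp) {
  n1 <- sum(grp); n2 <- sum(!grp); n <- n1 + n2
  det <- m > 0
  a <- colSums(det[grp, , drop = FALSE])   # detected, in type
  b <- colSums(det[!grp, , drop = FALSE])  # detected, rest
  c_ <- n1 - a
  d <- n2 - b
  num <- n * (a * d - b * c_)^2
  den <- (a + b) * (c_ + d) * n1 * n2
  stat <- ifelse(den > 0, num / den, 0)
  stat
}

# Exact optimal two-cluster split of sorted 1-D values via cumulative sums;
# returns the bimodality index delta * sqrt(pi (1 - pi)).
.bimodality_index <- function(v) {
  n <- length(v)
  if (n < 4) return(0)
  s <- sort(v)
  if (s[1] == s[n]) return(0)
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  tot <- cs[n]; tot2 <- cs2[n]
  i <- seq_len(n - 1)
  ss1 <- cs2[i] - cs[i]^2 / i
  ss2 <- (tot2 - cs2[i]) - (tot - cs[i])^2 / (n - i)
  j <- which.min(ss1 + ss2)
  n1 <- j; n2 <- n - j
  mu1 <- cs[j] / n1
  mu2 <- (tot - cs[j]) / n2
  sigma <- sqrt(max((ss1[j] + ss2[j]) / (n - 2), 0))
  sigma <- max(sigma, 1e-6) # perfect separation: keep the score finite
  p1 <- n1 / n
  abs(mu1 - mu2) / sigma * sqrt(p1 * (1 - p1))
}

.score_bi <- function(m) {
  apply(m, 2, .bimodality_index)
}

# ---- unsupervised statistics ----------------------------------------------

# Gini coefficient per gene across cells (0 = perfectly even expression).
.score_gini <- function(m) {
  n <- nrow(m)
  apply(m, 2, function(v) {
    tot <- sum(v)
    if (tot <= 0) return(0)
    s <- sort(v)
    2 * sum(seq_len(n) * s) / (n * tot) - (n + 1) / n
  })
}

# Dispersion = var/mean, log-transformed and z-scored within 20 bins of mean.
.score_dispersion <- function(m, n_bins = 20) {
  mu <- colMeans(m)
  v <- .col_vars(m, means = mu)
  disp <- ifelse(mu > 0, v / mu, 0)
  ldisp <- ifelse(disp > 0, log(disp), 0)
  lmu <- log1p(mu)
  brk <- unique(stats::quantile(lmu, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 2) return(rep(0, ncol(m)))
  bins <- cut(lmu, breaks = brk, include.lowest = TRUE)
  out <- numeric(ncol(m))
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (length(idx) < 2) { out[idx] <- 0; next }
    mb <- mean(ldisp[idx]); sb <- stats::sd(ldisp[idx])
    out[idx] <- if (is.finite(sb) && sb > 0) (ldisp[idx] - mb) / sb else 0
  }
  out
}

# Variance-stabilizing recipe: loess fit of log10 variance on log10 mean,
# values standardized by the fitted sd and clipped at sqrt(n); score is the
# variance of the clipped standardized values.
.score_vst <- function(m, span = 0.3) {
  n <- nrow(m)
  mu <- colMeans(m)
  v <- .col_vars(m, means = mu)
  ok <- mu > 0 & v > 0
  score <- numeric(ncol(m))
  if (sum(ok) < 10) {
    # too few informative genes for a smooth fit; fall back to raw variance
    score[ok] <- v[ok]
    return(score)
  }
  fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = span, degree = 2)
  exp_sd <- sqrt(10^stats::predict(fit, log10(mu[ok])))
  exp_sd[!is.finite(exp_sd) | exp_sd <= 0] <- sqrt(v[ok])[!is.finite(exp_sd) | exp_sd <= 0]
  z <- sweep(m[, ok, drop = FALSE], 2, mu[ok], "-")
  z <- sweep(z, 2, exp_sd, "/")
  z <- pmin(z, sqrt(n))
  score[ok] <- .col_vars(z)
  score
}

# ---- selection -------------------------------------------------------------

#' Select the top-scoring genes from a score table
#'
#' Ranks by descending score with ties broken by input order (earlier gene
#' kept), so selection is deterministic. Alternatively, a minimum-score
#' threshold can be supplied instead of a count.
#'
#' @param table a `gene_score_table` from [score_genes()].
#' @param n_top number of genes to keep (default 500). Ignored when
#'   `min_score` is given. If `n_top` exceeds the number of genes, all genes
#'   are returned with a warning.
#' @param min_score optional score threshold: keep genes with
#'   `score >= min_score`.
#' @return Character vector of selected gene identifiers, in rank order.
#' @export
select_top_genes <- function(table, n_top = 500, min_score = NULL) {
  if (!is.data.frame(table) || !all(c("gene", "score") %in% names(table))) {
    stop("`table` must be a gene_score_table with columns gene, score",
         call. = FALSE)
  }
  if (nrow(table) == 0) stop("empty gene score table", call. = FALSE)
  o <- order(-table$score) # stable: ties keep input order
  if (!is.null(min_score)) {
    keep <- table$score[o] >= min_score
    return(table$gene[o][keep])
  }
  if (n_top < 1) stop("n_top must be >= 1", call. = FALSE)
  if (n_top > nrow(table)) {
    warning("n_top (", n_top, ") exceeds the number of genes (", nrow(table),
            "); returning all genes", call. = FALSE)
    n_top <- nrow(table)
  }
  table$gene[o][seq_len(n_top)]
}
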