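#' Fit a one-dimensional Gaussian mixture with AIC model selection
#'
#' Fits univariate Gaussian mixtures to the ensemble uncertainty score by
#' EM for each component count in `k_range` (default 1 to 5), using several
#' seeded random restarts per count and a variance floor, and selects the
#' count minimizing the Akaike information criterion with `3k - 1` free
#' parameters (weights, means, variances). One-dimensional EM is
#' restart-sensitive, hence the multiple restarts; the fit is fully
#' deterministic given `seed`.
#'
#' @param m numeric vector of per-cell scores (at least 10 values).
#' @param k_range candidate component counts (default `1:5`).
#' @param n_restarts EM restarts per component count (default 10).
#' @param seed RNG seed for the restarts.
#' @param var_floor lower bound on component variances (default 1e-6).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance. The defaults follow common mixture-fitting
#'   practice; substantially tighter settings let the best-of-restarts
#'   search over-converge into spurious small-component optima on smooth
#'   unimodal data.
#' @return A `gmm1d` object: `k` (chosen count), `weights`, `means`,
#'   `vars` (components sorted by mean), `loglik`, `aic` (named vector over
#'   `k_range`, NA where every restart failed).
#' @export
fit_gmm_1d <- function(m, k_range = 1:5, n_restarts = 10, seed = 1L,
                       var_floor = 1e-6, max_iter = 100, tol = 1e-5) {
  m <- as.numeric(m)
  n <- length(m)
  if (n < 10) stop("need at least 10 values to fit a mixture", call. = FALSE)
  if (any(!is.finite(m))) stop("scores must be finite", call. = FALSE)

  fits <- vector("list", length(k_range))
  aic <- rep(NA_real_, length(k_range))
  names(aic) <- as.character(k_range)

  withr::with_seed(as.integer(seed), {
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      best <- NULL
      for (r in seq_len(n_restarts)) {
        fit <- tryCatch(
          .em_gmm_1d(m, k, var_floor = var_floor, max_iter = max_iter,
                     tol = tol),
          error = function(e) NULL)
        if (!is.null(fit) &&
            (is.null(best) || fit$loglik > best$loglik)) {
          best <- fit
        }
        if (k == 1) break # closed form, restarts are identical
      }
      if (!is.null(best)) {
        fits[[ki]] <- best
        aic[ki] <- 2 * (3 * k - 1) - 2 * best$loglik
      }
    }
  })

  if (all(is.na(aic))) {
    stop("Gaussian mixture fitting failed for every component count",
         call. = FALSE)
  }
  chosen <- which.min(aic)
  fit <- fits[[chosen]]
  o <- order(fit$means)
  structure(
    list(k = k_range[chosen], weights = fit$weights[o], means = fit$means[o],
         vars = fit$vars[o], loglik = fit$loglik, aic = aic),
    class = "gmm1d")
}

# One EM run; k = 1 is the closed-form MLE. Initial means are drawn from the
# data, initial variances are the overall variance.
.em_gmm_1d <- function(x, k, var_floor, max_iter, tol) {
  n <- length(x)
  if (k == 1) {
    mu <- mean(x)
    v <- max(mean((x - mu)^2), var_floor)
    ll <- sum(stats::dnorm(x, mu, sqrt(v), log = TRUE))
    return(list(weights = 1, means = mu, vars = v, loglik = ll))
  }
  mu <- sample(x, k)
  v <- rep(max(stats::var(x), var_floor), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j) {
      log(w[j]) + stats::dnorm(x, mu[j], sqrt(v[j]), log = TRUE)
    }, numeric(n))
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stop("empty mixture component")
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk, var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(weights = w, means = mu, vars = v, loglik = ll)
}

#' @export
print.gmm1d <- function(x, ...) {
  cat("<gmm1d> k = ", x$k, " (AIC: ",
      paste0(names(x$aic), "->", round(x$aic, 1), collapse = ", "), ")\n",
      sep = "")
  cat("  weights:", paste(round(x$weights, 3), collapse = ", "), "\n")
  cat("  means:  ", paste(round(x$means, 4), collapse = ", "), "\n")
  cat("  sds:    ", paste(round(sqrt(x$vars), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Assign cells to mixture components by posterior probability
#'
#' Each cell goes to the component maximizing its posterior; exact ties go
#' to the component with the larger mean (components are stored sorted by
#' mean, so the higher-index component wins ties).
#'
#' @param fit a [fit_gmm_1d()] result.
#' @param m the score vector.
#' @return Integer vector of component ids (1 = lowest mean).
#' @export
assign_groups <- function(fit, m) {
  stopifnot(inherits(fit, "gmm1d"))
  k <- fit$k
  if (k == 1) return(rep(1L, length(m)))
  logd <- vapply(seq_len(k), function(j) {
    log(fit$weights[j]) + stats::dnorm(m, fit$means[j], sqrt(fit$vars[j]),
                                       log = TRUE)
  }, numeric(length(m)))
  if (length(m) == 1L) logd <- matrix(logd, nrow = 1)
  # ties.method = "last" => larger-mean component (columns sorted by mean)
  best <- apply(logd, 1, function(r) max(which(r == max(r))))
  as.integer(best)
}

#' Flag "unassigned" cells from the mixture grouping
#'
#' With a single mixture component no cells are flagged. Otherwise the
#' uncertain groups are the groups whose mean score is at least
#' `mean_cutoff` (default 0.6) together with, unconditionally, the group
#' with the largest mean; all their member cells are flagged. Set
#' `strict_cutoff_only = TRUE` to flag only groups passing the cutoff.
#'
#' @param fit a [fit_gmm_1d()] result.
#' @param groups component assignment from [assign_groups()].
#' @param m the score vector.
#' @param mean_cutoff group-mean threshold (default 0.6, on the `[0, 1]`
#'   ensemble score scale).
#' @param strict_cutoff_only drop the unconditional largest-mean rule.
#' @return List with `mask` (logical, TRUE = unassigned) and `diagnostics`
#'   (class `threshold_diagnostics`: `chosen_k`, `aic_per_k`, `group_means`,
#'   `uncertain_groups`, `implied_threshold` — the minimum score among
#'   flagged cells, NA when nothing is flagged).
#' @export
identify_unassigned <- function(fit, groups, m, mean_cutoff = 0.6,
                                strict_cutoff_only = FALSE) {
  stopifnot(inherits(fit, "gmm1d"), length(groups) == length(m))
  group_ids <- sort(unique(groups))
  group_means <- vapply(group_ids, function(g) mean(m[groups == g]),
                        numeric(1))
  names(group_means) <- group_ids
  if (fit$k == 1) {
    uncertain <- integer(0)
  } else {
    uncertain <- group_ids[group_means >= mean_cutoff]
    if (!strict_cutoff_only) {
      uncertain <- union(uncertain, group_ids[which.max(group_means)])
    }
  }
  mask <- groups %in% uncertain
  diagnostics <- structure(
    list(chosen_k = fit$k, aic_per_k = fit$aic, group_means = group_means,
         uncertain_groups = uncertain,
         implied_threshold = if (any(mask)) min(m[mask]) else NA_real_),
    class = "threshold_diagnostics")
  list(mask = mask, diagnostics = diagnostics)
}

#' @export
print.threshold_diagnostics <- function(x, ...) {
  cat("<threshold_diagnostics> k = ", x$chosen_k, "; group means: ",
      paste(round(x$group_means, 3), collapse = ", "), "\n", sep = "")
  if (length(x$uncertain_groups)) {
    cat("  uncertain groups:", paste(x$uncertain_groups, collapse = ", "),
        "| implied threshold:", round(x$implied_threshold, 4), "\n")
  } else {
    cat("  no uncertain groups\n")
  }
  invisible(x)
}

#' Merge the vote labels with the unassigned mask
#'
#' Flagged cells receive the label `"unassigned"`; all others keep their
#' consensus vote label.
#'
#' @param vote_labels character vector of consensus labels.
#' @param mask logical vector from [identify_unassigned()].
#' @return Character vector of final labels.
#' @export
finalize_annotation <- function(vote_labels, mask) {
  if (length(vote_labels) != length(mask)) {
    stop("labels and mask lengths differ", call. = FALSE)
  }
  out <- vote_labels
  out[mask] <- "unassigned"
  out
}
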