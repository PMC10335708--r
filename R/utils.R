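# Internal helpers shared across modules.

.STAGES <- c("raw", "libnorm", "selected", "log", "zscore", "minmax")

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage_index <- function(stage) {
  i <- match(stage, .STAGES)
  if (is.na(i)) stop("unknown preprocessing stage: ", stage, call. = FALSE)
  i
}

# Per-column variance without forming a centered copy. ddof = 0 gives the
# population variance used by z-scoring; ddof = 1 the sample variance used by
# the dispersion statistics.
.col_vars <- function(x, means = colMeans(x), ddof = 1L) {
  n <- nrow(x)
  v <- (colSums(x * x) - n * means^2) / (n - ddof)
  pmax(v, 0) # guard tiny negative values from cancellation
}

# Row-wise base-2 entropy of a nonnegative matrix whose rows sum to 1;
# 0 * log2(0) is taken as 0.
.row_entropy2 <- function(p) {
  h <- p * log2(p)
  h[!is.finite(h)] <- 0
  -rowSums(h)
}

# Linear min-max scaling of a vector to [0, 1]; constant vectors map to all
# zeros so that downstream averages stay defined.
.minmax_scale <- function(v) {
  r <- range(v)
  span <- r[2] - r[1]
  if (span <= .Machine$double.eps * max(1, abs(r[2]))) {
    return(rep(0, length(v)))
  }
  (v - r[1]) / span
}

.assert_finite_nonneg <- function(m, what = "expression matrix") {
  if (any(!is.finite(m))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  if (any(m < 0)) {
    stop(what, " contains negative values", call. = FALSE)
  }
  invisible(TRUE)
}
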