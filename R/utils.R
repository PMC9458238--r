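# Internal numerical helpers shared across modules.

#' @importFrom stats approx cor dnorm kmeans mad median quantile rbinom rgamma
#'   rlnorm rnorm runif sd var fisher.test wilcox.test kruskal.test t.test
#'   cor.test setNames ecdf
#' @importFrom utils head modifyList
NULL

# Rolling minimum along rows of a matrix (window w, centered, replicate-edge).
# Vectorized over rows: w shifted pmin passes over the whole matrix.
roll_min_rows <- function(m, w) {
  stopifnot(w >= 1)
  n <- ncol(m)
  if (w > n) stop("window larger than spectrum length")
  h <- (w - 1L) %/% 2L
  out <- m
  for (off in seq(-h, h)) {
    if (off == 0L) next
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- pmin(out, m[, idx, drop = FALSE])
  }
  out
}

# Rolling mean along rows (centered, replicate-edge padding).
roll_mean_rows <- function(m, w) {
  stopifnot(w >= 1)
  n <- ncol(m)
  if (w > n) stop("window larger than spectrum length")
  h <- (w - 1L) %/% 2L
  acc <- m
  for (off in seq(-h, h)) {
    if (off == 0L) next
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    acc <- acc + m[, idx, drop = FALSE]
  }
  acc / (2L * h + 1L)
}

# Column variances with the usual n-1 denominator, without extra copies.
col_vars <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(NA_real_, ncol(m)))
  mu <- colMeans(m)
  (colSums(m * m) - n * mu * mu) / (n - 1)
}

# Standardize rows to zero mean / unit variance. Rows with (near) zero
# variance are mapped to all-zeros (correlation to anything is undefined;
# distance to every centroid then equals 1).
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  cm <- m - mu
  s <- sqrt(rowSums(cm * cm) / (ncol(m) - 1L))
  bad <- !is.finite(s) | s < 1e-12
  s[bad] <- 1
  out <- cm / s
  out[bad, ] <- 0
  out
}

# Deterministic integer sub-seeds derived from a master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 0
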