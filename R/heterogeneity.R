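#' Pairwise spectral similarity index
#'
#' Similarity between two component-abundance vectors: the Pearson
#' correlation by default (cosine similarity by choice). Symmetric, and equal
#' to 1 for identical nonconstant vectors.
#'
#' @param spec_a,spec_b Numeric vectors of equal length >= 2, nonconstant.
#' @param method `"pearson"` or `"cosine"`.
#' @return The similarity in `[-1, 1]`.
#' @export
similarity <- function(spec_a, spec_b, method = c("pearson", "cosine")) {
  method <- match.arg(method)
  if (length(spec_a) != length(spec_b) || length(spec_a) < 2L)
    stop("vectors must have equal length >= 2")
  if (method == "pearson") {
    if (sd(spec_a) == 0 || sd(spec_b) == 0)
      stop("similarity undefined for constant vectors")
    cor(spec_a, spec_b)
  } else {
    na <- sqrt(sum(spec_a^2)); nb <- sqrt(sum(spec_b^2))
    if (na == 0 || nb == 0) stop("similarity undefined for zero vectors")
    sum(spec_a * spec_b) / (na * nb)
  }
}

# Decode unordered pair index in 1..n(n-1)/2 to (i, j), i < j, column-major
# over the upper triangle: pairs (1,2), (1,3), (2,3), (1,4), ...
decode_pairs <- function(id) {
  j <- ceiling((1 + sqrt(1 + 8 * id)) / 2)
  i <- id - (j - 1) * (j - 2) / 2
  cbind(as.integer(i), as.integer(j))
}

#' Distribution of pairwise similarities within or between pixel sets
#'
#' Intra mode (`pixels_b` missing) uses all unordered pixel pairs of
#' `pixels_a`, excluding self-pairs; inter mode uses the full cross product of
#' the two sets. When the number of pairs exceeds `max_pairs`, a seeded
#' uniform subsample of `max_pairs` distinct pairs is used instead.
#'
#' @param abund Abundance matrix (pixels x components).
#' @param pixels_a,pixels_b Integer pixel indices; `pixels_b = NULL` selects
#'   intra mode.
#' @param max_pairs Cap on evaluated pairs (default 1e7).
#' @param seed Integer seed for the subsample.
#' @param method Passed to [similarity()].
#' @param context Free-text label (e.g. `"intra-T"`).
#' @param grid Grid on which the empirical CDF is evaluated.
#' @return A `similarity_distribution`: list with `values`, `median`, `n_pairs`
#'   (total available), `cdf` (data frame `s`, `p`), `context`.
#' @export
similarity_distribution <- function(abund, pixels_a, pixels_b = NULL,
                                    max_pairs = 1e7, seed = 1L,
                                    method = "pearson",
                                    context = if (is.null(pixels_b)) "intra" else "inter",
                                    grid = seq(-1, 1, by = 0.01)) {
  abund <- as.matrix(abund)
  if (is.logical(pixels_a)) pixels_a <- which(pixels_a)
  if (is.logical(pixels_b)) pixels_b <- which(pixels_b)
  intra <- is.null(pixels_b)
  if (intra) {
    if (length(pixels_a) < 2L) stop("intra mode needs at least 2 pixels")
    n_total <- length(pixels_a) * (length(pixels_a) - 1) / 2
  } else {
    if (!length(pixels_a) || !length(pixels_b)) stop("empty pixel set")
    n_total <- as.numeric(length(pixels_a)) * length(pixels_b)
  }
  if (n_total > max_pairs) {
    ids <- withr::with_seed(seed, sample(n_total, max_pairs))
  } else {
    ids <- seq_len(n_total)
  }
  if (intra) {
    pr <- decode_pairs(ids)
    ia <- pixels_a[pr[, 1L]]
    ib <- pixels_a[pr[, 2L]]
  } else {
    ia <- pixels_a[((ids - 1) %% length(pixels_a)) + 1]
    ib <- pixels_b[((ids - 1) %/% length(pixels_a)) + 1]
  }
  if (method == "pearson") {
    za <- standardize_rows(abund[ia, , drop = FALSE])
    zb <- standardize_rows(abund[ib, , drop = FALSE])
    vals <- rowSums(za * zb) / (ncol(abund) - 1L)
  } else {
    a <- abund[ia, , drop = FALSE]; b <- abund[ib, , drop = FALSE]
    vals <- rowSums(a * b) /
      (sqrt(rowSums(a * a)) * sqrt(rowSums(b * b)))
  }
  cdf <- ecdf(vals)(grid)
  structure(list(values = vals, median = median(vals),
                 n_pairs = n_total, subsampled = n_total > max_pairs,
                 cdf = data.frame(s = grid, p = cdf), context = context),
            class = "similarity_distribution")
}

#' @export
print.similarity_distribution <- function(x, ...) {
  cat(sprintf("similarity_distribution (%s): %d values of %g pairs, median %.4f\n",
              x$context, length(x$values), x$n_pairs, x$median))
  invisible(x)
}

#' Simpson (Gini-Simpson) diversity index over cluster sizes
#'
#' The probability that two randomly selected pixels belong to different
#' clusters: `D = 1 - sum(p_i^2)` with `p_i = n_i / N` (draws with
#' replacement). `method = "unbiased"` uses the finite-sample form
#' `1 - sum(n_i (n_i - 1)) / (N (N - 1))` (draws without replacement).
#'
#' @param cluster_counts Nonnegative counts per cluster (e.g. from
#'   [cluster_sizes()]).
#' @param method `"gini"` (default) or `"unbiased"`.
#' @return The diversity `D` in `[0, 1 - 1/k]`.
#' @export
simpson_index <- function(cluster_counts, method = c("gini", "unbiased")) {
  method <- match.arg(method)
  n <- as.numeric(cluster_counts)
  stopifnot(all(n >= 0), sum(n) >= 1)
  total <- sum(n)
  if (method == "gini") {
    1 - sum((n / total)^2)
  } else {
    if (total < 2) return(0)
    1 - sum(n * (n - 1)) / (total * (total - 1))
  }
}

#' Compare a per-patient heterogeneity statistic between groups
#'
#' Two groups are compared with the two-sided Wilcoxon rank-sum test (exact
#' for 20 or fewer observations in total and no ties, otherwise the normal
#' approximation with tie correction); more than two groups with the
#' Kruskal-Wallis test.
#'
#' @param values Numeric statistic per patient (e.g. Simpson D, median
#'   similarity).
#' @param groups Group label per patient (2 or more levels, each with at
#'   least 2 observations).
#' @return List with `test`, `statistic`, `p.value`, and `medians` per group.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("each group needs at least 2 observations")
  meds <- tapply(values, groups, median)
  if (nlevels(groups) == 2L) {
    a <- values[groups == levels(groups)[1L]]
    b <- values[groups == levels(groups)[2L]]
    exact <- length(values) <= 20L && !any(duplicated(values))
    ht <- suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = !exact))
    list(test = "wilcoxon", statistic = unname(ht$statistic),
         p.value = ht$p.value, medians = meds)
  } else {
    ht <- kruskal.test(values, groups)
    list(test = "kruskal-wallis", statistic = unname(ht$statistic),
         p.value = ht$p.value, medians = meds)
  }
}

#' Per-ROI heterogeneity summary table
#'
#' Computes, for each ROI, the number of clusters and Simpson diversity at a
#' segmentation level, and the median intra-ROI pairwise similarity.
#'
#' @param abund Pooled abundance matrix.
#' @param tree A `segmentation_tree` over the same pixels.
#' @param pixels Pixel metadata data frame (as from [preprocess_study()]):
#'   columns `roi`, `patient_id`, `group`, `tissue`.
#' @param level Segmentation level for cluster-based indices.
#' @param max_pairs,seed Passed to [similarity_distribution()].
#' @return Data frame: one row per ROI with `roi`, `patient_id`, `group`,
#'   `tissue`, `n_pixels`, `n_clusters`, `simpson_d`, `median_similarity`.
#' @export
heterogeneity_summary <- function(abund, tree, pixels, level = 1L,
                                  max_pairs = 1e5, seed = 1L) {
  stopifnot(nrow(abund) == nrow(pixels), nrow(abund) == tree$n_pixels)
  rois <- unique(pixels$roi)
  rows <- lapply(rois, function(r) {
    idx <- which(pixels$roi == r)
    cs <- cluster_sizes(tree, level, idx)
    sim <- similarity_distribution(abund, idx, max_pairs = max_pairs,
                                   seed = seed, context = paste0("intra-", r))
    meta <- pixels[idx[1L], c("patient_id", "group", "tissue")]
    data.frame(roi = r, meta, n_pixels = length(idx),
               n_clusters = length(cs), simpson_d = simpson_index(cs),
               median_similarity = sim$median,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
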