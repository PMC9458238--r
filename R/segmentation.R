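#' Parameters of the DivIK segmentation
#'
#' @param k_max Largest number of clusters tried per split.
#' @param max_levels Maximum tree depth (number of segmentation levels).
#' @param min_cluster_fraction A split is accepted only if every child holds
#'   at least this fraction of the input pixels.
#' @param tau Minimum Dunn index for a split to be accepted. In the
#'   correlation metric an arbitrary bisection of an unstructured point cloud
#'   has inter-centroid distance close to 2 (the centroids are anti-correlated)
#'   over an intra-cluster diameter approaching 2, so its Dunn index
#'   concentrates near 1; requiring the minimum centroid separation to exceed
#'   twice the largest cluster diameter (`tau = 2`) rejects such null splits
#'   while genuinely clustered nodes score well above it.
#' @param n_restarts Number of seeded k-means++ restarts per candidate k.
#' @param filter_amplitude,filter_variance Switch the two region-driven
#'   feature-filter stages (low-amplitude drop, high-variance keep).
#' @param diameter_cap Clusters larger than this are subsampled (seeded) when
#'   computing the Dunn intra-cluster diameter.
#' @param min_features Passed to [select_features()].
#' @param seed Integer seed fixing all randomness.
#' @return A `divik_params` list.
#' @export
divik_params <- function(k_max = 10L, max_levels = 4L,
                         min_cluster_fraction = 0.001, tau = 2,
                         n_restarts = 10L, filter_amplitude = TRUE,
                         filter_variance = TRUE, diameter_cap = 2000L,
                         min_features = 8L, seed = 1L) {
  stopifnot(k_max >= 2L, max_levels >= 1L)
  list(k_max = as.integer(k_max), max_levels = as.integer(max_levels),
       min_cluster_fraction = min_cluster_fraction, tau = tau,
       n_restarts = as.integer(n_restarts),
       filter_amplitude = filter_amplitude,
       filter_variance = filter_variance,
       diameter_cap = as.integer(diameter_cap),
       min_features = as.integer(min_features), seed = as.integer(seed))
}

#' Region-driven feature selection
#'
#' Two-stage filter computed on the node's own pixels. Stage 1 fits a
#' 2-component Gaussian mixture to the log mean abundance per feature and
#' drops the low-mean (noise) component. Stage 2 fits a 2-component mixture to
#' the log variance of the remaining features and keeps the high-variance
#' component. A stage whose fit degenerates (component means closer than the
#' larger component SD, or SD ratio above 10) is skipped.
#'
#' @param abund Node abundance matrix (pixels x features, >= 2 features).
#' @param filter_amplitude,filter_variance Stage switches.
#' @param min_features A stage that would leave fewer than this many features
#'   is skipped: correlation distance over a handful of dimensions is
#'   degenerate (with 2 features every standardized vector collapses onto two
#'   points), so a filter must not starve the metric.
#' @return Logical feature mask. Fewer than 2 surviving features signals that
#'   the node should become a leaf (handled by [divik()]).
#' @export
select_features <- function(abund, filter_amplitude = TRUE,
                            filter_variance = TRUE, min_features = 4L) {
  if (ncol(abund) < 2L) stop("need at least 2 features")
  mask <- rep(TRUE, ncol(abund))
  floor_val <- 1e-12
  if (filter_amplitude) {
    lm <- log(pmax(colMeans(abund), floor_val))
    keep <- gmm_threshold_keep(lm, keep = "high")
    if (!is.null(keep) && sum(mask & keep) >= min_features)
      mask <- mask & keep
  }
  if (filter_variance && sum(mask) >= 2L) {
    lv <- log(pmax(col_vars(abund[, mask, drop = FALSE]), floor_val))
    keep <- gmm_threshold_keep(lv, keep = "high")
    if (!is.null(keep) && sum(keep) >= min_features) mask[mask] <- keep
  }
  mask
}

# Fit a 2-component 1-D GMM and return the keep-mask for the high-mean
# component, or NULL when the fit degenerates and the stage must be skipped.
# Degenerate means: the two components overlap (mean gap below the larger SD),
# their SD ratio exceeds 10, or a single Gaussian explains the values at least
# as well by BIC (i.e. there is no bimodality to threshold on).
gmm_threshold_keep <- function(values, keep = "high") {
  n <- length(values)
  if (n < 8L || sd(values) < 1e-12) return(NULL)
  fit <- tryCatch(fit_gmm1d_2comp(values), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  mu <- fit$mu; sg <- fit$sigma
  if (abs(mu[2] - mu[1]) < max(sg) || max(sg) / max(min(sg), 1e-12) > 10)
    return(NULL)
  s1 <- sd(values) * sqrt((n - 1) / n)
  bic1 <- -2 * sum(dnorm(values, mean(values), s1, log = TRUE)) + 2 * log(n)
  bic2 <- -2 * fit$loglik + 5 * log(n)
  if (bic1 <= bic2) return(NULL)
  post_hi <- fit$weight[2] * dnorm(values, mu[2], sg[2])
  post_lo <- fit$weight[1] * dnorm(values, mu[1], sg[1])
  mask <- if (keep == "high") post_hi >= post_lo else post_lo > post_hi
  if (sum(mask) < 2L || sum(!mask) < 1L) return(NULL)
  mask
}

# k-means++ initial centers (squared-Euclidean seeding) on row matrix xs.
kmeanspp_init <- function(xs, k) {
  n <- nrow(xs)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((xs - matrix(xs[centers[1L], ], n, ncol(xs), byrow = TRUE))^2)
  if (k > 1L) for (j in 2:k) {
    if (sum(d2) <= 0) {
      centers[j] <- sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums((xs - matrix(xs[centers[j], ], n, ncol(xs),
                                        byrow = TRUE))^2))
  }
  xs[centers, , drop = FALSE]
}

#' k-means under Pearson correlation distance
#'
#' Correlation distance `1 - r(x, y)` equals squared Euclidean distance
#' between row-standardized vectors divided by `2(p - 1)`, so Lloyd iterations
#' on standardized rows optimize the correlation-distance objective exactly.
#' Runs `n_restarts` seeded k-means++ initializations and keeps the solution
#' with the lowest objective; cluster numbering is canonicalized by centroid
#' order so equal partitions get equal labels.
#'
#' @param x Numeric matrix (observations in rows).
#' @param k Number of clusters.
#' @param n_restarts Restarts.
#' @param seed Integer seed.
#' @param iter_max Lloyd iteration cap per restart.
#' @return List with `cluster`, `centers` (on standardized rows), and
#'   `objective` (total within-cluster sum of squared standardized distances;
#'   divide by `2 (p - 1)` for summed correlation distances).
#' @export
kmeans_cor <- function(x, k, n_restarts = 10L, seed = 1L, iter_max = 100L) {
  xs <- standardize_rows(as.matrix(x))
  n <- nrow(xs)
  stopifnot(k >= 1L, k <= n)
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- withr::with_seed(seeds[r], {
      init <- kmeanspp_init(xs, k)
      tryCatch(suppressWarnings(
        kmeans(xs, centers = init, iter.max = iter_max,
               algorithm = "Lloyd")),
        error = function(e) NULL)
    })
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed for every restart (degenerate node)")
  ord <- do.call(order, as.data.frame(round(best$centers, 8)))
  relab <- match(seq_len(k), ord)
  list(cluster = relab[best$cluster],
       centers = best$centers[ord, , drop = FALSE],
       objective = best$tot.withinss)
}

# Dunn index in the correlation metric: minimum inter-centroid correlation
# distance over maximum intra-cluster diameter. Diameters of clusters above
# `cap` pixels are estimated on a seeded subsample.
dunn_index_cor <- function(xs, cluster, cap = 2000L, seed = 1L) {
  k <- max(cluster)
  p <- ncol(xs)
  cent <- t(vapply(seq_len(k), function(j)
    colMeans(xs[cluster == j, , drop = FALSE]), numeric(p)))
  cc <- suppressWarnings(cor(t(cent)))
  cc[!is.finite(cc)] <- 1
  inter <- 1 - cc
  min_inter <- min(inter[upper.tri(inter)])
  diam <- 0
  for (j in seq_len(k)) {
    idx <- which(cluster == j)
    if (length(idx) < 2L) next
    if (length(idx) > cap)
      idx <- withr::with_seed(seed + j, sample(idx, cap))
    sub <- xs[idx, , drop = FALSE]
    cm <- tcrossprod(sub) / (p - 1)
    dj <- 1 - min(cm)
    diam <- max(diam, dj)
  }
  if (diam <= 1e-12) return(Inf)
  min_inter / diam
}

#' DivIK: divisive iK-means segmentation with region-driven feature selection
#'
#' Recursively splits the pooled pixel set. At each node: select features on
#' the node's own pixels; standardize them within the node; try k-means with
#' correlation distance for k = 2..k_max (seeded k-means++ with restarts);
#' choose the k with the highest Dunn index; accept the split only when that
#' Dunn index reaches `tau` and every child is large enough; recurse to
#' `max_levels`. Pixels in a node that stops early keep their label at all
#' deeper levels, so every pixel is labeled at every level.
#'
#' @param abund Pooled abundance matrix (pixels x components).
#' @param params A [divik_params()] list.
#' @return A `segmentation_tree`: `labels` (pixels x levels integer matrix,
#'   level-wise consecutive ids), `nodes` (per-node records: level, parent,
#'   pixel count, chosen k, Dunn index, selected feature indices), `params`.
#' @export
divik <- function(abund, params = divik_params()) {
  abund <- as.matrix(abund)
  n <- nrow(abund)
  if (n < 2L * params$k_max)
    stop("need at least 2 * k_max pixels")
  node_at_level <- matrix(NA_integer_, n, params$max_levels)
  nodes <- list()
  next_id <- 0L

  new_node <- function(parent, level, idx) {
    next_id <<- next_id + 1L
    nodes[[next_id]] <<- list(id = next_id, parent = parent, level = level,
                              n_pixels = length(idx), k = NA_integer_,
                              dunn = NA_real_, features = integer(0),
                              is_leaf = TRUE)
    next_id
  }

  seal_leaf <- function(id, idx, level) {
    if (level < params$max_levels && level >= 1L)
      node_at_level[idx, (level + 1L):params$max_levels] <<- id
  }

  split_node <- function(id, idx, level) {
    # level = depth of this node; its children live at level + 1
    if (level >= params$max_levels) { seal_leaf(id, idx, level); return() }
    if (length(idx) < 4L ||
        length(idx) < 2 * params$min_cluster_fraction * n) {
      seal_leaf(id, idx, level); return()
    }
    sub <- abund[idx, , drop = FALSE]
    mask <- tryCatch(select_features(sub, params$filter_amplitude,
                                     params$filter_variance,
                                     params$min_features),
                     error = function(e) NULL)
    if (is.null(mask)) { seal_leaf(id, idx, level); return() }
    mask <- mask & col_vars(sub) > 1e-24
    if (sum(mask) < 2L) { seal_leaf(id, idx, level); return() }
    feat <- which(mask)
    z <- scale(sub[, feat, drop = FALSE])
    xs <- standardize_rows(z)
    if (all(abs(xs) < 1e-12)) { seal_leaf(id, idx, level); return() }

    ks <- 2:min(params$k_max, floor(length(idx) / 2))
    if (!length(ks)) { seal_leaf(id, idx, level); return() }
    node_seed <- params$seed + 7919L * (id %% 1000L)
    best_k <- NA_integer_; best_dunn <- -Inf; best_fit <- NULL
    for (k in ks) {
      fit <- tryCatch(
        kmeans_cor(xs, k, n_restarts = params$n_restarts, seed = node_seed + k),
        error = function(e) NULL)
      if (is.null(fit) || length(unique(fit$cluster)) < k) next
      d <- dunn_index_cor(xs, fit$cluster, cap = params$diameter_cap,
                          seed = node_seed)
      if (d > best_dunn) { best_dunn <- d; best_k <- k; best_fit <- fit }
    }
    min_child <- max(1, params$min_cluster_fraction * n)
    if (is.null(best_fit) || best_dunn < params$tau ||
        min(table(best_fit$cluster)) < min_child) {
      seal_leaf(id, idx, level)
      return()
    }
    nodes[[id]]$k <<- best_k
    nodes[[id]]$dunn <<- best_dunn
    nodes[[id]]$features <<- feat
    nodes[[id]]$is_leaf <<- FALSE
    for (j in seq_len(best_k)) {
      child_idx <- idx[best_fit$cluster == j]
      cid <- new_node(id, level + 1L, child_idx)
      node_at_level[child_idx, level + 1L] <<- cid
      split_node(cid, child_idx, level + 1L)
    }
  }

  root <- new_node(NA_integer_, 0L, seq_len(n))
  # root is level 0; if it never splits the whole image is one cluster
  node_at_level[, 1L] <- root
  split_node(root, seq_len(n), 0L)

  labels <- apply(node_at_level, 2L, function(col) as.integer(factor(col)))
  labels <- matrix(labels, nrow = n)
  structure(list(labels = labels, nodes = nodes, params = params,
                 n_pixels = n),
            class = "segmentation_tree")
}

#' @export
print.segmentation_tree <- function(x, ...) {
  counts <- apply(x$labels, 2L, function(l) length(unique(l)))
  cat(sprintf("segmentation_tree: %d pixels, %d levels; clusters per level: %s\n",
              x$n_pixels, ncol(x$labels), paste(counts, collapse = ", ")))
  invisible(x)
}

#' Cluster sizes at one segmentation level
#'
#' @param tree A `segmentation_tree` from [divik()].
#' @param level Level (1-based).
#' @param pixels Optional logical or integer pixel filter (e.g. one ROI).
#' @return Named integer vector: pixels per cluster id; sums to the number of
#'   selected pixels.
#' @export
cluster_sizes <- function(tree, level, pixels = NULL) {
  stopifnot(inherits(tree, "segmentation_tree"))
  if (!is_count(level) || level < 1 || level > ncol(tree$labels))
    stop("unknown segmentation level")
  lab <- tree$labels[, level]
  if (!is.null(pixels)) lab <- lab[pixels]
  tab <- table(lab)
  setNames(as.integer(tab), names(tab))
}

#' Serialize a segmentation tree
#'
#' Writes the node records as JSON (`<prefix>.json`) and the per-level labels
#' as TSV (`<prefix>_labels.tsv`, one row per pixel).
#'
#' @param tree A `segmentation_tree`.
#' @param prefix Output path prefix.
#' @export
write_segmentation_tree <- function(tree, prefix) {
  jsonlite::write_json(
    list(params = tree$params, n_pixels = tree$n_pixels, nodes = tree$nodes),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  lab <- as.data.frame(tree$labels)
  names(lab) <- paste0("level_", seq_len(ncol(lab)))
  utils::write.table(cbind(pixel = seq_len(nrow(lab)), lab),
                     paste0(prefix, "_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
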