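test_that("similarity index behaves like a correlation", {
  expect_equal(similarity(c(1, 5, 2, 7), c(1, 5, 2, 7)), 1)
  x <- c(1, 5, 2, 7)
  expect_equal(similarity(x, -x), -1)
  expect_equal(similarity(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1)
  expect_equal(similarity(c(1, 2, 3), c(5, 7, 9)), 1)  # affine invariance
  expect_error(similarity(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(similarity(1, 2), "length")
  expect_equal(similarity(c(1, 0, 0), c(2, 0, 0), method = "cosine"), 1)
})

test_that("similarity distributions count pairs correctly", {
  withr::local_seed(1L)
  ab <- matrix(rnorm(40), 4L)
  # two pixels -> exactly one pair
  sd2 <- similarity_distribution(ab, 1:2)
  expect_length(sd2$values, 1L)
  expect_equal(sd2$n_pairs, 1)
  # intra mode: n(n-1)/2 unordered pairs, no self-pairs
  sd4 <- similarity_distribution(ab, 1:4)
  expect_length(sd4$values, 6L)
  # inter mode: full cross product
  sdx <- similarity_distribution(ab, 1:2, 3:4)
  expect_length(sdx$values, 4L)
  expect_error(similarity_distribution(ab, integer(0), 1:2), "empty")

  # identical spectra: all similarities 1, median 1, CDF ends at 1
  ab1 <- matrix(rep(c(1, 3, 2, 5, 4), each = 6L), 6L)
  sdi <- similarity_distribution(ab1, 1:6)
  expect_true(all(abs(sdi$values - 1) < 1e-12))
  expect_equal(sdi$median, 1)
  expect_true(all(diff(sdi$cdf$p) >= 0))
  expect_equal(sdi$cdf$p[nrow(sdi$cdf)], 1)
})

test_that("subsampled similarity median matches the exhaustive value", {
  withr::local_seed(2L)
  prof <- matrix(rlnorm(3 * 25), 3L)
  ab <- prof[sample(1:3, 300L, replace = TRUE), ] *
    exp(matrix(rnorm(300 * 25, 0, 0.2), 300L))
  full <- similarity_distribution(ab, 1:300, max_pairs = Inf)
  expect_equal(full$n_pairs, 300 * 299 / 2)
  sub <- similarity_distribution(ab, 1:300, max_pairs = 1e4, seed = 7L)
  expect_true(sub$subsampled)
  expect_length(sub$values, 1e4)
  expect_lt(abs(sub$median - full$median), 0.01)
})

test_that("similarity is invariant under component permutation", {
  withr::local_seed(3L)
  ab <- matrix(rlnorm(20 * 30), 20L)
  perm <- sample(30L)
  a <- similarity_distribution(ab, 1:20, seed = 1L)
  b <- similarity_distribution(ab[, perm], 1:20, seed = 1L)
  expect_equal(a$median, b$median)
  expect_equal(sort(a$values), sort(b$values))
})

test_that("Simpson index matches hand values and its brute-force definition", {
  expect_equal(simpson_index(10), 0)
  expect_equal(simpson_index(rep(5, 4)), 0.75)
  expect_equal(simpson_index(c(3, 1)), 0.375)

  # oracle: probability two draws (with replacement) differ, by enumeration
  brute <- function(counts) {
    lab <- rep(seq_along(counts), counts)
    mean(outer(lab, lab, "!="))
  }
  withr::local_seed(4L)
  for (i in 1:25) {
    k <- sample(1:6, 1L)
    counts <- sample(1:12, k, replace = TRUE)
    while (sum(counts) > 50) counts <- ceiling(counts / 2)
    expect_equal(simpson_index(counts), brute(counts), tolerance = 1e-12)
  }

  # bounds: 0 <= D <= 1 - 1/k; unbiased form differs by < 1/N
  for (i in 1:25) {
    counts <- sample(1:20, sample(1:5, 1L), replace = TRUE)
    d <- simpson_index(counts)
    expect_gte(d, 0)
    expect_lte(d, 1 - 1 / length(counts) + 1e-12)
    du <- simpson_index(counts, method = "unbiased")
    expect_lt(abs(d - du), 1 / sum(counts) + 1e-12)
  }
})

test_that("moving a pixel from a larger to a smaller cluster never lowers D", {
  withr::local_seed(5L)
  for (i in 1:50) {
    counts <- sample(2:30, sample(2:6, 1L), replace = TRUE)
    big <- which.max(counts)
    small <- which.min(counts)
    if (big == small) next
    moved <- counts
    moved[big] <- moved[big] - 1L
    moved[small] <- moved[small] + 1L
    expect_gte(simpson_index(moved) + 1e-12, simpson_index(counts))
  }
})

test_that("group comparisons use the right test and match enumeration", {
  # identical groups: rank statistic at its mean, p = 1
  res <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3L))
  expect_equal(res$p.value, 1)

  # (1,2,3) vs (4,5,6): exact two-sided p = 2/20 by enumerating C(6,3) splits
  vals <- c(1, 2, 3, 4, 5, 6)
  splits <- combn(6L, 3L)
  w_obs <- sum(rank(vals)[1:3]) # rank sum of group a
  extreme <- apply(splits, 2L, function(idx) {
    w <- sum(rank(vals)[idx])
    abs(w - 10.5) >= abs(w_obs - 10.5)
  })
  expect_equal(mean(extreme), 0.1)
  res <- compare_groups(vals, rep(c("a", "b"), each = 3L))
  expect_equal(res$test, "wilcoxon")
  expect_equal(res$p.value, 0.1)

  # three groups route to Kruskal-Wallis
  res3 <- compare_groups(rnorm(30), rep(c("a", "b", "c"), 10L))
  expect_equal(res3$test, "kruskal-wallis")
  expect_error(compare_groups(1:5, rep("a", 5L)), "2 groups")
})

test_that("two-arm synthetic study shows the NED-analog heterogeneity pattern", {
  ch <- tiny_config(n_clusters_per_roi = 4L, n_patients_per_group = 8L,
                    seed = 71L)
  cl <- ch
  cl$n_clusters_per_roi <- 2L
  cl$cluster_proportions <- "skewed"
  study <- simulate_two_arm_study(ch, cl)
  prep <- preprocess_study(lapply(study$patients, `[[`, "dataset"))
  tree <- divik(prep$abundance, divik_params(max_levels = 1L, seed = 2L))
  het <- heterogeneity_summary(prep$abundance, tree, prep$pixels,
                               max_pairs = 5e3, seed = 2L)
  expect_equal(nrow(het), 16L)
  simp <- compare_groups(het$simpson_d, het$group)
  sim <- compare_groups(het$median_similarity, het$group)
  expect_gt(simp$medians[["high"]], simp$medians[["low"]])
  expect_lt(sim$medians[["high"]], sim$medians[["low"]])
  expect_lt(simp$p.value, 0.05)
})
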