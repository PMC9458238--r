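test_that("Cohen's d matches hand arithmetic and Monte Carlo", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(0, 2), c(2, 4)), -sqrt(2))
  expect_warning(d0 <- cohens_d(c(1, 1, 1), c(1, 1, 1)), "pooled")
  expect_true(is.na(d0))

  withr::local_seed(10L)
  a <- rnorm(1e4, 0.5, 1)
  b <- rnorm(1e4, 0, 1)
  expect_lt(abs(cohens_d(a, b) - 0.5), 0.05)
})

test_that("Cohen's d is antisymmetric and scale invariant", {
  withr::local_seed(11L)
  for (i in 1:20) {
    a <- rnorm(20, runif(1, -2, 2), runif(1, 0.5, 2))
    b <- rnorm(15, runif(1, -2, 2), runif(1, 0.5, 2))
    expect_equal(cohens_d(a, b), -cohens_d(b, a))
    cc <- runif(1, 0.1, 10)
    expect_equal(cohens_d(cc * a, cc * b), cohens_d(a, b), tolerance = 1e-12)
  }
})

test_that("Cohen's h matches exact arcsine values", {
  expect_equal(cohens_h(0.3, 0.3), 0)
  expect_equal(cohens_h(1, 0), pi)
  expect_equal(cohens_h(0.25, 0.75), -pi / 3)
  expect_equal(cohens_h(0.75, 0.25), pi / 3)
  expect_error(cohens_h(1.2, 0.5), "proportions")
})

test_that("effect size classes follow the 0.2 / 0.5 / 0.8 conventions", {
  cls <- effect_size_class(c(0.1, -0.2, 0.49, -0.5, 0.79, 0.8, -3))
  expect_equal(as.character(cls),
               c("negligible", "small", "small", "medium", "medium",
                 "large", "large"))
})

test_that("differential selection finds planted shifted components", {
  withr::local_seed(12L)
  n <- 2000L
  null_a <- matrix(rnorm(n * 500L), n)
  null_b <- matrix(rnorm(n * 500L), n)
  shift_a <- matrix(rnorm(n * 50L, mean = 1), n)  # true d = 1.0
  shift_b <- matrix(rnorm(n * 50L), n)
  ab <- rbind(cbind(null_a, shift_a), cbind(null_b, shift_b))
  res <- differential_components(ab, seq_len(n), n + seq_len(n),
                                 threshold_class = "medium")
  truth <- c(rep(FALSE, 500L), rep(TRUE, 50L))
  sel <- seq_len(550L) %in% as.integer(res$selected)
  expect_gte(sum(sel & truth) / 50L, 0.95)
  expect_lte(sum(sel & !truth) / 500L, 0.05)

  # a group contrasted against itself selects nothing
  self <- differential_components(ab, seq_len(n), seq_len(n))
  expect_length(self$selected, 0L)

  # swapping the contrast inverts directions, |d| unchanged
  swp <- differential_components(ab, n + seq_len(n), seq_len(n))
  expect_equal(swp$table$d, -res$table$d)
  expect_setequal(swp$selected, res$selected)
})

test_that("Venn region counts equal brute-force membership enumeration", {
  expect_equal(unname(overlap_sets(1:3, 4:6, 7:9)[c("AB", "AC", "BC", "ABC")]),
               c(0L, 0L, 0L, 0L))
  ident <- overlap_sets(1:5, 1:5, 1:5)
  expect_equal(unname(ident[["ABC"]]), 5L)
  expect_equal(sum(ident), 5L)

  withr::local_seed(13L)
  for (i in 1:10) {
    u <- 1:40
    A <- sample(u, sample(0:30, 1L))
    B <- sample(u, sample(0:30, 1L))
    C <- sample(u, sample(0:30, 1L))
    v <- overlap_sets(A, B, C)
    brute <- table(factor(paste0(u %in% A + 0, u %in% B + 0, u %in% C + 0),
                          levels = c("100", "010", "001", "110", "101",
                                     "011", "111")))
    expect_equal(unname(as.integer(v)), unname(as.integer(brute)))
  }
})

test_that("Fisher's exact test matches exhaustive enumeration for 2x2 tables", {
  # oracle: enumerate all tables with the observed margins, sum probabilities
  # of tables at most as likely as the observed one
  fisher_brute <- function(tab) {
    r <- rowSums(tab); cns <- colSums(tab); n <- sum(tab)
    p_of <- function(a) dhyper(a, r[1L], r[2L], cns[1L])
    p_obs <- p_of(tab[1L, 1L])
    a_all <- max(0L, cns[1L] - r[2L]):min(r[1L], cns[1L])
    sum(p_of(a_all)[p_of(a_all) <= p_obs * (1 + 1e-7)])
  }
  withr::local_seed(14L)
  for (i in 1:30) {
    tab <- matrix(sample(0:10, 4L, replace = TRUE), 2L)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) next
    expect_equal(fisher_exact(tab), fisher_brute(tab), tolerance = 1e-9)
  }
})

test_that("Fisher's exact test is invariant to empty categories and bounded tables", {
  tab <- matrix(c(4, 6, 25, 11, 12, 16), 3L, byrow = TRUE)
  with_zero <- rbind(tab, c(0, 0))
  expect_equal(fisher_exact(with_zero), fisher_exact(tab), tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(2, 1), 1L)), "2 x 2")
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2L)), "nonnegative")
  big <- matrix(c(9000, 2000, 2000, 9000), 2L)
  expect_error(fisher_exact(big), "Monte Carlo")
  p_mc <- fisher_exact(matrix(c(20, 10, 10, 20), 2L), simulate = TRUE,
                       B = 2e4, seed = 5L)
  p_ex <- fisher_exact(matrix(c(20, 10, 10, 20), 2L))
  expect_lt(abs(p_mc - p_ex), 0.02)
})

test_that("Student's t matches the closed form on hand-computable inputs", {
  a <- c(1, 2, 3, 4)
  b <- c(3, 5, 7, 9)
  res <- students_t(a, b)
  sp <- sqrt(((3) * var(a) + (3) * var(b)) / 6)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, 6)
  expect_equal(res$p.value, 2 * pt(t_hand, 6))
})

test_that("LHR association detects a planted ordinal trend and is calibrated", {
  # constant diversity: rho exactly 0
  flat <- lhr_association(rep(0.5, 30),
                          rep(c("weak", "intermediate", "strong"), 10L))
  expect_equal(flat$spearman$rho, 0)

  withr::local_seed(15L)
  lhr <- rep(c("weak", "intermediate", "strong"), each = 25L)
  d <- 0.3 + 0.1 * rep(0:2, each = 25L) + rnorm(75, 0, 0.08)
  res <- lhr_association(d, lhr)
  expect_gt(res$spearman$rho, 0)
  expect_lt(res$spearman$p.value, 0.05)
  expect_lt(res$kruskal$p.value, 0.05)

  # permuting the labels kills the association ~95% of the time at alpha=0.05
  rej <- vapply(1:200, function(i) {
    perm <- withr::with_seed(2000L + i, sample(lhr))
    lhr_association(d, perm)$spearman$p.value < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.10)
  expect_gt(mean(rej), 0.005)

  # contingency side: LHR x group Fisher's p
  grp <- rep(c("NED", "PD"), length.out = 75L)
  res2 <- lhr_association(d, lhr, group = grp)
  expect_true(res2$fisher_p >= 0 && res2$fisher_p <= 1)
  expect_error(lhr_association(d[1:25], lhr[1:25]), "categories")
})
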