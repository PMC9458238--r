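make_ds <- function(mz, spectra) {
  n <- nrow(spectra)
  msi_dataset(mz, spectra,
              coords = data.frame(x = seq_len(n), y = rep(1L, n)),
              roi = rep("r1", n),
              roi_meta = data.frame(roi = "r1", patient_id = "p1",
                                    group = "high", tissue = "T",
                                    lhr = NA_character_))
}

test_that("mass-channel unification is the identity on matching axes and exact on linear spectra", {
  mz <- seq(700, 710, by = 0.5)
  s <- matrix(runif(2 * length(mz)), 2L)
  ds <- make_ds(mz, s)
  out <- unify_mass_channels(list(ds, ds))
  expect_equal(out[[1L]]$spectra, s)
  expect_equal(out[[2L]]$mz, mz)

  # axes offset by half a channel; constant spectrum stays constant
  mz2 <- mz + 0.25
  ds2 <- make_ds(mz2, matrix(3, 2L, length(mz)))
  out <- unify_mass_channels(list(make_ds(mz, matrix(3, 2L, length(mz))), ds2))
  expect_true(all(abs(out[[2L]]$spectra - 3) < 1e-12))

  # linear ramp resampled to midpoints equals analytic midpoint values
  ramp <- matrix(2 * mz + 1, 1L)
  dsr <- make_ds(mz, ramp)
  out <- unify_mass_channels(list(dsr, make_ds(mz2, matrix(0, 1L, length(mz2)))))
  expect_equal(as.numeric(out[[1L]]$spectra), 2 * out[[1L]]$mz + 1,
               tolerance = 1e-12)
})

test_that("unification rejects disjoint m/z ranges", {
  a <- make_ds(seq(700, 710, 0.5), matrix(1, 1L, 21L))
  b <- make_ds(seq(800, 810, 0.5), matrix(1, 1L, 21L))
  expect_error(unify_mass_channels(list(a, b)), "disjoint")
})

test_that("baseline subtraction removes flat baselines and preserves peaks", {
  expect_equal(subtract_baseline(rep(5, 200), 21L), rep(0, 200))
  expect_error(subtract_baseline(rep(5, 10), 21L), "larger")

  mz <- seq(0, 100, by = 0.1)
  peak <- 10 * dnorm(mz, 50, 1)
  out <- subtract_baseline(peak, 201L)  # window of 20 m/z >> peak width
  apex <- which.max(peak)
  expect_equal(out[apex], peak[apex], tolerance = 0.01 * max(peak))

  # peak on a linear ramp: residual baseline bounded by slope * window
  slope <- 0.02
  ramp <- slope * mz
  out2 <- subtract_baseline(peak + ramp, 201L)
  off_peak <- abs(mz - 50) > 10
  expect_lt(max(out2[off_peak]), slope * 20.1)
})

test_that("TIC outlier flagging finds planted outliers and nothing else", {
  mz <- seq(700, 710, 0.5)
  s <- matrix(rep(1 + runif(21), each = 1000), 1000L, byrow = FALSE)
  ds <- make_ds(mz, s)
  expect_false(any(detect_outlier_pixels(ds)))

  s2 <- s
  s2[500L, ] <- s2[500L, ] * 100
  flags <- detect_outlier_pixels(make_ds(mz, s2))
  expect_equal(which(flags), 500L)

  sim <- simulate_dataset(tiny_config(outlier_fraction = 0.02, seed = 13L))
  flags <- detect_outlier_pixels(sim$dataset)
  truth <- sim$truth$outlier_mask
  sens <- sum(flags & truth) / sum(truth)
  false_rate <- sum(flags & !truth) / sum(!truth)
  expect_gte(sens, 0.9)
  expect_lte(false_rate, 0.01)
})

test_that("peak alignment recovers constructed shifts", {
  sim <- simulate_dataset(clean_config(seed = 17L))
  ref <- colMeans(sim$dataset$spectra)
  ds <- sim$dataset

  out <- align_peaks(ds, ref)
  expect_true(all(attr(out, "shifts")[1:5] == 0L))

  # a pixel shifted +2 channels gets estimated shift -2 and is restored
  n <- length(ref)
  shifted <- ds
  orig <- shifted$spectra[1L, ]
  shifted$spectra[1L, ] <- c(0, 0, orig[1:(n - 2)])
  out <- align_peaks(shifted, ref)
  expect_equal(attr(out, "shifts")[1L], -2L)
  # edge channels shifted out of range are zero-padded, so compare the interior
  expect_equal(out$spectra[1L, 3:(n - 2L)], orig[3:(n - 2L)])

  # random per-pixel jitter in U{-3..3} is recovered for >= 95% of pixels
  jit <- withr::with_seed(99L, sample(-3:3, nrow(ds$spectra), replace = TRUE))
  jds <- ds
  for (i in seq_len(nrow(ds$spectra))) {
    src <- seq_len(n) + jit[i]
    ok <- src >= 1L & src <= n
    row <- numeric(n); row[ok] <- ds$spectra[i, src[ok]]
    jds$spectra[i, ] <- row
  }
  out <- align_peaks(jds, ref)
  expect_gte(mean(attr(out, "shifts") == jit), 0.95)
})

test_that("TIC normalization equalizes totals while keeping the scale", {
  sim <- simulate_dataset(tiny_config(seed = 19L, outlier_fraction = 0))
  ds <- tic_normalize(sim$dataset)
  tics <- rowSums(ds$spectra)
  expect_lt(diff(range(tics)) / mean(tics), 1e-9)
  expect_equal(mean(tics), mean(rowSums(sim$dataset$spectra)))

  # a pixel with TIC twice the mean is halved
  mz <- seq(700, 710, 0.5)
  s <- rbind(rep(1, 21), rep(1, 21), rep(4, 21))  # TICs 21, 21, 84; mean 42
  ds2 <- tic_normalize(make_ds(mz, s))
  expect_equal(ds2$spectra[3L, ], rep(2, 21))
  # equal-TIC input is unchanged
  ds3 <- tic_normalize(make_ds(mz, s[1:2, ]))
  expect_equal(ds3$spectra, s[1:2, ])
})

test_that("GMM componentization recovers planted single and double peaks", {
  mz <- seq(990, 1010, by = 0.05)
  y <- 5 * dnorm(mz, 1000, 0.3)
  m <- fit_gmm_components(y, mz, sigma_bounds = c(0.05, 3))
  expect_equal(nrow(m), 1L)
  expect_lt(abs(m$mu - 1000), 0.05)
  expect_lt(abs(m$sigma - 0.3), 0.05)

  y2 <- 5 * dnorm(mz, 1000, 0.3) + 3 * dnorm(mz, 1003, 0.3)
  m2 <- fit_gmm_components(y2, mz, sigma_bounds = c(0.05, 3))
  expect_equal(nrow(m2), 2L)
  expect_lt(abs(m2$mu[1] - 1000), 0.025)
  expect_lt(abs(m2$mu[2] - 1003), 0.025)
  expect_gt(m2$weight[1], m2$weight[2])

  expect_error(fit_gmm_components(rep(1, length(mz)), mz), "maxima")
})

test_that("abundance estimation matches the analytic Gaussian inner product", {
  mz <- seq(900, 1100, by = 0.1)
  model <- component_model(mu = c(950, 1050), sigma = c(1, 2),
                           weight = c(0.5, 0.5))
  a <- 7
  spec <- a * dnorm(mz, 950, 1)
  ab <- estimate_abundance(matrix(spec, 1L), model, mz)
  # integral of a Gaussian squared: 1 / (2 sigma sqrt(pi))
  expect_equal(unname(ab[1L, 1L]), a / (2 * 1 * sqrt(pi)), tolerance = 1e-6)
  expect_lt(ab[1L, 2L], 1e-10)
  expect_equal(as.numeric(estimate_abundance(matrix(0, 1L, length(mz)), model, mz)),
               c(0, 0))
  expect_error(estimate_abundance(matrix(1, 1L, length(mz)), model,
                                  seq(1, 2, length.out = length(mz))),
               "axis")
})

test_that("estimated abundances correlate with planted profiles on clean data", {
  sim <- simulate_dataset(clean_config(seed = 23L))
  prep <- preprocess_study(list(sim$dataset))
  truth <- sim$truth
  # match fitted components to planted peaks, then compare profiles per pixel
  comp_peak <- vapply(prep$model$mu, function(m)
    which.min(abs(truth$peak_means - m)), integer(1))
  # expected estimator value for spectrum a * Gauss(mu, sigma) is
  # a / (2 sigma sqrt(pi)), so scale the planted profiles accordingly
  planted <- truth$cluster_mean_profiles[truth$cluster_label_map, comp_peak]
  planted <- sweep(planted, 2L, 2 * prep$model$sigma * sqrt(pi), "/")
  cors <- vapply(seq_len(nrow(planted)), function(i)
    cor(prep$abundance[i, ], planted[i, ]), numeric(1))
  expect_gt(min(cors), 0.99)
})

test_that("the pipeline applies stages in the canonical order and is idempotent", {
  sim <- simulate_dataset(tiny_config(seed = 29L))
  prep <- preprocess_study(list(sim$dataset))
  expect_equal(prep$provenance,
               c("unify_mass_channels", "subtract_baseline",
                 "detect_outlier_pixels", "align_peaks", "tic_normalize",
                 "fit_gmm_components", "estimate_abundance"))

  # idempotence on clean data: re-running the pixel-level stages changes nothing
  clean <- simulate_dataset(clean_config(seed = 29L))$dataset
  once <- tic_normalize(align_peaks(subtract_baseline(clean, 101L)))
  twice <- tic_normalize(align_peaks(subtract_baseline(once, 101L)))
  # residual change is bounded by the Gaussian tail floor between peaks
  expect_lt(max(abs(twice$spectra - once$spectra)), 1e-3 * max(once$spectra))
  expect_true(all(attr(twice, "shifts") == 0L))
  tics <- rowSums(twice$spectra)
  expect_lt(diff(range(tics)) / mean(tics), 1e-9)
})

test_that("a full-range model with ~1776 peptide species fits within minutes", {
  withr::local_seed(31L)
  n_pk <- 1776L
  mu <- 712 + (seq_len(n_pk) - 1) * 1.25 + runif(n_pk, -0.2, 0.2)
  sg <- runif(n_pk, 0.25, 0.35)
  mz <- seq(700, 3000, by = 0.125)
  y <- numeric(length(mz))
  for (k in seq_len(n_pk)) {
    idx <- which(mz > mu[k] - 3 & mz < mu[k] + 3)
    y[idx] <- y[idx] + rlnorm(1, 0, 0.5) * dnorm(mz[idx], mu[k], sg[k])
  }
  t0 <- Sys.time()
  m <- fit_gmm_components(y, mz, sigma_bounds = c(0.06, 1))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 300)
  # the model operates at the same scale as the planted species set
  expect_gt(nrow(m), n_pk / 2)
  expect_lt(nrow(m), n_pk * 2)
})
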