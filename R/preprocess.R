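#' Unify the mass channels of several MSI datasets
#'
#' Resamples every dataset onto one common m/z axis by linear interpolation.
#' The common axis spans the intersection of the native ranges and uses the
#' finest native channel spacing. Datasets already sharing an identical axis
#' are returned unchanged.
#'
#' @param datasets A list of [msi_dataset()]s with overlapping m/z ranges.
#' @return The list of datasets, all on the common axis.
#' @export
unify_mass_channels <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  lapply(datasets, validate_msi_dataset)
  axes <- lapply(datasets, `[[`, "mz")
  same <- all(vapply(axes, function(a)
    length(a) == length(axes[[1L]]) && max(abs(a - axes[[1L]])) < 1e-9,
    logical(1)))
  if (same)
    return(lapply(datasets, record_stage, "unify_mass_channels"))
  lo <- max(vapply(axes, min, numeric(1)))
  hi <- min(vapply(axes, max, numeric(1)))
  if (lo >= hi) stop("m/z ranges are disjoint; cannot unify mass channels")
  spacing <- min(vapply(axes, function(a) median(diff(a)), numeric(1)))
  new_mz <- seq(lo, hi, by = spacing)
  lapply(datasets, function(d) {
    pos <- findInterval(new_mz, d$mz, rightmost.closed = TRUE)
    pos <- pmin(pmax(pos, 1L), length(d$mz) - 1L)
    t <- (new_mz - d$mz[pos]) / (d$mz[pos + 1L] - d$mz[pos])
    s <- sweep(d$spectra[, pos, drop = FALSE], 2L, 1 - t, "*") +
      sweep(d$spectra[, pos + 1L, drop = FALSE], 2L, t, "*")
    out <- msi_dataset(new_mz, s, d$coords, d$roi, d$roi_meta)
    out$provenance <- c(d$provenance, "unify_mass_channels")
    out
  })
}

#' Subtract the chemical baseline from spectra
#'
#' Estimates the baseline as a rolling minimum followed by moving-average
#' smoothing of the minimum envelope, subtracts it, and clips negatives to
#' zero.
#'
#' @param x A numeric spectrum, a pixels-by-channels matrix, or an
#'   [msi_dataset()].
#' @param window Window width in channels (>= 3); should be much wider than a
#'   peak so peaks survive and much narrower than the baseline's variation.
#' @return Object of the same shape with the baseline removed.
#' @export
subtract_baseline <- function(x, window = 101L) {
  if (inherits(x, "msi_dataset")) {
    x$spectra <- subtract_baseline(x$spectra, window)
    return(record_stage(x, "subtract_baseline"))
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else x
  window <- as.integer(window)
  if (window < 3L) stop("window must be at least 3 channels")
  if (window > ncol(m)) stop("window larger than spectrum length")
  env <- roll_mean_rows(roll_min_rows(m, window), window)
  out <- pmax(m - env, 0)
  if (vec) as.numeric(out) else out
}

#' Flag outlying pixel spectra by robust TIC screening
#'
#' Flags pixels whose log total ion current (TIC) lies outside the median
#' +/- 3 robust standard deviations (MAD-based) of the dataset. Flagged pixels
#' are meant to be excluded from all downstream stages.
#'
#' @param dataset An [msi_dataset()] with at least 10 pixels.
#' @param n_sd Number of robust SDs delimiting the inlier band.
#' @param sd_floor Lower bound (log-intensity units) on the robust SD. On
#'   nearly noise-free data the MAD collapses toward zero and legitimate
#'   biological TIC structure (e.g. molecular clusters with different total
#'   signal) would be flagged wholesale; the floor encodes the smallest TIC
#'   spread still considered ordinary acquisition variation.
#' @return Logical vector, `TRUE` for outlier pixels.
#' @export
detect_outlier_pixels <- function(dataset, n_sd = 3, sd_floor = 0.25) {
  validate_msi_dataset(dataset)
  if (n_pixels(dataset) < 10L) stop("need at least 10 pixels")
  tic <- rowSums(dataset$spectra)
  if (any(tic <= 0)) {
    pos_min <- min(tic[tic > 0])
    return(tic <= 0 |
             detect_outlier_pixels_log(log(pmax(tic, pos_min)), n_sd, sd_floor))
  }
  detect_outlier_pixels_log(log(tic), n_sd, sd_floor)
}

detect_outlier_pixels_log <- function(lt, n_sd, sd_floor) {
  med <- median(lt)
  s <- max(mad(lt), sd_floor)
  abs(lt - med) > n_sd * s
}

#' Align pixel spectra to a reference by constant channel shift
#'
#' For each pixel, the integer channel shift (within `+/- max_shift`) that
#' maximizes the cross-correlation with the reference spectrum is estimated
#' and applied. A pixel whose features sit `+s` channels right of the
#' reference gets shift `-s`.
#'
#' @param dataset An [msi_dataset()].
#' @param reference Reference spectrum on the same axis; defaults to the
#'   dataset's mean spectrum.
#' @param max_shift Maximum absolute shift in channels.
#' @return The dataset with shifted spectra; the applied per-pixel shift is
#'   attached as attribute `"shifts"`.
#' @export
align_peaks <- function(dataset, reference = NULL, max_shift = 5L) {
  validate_msi_dataset(dataset)
  s <- dataset$spectra
  n <- ncol(s)
  if (is.null(reference)) reference <- colMeans(s)
  if (length(reference) != n) stop("reference must be on the same m/z axis")
  shifts <- seq.int(-max_shift, max_shift)
  scores <- vapply(shifts, function(sh) {
    # score(sh) = sum_j spec[j] * ref[j + sh]
    rs <- numeric(n)
    src <- seq_len(n) + sh
    ok <- src >= 1L & src <= n
    rs[ok] <- reference[src[ok]]
    as.numeric(s %*% rs)
  }, numeric(nrow(s)))
  best <- shifts[max.col(scores, ties.method = "first")]
  out <- matrix(0, nrow(s), n)
  for (sh in unique(best)) {
    rows <- which(best == sh)
    src <- seq_len(n) - sh
    ok <- src >= 1L & src <= n
    out[rows, which(ok)] <- s[rows, src[ok], drop = FALSE]
  }
  dataset$spectra <- out
  dataset <- record_stage(dataset, "align_peaks")
  attr(dataset, "shifts") <- best
  dataset
}

#' Normalize pixel spectra to a common total ion current
#'
#' Divides each spectrum by its summed intensity and multiplies by the mean
#' TIC over pixels, so intensities keep their original scale.
#'
#' @param dataset An [msi_dataset()] with nonnegative spectra.
#' @param target Target TIC; defaults to the dataset's mean TIC. Pass a pooled
#'   value to put several datasets on one scale.
#' @return The TIC-normalized dataset.
#' @export
tic_normalize <- function(dataset, target = NULL) {
  validate_msi_dataset(dataset)
  tic <- rowSums(dataset$spectra)
  if (any(tic <= 0))
    stop("zero-TIC pixel encountered; remove outliers before normalization")
  if (is.null(target)) target <- mean(tic)
  dataset$spectra <- dataset$spectra * (target / tic)
  record_stage(dataset, "tic_normalize")
}

#' Model the average spectrum as a mixture of Gaussian peaks
#'
#' Treats the (baseline-subtracted, nonnegative) average spectrum as a density
#' over m/z; initializes one component at every local maximum above a noise
#' threshold; refines centers, widths and weights by expectation-maximization
#' on the binned intensities; prunes vanishing or implausibly wide/narrow
#' components. Each retained component represents one tryptic peptide species.
#'
#' @param average_spectrum Nonnegative intensity vector.
#' @param mz_axis The m/z axis (strictly increasing, same length).
#' @param noise_quantile Intensity quantile used as the local-maximum
#'   threshold (default 0.5, the median).
#' @param w_min Minimum mixture weight of a retained component.
#' @param sigma_bounds Plausible peak-width range in m/z; defaults to
#'   `c(0.5, 50) * channel spacing`.
#' @param sigma_init Initial component width; defaults to 3 channel spacings.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return A [component_model()].
#' @export
fit_gmm_components <- function(average_spectrum, mz_axis,
                               noise_quantile = 0.5, w_min = 1e-5,
                               sigma_bounds = NULL, sigma_init = NULL,
                               max_iter = 500L, tol = 1e-8) {
  y <- as.numeric(average_spectrum)
  stopifnot(length(y) == length(mz_axis), !is.unsorted(mz_axis))
  if (any(y < 0)) stop("average spectrum must be nonnegative (baseline-subtracted)")
  n <- length(y)
  spacing <- median(diff(mz_axis))
  if (is.null(sigma_bounds)) sigma_bounds <- c(0.5, 50) * spacing
  if (is.null(sigma_init)) sigma_init <- 3 * spacing
  thr <- quantile(y, noise_quantile, names = FALSE)
  is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE) & y > thr & y > 0
  # collapse plateau runs to their first channel
  peaks <- which(is_max)
  if (length(peaks) > 1L)
    peaks <- peaks[c(TRUE, diff(peaks) > 1L)]
  if (!length(peaks))
    stop("no local maxima above the noise threshold; cannot initialize components")
  fit <- fit_gmm1d(mz_axis, w = y, mu0 = mz_axis[peaks],
                   sigma0 = sigma_init, pi0 = y[peaks],
                   max_iter = max_iter, tol = tol,
                   sigma_floor = sigma_bounds[1])
  keep <- fit$weight >= w_min & fit$sigma >= sigma_bounds[1] &
    fit$sigma <= sigma_bounds[2]
  if (!any(keep)) stop("all components pruned; check sigma_bounds / w_min")
  component_model(fit$mu[keep], fit$sigma[keep],
                  fit$weight[keep] / sum(fit$weight[keep]))
}

#' Estimate per-pixel component abundances
#'
#' The abundance of component k in pixel p is the inner product of the pixel
#' spectrum with the component's unit-area Gaussian profile:
#' `sum_channels spectrum_p(mz) * Gauss(mz; mu_k, sigma_k) * dmz`.
#'
#' @param x An [msi_dataset()] or a pixels-by-channels matrix.
#' @param model A [component_model()].
#' @param mz_axis Required when `x` is a bare matrix.
#' @return Pixels-by-components abundance matrix (nonnegative for nonnegative
#'   spectra), columns named by component id.
#' @export
estimate_abundance <- function(x, model, mz_axis = NULL) {
  if (inherits(x, "msi_dataset")) {
    mz_axis <- x$mz
    x <- x$spectra
  }
  stopifnot(inherits(model, "component_model"), !is.null(mz_axis),
            ncol(x) == length(mz_axis))
  if (any(model$mu < min(mz_axis) - 1e-9) || any(model$mu > max(mz_axis) + 1e-9))
    stop("component model does not match the m/z axis")
  dmz <- median(diff(mz_axis))
  p <- vapply(seq_len(nrow(model)),
              function(k) dnorm(mz_axis, model$mu[k], model$sigma[k]),
              numeric(length(mz_axis)))
  a <- (x %*% p) * dmz
  colnames(a) <- model$component
  a
}

#' Default parameters of the preprocessing pipeline
#'
#' @param baseline_window Rolling-minimum window (channels).
#' @param max_shift Maximum alignment shift (channels).
#' @param outlier_sd Robust-SD multiplier for TIC outlier flagging.
#' @param noise_quantile,w_min,sigma_bounds,sigma_init Passed to
#'   [fit_gmm_components()].
#' @return A named parameter list.
#' @export
preprocess_params <- function(baseline_window = 101L, max_shift = 5L,
                              outlier_sd = 3, noise_quantile = 0.5,
                              w_min = 1e-5, sigma_bounds = NULL,
                              sigma_init = NULL) {
  list(baseline_window = baseline_window, max_shift = max_shift,
       outlier_sd = outlier_sd, noise_quantile = noise_quantile,
       w_min = w_min, sigma_bounds = sigma_bounds, sigma_init = sigma_init)
}

#' Run the full preprocessing pipeline on one or more datasets
#'
#' Stage order: mass-channel unification, baseline subtraction, outlier pixel
#' removal, peak alignment against the pooled mean spectrum, TIC normalization
#' to the pooled mean TIC, Gaussian mixture modeling of the pooled average
#' spectrum, and abundance estimation. Per-patient datasets are processed one
#' at a time so only abundances and metadata are pooled in memory.
#'
#' @param datasets A list of [msi_dataset()]s (e.g. one per patient).
#' @param params A [preprocess_params()] list.
#' @param keep_spectra Also return the pooled preprocessed spectra matrix
#'   (memory-heavy; off by default).
#' @return A list with `abundance` (pooled pixels x components), `model`
#'   (the [component_model()]), `pixels` (data frame: roi, patient_id, group,
#'   tissue, lhr, x, y per retained pixel), `roi_meta`, `outliers` (per input
#'   dataset, logical), `average_spectrum`, `mz`, `provenance` (ordered stage
#'   log) and optionally `spectra`.
#' @export
preprocess_study <- function(datasets, params = preprocess_params(),
                             keep_spectra = FALSE) {
  if (inherits(datasets, "msi_dataset")) datasets <- list(datasets)
  provenance <- character(0)

  datasets <- unify_mass_channels(datasets)
  provenance <- c(provenance, "unify_mass_channels")
  mz <- datasets[[1L]]$mz

  datasets <- lapply(datasets, subtract_baseline, params$baseline_window)
  provenance <- c(provenance, "subtract_baseline")

  outliers <- lapply(datasets, detect_outlier_pixels, params$outlier_sd)
  datasets <- mapply(function(d, fl) {
    d$spectra <- d$spectra[!fl, , drop = FALSE]
    d$coords <- d$coords[!fl, , drop = FALSE]
    d$roi <- d$roi[!fl]
    d
  }, datasets, outliers, SIMPLIFY = FALSE)
  provenance <- c(provenance, "detect_outlier_pixels")

  npx <- vapply(datasets, n_pixels, integer(1))
  reference <- Reduce(`+`, lapply(datasets, function(d)
    colSums(d$spectra))) / sum(npx)
  datasets <- lapply(datasets, align_peaks, reference, params$max_shift)
  provenance <- c(provenance, "align_peaks")

  pooled_tic <- sum(vapply(datasets, function(d) sum(d$spectra), numeric(1))) /
    sum(npx)
  datasets <- lapply(datasets, tic_normalize, target = pooled_tic)
  provenance <- c(provenance, "tic_normalize")

  avg <- Reduce(`+`, lapply(datasets, function(d)
    colSums(d$spectra))) / sum(npx)
  model <- fit_gmm_components(avg, mz,
                              noise_quantile = params$noise_quantile,
                              w_min = params$w_min,
                              sigma_bounds = params$sigma_bounds,
                              sigma_init = params$sigma_init)
  provenance <- c(provenance, "fit_gmm_components")

  abundance <- do.call(rbind, lapply(datasets, estimate_abundance, model))
  provenance <- c(provenance, "estimate_abundance")

  roi_meta <- unique(do.call(rbind, lapply(datasets, `[[`, "roi_meta")))
  pixels <- do.call(rbind, lapply(datasets, function(d) {
    m <- d$roi_meta[match(d$roi, d$roi_meta$roi), , drop = FALSE]
    cbind(data.frame(roi = d$roi, stringsAsFactors = FALSE),
          m[setdiff(names(m), "roi")], d$coords)
  }))
  rownames(pixels) <- NULL

  out <- list(abundance = abundance, model = model, pixels = pixels,
              roi_meta = roi_meta, outliers = outliers,
              average_spectrum = avg, mz = mz, provenance = provenance)
  if (keep_spectra)
    out$spectra <- do.call(rbind, lapply(datasets, `[[`, "spectra"))
  out
}
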