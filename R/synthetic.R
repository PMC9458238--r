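#' Configuration for the synthetic MSI generator
#'
#' Describes one simulated patient ROI (optionally a paired tumor/lymph-node
#' ROI couple): a common m/z axis, a set of Gaussian peptide peaks, a number of
#' molecular clusters laid out as contiguous spatial patches, and the nuisance
#' structure the preprocessing pipeline is meant to remove (baseline drift,
#' per-pixel TIC variation, additive noise, outlier pixels).
#'
#' @param n_patients_per_group Patients per study arm (used by
#'   [simulate_two_arm_study()]).
#' @param mz_min,mz_max m/z range of the axis (instrument acquisition range).
#' @param n_channels Number of equally spaced m/z channels.
#' @param n_peaks Number of peptide species (Gaussian peaks).
#' @param peak_sigma_range Range (m/z) the per-peak Gaussian widths are drawn
#'   from, uniformly.
#' @param roi_shape Integer `c(rows, cols)` of the rectangular ROI pixel grid.
#' @param n_clusters_per_roi Number of molecular clusters planted in each ROI.
#' @param cluster_proportions `"balanced"`, `"skewed"`, or a numeric simplex
#'   vector of length `n_clusters_per_roi`. `"skewed"` uses weights
#'   proportional to `4^-(i-1)`.
#' @param tn_divergence Fraction of peaks whose abundance differs between the
#'   paired T and N ROIs (scaled x2 or x0.5).
#' @param paired_tn Emit a paired lymph-node (N) ROI next to the tumor (T) ROI.
#' @param baseline_amplitude Amplitude of the smooth decaying chemical
#'   baseline added to every spectrum (intensity units).
#' @param tic_cv Coefficient of variation of the per-pixel multiplicative TIC
#'   scale (log-normal, mean 1).
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity).
#' @param outlier_fraction Fraction of pixels turned into TIC outliers
#'   (scaled x10 or x0.1).
#' @param n_profile_library Size of the study-level cluster profile library
#'   used by [simulate_two_arm_study()] so that clusters are shared across
#'   patients.
#' @param seed Integer seed fixing all randomness end-to-end.
#'
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_patients_per_group = 20L,
                              mz_min = 700, mz_max = 3000,
                              n_channels = 4601L,
                              n_peaks = 150L,
                              peak_sigma_range = c(1.25, 2.5),
                              roi_shape = c(20L, 20L),
                              n_clusters_per_roi = 3L,
                              cluster_proportions = "balanced",
                              tn_divergence = 0,
                              paired_tn = FALSE,
                              baseline_amplitude = 0.1,
                              tic_cv = 0.15,
                              noise_sd = 0.01,
                              outlier_fraction = 0.01,
                              n_profile_library = 8L,
                              seed = 1L) {
  cfg <- list(n_patients_per_group = as.integer(n_patients_per_group),
              mz_min = mz_min, mz_max = mz_max,
              n_channels = as.integer(n_channels),
              n_peaks = as.integer(n_peaks),
              peak_sigma_range = peak_sigma_range,
              roi_shape = as.integer(roi_shape),
              n_clusters_per_roi = as.integer(n_clusters_per_roi),
              cluster_proportions = cluster_proportions,
              tn_divergence = tn_divergence, paired_tn = paired_tn,
              baseline_amplitude = baseline_amplitude,
              tic_cv = tic_cv, noise_sd = noise_sd,
              outlier_fraction = outlier_fraction,
              n_profile_library = as.integer(n_profile_library),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$mz_min >= cfg$mz_max) stop("mz_min must be < mz_max")
  if (cfg$n_clusters_per_roi < 1L) stop("n_clusters_per_roi must be >= 1")
  if (cfg$n_channels < 10L) stop("n_channels too small")
  if (cfg$tn_divergence < 0 || cfg$tn_divergence > 1 ||
      cfg$outlier_fraction < 0 || cfg$outlier_fraction > 1)
    stop("proportions must lie in [0, 1]")
  if (is.numeric(cfg$cluster_proportions)) {
    p <- cfg$cluster_proportions
    if (length(p) != cfg$n_clusters_per_roi || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8)
      stop("cluster_proportions must be a simplex vector of length n_clusters_per_roi")
  } else if (!cfg$cluster_proportions %in% c("balanced", "skewed")) {
    stop("cluster_proportions must be numeric, 'balanced' or 'skewed'")
  }
  if (length(cfg$peak_sigma_range) != 2L ||
      cfg$peak_sigma_range[1] <= 0 ||
      diff(cfg$peak_sigma_range) < 0)
    stop("peak_sigma_range must be positive and increasing")
  invisible(cfg)
}

resolve_proportions <- function(cfg) {
  k <- cfg$n_clusters_per_roi
  if (is.numeric(cfg$cluster_proportions)) return(cfg$cluster_proportions)
  if (cfg$cluster_proportions == "balanced") return(rep(1 / k, k))
  w <- 4^-(seq_len(k) - 1)
  w / sum(w)
}

# Random sequential placement of peak centers with minimum spacing 3*sigma_max,
# keeping peaks resolvable for the downstream mixture model.
draw_peaks <- function(n_peaks, mz_min, mz_max, sigma_range) {
  spacing <- 3 * sigma_range[2]
  pad <- 3 * sigma_range[2]
  lo <- mz_min + pad
  hi <- mz_max - pad
  mus <- numeric(0)
  attempts <- 0L
  while (length(mus) < n_peaks) {
    cand <- runif(1, lo, hi)
    if (!length(mus) || min(abs(mus - cand)) >= spacing)
      mus <- c(mus, cand)
    attempts <- attempts + 1L
    if (attempts > n_peaks * 2000L)
      stop("cannot place peaks: range too crowded for the requested spacing")
  }
  list(mu = sort(mus), sigma = runif(n_peaks, sigma_range[1], sigma_range[2]))
}

# Contiguous patch layout: greedy capacity-constrained nearest-seed assignment
# (a Voronoi diagram whose cells are grown to prescribed pixel counts).
patch_layout <- function(rows, cols, proportions) {
  n <- rows * cols
  k <- length(proportions)
  gx <- rep(seq_len(cols), each = rows)
  gy <- rep(seq_len(rows), times = cols)
  centers <- sample.int(n, k)
  d2 <- outer(gx, gx[centers], "-")^2 + outer(gy, gy[centers], "-")^2
  target <- floor(proportions * n)
  rem <- n - sum(target)
  if (rem > 0) {
    extra <- order(proportions * n - target, decreasing = TRUE)[seq_len(rem)]
    target[extra] <- target[extra] + 1L
  }
  ord <- order(as.vector(d2))
  pix <- ((ord - 1L) %% n) + 1L
  cl <- ((ord - 1L) %/% n) + 1L
  lab <- integer(n)
  left <- target
  for (i in seq_along(ord)) {
    p <- pix[i]
    if (lab[p] == 0L && left[cl[i]] > 0L) {
      lab[p] <- cl[i]
      left[cl[i]] <- left[cl[i]] - 1L
    }
  }
  # any pixel still unassigned (all its near seeds full) goes to whatever
  # cluster has capacity, nearest first
  for (p in which(lab == 0L)) {
    open <- which(left > 0L)
    c_sel <- open[which.min(d2[p, open])]
    lab[p] <- c_sel
    left[c_sel] <- left[c_sel] - 1L
  }
  list(label = lab, coords = data.frame(x = gx, y = gy))
}

simulate_roi <- function(cfg, mz, gmat, profiles, roi_id, x_offset = 0) {
  rows <- cfg$roi_shape[1]; cols <- cfg$roi_shape[2]
  props <- resolve_proportions(cfg)[seq_len(nrow(profiles))]
  props <- props / sum(props)
  lay <- patch_layout(rows, cols, props)
  n <- rows * cols
  clean <- profiles[lay$label, , drop = FALSE] %*% t(gmat)
  if (cfg$baseline_amplitude > 0) {
    bl <- cfg$baseline_amplitude *
      exp(-3 * (mz - cfg$mz_min) / (cfg$mz_max - cfg$mz_min))
    clean <- sweep(clean, 2L, bl, "+")
  }
  scale <- rep(1, n)
  if (cfg$tic_cv > 0) {
    sdl <- sqrt(log(1 + cfg$tic_cv^2))
    scale <- rlnorm(n, -sdl^2 / 2, sdl)
  }
  outlier <- rep(FALSE, n)
  n_out <- round(cfg$outlier_fraction * n)
  if (n_out > 0) {
    idx <- sample.int(n, n_out)
    outlier[idx] <- TRUE
    scale[idx] <- scale[idx] * sample(c(10, 0.1), n_out, replace = TRUE)
  }
  spectra <- clean * scale
  if (cfg$noise_sd > 0) {
    spectra <- spectra + matrix(rnorm(length(spectra), 0, cfg$noise_sd),
                                nrow = n)
    spectra[spectra < 0] <- 0
  }
  lay$coords$x <- lay$coords$x + x_offset
  list(spectra = spectra, coords = lay$coords, label = lay$label,
       outlier = outlier, roi = rep(roi_id, n))
}

#' Simulate one synthetic MSI patient dataset with ground truth
#'
#' Generates a tumor ROI (and, when `paired_tn = TRUE`, a paired lymph-node
#' ROI) of pixel spectra built as sums of Gaussian peptide peaks: each pixel's
#' spectrum is `TIC_scale * (sum_k A[cluster, k] * Gauss(mz; mu_k, sigma_k) +
#' baseline(mz)) + noise`, with molecular clusters laid out as contiguous
#' spatial patches.
#'
#' @param config A [simulation_config()].
#' @param patient_id,group,lhr Metadata attached to the emitted ROI(s).
#' @param peaks Optional shared peak set (list with `mu`, `sigma`), e.g. drawn
#'   once per study; defaults to drawing from `config`.
#' @param profile_library Optional matrix (profiles x peaks) of nonnegative
#'   cluster mean profiles shared across patients; the patient's clusters are
#'   sampled from its rows. Defaults to drawing fresh profiles.
#'
#' @return A list with `dataset` (an [msi_dataset()]) and `truth`, the ground
#'   truth: peak positions/widths, per-pixel cluster label map, cluster mean
#'   profiles, outlier mask and the planted (Gini-)Simpson index per ROI.
#' @export
simulate_dataset <- function(config, patient_id = "P01", group = "high",
                             lhr = NA_character_, peaks = NULL,
                             profile_library = NULL) {
  validate_simulation_config(config)
  withr::local_seed(config$seed)
  k <- config$n_clusters_per_roi
  if (is.null(peaks))
    peaks <- draw_peaks(config$n_peaks, config$mz_min, config$mz_max,
                        config$peak_sigma_range)
  n_pk <- length(peaks$mu)
  mz <- seq(config$mz_min, config$mz_max, length.out = config$n_channels)
  gmat <- vapply(seq_len(n_pk),
                 function(j) dnorm(mz, peaks$mu[j], peaks$sigma[j]),
                 numeric(length(mz)))
  if (is.null(profile_library)) {
    profiles <- matrix(rlnorm(k * n_pk, 0, 1), nrow = k)
    profile_ids <- seq_len(k)
  } else {
    stopifnot(ncol(profile_library) == n_pk)
    profile_ids <- sample.int(nrow(profile_library), k)
    profiles <- profile_library[profile_ids, , drop = FALSE]
  }

  roi_t <- sprintf("%s_T", patient_id)
  parts <- list(simulate_roi(config, mz, gmat, profiles, roi_t))
  rois <- data.frame(roi = roi_t, patient_id = patient_id, group = group,
                     tissue = "T", lhr = lhr, stringsAsFactors = FALSE)
  profiles_n <- NULL
  if (config$paired_tn) {
    profiles_n <- profiles
    n_shift <- round(config$tn_divergence * n_pk)
    if (n_shift > 0) {
      sh <- sample.int(n_pk, n_shift)
      fac <- sample(c(2, 0.5), n_shift, replace = TRUE)
      profiles_n[, sh] <- sweep(profiles_n[, sh, drop = FALSE], 2L, fac, "*")
    }
    roi_n <- sprintf("%s_N", patient_id)
    parts <- c(parts, list(
      simulate_roi(config, mz, gmat, profiles_n, roi_n,
                   x_offset = config$roi_shape[2] + 5L)))
    rois <- rbind(rois, data.frame(roi = roi_n, patient_id = patient_id,
                                   group = group, tissue = "N", lhr = lhr,
                                   stringsAsFactors = FALSE))
  }

  ds <- msi_dataset(
    mz = mz,
    spectra = do.call(rbind, lapply(parts, `[[`, "spectra")),
    coords = do.call(rbind, lapply(parts, `[[`, "coords")),
    roi = unlist(lapply(parts, `[[`, "roi"), use.names = FALSE),
    roi_meta = rois)
  label <- unlist(lapply(parts, `[[`, "label"), use.names = FALSE)
  planted_simpson <- vapply(split(label, ds$roi), function(l)
    simpson_index(table(l)), numeric(1))
  truth <- list(
    peak_means = peaks$mu, peak_sigmas = peaks$sigma,
    cluster_label_map = label,
    cluster_mean_profiles = profiles,
    cluster_mean_profiles_n = profiles_n,
    profile_ids = profile_ids,
    outlier_mask = unlist(lapply(parts, `[[`, "outlier"), use.names = FALSE),
    planted_simpson = planted_simpson)
  list(dataset = ds, truth = truth)
}

#' Simulate a two-arm heterogeneity study
#'
#' Generates per-patient datasets for a high-ITH arm and a low-ITH arm that
#' share one peptide species set and one cluster-profile library (so pooled
#' segmentation sees common molecular clusters across patients), differing
#' only in their heterogeneity parameters (number and balance of clusters).
#'
#' @param config_high,config_low [simulation_config()]s for the two arms; they
#'   must agree on the m/z axis and peak set definition.
#' @param seeds Optional integer vector of per-patient seeds (high arm first);
#'   defaults to seeds derived from `config_high$seed`.
#' @return A list with `patients` (per-patient lists: `dataset`, `truth`,
#'   `arm`, `patient_id`), `arm` per patient, `planted_simpson` per patient
#'   (tumor ROI, ground truth), and `planted_simpson_diff`, the difference of
#'   arm medians.
#' @export
simulate_two_arm_study <- function(config_high, config_low, seeds = NULL) {
  validate_simulation_config(config_high)
  validate_simulation_config(config_low)
  stopifnot(config_high$mz_min == config_low$mz_min,
            config_high$mz_max == config_low$mz_max,
            config_high$n_channels == config_low$n_channels,
            config_high$n_peaks == config_low$n_peaks)
  n_hi <- config_high$n_patients_per_group
  n_lo <- config_low$n_patients_per_group
  lib_k <- max(config_high$n_profile_library,
               config_high$n_clusters_per_roi, config_low$n_clusters_per_roi)
  study <- withr::with_seed(config_high$seed, {
    pk <- draw_peaks(config_high$n_peaks, config_high$mz_min,
                     config_high$mz_max, config_high$peak_sigma_range)
    list(peaks = pk,
         library = matrix(rlnorm(lib_k * length(pk$mu), 0, 1), nrow = lib_k))
  })
  if (is.null(seeds)) seeds <- derive_seeds(config_high$seed + 1L, n_hi + n_lo)
  stopifnot(length(seeds) == n_hi + n_lo)

  patients <- vector("list", n_hi + n_lo)
  arm <- rep(c("high", "low"), c(n_hi, n_lo))
  for (i in seq_len(n_hi + n_lo)) {
    cfg <- if (arm[i] == "high") config_high else config_low
    cfg$seed <- as.integer(seeds[i])
    pid <- sprintf("%s%02d", ifelse(arm[i] == "high", "H", "L"),
                   if (i <= n_hi) i else i - n_hi)
    sim <- simulate_dataset(cfg, patient_id = pid, group = arm[i],
                            peaks = study$peaks,
                            profile_library = study$library)
    patients[[i]] <- list(dataset = sim$dataset, truth = sim$truth,
                          arm = arm[i], patient_id = pid)
  }
  planted <- vapply(patients, function(p)
    unname(p$truth$planted_simpson[paste0(p$patient_id, "_T")]), numeric(1))
  list(patients = patients, arm = arm,
       peaks = study$peaks, profile_library = study$library,
       planted_simpson = planted,
       planted_simpson_diff = median(planted[arm == "high"]) -
         median(planted[arm == "low"]))
}

#' Write the ground truth of a simulated dataset as JSON
#'
#' @param truth The `truth` element returned by [simulate_dataset()].
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
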