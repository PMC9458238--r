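#' MSI dataset container
#'
#' Bundles per-pixel mass spectra with their spatial coordinates, ROI
#' membership and per-ROI clinical metadata. All pixels share one m/z axis.
#'
#' @param mz Numeric vector of strictly increasing m/z channel centers.
#' @param spectra Numeric matrix, pixels in rows, channels in columns.
#' @param coords Data frame with integer columns `x`, `y` (one row per pixel).
#' @param roi Character vector: ROI id of each pixel.
#' @param roi_meta Data frame with one row per ROI: columns `roi`,
#'   `patient_id`, `group` (`"NED"`/`"PD"`), `tissue` (`"T"`/`"N"`) and
#'   optionally `lhr` (`"weak"`/`"intermediate"`/`"strong"`).
#'
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(mz, spectra, coords, roi, roi_meta) {
  spectra <- as.matrix(spectra)
  obj <- structure(
    list(mz = as.numeric(mz), spectra = spectra,
         coords = as.data.frame(coords), roi = as.character(roi),
         roi_meta = as.data.frame(roi_meta), provenance = character(0)),
    class = "msi_dataset")
  validate_msi_dataset(obj)
  obj
}

validate_msi_dataset <- function(x) {
  stopifnot(inherits(x, "msi_dataset"))
  n <- nrow(x$spectra)
  if (length(x$mz) != ncol(x$spectra))
    stop("mz axis length does not match spectra columns")
  if (is.unsorted(x$mz, strictly = TRUE))
    stop("mz axis must be strictly increasing")
  if (nrow(x$coords) != n || length(x$roi) != n)
    stop("coords/roi length does not match number of pixels")
  if (!all(c("x", "y") %in% names(x$coords)))
    stop("coords must have columns x and y")
  if (!all(x$roi %in% x$roi_meta$roi))
    stop("pixel ROI id missing from roi_meta")
  invisible(x)
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("msi_dataset: %d pixels x %d channels, m/z %.1f-%.1f, %d ROI(s)\n",
              nrow(x$spectra), length(x$mz), min(x$mz), max(x$mz),
              nrow(x$roi_meta)))
  if (length(x$provenance))
    cat("  stages:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

n_pixels <- function(x) nrow(x$spectra)

record_stage <- function(x, stage) {
  x$provenance <- c(x$provenance, stage)
  x
}

# Row-bind several datasets that already share an identical m/z axis.
combine_datasets <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  mz <- datasets[[1L]]$mz
  for (d in datasets) {
    if (length(d$mz) != length(mz) || max(abs(d$mz - mz)) > 1e-9)
      stop("datasets must share one m/z axis (run unify_mass_channels first)")
  }
  roi_meta <- unique(do.call(rbind, lapply(datasets, `[[`, "roi_meta")))
  out <- msi_dataset(
    mz = mz,
    spectra = do.call(rbind, lapply(datasets, `[[`, "spectra")),
    coords = do.call(rbind, lapply(datasets, `[[`, "coords")),
    roi = unlist(lapply(datasets, `[[`, "roi"), use.names = FALSE),
    roi_meta = roi_meta)
  out$provenance <- datasets[[1L]]$provenance
  out
}

#' Write / read an MSI dataset as a compact matrix container
#'
#' The container is a little-endian float32 pixel-by-channel matrix
#' (`<prefix>.f32`, row-major) plus a JSON header (`<prefix>.json`) holding the
#' m/z axis, coordinates, ROI labels and ROI metadata. It exists for fast,
#' dependency-free interchange of desk-scale datasets.
#'
#' @param x An [msi_dataset()].
#' @param prefix Path prefix; the two files get `.f32` and `.json` appended.
#' @return `write_msi_matrix` returns `prefix` invisibly; `read_msi_matrix`
#'   returns the reconstructed [msi_dataset()].
#' @export
write_msi_matrix <- function(x, prefix) {
  validate_msi_dataset(x)
  header <- list(
    format = "msith-matrix-v1", dtype = "float32", order = "row-major",
    n_pixels = nrow(x$spectra), n_channels = ncol(x$spectra),
    mz = x$mz, coords = x$coords, roi = x$roi, roi_meta = x$roi_meta,
    provenance = x$provenance)
  jsonlite::write_json(header, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(prefix, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(x$spectra)), con, size = 4L, endian = "little")
  invisible(prefix)
}

#' @rdname write_msi_matrix
#' @export
read_msi_matrix <- function(prefix) {
  h <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(h$format, "msith-matrix-v1")) stop("unknown container format")
  n <- h$n_pixels * h$n_channels
  con <- file(paste0(prefix, ".f32"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  out <- msi_dataset(mz = h$mz,
                     spectra = matrix(vals, h$n_pixels, h$n_channels,
                                      byrow = TRUE),
                     coords = h$coords, roi = h$roi, roi_meta = h$roi_meta)
  out$provenance <- as.character(h$provenance)
  out
}

#' Fitted Gaussian component model of an average spectrum
#'
#' @param mu,sigma,weight Numeric vectors of equal length: component centers
#'   (m/z), widths (m/z) and mixture weights.
#' @return A `component_model`: data frame with columns `component`, `mu`,
#'   `sigma`, `weight`, sorted by `mu`.
#' @export
component_model <- function(mu, sigma, weight) {
  stopifnot(length(mu) == length(sigma), length(mu) == length(weight),
            all(sigma > 0), all(weight > 0))
  ord <- order(mu)
  structure(data.frame(component = seq_along(mu),
                       mu = mu[ord], sigma = sigma[ord], weight = weight[ord]),
            class = c("component_model", "data.frame"))
}

#' @rdname component_model
#' @param x A `component_model`.
#' @param path File path for the JSON serialization.
#' @export
write_component_model <- function(x, path) {
  jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname component_model
#' @export
read_component_model <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  component_model(d$mu, d$sigma, d$weight)
}

#' Write an abundance matrix as TSV
#'
#' @param abund Pixel-by-component abundance matrix.
#' @param path Output file.
#' @export
write_abundance_tsv <- function(abund, path) {
  utils::write.table(abund, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
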