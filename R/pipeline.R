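# Polynomial rolling hash (mod 2^31 - 1) over a serialized R object; used for
# provenance fingerprints, not for cryptographic purposes.
fnv1a <- function(obj) {
  b <- as.integer(serialize(obj, NULL, version = 3L))
  h <- 0
  # horner evaluation in chunks keeps the double arithmetic exact (< 2^53)
  for (x in b) h <- (h * 131 + x + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Configuration of an end-to-end pipeline run
#'
#' @param simulation Either one [simulation_config()] (single-arm run) or a
#'   list `list(high = ..., low = ...)` of two configs for a two-arm study.
#' @param stages Character vector of stages to execute, in order, out of
#'   `"simulate"`, `"preprocess"`, `"segment"`, `"heterogeneity"`,
#'   `"differential"`. Each stage requires its predecessor.
#' @param preprocess A [preprocess_params()] list.
#' @param divik A [divik_params()] list.
#' @param het_level Segmentation level for the cluster-based heterogeneity
#'   indices.
#' @param max_pairs Pair cap for similarity distributions.
#' @param patient_seeds Optional per-patient seeds for the two-arm study.
#' @param seed Master seed; propagated to every stochastic stage unless a
#'   stage config carries its own.
#' @param out_dir Optional directory for machine-readable artifacts
#'   (report.json, provenance.json, model.json, tree.json + labels,
#'   heterogeneity.tsv).
#' @return A `run_config` list.
#' @export
run_config <- function(simulation,
                       stages = c("simulate", "preprocess", "segment",
                                  "heterogeneity"),
                       preprocess = preprocess_params(),
                       divik = divik_params(),
                       het_level = 1L, max_pairs = 1e5,
                       patient_seeds = NULL, seed = 1L, out_dir = NULL) {
  cfg <- list(simulation = simulation, stages = stages,
              preprocess = preprocess, divik = divik,
              het_level = as.integer(het_level), max_pairs = max_pairs,
              patient_seeds = patient_seeds, seed = as.integer(seed),
              out_dir = out_dir)
  order_all <- c("simulate", "preprocess", "segment", "heterogeneity",
                 "differential")
  bad <- setdiff(stages, order_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

require_stage <- function(stages, stage, dependency) {
  if (stage %in% stages && !dependency %in% stages)
    stop(sprintf("stage '%s' requires stage '%s' (missing upstream artifact)",
                 stage, dependency))
}

#' Run the end-to-end heterogeneity pipeline
#'
#' Executes the configured stages in the canonical order (simulate ->
#' preprocess -> segment -> heterogeneity [-> differential]) and returns a
#' machine-readable report together with a provenance log (stage order, seeds,
#' input fingerprints). The whole run is deterministic under a fixed
#' configuration.
#'
#' @param config A [run_config()].
#' @return A list with `report` (per-ROI heterogeneity table, group medians,
#'   test results, cluster contributions, and differential class counts when
#'   run), `provenance`, and the heavier in-memory artifacts (`prep`, `tree`,
#'   `study`) for inspection.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  require_stage(stages, "preprocess", "simulate")
  require_stage(stages, "segment", "preprocess")
  require_stage(stages, "heterogeneity", "segment")
  require_stage(stages, "differential", "preprocess")

  two_arm <- !inherits(config$simulation, "simulation_config")
  provenance <- list(package_version = as.character(utils::packageVersion("msith")),
                     seed = config$seed,
                     config_hash = fnv1a(unclass(config)[setdiff(
                       names(config), "out_dir")]),
                     stages = character(0))
  report <- list(seed = config$seed, two_arm = two_arm)
  study <- prep <- tree <- NULL

  if ("simulate" %in% stages) {
    if (two_arm) {
      study <- simulate_two_arm_study(config$simulation$high,
                                      config$simulation$low,
                                      seeds = config$patient_seeds)
      datasets <- lapply(study$patients, `[[`, "dataset")
      report$n_patients <- length(datasets)
      report$planted_simpson_diff <- study$planted_simpson_diff
    } else {
      sim <- simulate_dataset(config$simulation)
      study <- list(patients = list(list(dataset = sim$dataset,
                                         truth = sim$truth, arm = "single")),
                    arm = "single")
      datasets <- list(sim$dataset)
      report$n_patients <- 1L
    }
    provenance$stages <- c(provenance$stages, "simulate")
    # fingerprint of the simulated spectra via their first two moments
    provenance$data_hash <- fnv1a(lapply(datasets, function(d)
      c(dim(d$spectra), sum(d$spectra), sum(d$spectra^2))))
  }

  if ("preprocess" %in% stages) {
    prep <- preprocess_study(datasets, config$preprocess)
    provenance$stages <- c(provenance$stages, prep$provenance)
    report$n_components <- nrow(prep$model)
    report$n_pixels_retained <- nrow(prep$abundance)
    report$n_outliers <- sum(unlist(prep$outliers))
  }

  if ("segment" %in% stages) {
    dv <- config$divik
    dv$seed <- dv$seed + config$seed
    tree <- divik(prep$abundance, dv)
    provenance$stages <- c(provenance$stages, "divik")
    report$clusters_per_level <-
      apply(tree$labels, 2L, function(l) length(unique(l)))
  }

  if ("heterogeneity" %in% stages) {
    het <- heterogeneity_summary(prep$abundance, tree, prep$pixels,
                                 level = config$het_level,
                                 max_pairs = config$max_pairs,
                                 seed = config$seed)
    provenance$stages <- c(provenance$stages, "heterogeneity")
    report$heterogeneity <- het
    tumor <- het[het$tissue == "T", , drop = FALSE]
    if (length(unique(tumor$group)) == 2L) {
      simp <- compare_groups(tumor$simpson_d, tumor$group)
      sim <- compare_groups(tumor$median_similarity, tumor$group)
      report$tests <- list(
        simpson = list(p.value = simp$p.value,
                       medians = as.list(simp$medians)),
        similarity = list(p.value = sim$p.value,
                          medians = as.list(sim$medians)))
    }
    # Fig-1D-style relative cluster contributions per tumor ROI
    lev <- config$het_level
    labs <- tree$labels[, lev]
    contrib <- t(vapply(unique(tumor$roi), function(r) {
      idx <- prep$pixels$roi == r
      tabulate(labs[idx], nbins = max(labs)) / sum(idx)
    }, numeric(max(labs))))
    rownames(contrib) <- unique(tumor$roi)
    report$cluster_contributions <- contrib
  }

  if ("differential" %in% stages) {
    px <- prep$pixels
    if (all(c("T", "N") %in% px$tissue)) {
      diffr <- differential_components(prep$abundance,
                                       px$tissue == "T", px$tissue == "N",
                                       contrast = "T-vs-N")
      report$differential <- list(contrast = diffr$contrast,
                                  class_counts = as.list(diffr$class_counts),
                                  n_selected = length(diffr$selected))
      provenance$stages <- c(provenance$stages, "differential")
    }
  }

  out <- list(report = report, provenance = provenance,
              prep = prep, tree = tree, study = study)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    serializable <- report
    if (!is.null(serializable$cluster_contributions))
      serializable$cluster_contributions <-
        as.data.frame(serializable$cluster_contributions)
    jsonlite::write_json(serializable,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(provenance,
                         file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(prep))
      write_component_model(prep$model, file.path(config$out_dir, "model.json"))
    if (!is.null(tree))
      write_segmentation_tree(tree, file.path(config$out_dir, "tree"))
    if (!is.null(report$heterogeneity))
      utils::write.table(report$heterogeneity,
                         file.path(config$out_dir, "heterogeneity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
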