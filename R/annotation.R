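#' Read a tryptic peptide library from TSV
#'
#' The library is the table of peptides identified by LC-MS/MS: one row per
#' peptide with its measured mass (as m/z of the singly protonated species),
#' sequence and protein accession. Expected columns: `mass`, `sequence`,
#' `accession`, and optionally `protein_name`. A converter from search-engine
#' exports only needs to produce these four columns.
#'
#' @param path TSV file path.
#' @param mass_range Plausible instrument detection range; masses outside it
#'   raise a warning.
#' @return A `peptide_library` data frame sorted by mass.
#' @export
read_peptide_library <- function(path, mass_range = c(700, 3500)) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  peptide_library(d$mass, d$sequence, d$accession, d$protein_name, mass_range)
}

#' @rdname read_peptide_library
#' @param mass,sequence,accession,protein_name Library columns.
#' @export
peptide_library <- function(mass, sequence, accession, protein_name = NULL,
                            mass_range = c(700, 3500)) {
  stopifnot(is.numeric(mass), length(mass) == length(sequence),
            length(mass) == length(accession))
  if (any(!nzchar(accession)) || any(is.na(accession)))
    stop("accessions must be nonempty")
  if (any(mass < mass_range[1] | mass > mass_range[2]))
    warning("some peptide masses lie outside the instrument detection range")
  if (is.null(protein_name)) protein_name <- rep(NA_character_, length(mass))
  ord <- order(mass)
  structure(data.frame(mass = mass[ord], sequence = sequence[ord],
                       accession = accession[ord],
                       protein_name = protein_name[ord],
                       stringsAsFactors = FALSE),
            class = c("peptide_library", "data.frame"))
}

#' Match spectral components to library peptides by relative mass tolerance
#'
#' Component k matches library entry e when
#' `|mu_k - mass_e| / mass_e <= tol` (the library's measured mass is the
#' reference denominator). The default tolerance is 5e-4, i.e. +/- 0.05%.
#' Matching uses binary search on the mass-sorted library; a component may
#' match zero, one or several peptides (the annotation is not unique).
#'
#' @param model A [component_model()].
#' @param library A `peptide_library`.
#' @param tol Relative mass tolerance (> 0).
#' @return An `annotation_table` data frame: `component`, `mu`, `mass`,
#'   `sequence`, `accession`, `protein_name`, `rel_error`, sorted by
#'   `rel_error` within component. Zero rows when nothing matches.
#' @export
match_components <- function(model, library, tol = 5e-4) {
  stopifnot(inherits(model, "component_model"), tol > 0)
  empty <- data.frame(component = integer(0), mu = numeric(0),
                      mass = numeric(0), sequence = character(0),
                      accession = character(0), protein_name = character(0),
                      rel_error = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(library)) {
    warning("empty peptide library; no annotations")
    return(structure(empty, class = c("annotation_table", "data.frame")))
  }
  m <- library$mass  # sorted ascending by construction
  # |mu - m| / m <= tol  <=>  m in [mu / (1 + tol), mu / (1 - tol)]
  lo <- findInterval(model$mu / (1 + tol), m, left.open = TRUE) + 1L
  hi <- findInterval(model$mu / (1 - tol), m)
  rows <- lapply(seq_len(nrow(model)), function(k) {
    if (lo[k] > hi[k]) return(NULL)
    j <- lo[k]:hi[k]
    err <- abs(model$mu[k] - m[j]) / m[j]
    keep <- err <= tol
    if (!any(keep)) return(NULL)
    j <- j[keep]; err <- err[keep]
    ord <- order(err)
    data.frame(component = model$component[k], mu = model$mu[k],
               mass = m[j][ord], sequence = library$sequence[j][ord],
               accession = library$accession[j][ord],
               protein_name = library$protein_name[j][ord],
               rel_error = err[ord], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty), rows))
  rownames(out) <- NULL
  structure(out, class = c("annotation_table", "data.frame"))
}

#' Proteins matched by a set of components
#'
#' @param table An `annotation_table` from [match_components()].
#' @param components Component ids to restrict to (default: all annotated).
#' @return Deduplicated character vector of protein accessions.
#' @export
proteins_for_components <- function(table, components = NULL) {
  if (!nrow(table)) return(character(0))
  if (!is.null(components))
    table <- table[table$component %in% components, , drop = FALSE]
  unique(table$accession)
}
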