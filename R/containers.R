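#' Reporter-ion site table
#'
#' Light container for per-cysteine-site TMT reporter intensities across
#' samples and redox states, in the style of limma's list-based classes.
#' Each state holds a sites x channels matrix whose columns are the sample
#' ids plus the common reference channel \code{"REF"}; \code{NA} means the
#' site was not quantified in that channel.
#'
#' @param annotation data.frame with columns \code{site_id}, \code{protein},
#'   \code{position} (1-based residue position of the cysteine) and
#'   \code{localization_prob}.
#' @param intensity named list of non-negative matrices, one per redox state
#'   (\code{SH}, \code{Sto}, \code{SOH}, \code{SNO}, \code{SSG}), with
#'   identical dimnames: rownames = \code{annotation$site_id}, colnames =
#'   samples plus \code{"REF"}.
#' @return An object of class \code{"reporter_sites"}.
#' @export
reporter_sites <- function(annotation, intensity) {
  req <- c("site_id", "protein", "position", "localization_prob")
  miss <- setdiff(req, names(annotation))
  if (length(miss) > 0)
    stop_schema(paste0("annotation lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(annotation$site_id))
    stop_schema("duplicate site_id in annotation")
  states <- names(intensity)
  if (length(states) == 0 || any(!nzchar(states)))
    stop_schema("intensity must be a named list of state matrices")
  cols <- colnames(intensity[[1]])
  for (st in states) {
    m <- intensity[[st]]
    rn <- rownames(m) %||% character(0)
    if (!is.matrix(m) || !identical(colnames(m), cols) ||
        !identical(rn, as.character(annotation$site_id)))
      stop_schema(sprintf("intensity matrix '%s' has inconsistent dimnames", st))
    if (any(m < 0, na.rm = TRUE))
      stop_schema(sprintf("negative intensity in state '%s'", st))
  }
  structure(list(annotation = annotation, intensity = intensity),
            samples = setdiff(cols, REF_CHANNEL),
            class = "reporter_sites")
}

#' @export
print.reporter_sites <- function(x, ...) {
  cat(sprintf("reporter_sites: %d sites, states [%s], %d samples (+%s)\n",
              nrow(x$annotation), paste(names(x$intensity), collapse = ", "),
              length(attr(x, "samples")), REF_CHANNEL))
  invisible(x)
}

#' @export
dim.reporter_sites <- function(x) {
  c(nrow(x$annotation), length(attr(x, "samples")))
}

#' Sample ids of a container
#'
#' @param x a \code{reporter_sites}, \code{normalized_redox} or
#'   \code{occupancy_table} object.
#' @return Character vector of sample ids (excluding the reference channel).
#' @export
sample_ids <- function(x) attr(x, "samples")

#' Protein-level channel quantification
#'
#' Per-protein summed reporter abundance of the unenriched aliquot of each
#' TMT channel, used to derive total-protein channel ratios. One matrix per
#' redox-state plex (columns = samples + \code{"REF"}).
#'
#' @param abundance named list of non-negative proteins x channels matrices.
#' @return An object of class \code{"protein_quant"}.
#' @export
protein_quant <- function(abundance) {
  cols <- colnames(abundance[[1]])
  for (st in names(abundance)) {
    m <- abundance[[st]]
    if (!is.matrix(m) || !identical(colnames(m), cols))
      stop_schema(sprintf("abundance matrix '%s' has inconsistent columns", st))
    if (any(m < 0, na.rm = TRUE))
      stop_schema(sprintf("negative abundance in state '%s'", st))
  }
  structure(list(abundance = abundance),
            samples = setdiff(cols, REF_CHANNEL),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("protein_quant: %d proteins, plexes [%s], %d samples (+%s)\n",
              nrow(x$abundance[[1]]), paste(names(x$abundance), collapse = ", "),
              length(attr(x, "samples")), REF_CHANNEL))
  invisible(x)
}

#' Metabolite intensity table
#'
#' @param values non-negative metabolites x samples matrix (NA = missing).
#' @param qc metabolites x QC-replicate matrix (same rownames).
#' @param protein_concentration named per-sample protein concentration.
#' @param mode ion mode, \code{"pos"} or \code{"neg"}.
#' @return An object of class \code{"metabolite_table"}.
#' @export
metabolite_table <- function(values, qc, protein_concentration, mode) {
  if (!mode %in% c("pos", "neg"))
    stop_schema(sprintf("unknown ion mode '%s' (expected 'pos' or 'neg')", mode))
  if (any(values < 0, na.rm = TRUE)) stop_schema("negative metabolite intensity")
  if (!identical(rownames(values), rownames(qc)))
    stop_schema("QC rownames differ from value rownames")
  miss <- setdiff(colnames(values), names(protein_concentration))
  if (length(miss) > 0)
    stop_schema(paste0("missing protein_concentration for sample(s): ",
                       paste(miss, collapse = ", ")))
  structure(list(values = values, qc = qc,
                 protein_concentration = protein_concentration[colnames(values)],
                 mode = mode),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite_table (%s mode): %d metabolites, %d samples, %d QC replicates\n",
              x$mode, nrow(x$values), ncol(x$values), ncol(x$qc)))
  invisible(x)
}
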