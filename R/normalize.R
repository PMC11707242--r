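# Normalization: total-protein channel ratios against the common reference
# channel, redoxome channel correction and reference ratios, proteome
# peptide-to-protein workflow, metabolome QC/CV and correction-factor
# normalization, and QC correlation matrices.

#' Total-protein channel ratios of one plex
#'
#' The summed abundance of each TMT channel is scaled by the summed
#' abundance of the common reference channel, giving one total-protein
#' ratio per channel (the reference's ratio is identically 1).
#'
#' @param mat proteins x channels abundance matrix.
#' @param reference reference channel name (default \code{"REF"}).
#' @return Named numeric vector of ratios, one per channel.
#' @export
channel_ratios <- function(mat, reference = REF_CHANNEL) {
  if (!reference %in% colnames(mat))
    stop_schema(sprintf("reference channel '%s' not present", reference))
  totals <- colSums(mat, na.rm = TRUE)
  if (!is.finite(totals[reference]) || totals[reference] <= 0)
    stop_schema(sprintf("reference channel '%s' has non-positive total", reference))
  totals / totals[[reference]]
}

#' Channel ratios for every redox-state plex
#'
#' @param proteins a \code{\link{protein_quant}} object (unenriched-aliquot
#'   protein quantification of the same plexes as the site table).
#' @param reference reference channel name.
#' @return Object of class \code{"channel_ratio_set"}: named list (one per
#'   state) of per-channel ratio vectors.
#' @export
compute_channel_ratios <- function(proteins, reference = REF_CHANNEL) {
  stopifnot(inherits(proteins, "protein_quant"))
  ratios <- lapply(proteins$abundance, channel_ratios, reference = reference)
  structure(ratios, reference = reference, class = "channel_ratio_set")
}

#' @export
print.channel_ratio_set <- function(x, ...) {
  cat(sprintf("channel_ratio_set: %d plexes x %d channels (reference '%s')\n",
              length(x), length(x[[1]]), attr(x, "reference")))
  invisible(x)
}

#' Normalize redox reporter intensities by total-protein channel ratios
#'
#' Each reporter intensity is divided by its channel's total-protein ratio
#' (channel correction), and the corrected intensity of each site in each
#' sample is additionally expressed relative to the corrected intensity of
#' the same site in the common reference channel of the same plex
#' (\code{ref_ratio}). Missing values propagate.
#'
#' @param sites a \code{\link{reporter_sites}} object.
#' @param ratios a \code{channel_ratio_set} covering every state/channel of
#'   \code{sites}.
#' @return Object of class \code{"normalized_redox"}: list with
#'   \code{annotation}, \code{normalized} (per-state matrices incl. REF) and
#'   \code{ref_ratio} (per-state sites x samples matrices).
#' @export
normalize_redox <- function(sites, ratios) {
  stopifnot(inherits(sites, "reporter_sites"),
            inherits(ratios, "channel_ratio_set"))
  reference <- attr(ratios, "reference")
  normalized <- list()
  ref_ratio <- list()
  for (st in names(sites$intensity)) {
    if (is.null(ratios[[st]]))
      stop_schema(sprintf("no channel ratios for state '%s'", st))
    m <- sites$intensity[[st]]
    miss <- setdiff(colnames(m), names(ratios[[st]]))
    if (length(miss) > 0)
      stop_schema(sprintf("state '%s': unmapped channel(s): %s", st,
                          paste(miss, collapse = ", ")))
    nm <- sweep(m, 2, ratios[[st]][colnames(m)], "/")
    normalized[[st]] <- nm
    samples <- setdiff(colnames(nm), reference)
    ref_ratio[[st]] <- nm[, samples, drop = FALSE] / nm[, reference]
  }
  structure(list(annotation = sites$annotation, normalized = normalized,
                 ref_ratio = ref_ratio),
            samples = attr(sites, "samples"), reference = reference,
            class = "normalized_redox")
}

#' @export
print.normalized_redox <- function(x, ...) {
  cat(sprintf("normalized_redox: %d sites, states [%s], %d samples\n",
              nrow(x$annotation), paste(names(x$normalized), collapse = ", "),
              length(attr(x, "samples"))))
  invisible(x)
}

#' Proteome workflow: peptides to normalized protein matrix
#'
#' Unique peptides are summed per protein; proteins with fewer than
#' \code{min_unique} unique peptides are dropped. Per-sample totals are
#' equalized to their mean, each sample is divided by its batch's common
#' reference column, batches are merged, zeros become missing, the matrix is
#' log2-transformed, and proteins detected in fewer than
#' \code{min_detect_frac} of samples are removed.
#'
#' @param peptides peptide data.frame (see \code{\link{read_peptide_table}}).
#' @param design cohort design with \code{sample} and \code{batch} columns.
#' @param min_unique minimum unique peptides per retained protein.
#' @param min_detect_frac minimum fraction of samples a protein must be
#'   detected in.
#' @param log2_transform return log2 values (default TRUE).
#' @return proteins x samples matrix with attribute \code{"n_unique"}.
#' @export
normalize_proteome <- function(peptides, design, min_unique = 2,
                               min_detect_frac = 0.5, log2_transform = TRUE) {
  stopifnot(all(c("peptide_id", "protein", "is_unique") %in% names(peptides)))
  uq <- peptides[peptides$is_unique %in% TRUE, , drop = FALSE]
  if (nrow(uq) == 0) {
    warning("no unique peptides; returning empty matrix")
    return(matrix(numeric(0), nrow = 0, ncol = nrow(design),
                  dimnames = list(NULL, design$sample)))
  }
  n_unique <- table(uq$protein)
  keep <- names(n_unique)[n_unique >= min_unique]
  uq <- uq[uq$protein %in% keep, , drop = FALSE]
  if (nrow(uq) == 0) {
    warning(sprintf("no protein has >= %d unique peptides", min_unique))
    return(matrix(numeric(0), nrow = 0, ncol = nrow(design),
                  dimnames = list(NULL, design$sample)))
  }

  batches <- sort(unique(design$batch))
  ref_cols <- paste0("REF_", batches)
  have_ref <- all(ref_cols %in% names(peptides))
  val_cols <- c(design$sample, if (have_ref) ref_cols)
  miss <- setdiff(design$sample, names(peptides))
  if (length(miss) > 0)
    stop_schema(paste0("peptide table lacks sample column(s): ",
                       paste(miss, collapse = ", ")))

  vals <- as.matrix(uq[, val_cols, drop = FALSE])
  prot <- rowsum(vals, group = uq$protein, na.rm = TRUE)

  # equalize per-column totals to the common (mean) level
  totals <- colSums(prot, na.rm = TRUE)
  prot <- sweep(prot, 2, mean(totals) / totals, "*")

  # per-batch common-reference division removes batch effects
  if (have_ref) {
    for (b in batches) {
      sm <- design$sample[design$batch == b]
      prot[, sm] <- prot[, sm] / prot[, paste0("REF_", b)]
    }
    prot <- prot[, design$sample, drop = FALSE]
  }

  prot[!is.na(prot) & prot == 0] <- NA_real_
  detected <- rowMeans(!is.na(prot))
  prot <- prot[detected >= min_detect_frac, , drop = FALSE]
  out <- if (log2_transform) log2(prot) else prot
  attr(out, "n_unique") <- as.integer(n_unique[rownames(out)])
  out
}

#' Metabolome normalization with QC CV filter
#'
#' Metabolites whose coefficient of variation (sd/mean) across the QC
#' replicates is \code{>= cv_max} are excluded. Each value is divided by
#' its sample's protein concentration; then, per ion mode, each sample is
#' divided by its correction factor (sample total / mean of sample totals);
#' finally the modes are concatenated.
#'
#' @param tables list of \code{\link{metabolite_table}}s, one per ion mode.
#' @param cv_max QC CV exclusion threshold (default 0.3, inclusive
#'   \code{>=}).
#' @return metabolites x samples matrix with attributes \code{"qc_cv"} and
#'   \code{"n_excluded"}.
#' @export
normalize_metabolome <- function(tables, cv_max = 0.3) {
  if (inherits(tables, "metabolite_table")) tables <- list(tables)
  out <- list()
  cvs <- c()
  n_excl <- 0L
  for (mt in tables) {
    stopifnot(inherits(mt, "metabolite_table"))
    if (ncol(mt$qc) < 2)
      stop_schema(sprintf("mode '%s': need >= 2 QC replicates", mt$mode))
    qc_mean <- rowMeans(mt$qc, na.rm = TRUE)
    qc_sd <- apply(mt$qc, 1, sd, na.rm = TRUE)
    cv <- qc_sd / qc_mean
    bad_mean <- !is.finite(qc_mean) | qc_mean == 0
    if (any(bad_mean)) {
      warning(sprintf("mode '%s': %d metabolite(s) with zero/undefined QC mean excluded",
                      mt$mode, sum(bad_mean)))
      cv[bad_mean] <- Inf
    }
    keep <- cv < cv_max
    n_excl <- n_excl + sum(!keep)
    vals <- mt$values[keep, , drop = FALSE]
    cvs <- c(cvs, setNames(cv[keep], rownames(vals)))
    # per-sample protein concentration
    vals <- sweep(vals, 2, mt$protein_concentration[colnames(vals)], "/")
    # per-mode correction factor = sample total / mean sample total
    totals <- colSums(vals, na.rm = TRUE)
    corr <- totals / mean(totals)
    vals <- sweep(vals, 2, corr, "/")
    out[[mt$mode]] <- vals
  }
  samples <- colnames(out[[1]])
  for (m in out) stopifnot(identical(colnames(m), samples))
  merged <- do.call(rbind, out)
  attr(merged, "qc_cv") <- cvs
  attr(merged, "n_excluded") <- n_excl
  merged
}

#' Sample-sample QC correlation matrix
#'
#' @param mat features x samples matrix.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param min_pairs minimum pairwise-complete observations per sample pair.
#' @return Symmetric samples x samples correlation matrix with unit
#'   diagonal; pairs with too few complete observations or a constant
#'   column are \code{NA} (with a warning for constant columns).
#' @export
qc_correlation <- function(mat, method = c("pearson", "spearman"),
                           min_pairs = 3) {
  method <- match.arg(method)
  if (ncol(mat) < 2) stop_schema("need >= 2 samples for a correlation matrix")
  const <- apply(mat, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && all(v == v[1])
  })
  if (any(const))
    warning(paste0("constant column(s): ",
                   paste(colnames(mat)[const], collapse = ", ")))
  cc <- suppressWarnings(
    cor(mat, use = "pairwise.complete.obs", method = method))
  npairs <- crossprod(!is.na(mat))
  cc[npairs < min_pairs] <- NA_real_
  diag(cc) <- 1
  cc
}
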