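# Motif analysis: +/-10-residue windows around modified cysteines and
# per-position residue frequency matrices per occupancy region.

MOTIF_PAD <- "_"

#' Extract flanking-sequence windows around cysteine sites
#'
#' Returns the \code{2*flank + 1}-residue window centred on each site's
#' cysteine; positions outside the protein are padded with \code{"_"}.
#' A site whose stated position does not hold a cysteine, or whose
#' accession is absent from the sequence collection, is an error.
#'
#' @param sequences named character vector of protein sequences (as from
#'   \code{\link{read_fasta_sequences}}).
#' @param sites data.frame with \code{site_id}, \code{protein},
#'   \code{position} (1-based).
#' @param flank residues on each side (default 10).
#' @return Named character vector of windows (names = site ids).
#' @export
extract_windows <- function(sequences, sites, flank = 10) {
  miss <- setdiff(unique(sites$protein), names(sequences))
  if (length(miss) > 0)
    stop_schema(paste0("accession(s) missing from FASTA: ",
                       paste(miss, collapse = ", ")))
  out <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    seqc <- sequences[[sites$protein[i]]]
    pos <- sites$position[i]
    L <- nchar(seqc)
    if (pos < 1 || pos > L)
      stop_schema(sprintf("site %s: position %d outside sequence of length %d",
                          sites$site_id[i], pos, L))
    centre <- substr(seqc, pos, pos)
    if (centre != "C")
      stop_schema(sprintf("site %s: residue at position %d is '%s', not 'C'",
                          sites$site_id[i], pos, centre))
    lo <- pos - flank
    hi <- pos + flank
    core <- substr(seqc, max(lo, 1), min(hi, L))
    out[i] <- paste0(strrep(MOTIF_PAD, max(0, 1 - lo)), core,
                     strrep(MOTIF_PAD, max(0, hi - L)))
  }
  names(out) <- sites$site_id
  out
}

#' Per-position residue frequency matrix of a window set
#'
#' Plain relative frequencies (probability-style, as drawn by sequence-logo
#' tools) of the 20 amino acids plus the terminal padding placeholder at
#' each window position; each position's frequencies sum to 1.
#'
#' @param windows character vector of equal-length windows (odd length,
#'   cysteine at the centre).
#' @param region optional region label stored on the result.
#' @return Object of class \code{"motif_matrix"}: a residues x positions
#'   frequency matrix (rows = 20 amino acids + \code{"_"}; columns
#'   labelled by offset -flank..flank) with attributes \code{"n_windows"}
#'   and \code{"region"}.
#' @export
position_frequencies <- function(windows, region = NA_character_) {
  if (length(windows) == 0) stop_schema("no windows supplied")
  w <- nchar(windows)
  if (length(unique(w)) != 1) stop_schema("windows have differing lengths")
  width <- w[1]
  flank <- (width - 1) / 2
  residues <- c(AA20, MOTIF_PAD)
  chars <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  freq <- sapply(seq_len(width), function(j) {
    tab <- table(factor(chars[, j], levels = residues))
    as.numeric(tab) / length(windows)
  })
  dimnames(freq) <- list(residues, as.character(seq_len(width) - 1 - flank))
  structure(freq, n_windows = length(windows), region = region,
            class = c("motif_matrix", class(freq)))
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix: %d windows, positions %s..%s%s\n",
              attr(x, "n_windows"), colnames(x)[1], colnames(x)[ncol(x)],
              if (is.na(attr(x, "region"))) "" else
                sprintf(" (region %s)", attr(x, "region"))))
  invisible(x)
}

#' Modal residue at a window offset
#'
#' @param motif a \code{motif_matrix}.
#' @param offset position relative to the cysteine (e.g. -1).
#' @param include_pad count the terminal placeholder as a candidate
#'   (default FALSE).
#' @return Single residue letter with the highest frequency at the offset.
#' @export
modal_residue <- function(motif, offset, include_pad = FALSE) {
  col <- motif[, as.character(offset)]
  if (!include_pad) col <- col[names(col) != MOTIF_PAD]
  names(col)[which.max(col)]
}

#' Select sites near an occupancy peak
#'
#' Motif sets can be restricted to cysteines whose group-median occupancy
#' lies within \code{width} of a density peak.
#'
#' @param medians named group-median occupancies.
#' @param peak peak position.
#' @param width half-width of the selection band (default 0.10).
#' @return Character vector of site ids.
#' @export
sites_near_peak <- function(medians, peak, width = 0.10) {
  names(medians)[!is.na(medians) & abs(medians - peak) <= width]
}
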