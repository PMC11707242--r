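# Ingest: MaxQuant-dialect site/protein/peptide tables, metabolite exports
# and FASTA, with the row-level quality filters applied on read.

default_site_cols <- function() {
  c(site_id = "site_id", protein = "Protein", position = "Position",
    localization_prob = "Localization prob", reverse = "Reverse",
    contaminant = "Potential contaminant")
}

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE,
             na.strings = c("NA", ""))
}

require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop_schema(sprintf("'%s' lacks required column(s): %s", path,
                        paste(miss, collapse = ", ")))
}

# split "intensity.<state>.<channel>" column names into state/channel
parse_channel_cols <- function(nms, prefix) {
  hit <- startsWith(nms, paste0(prefix, "."))
  rest <- substring(nms[hit], nchar(prefix) + 2)
  state <- sub("\\..*$", "", rest)
  channel <- sub("^[^.]*\\.", "", rest)
  data.frame(column = nms[hit], state = state, channel = channel,
             stringsAsFactors = FALSE)
}

#' Read and filter a MaxQuant-dialect redox site table
#'
#' Applies the standard row-level quality filters: rows flagged \code{"+"}
#' in \code{Reverse} or \code{Potential contaminant}, rows whose accession
#' is prefixed \code{REV_} or \code{CON_}, and rows with localization
#' probability not strictly greater than \code{loc_prob_threshold} are
#' removed. Zero reporter intensities are converted to missing (a zero
#' reporter means the site was not quantified in that channel). Removal
#' counts are attached as attribute \code{"filter_counts"}.
#'
#' @param path TSV path with annotation columns and
#'   \code{intensity.<state>.<sample>} reporter columns (one \code{REF}
#'   channel per state plex).
#' @param loc_prob_threshold localization probability cutoff (strict
#'   \code{>}; the conventional value is 0.75).
#' @param col_map named character vector mapping the canonical annotation
#'   fields to the file's column names (see \code{default_site_cols}).
#' @return A \code{\link{reporter_sites}} object.
#' @export
read_site_table <- function(path, loc_prob_threshold = 0.75,
                            col_map = default_site_cols()) {
  df <- read_tsv_checked(path)
  require_cols(df, unname(col_map[c("protein", "position", "localization_prob",
                                    "reverse", "contaminant")]), path)
  n_in <- nrow(df)
  if (n_in == 0) warning(sprintf("'%s' contains no data rows", path))

  rev_flag <- !is.na(df[[col_map["reverse"]]]) & df[[col_map["reverse"]]] == "+"
  con_flag <- !is.na(df[[col_map["contaminant"]]]) & df[[col_map["contaminant"]]] == "+"
  acc <- as.character(df[[col_map["protein"]]])
  rev_flag <- rev_flag | startsWith(acc, "REV_")
  con_flag <- con_flag | startsWith(acc, "CON_")
  loc <- df[[col_map["localization_prob"]]]
  loc_fail <- !(!is.na(loc) & loc > loc_prob_threshold)

  drop_rev <- rev_flag
  drop_con <- !rev_flag & con_flag
  drop_loc <- !rev_flag & !con_flag & loc_fail
  keep <- !(rev_flag | con_flag | loc_fail)
  counts <- c(input = n_in, retained = sum(keep), reverse = sum(drop_rev),
              contaminant = sum(drop_con), localization = sum(drop_loc))
  df <- df[keep, , drop = FALSE]

  sid <- if (!is.null(col_map["site_id"]) && col_map["site_id"] %in% names(df))
    as.character(df[[col_map["site_id"]]])
  else paste0(df[[col_map["protein"]]], "_C", df[[col_map["position"]]])
  ann <- data.frame(site_id = sid,
                    protein = as.character(df[[col_map["protein"]]]),
                    position = as.integer(df[[col_map["position"]]]),
                    localization_prob = as.numeric(df[[col_map["localization_prob"]]]),
                    stringsAsFactors = FALSE)

  chan <- parse_channel_cols(names(df), "intensity")
  if (nrow(chan) == 0)
    stop_schema(sprintf("'%s' has no 'intensity.<state>.<sample>' columns", path))
  intensity <- list()
  for (st in unique(chan$state)) {
    sub <- chan[chan$state == st, ]
    m <- as.matrix(df[, sub$column, drop = FALSE])
    colnames(m) <- sub$channel
    rownames(m) <- sid
    m[!is.na(m) & m == 0] <- NA_real_   # zero reporter = not quantified
    if (any(m < 0, na.rm = TRUE))
      stop_schema(sprintf("negative intensity in '%s', state %s", path, st))
    intensity[[st]] <- m
  }
  out <- reporter_sites(ann, intensity)
  attr(out, "filter_counts") <- counts
  out
}

#' Read a protein-level channel quantification table
#'
#' Removes contaminant (\code{CON_}) and decoy (\code{REV_}) accessions and
#' rows flagged in \code{Reverse} / \code{Potential contaminant} columns if
#' present, then collects \code{abundance.<state>.<channel>} columns into
#' per-plex matrices.
#'
#' @param path TSV path.
#' @return A \code{\link{protein_quant}} object with attribute
#'   \code{"filter_counts"}.
#' @export
read_protein_table <- function(path) {
  df <- read_tsv_checked(path)
  require_cols(df, "Protein", path)
  n_in <- nrow(df)
  if (n_in == 0) warning(sprintf("'%s' contains no data rows", path))
  acc <- as.character(df$Protein)
  drop <- startsWith(acc, "REV_") | startsWith(acc, "CON_")
  for (fl in c("Reverse", "Potential contaminant"))
    if (fl %in% names(df)) drop <- drop | (!is.na(df[[fl]]) & df[[fl]] == "+")
  counts <- c(input = n_in, retained = sum(!drop), removed = sum(drop))
  df <- df[!drop, , drop = FALSE]
  chan <- parse_channel_cols(names(df), "abundance")
  if (nrow(chan) == 0)
    stop_schema(sprintf("'%s' has no 'abundance.<state>.<channel>' columns", path))
  ab <- list()
  for (st in unique(chan$state)) {
    sub <- chan[chan$state == st, ]
    m <- as.matrix(df[, sub$column, drop = FALSE])
    colnames(m) <- sub$channel
    rownames(m) <- as.character(df$Protein)
    ab[[st]] <- m
  }
  out <- protein_quant(ab)
  attr(out, "filter_counts") <- counts
  out
}

#' Read a peptide quantification table
#'
#' @param path TSV with columns \code{peptide_id}, \code{protein},
#'   \code{is_unique}, per-sample intensity columns and optional per-batch
#'   \code{REF_<batch>} reference columns. Contaminant/decoy accessions are
#'   removed.
#' @return data.frame.
#' @export
read_peptide_table <- function(path) {
  df <- read_tsv_checked(path)
  require_cols(df, c("peptide_id", "protein", "is_unique"), path)
  acc <- as.character(df$protein)
  df <- df[!(startsWith(acc, "REV_") | startsWith(acc, "CON_")), , drop = FALSE]
  df$is_unique <- as.logical(df$is_unique)
  df
}

#' Read an untargeted metabolomics export
#'
#' Expects a \code{metabolite_id} column, per-sample intensity columns,
#' \code{qc.<i>} QC replicate columns, and one row with metabolite id
#' \code{protein_concentration} holding the per-sample protein
#' concentration used for normalization.
#'
#' @param path TSV path.
#' @param mode ion mode, \code{"pos"} or \code{"neg"}.
#' @return A \code{\link{metabolite_table}}.
#' @export
read_metabolite_table <- function(path, mode) {
  if (!mode %in% c("pos", "neg"))
    stop_schema(sprintf("unknown ion mode '%s' (expected 'pos' or 'neg')", mode))
  df <- read_tsv_checked(path)
  require_cols(df, "metabolite_id", path)
  qc_cols <- grep("^qc\\.", names(df), value = TRUE)
  sample_cols <- setdiff(names(df), c("metabolite_id", qc_cols))
  conc_row <- df$metabolite_id == "protein_concentration"
  if (!any(conc_row))
    stop_schema(sprintf("'%s' lacks the protein_concentration row", path))
  conc <- as.numeric(df[which(conc_row)[1], sample_cols])
  names(conc) <- sample_cols
  if (anyNA(conc))
    stop_schema(paste0("missing protein_concentration for sample(s): ",
                       paste(sample_cols[is.na(conc)], collapse = ", ")))
  df <- df[!conc_row, , drop = FALSE]
  vals <- as.matrix(df[, sample_cols, drop = FALSE])
  qc <- as.matrix(df[, qc_cols, drop = FALSE])
  rownames(vals) <- rownames(qc) <- df$metabolite_id
  if (any(vals < 0, na.rm = TRUE) || any(qc < 0, na.rm = TRUE))
    stop_schema(sprintf("negative metabolite intensity in '%s'", path))
  vals[!is.na(vals) & vals == 0] <- NA_real_
  metabolite_table(vals, qc, conc, mode)
}

#' Read a protein FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of uppercased sequences keyed by
#'   accession (first word of the header). Duplicate accessions are an
#'   error.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  first_content <- which(nzchar(trimws(lines)))[1]
  if (!is.na(first_content) && !startsWith(trimws(lines[first_content]), ">"))
    stop_schema(sprintf("malformed FASTA '%s': line %d does not start a record",
                        path, first_content))
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e)
                   stop_schema(sprintf("malformed FASTA '%s': %s", path,
                                       conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop_schema(paste0("duplicate FASTA accession(s): ",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids
  seqs
}
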