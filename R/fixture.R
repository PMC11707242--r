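# Fixture writing: emits the MaxQuant-dialect TSVs, metabolite exports,
# FASTA and ground-truth tables that the ingest module consumes.

# write a data.frame as TSV with full double precision so numeric values
# round-trip exactly through read.delim
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    v <- df[[j]]
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    df[[j]] <- out
  }
  tryCatch(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", fileEncoding = "UTF-8"),
    error = function(e) stop(sprintf("failed to write '%s': %s", path,
                                     conditionMessage(e))))
  path
}

intensity_wide <- function(intensity, missing_as_zero = TRUE) {
  cols <- list()
  for (st in names(intensity)) {
    m <- intensity[[st]]
    for (ch in colnames(m)) {
      v <- m[, ch]
      if (missing_as_zero) v[is.na(v)] <- 0
      cols[[paste("intensity", st, ch, sep = ".")]] <- unname(v)
    }
  }
  as.data.frame(cols, check.names = FALSE, optional = TRUE)
}

#' Write a synthetic cohort to disk as ingestible fixture files
#'
#' Emits the MaxQuant-dialect site table (reporter intensities as
#' \code{intensity.<state>.<sample>} columns, zeros for missing values,
#' \code{Reverse} / \code{Potential contaminant} flag columns), the
#' protein-level channel table, the peptide table, per-mode metabolite
#' tables carrying QC replicate columns and a \code{protein_concentration}
#' row, the protein FASTA, the ground-truth tables and the configuration as
#' YAML. Everything round-trips through the \code{read_*} ingest functions.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "redox_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory '%s'", dir))
  p <- function(f) file.path(dir, f)
  paths <- c()

  ann <- cohort$sites$annotation
  site_df <- data.frame(site_id = ann$site_id, Protein = ann$protein,
                        Position = ann$position,
                        `Localization prob` = ann$localization_prob,
                        Reverse = rep("-", nrow(ann)),
                        `Potential contaminant` = rep("-", nrow(ann)),
                        check.names = FALSE, stringsAsFactors = FALSE)
  site_df <- cbind(site_df, intensity_wide(cohort$sites$intensity))
  paths["sites"] <- write_tsv(site_df, p("redox_sites.tsv"))

  prot_df <- data.frame(Protein = rownames(cohort$proteins$abundance[[1]]),
                        stringsAsFactors = FALSE)
  ab_cols <- list()
  for (st in names(cohort$proteins$abundance)) {
    m <- cohort$proteins$abundance[[st]]
    for (ch in colnames(m))
      ab_cols[[paste("abundance", st, ch, sep = ".")]] <- unname(m[, ch])
  }
  prot_df <- cbind(prot_df, as.data.frame(ab_cols, check.names = FALSE))
  paths["proteins"] <- write_tsv(prot_df, p("protein_groups.tsv"))

  paths["peptides"] <- write_tsv(cohort$peptides, p("peptides.tsv"))

  for (md in names(cohort$metabolites)) {
    mt <- cohort$metabolites[[md]]
    df <- data.frame(metabolite_id = rownames(mt$values),
                     stringsAsFactors = FALSE)
    sdf <- as.data.frame(mt$values, check.names = FALSE)
    qdf <- as.data.frame(mt$qc, check.names = FALSE)
    colnames(qdf) <- paste0("qc.", seq_len(ncol(qdf)))
    df <- cbind(df, sdf, qdf)
    conc_row <- df[0, ]
    conc_row[1, "metabolite_id"] <- "protein_concentration"
    conc_row[1, colnames(mt$values)] <- mt$protein_concentration
    df <- rbind(conc_row, df)
    rownames(df) <- NULL
    paths[paste0("metabolites_", md)] <-
      write_tsv(df, p(sprintf("metabolites_%s.tsv", md)))
  }

  aa <- Biostrings::AAStringSet(cohort$sequences)
  Biostrings::writeXStringSet(aa, p("proteins.fasta"))
  paths["fasta"] <- p("proteins.fasta")

  paths["truth_sites"] <- write_tsv(cohort$truth$sites, p("truth_sites.tsv"))
  theta_df <- data.frame(site_id = rownames(cohort$truth$theta),
                         as.data.frame(cohort$truth$theta, check.names = FALSE),
                         check.names = FALSE, stringsAsFactors = FALSE)
  paths["truth_theta"] <- write_tsv(theta_df, p("truth_theta.tsv"))
  paths["truth_metabolites"] <-
    write_tsv(cohort$truth$metabolites, p("truth_metabolites.tsv"))
  paths["truth_latent"] <- write_tsv(cohort$truth$latent, p("truth_latent.tsv"))
  paths["design"] <- write_tsv(transform(cohort$design, group = as.character(group)),
                               p("design.tsv"))

  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, p("config.yaml"))
  paths["config"] <- p("config.yaml")
  paths
}
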