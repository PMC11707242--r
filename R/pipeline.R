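# Pipeline orchestration: one flat configuration drives simulate -> ingest
# -> normalize -> stoichiometry -> differential -> crosstalk -> motif, with
# plain-TSV outputs and a JSON manifest for provenance.

default_run_config <- function() {
  list(
    seed = 1L,
    out = "redoxmap_run",
    simulate = list(enabled = TRUE),
    inputs = list(),
    ingest = list(loc_prob = 0.75),
    normalize = list(cv_max = 0.3, min_unique = 2, min_detect_frac = 0.5),
    stoich = list(min_n = 3, delta_min = 0.10, bw = "nrd0", min_values = 50),
    diff = list(alpha = 0.05, min_n = 3, min_frac = 0.5,
                log2fc = 0.263),
    crosstalk = list(alpha = 0.05, p_max = 0.05, rho_min = 0.6,
                     min_pairs = 8, min_total = 3, k = 50),
    motif = list(flank = 10))
}

#' Read and validate a pipeline run configuration
#'
#' A flat YAML file with per-stage sections; omitted keys take the
#' conventional defaults (localization probability 0.75, min 3 detections
#' per group, alpha 0.05, |rho| > 0.6, |log2FC| > 0.263, QC CV < 0.3,
#' occupancy delta > 0.10, +/-10-residue windows, top-50 overlap). Unknown
#' keys and out-of-range thresholds are rejected before any stage runs.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides named list merged over the file (e.g. list(seed = 7)).
#' @return Validated configuration list of class \code{"run_config"}.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  merge_section <- function(base, upd, where) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown) > 0)
      stop_config(paste0(where, ".", unknown[1]), "unknown configuration key")
    base[names(upd)] <- upd
    base
  }
  for (src in list(user, overrides)) {
    top_unknown <- setdiff(names(src), names(cfg))
    if (length(top_unknown) > 0)
      stop_config(top_unknown[1], "unknown configuration key")
    for (k in names(src)) {
      if (is.list(cfg[[k]]) && k != "simulate" && k != "inputs")
        cfg[[k]] <- merge_section(cfg[[k]], src[[k]], k)
      else cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(src[[k]]))
        modifyList(cfg[[k]], src[[k]]) else src[[k]]
    }
  }
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  chk_prob <- function(val, field) {
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val <= 0 || val > 1)
      stop_config(field, "must be in (0, 1]")
  }
  chk_prob(cfg$ingest$loc_prob, "ingest.loc_prob")
  chk_prob(cfg$normalize$cv_max, "normalize.cv_max")
  chk_prob(cfg$normalize$min_detect_frac, "normalize.min_detect_frac")
  chk_prob(cfg$diff$alpha, "diff.alpha")
  chk_prob(cfg$diff$min_frac, "diff.min_frac")
  chk_prob(cfg$crosstalk$alpha, "crosstalk.alpha")
  chk_prob(cfg$crosstalk$p_max, "crosstalk.p_max")
  if (cfg$crosstalk$rho_min < 0 || cfg$crosstalk$rho_min >= 1)
    stop_config("crosstalk.rho_min", "must be in [0, 1)")
  if (cfg$stoich$delta_min < 0 || cfg$stoich$delta_min >= 1)
    stop_config("stoich.delta_min", "must be in [0, 1)")
  for (f in c("stoich.min_n", "diff.min_n", "crosstalk.min_pairs",
              "crosstalk.k", "motif.flank", "normalize.min_unique")) {
    parts <- strsplit(f, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1)
      stop_config(f, "must be a count >= 1")
  }
  if (!is.numeric(cfg$seed) || is.na(cfg$seed))
    stop_config("seed", "must be an integer")
  invisible(cfg)
}

md5_of <- function(path) unname(tools::md5sum(path))

#' Run the full redoxome analysis pipeline
#'
#' Executes the stages in dependency order on either a simulated cohort
#' (default) or fixture files named in \code{config$inputs}, writing
#' plain-TSV stage outputs and a JSON manifest (configuration hash, seed,
#' per-stage row counts, output checksums) to \code{config$out}. Reruns
#' with the same configuration and seed produce byte-identical outputs.
#'
#' @param config a \code{\link{read_run_config}} result (or NULL for
#'   defaults).
#' @param out output directory, overriding \code{config$out}.
#' @return Invisibly, the manifest list (with element \code{paths}).
#' @export
run_pipeline <- function(config = NULL, out = NULL) {
  if (is.null(config)) config <- read_run_config()
  if (!inherits(config, "run_config")) stop_schema("config must be a run_config")
  out_dir <- out %||% config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "redoxmap",
                   version = as.character(packageVersion("redoxmap")),
                   seed = config$seed, stages = list())
  cfgfile <- file.path(out_dir, "run_config.yaml")
  cfg_plain <- config; class(cfg_plain) <- NULL
  yaml::write_yaml(cfg_plain, cfgfile)
  manifest$config_md5 <- md5_of(cfgfile)

  # --- simulate / locate inputs -------------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    sim_args <- config$simulate
    sim_args$enabled <- NULL
    sim_args$seed <- sim_args$seed %||% config$seed
    cohort <- generate_cohort(do.call(cohort_config, sim_args))
    fixdir <- file.path(out_dir, "fixture")
    inputs <- as.list(write_fixture(cohort, fixdir))
    manifest$stages$simulate <- list(
      n_sites = cohort$config$n_sites,
      n_samples = nrow(cohort$design),
      n_metabolites = cohort$config$n_metabolites)
  } else {
    inputs <- config$inputs
    req <- c("sites", "proteins", "peptides", "metabolites_pos",
             "metabolites_neg", "fasta", "design")
    for (r in req) {
      if (is.null(inputs[[r]]))
        stop_schema(sprintf("inputs.%s not set and simulation disabled", r))
      if (!file.exists(inputs[[r]]))
        stop_schema(sprintf("missing input file for '%s': %s", r, inputs[[r]]))
    }
  }

  # --- ingest --------------------------------------------------------------
  sites <- read_site_table(inputs$sites, loc_prob_threshold = config$ingest$loc_prob)
  proteins <- read_protein_table(inputs$proteins)
  peptides <- read_peptide_table(inputs$peptides)
  met_pos <- read_metabolite_table(inputs$metabolites_pos, "pos")
  met_neg <- read_metabolite_table(inputs$metabolites_neg, "neg")
  sequences <- read_fasta_sequences(inputs$fasta)
  design <- read.delim(inputs$design, stringsAsFactors = FALSE)
  groups <- unique(design$group)
  design$group <- factor(design$group, levels = groups)
  manifest$stages$ingest <- list(
    site_filter = as.list(attr(sites, "filter_counts")),
    n_proteins = nrow(proteins$abundance[[1]]),
    n_metabolites = nrow(met_pos$values) + nrow(met_neg$values))

  # --- normalize -----------------------------------------------------------
  ratios <- compute_channel_ratios(proteins)
  norm <- normalize_redox(sites, ratios)
  prot_mat <- suppressWarnings(
    normalize_proteome(peptides, design,
                       min_unique = config$normalize$min_unique,
                       min_detect_frac = config$normalize$min_detect_frac))
  met_mat <- suppressWarnings(
    normalize_metabolome(list(met_pos, met_neg), cv_max = config$normalize$cv_max))
  qc_cor <- qc_correlation(rbind(met_pos$qc, met_neg$qc))
  write_tsv(as.data.frame(cbind(sample = rownames(qc_cor), qc_cor),
                          check.names = FALSE),
            file.path(out_dir, "qc_correlation.tsv"))
  manifest$stages$normalize <- list(
    n_proteins_quantified = nrow(prot_mat),
    n_metabolites_retained = nrow(met_mat),
    n_metabolites_cv_excluded = attr(met_mat, "n_excluded"))

  # --- stoichiometry -------------------------------------------------------
  occ <- suppressWarnings(compute_occupancy(norm))
  st_cfg <- config$stoich
  med_sto <- group_median_occupancy(occ$occ$Sto, design, min_n = st_cfg$min_n)
  occ_long <- data.frame(site_id = rep(rownames(med_sto$median),
                                       ncol(med_sto$median)),
                         group = rep(colnames(med_sto$median),
                                     each = nrow(med_sto$median)),
                         median_sto = as.vector(med_sto$median),
                         n_quantified = as.vector(med_sto$n))
  write_tsv(occ_long, file.path(out_dir, "sto_group_medians.tsv"))

  young <- groups[1]; old <- groups[length(groups)]
  models <- list()
  regions <- list()
  for (gset in c(young, old)) {
    mod <- tryCatch(
      fit_region_model(med_sto$median[, gset], bw = st_cfg$bw,
                       min_values = st_cfg$min_values),
      redoxmap_unimodal_error = function(e) NULL)
    models[[gset]] <- mod
    if (!is.null(mod))
      regions[[gset]] <- assign_regions(
        setNames(med_sto$median[, gset], rownames(med_sto$median)), mod,
        prefix = toupper(substr(gset, 1, 1)))
  }
  trans <- NULL
  if (!is.null(models[[young]]) && !is.null(models[[old]])) {
    trans <- count_transitions(
      setNames(med_sto$median[, young], rownames(med_sto$median)),
      attr(regions[[young]], "region"),
      setNames(med_sto$median[, old], rownames(med_sto$median)),
      attr(regions[[old]], "region"),
      delta_min = st_cfg$delta_min)
    write_tsv(data.frame(direction = c("low_to_high", "high_to_low"),
                         n = c(trans$n_low_to_high, trans$n_high_to_low),
                         n_delta = c(trans$n_low_to_high_delta,
                                     trans$n_high_to_low_delta)),
              file.path(out_dir, "transitions.tsv"))
  }
  contrib <- modification_contribution(
    setNames(group_median_occupancy(occ$occ$Sto, design, st_cfg$min_n)$median[, old],
             rownames(med_sto$median)),
    group_median_occupancy(occ$occ$SSG, design, st_cfg$min_n)$median[, old],
    group_median_occupancy(occ$occ$SOH, design, st_cfg$min_n)$median[, old],
    group_median_occupancy(occ$occ$SNO, design, st_cfg$min_n)$median[, old])
  write_tsv(contrib, file.path(out_dir, "sto_contributions.tsv"))
  manifest$stages$stoich <- list(
    n_sites_with_occupancy = sum(rowSums(!is.na(occ$occ$Sto)) > 0),
    peaks = lapply(models, function(m) if (is.null(m)) NULL else
      list(peaks = m$peaks, valley = m$valley)),
    transitions = if (is.null(trans)) NULL else list(
      low_to_high = trans$n_low_to_high, high_to_low = trans$n_high_to_low,
      low_to_high_delta = trans$n_low_to_high_delta,
      high_to_low_delta = trans$n_high_to_low_delta))

  # --- differential --------------------------------------------------------
  diff_res <- screen_redox_differential(
    occ$occ$Sto, design, alpha = config$diff$alpha,
    min_n = config$diff$min_n, min_frac = config$diff$min_frac)
  write_tsv(diff_res, file.path(out_dir, "differential_sto.tsv"))
  manifest$stages$differential <- list(
    n_tested = sum(diff_res$rule == "anova"),
    n_significant = sum(diff_res$significant),
    n_presence = sum(diff_res$rule == "presence" & diff_res$significant))

  # --- crosstalk -----------------------------------------------------------
  ct <- config$crosstalk
  met_log <- log2(met_mat)
  age_met <- select_age_related_features(met_log, design, alpha = ct$alpha,
                                         min_n = config$diff$min_n)
  diff_sites <- diff_res$site_id[diff_res$significant]
  sto_levels <- norm$ref_ratio$Sto[intersect(diff_sites,
                                             rownames(norm$ref_ratio$Sto)), ,
                                   drop = FALSE]
  pairs <- spearman_pairs(sto_levels, met_mat[age_met, , drop = FALSE],
                          p_max = ct$p_max, rho_min = ct$rho_min,
                          min_pairs = ct$min_pairs)
  tally <- tally_features(pairs, min_total = ct$min_total)
  write_tsv(pairs, file.path(out_dir, "crosstalk_pairs.tsv"))
  write_tsv(tally, file.path(out_dir, "crosstalk_tally.tsv"))
  manifest$stages$crosstalk <- list(
    n_age_related_metabolites = length(age_met),
    n_pairs = nrow(pairs),
    n_suppressor = sum(tally$call == "suppressor_candidate"),
    n_promoter = sum(tally$call == "promoter_candidate"))

  # --- motif ---------------------------------------------------------------
  manifest$stages$motif <- list(n_regions = 0)
  if (!is.null(regions[[young]])) {
    lab <- regions[[young]]
    mats <- list()
    for (rg in sort(unique(lab[!is.na(lab)]))) {
      ids <- names(lab)[!is.na(lab) & lab == rg]
      ann <- occ$annotation[occ$annotation$site_id %in% ids, , drop = FALSE]
      if (nrow(ann) == 0) next
      win <- extract_windows(sequences, ann, flank = config$motif$flank)
      mats[[rg]] <- position_frequencies(win, region = rg)
      mm <- mats[[rg]]
      write_tsv(data.frame(position = colnames(mm),
                           t(unclass(mm)), check.names = FALSE),
                file.path(out_dir, sprintf("motif_%s.tsv", rg)))
    }
    manifest$stages$motif <- list(
      n_regions = length(mats),
      n_windows = lapply(mats, attr, "n_windows"))
  }

  # --- manifest ------------------------------------------------------------
  outs <- sort(list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE))
  manifest$outputs <- lapply(outs, function(f)
    list(file = basename(f), md5 = md5_of(f)))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest$paths <- list(out = out_dir, manifest = mpath, inputs = inputs)
  invisible(manifest)
}
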