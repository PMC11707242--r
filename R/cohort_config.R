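#' Synthetic cohort configuration
#'
#' Parameters of the synthetic redox cohort generator. Defaults emulate the
#' study design the pipeline targets: 3 age groups (young / middle / old) x 2
#' colon locations (A = ascending, D = descending) x 4 animals, five redox
#' states plus a fully-reduced common reference channel per plex, a bimodal
#' true total-oxidation occupancy, a small set of sites whose occupancy is
#' planted to shift with age, intensity-dependent (MNAR) dropout, and
#' metabolites coupled to a latent per-sample oxidative-stress factor.
#'
#' @param n_groups number of age groups (3 gives young/middle/old labels).
#' @param n_locations number of tissue locations (2 gives A/D labels).
#' @param n_per_cell animals per group x location cell (>= 3 so per-group
#'   screens are testable).
#' @param n_sites number of cysteine sites.
#' @param n_proteins number of proteins carrying the sites.
#' @param n_metabolites number of metabolites across both ion modes.
#' @param n_qc number of metabolomics QC replicate injections.
#' @param mixture_modes modes of the two-component Beta mixture of true Sto
#'   occupancy, strictly inside (0,1) and increasing.
#' @param mixture_weight fraction of sites in the low-occupancy component.
#' @param mixture_concentration Beta concentration (peak sharpness) of both
#'   components.
#' @param frac_age_up,frac_age_down fractions of sites with a planted
#'   monotone occupancy increase/decrease across age groups.
#' @param age_effect occupancy shift in each extreme group for planted age
#'   sites (+age_effect in old, -age_effect in young, middle unchanged).
#' @param frac_stress_sites fraction of sites whose occupancy is additively
#'   driven by the latent stress factor.
#' @param stress_coupling occupancy shift per unit of the latent factor for
#'   stress-driven sites.
#' @param frac_metab_suppressor,frac_metab_promoter fractions of metabolites
#'   coupled negatively/positively to the latent stress factor.
#' @param metab_slope magnitude of the latent-factor slope on metabolite
#'   log10 intensity for coupled metabolites (0.4 gives site-metabolite
#'   Spearman correlations around 0.7 under the default noise).
#' @param frac_metab_unstable fraction of metabolites given large QC
#'   variability so the CV filter has true positives.
#' @param dropout logical; apply intensity-dependent dropout.
#' @param dropout_midpoint,dropout_steepness logistic dropout parameters on
#'   log10 reporter intensity: P(missing) = plogis(steepness * (midpoint -
#'   log10 intensity)).
#' @param noise_cv coefficient of variation of multiplicative reporter /
#'   metabolite measurement noise.
#' @param channel_load_range range of per-channel loading multipliers
#'   (c(1, 1) disables loading imbalance).
#' @param motif_enrich_residue,motif_enrich_offset,motif_enrich_prob planted
#'   flanking-residue enrichment: residue, offset relative to the cysteine,
#'   and per-site probability, applied to low-occupancy-component sites.
#' @param seed master integer seed; every random block derives its own
#'   stream from it.
#' @return A validated list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_groups = 3L, n_locations = 2L, n_per_cell = 4L,
                          n_sites = 3000L, n_proteins = 800L,
                          n_metabolites = 120L, n_qc = 8L,
                          mixture_modes = c(0.25, 0.85),
                          mixture_weight = 0.6,
                          mixture_concentration = 18,
                          frac_age_up = 0.05, frac_age_down = 0.02,
                          age_effect = 0.15,
                          frac_stress_sites = 0.05, stress_coupling = 0.15,
                          frac_metab_suppressor = 0.08,
                          frac_metab_promoter = 0.08,
                          metab_slope = 0.4,
                          frac_metab_unstable = 0.05,
                          dropout = TRUE,
                          dropout_midpoint = 4.2, dropout_steepness = 1.5,
                          noise_cv = 0.2,
                          channel_load_range = c(0.7, 1.4),
                          motif_enrich_residue = "K",
                          motif_enrich_offset = -1L,
                          motif_enrich_prob = 0.4,
                          seed = 1L) {
  cfg <- list(n_groups = as.integer(n_groups), n_locations = as.integer(n_locations),
              n_per_cell = as.integer(n_per_cell), n_sites = as.integer(n_sites),
              n_proteins = as.integer(n_proteins),
              n_metabolites = as.integer(n_metabolites), n_qc = as.integer(n_qc),
              mixture_modes = as.numeric(mixture_modes),
              mixture_weight = mixture_weight,
              mixture_concentration = mixture_concentration,
              frac_age_up = frac_age_up, frac_age_down = frac_age_down,
              age_effect = age_effect,
              frac_stress_sites = frac_stress_sites,
              stress_coupling = stress_coupling,
              frac_metab_suppressor = frac_metab_suppressor,
              frac_metab_promoter = frac_metab_promoter,
              metab_slope = metab_slope,
              frac_metab_unstable = frac_metab_unstable,
              dropout = isTRUE(dropout),
              dropout_midpoint = dropout_midpoint,
              dropout_steepness = dropout_steepness,
              noise_cv = noise_cv,
              channel_load_range = as.numeric(channel_load_range),
              motif_enrich_residue = motif_enrich_residue,
              motif_enrich_offset = as.integer(motif_enrich_offset),
              motif_enrich_prob = motif_enrich_prob,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  chk_count <- function(field, min = 1L) {
    v <- cfg[[field]]
    if (length(v) != 1 || is.na(v) || v < min)
      stop_config(field, sprintf("must be a single count >= %d", min))
  }
  chk_frac <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop_config(field, "must be a fraction in [0, 1]")
  }
  chk_count("n_groups"); chk_count("n_locations"); chk_count("n_sites", 0L)
  chk_count("n_proteins"); chk_count("n_metabolites", 0L); chk_count("n_qc", 2L)
  if (cfg$n_per_cell < 3)
    stop_config("n_per_cell", "must be >= 3 (per-group screens need 3 detections)")
  m <- cfg$mixture_modes
  if (length(m) != 2 || any(m <= 0) || any(m >= 1) || m[1] >= m[2])
    stop_config("mixture_modes", "must be two increasing values strictly inside (0, 1)")
  for (f in c("mixture_weight", "frac_age_up", "frac_age_down",
              "frac_stress_sites", "frac_metab_suppressor",
              "frac_metab_promoter", "frac_metab_unstable",
              "motif_enrich_prob"))
    chk_frac(f)
  if (cfg$frac_age_up + cfg$frac_age_down > 1)
    stop_config("frac_age_up", "frac_age_up + frac_age_down must be <= 1")
  if (cfg$frac_metab_suppressor + cfg$frac_metab_promoter > 1)
    stop_config("frac_metab_suppressor",
                "frac_metab_suppressor + frac_metab_promoter must be <= 1")
  if (cfg$mixture_concentration <= 2)
    stop_config("mixture_concentration", "must be > 2 for an interior mode")
  if (cfg$noise_cv < 0) stop_config("noise_cv", "must be >= 0")
  r <- cfg$channel_load_range
  if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
    stop_config("channel_load_range", "must be a positive increasing range")
  if (cfg$dropout_steepness < 0) stop_config("dropout_steepness", "must be >= 0")
  if (!is.character(cfg$motif_enrich_residue) ||
      nchar(cfg$motif_enrich_residue) != 1)
    stop_config("motif_enrich_residue", "must be a single residue letter")
  if (is.na(cfg$seed)) stop_config("seed", "must be an integer")
  invisible(cfg)
}

#' Sample design of a cohort configuration
#'
#' @param config a \code{\link{cohort_config}}.
#' @return data.frame with one row per sample: \code{sample}, \code{group},
#'   \code{location}, \code{animal}, \code{age_index} (0-based), and
#'   \code{batch} for the proteome workflow.
#' @export
cohort_design <- function(config) {
  groups <- if (config$n_groups == 3) c("young", "middle", "old")
            else paste0("G", seq_len(config$n_groups))
  locs <- if (config$n_locations == 2) c("A", "D")
          else paste0("L", seq_len(config$n_locations))
  d <- expand.grid(animal = seq_len(config$n_per_cell), location = locs,
                   group = groups, stringsAsFactors = FALSE)
  d <- d[, c("group", "location", "animal")]
  abbr <- toupper(substr(d$group, 1, 1))
  d$sample <- paste(abbr, d$location, d$animal, sep = "_")
  d$age_index <- match(d$group, groups) - 1L
  # two proteome TMT batches, split by animal parity
  d$batch <- ifelse(d$animal %% 2 == 1, 1L, 2L)
  d$group <- factor(d$group, levels = groups)
  rownames(d) <- NULL
  d[, c("sample", "group", "location", "animal", "age_index", "batch")]
}
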