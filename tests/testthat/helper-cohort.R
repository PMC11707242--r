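# Shared fixtures: cohorts are expensive enough to build once per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(config)
  .cohort_cache[[key]]
}

# default study-design cohort (3 x 2 x 4 samples, 3000 sites)
default_cohort <- function() cached_cohort("default", cohort_config(seed = 1))

# cohort with all noise sources disabled: occupancy must equal truth exactly
clean_cohort <- function() {
  cached_cohort("clean", cohort_config(
    n_sites = 300, n_proteins = 120, noise_cv = 0, dropout = FALSE,
    channel_load_range = c(1, 1), seed = 7))
}

# small cohort for I/O and motif tests
small_cohort <- function() {
  cached_cohort("small", cohort_config(
    n_sites = 400, n_proteins = 150, n_metabolites = 40, seed = 5))
}

# run the normalization chain up to occupancy
occupancy_chain <- function(cohort) {
  ratios <- compute_channel_ratios(cohort$proteins)
  norm <- normalize_redox(cohort$sites, ratios)
  occ <- suppressWarnings(compute_occupancy(norm))
  list(ratios = ratios, norm = norm, occ = occ)
}

# build a reporter_sites object from per-state intensity matrices given as
# plain lists of named rows; NULL entries become NA
make_sites <- function(intensity, positions = NULL) {
  sids <- rownames(intensity[[1]])
  ann <- data.frame(site_id = sids, protein = paste0("PR", seq_along(sids)),
                    position = positions %||% rep(15L, length(sids)),
                    localization_prob = 0.99, stringsAsFactors = FALSE)
  reporter_sites(ann, intensity)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# identity channel-ratio set for the given states/channels
identity_ratios <- function(states, channels) {
  structure(lapply(setNames(states, states),
                   function(s) setNames(rep(1, length(channels)), channels)),
            reference = "REF", class = "channel_ratio_set")
}
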