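#' Generate a synthetic redox cohort with known ground truth
#'
#' Simulates the full multi-omic study design end to end: per-site true total
#' oxidation occupancies drawn from a two-component Beta mixture, reporter
#' intensities for the five redox-state plexes plus a fully-reduced common
#' reference channel, a protein-level channel quantification for
#' normalization, a peptide table for the proteome workflow, two ion-mode
#' metabolite tables with QC replicates coupled to a latent per-sample
#' oxidative-stress factor, and protein sequences carrying the sites. Every
#' random block uses its own stream derived from \code{config$seed}, so the
#' output is a pure function of the configuration.
#'
#' The reporter model for site i, sample s with true occupancy theta:
#' total peptide intensity T_i is log-normal; I_Sto = T * theta * L * eps,
#' I_SH = T * (1 - theta) * L * eps, I_m = T * theta * c_m * L * eps for
#' m in SSG/SOH/SNO with per-site sub-fractions c_SSG > c_SOH, c_SNO summing
#' to <= 1, and the reference channel of every plex carries the full thiol
#' signal T * L_ref * eps. L are per-channel loading multipliers and eps
#' multiplicative log-normal noise. Missingness is logistic in log10
#' intensity (missing-not-at-random, low-abundance loss).
#'
#' @param config a \code{\link{cohort_config}}.
#' @return An object of class \code{"redox_cohort"}: list with elements
#'   \code{config}, \code{design}, \code{sites} (\code{reporter_sites}),
#'   \code{proteins} (\code{protein_quant}), \code{peptides} (data.frame),
#'   \code{metabolites} (list of two \code{metabolite_table}s),
#'   \code{sequences} (named character vector) and \code{truth}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  design <- cohort_design(config)
  ns <- nrow(design)
  streams <- derive_streams(config$seed,
    c("latent", "classes", "theta", "subfrac", "abundance", "sequences",
      "proteins", "peptides", "metabolites", "loading", "noise", "dropout"))

  # latent oxidative-stress factor: increases with age group
  z <- with_stream(streams, "latent",
    (design$age_index - (config$n_groups - 1) / 2) + rnorm(ns, sd = 0.5))
  names(z) <- design$sample

  n <- config$n_sites
  site_ids <- if (n > 0) sprintf("site_%04d", seq_len(n)) else character(0)

  cls <- with_stream(streams, "classes", {
    component <- ifelse(runif(n) < config$mixture_weight, "low", "high")
    age_class <- sample(c("up", "down", "none"), n, replace = TRUE,
                        prob = c(config$frac_age_up, config$frac_age_down,
                                 1 - config$frac_age_up - config$frac_age_down))
    stress <- runif(n) < config$frac_stress_sites
    list(component = component, age_class = age_class, stress = stress)
  })

  theta_base <- with_stream(streams, "theta", {
    mode <- ifelse(cls$component == "low",
                   config$mixture_modes[1], config$mixture_modes[2])
    kappa <- config$mixture_concentration
    rbeta(n, mode * (kappa - 2) + 1, (1 - mode) * (kappa - 2) + 1)
  })

  subfrac <- with_stream(streams, "subfrac", {
    data.frame(c_SSG = runif(n, 0.30, 0.60),
               c_SOH = runif(n, 0.05, 0.20),
               c_SNO = runif(n, 0.05, 0.20))
  })

  # per-site per-sample true occupancy
  age_dir <- c(up = 1, down = -1, none = 0)[cls$age_class]
  centre <- (config$n_groups - 1) / 2
  theta <- matrix(theta_base, nrow = n, ncol = ns,
                  dimnames = list(site_ids, design$sample))
  if (n > 0) {
    shift_age <- outer(age_dir * config$age_effect, design$age_index - centre)
    shift_stress <- outer(as.numeric(cls$stress) * config$stress_coupling, z)
    theta <- pmin(pmax(theta + shift_age + shift_stress, 0.02), 0.98)
  }

  site_abund <- with_stream(streams, "abundance", 10^rnorm(n, mean = 6, sd = 0.5))

  # protein sequences carrying the sites
  seqinfo <- with_stream(streams, "sequences",
    build_sequences(config, site_ids, cls$component))

  channels <- c(design$sample, REF_CHANNEL)
  loading <- with_stream(streams, "loading", {
    L <- matrix(runif(length(REDOX_STATES) * length(channels),
                      config$channel_load_range[1], config$channel_load_range[2]),
                nrow = length(REDOX_STATES),
                dimnames = list(REDOX_STATES, channels))
    L
  })

  intensity <- with_stream(streams, "noise", {
    out <- list()
    for (st in REDOX_STATES) {
      sig <- switch(st,
        SH  = site_abund * (1 - theta),
        Sto = site_abund * theta,
        SSG = site_abund * theta * subfrac$c_SSG,
        SOH = site_abund * theta * subfrac$c_SOH,
        SNO = site_abund * theta * subfrac$c_SNO)
      sig <- matrix(sig, nrow = n, ncol = ns, dimnames = dimnames(theta))
      ref <- site_abund
      m <- cbind(sig, ref)
      colnames(m) <- channels
      m <- sweep(m, 2, loading[st, ], "*")
      m <- m * matrix(rlnorm_cv(length(m), config$noise_cv),
                      nrow = nrow(m), ncol = ncol(m))
      rownames(m) <- site_ids
      out[[st]] <- m
    }
    out
  })

  if (config$dropout && n > 0) {
    intensity <- with_stream(streams, "dropout", {
      lapply(intensity, function(m) {
        p <- plogis(config$dropout_steepness * (config$dropout_midpoint - log10(m)))
        m[runif(length(m)) < p] <- NA_real_
        m
      })
    })
  }

  annotation <- data.frame(site_id = site_ids,
                           protein = seqinfo$site_protein,
                           position = seqinfo$site_position,
                           localization_prob = rep(0.99, n),
                           stringsAsFactors = FALSE)
  sites <- reporter_sites(annotation, intensity)

  proteins <- with_stream(streams, "proteins",
    build_protein_quant(config, seqinfo$protein_ids, channels, loading))

  peptides <- with_stream(streams, "peptides",
    build_peptides(config, seqinfo$protein_ids, design))

  met <- with_stream(streams, "metabolites",
    build_metabolites(config, design, z))

  truth <- list(
    sites = data.frame(site_id = site_ids, component = cls$component,
                       theta_base = theta_base, age_class = cls$age_class,
                       stress_driven = cls$stress,
                       c_SSG = subfrac$c_SSG, c_SOH = subfrac$c_SOH,
                       c_SNO = subfrac$c_SNO, stringsAsFactors = FALSE),
    theta = theta,
    metabolites = met$truth,
    latent = data.frame(sample = design$sample, z = unname(z),
                        stringsAsFactors = FALSE))

  structure(list(config = config, design = design, sites = sites,
                 proteins = proteins, peptides = peptides,
                 metabolites = met$tables, sequences = seqinfo$sequences,
                 truth = truth),
            class = "redox_cohort")
}

#' @export
print.redox_cohort <- function(x, ...) {
  cat(sprintf(paste0("redox_cohort: %d sites on %d proteins, %d samples ",
                     "(%d groups x %d locations x %d), %d metabolites\n"),
              x$config$n_sites, x$config$n_proteins, nrow(x$design),
              x$config$n_groups, x$config$n_locations, x$config$n_per_cell,
              x$config$n_metabolites))
  invisible(x)
}

AA20 <- c("A", "R", "N", "D", "E", "Q", "G", "H", "I", "L",
          "K", "M", "F", "P", "S", "T", "W", "Y", "V", "C")

build_sequences <- function(config, site_ids, component) {
  n <- length(site_ids)
  prot_ids <- sprintf("P%04d", seq_len(config$n_proteins))
  lens <- sample(150:400, config$n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(AA20[-20], L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- prot_ids

  site_protein <- character(n)
  site_position <- integer(n)
  if (n > 0) {
    idx <- sample.int(config$n_proteins, n, replace = TRUE)
    chars <- strsplit(seqs, "", fixed = TRUE)
    for (p in unique(idx)) {
      k <- which(idx == p)
      L <- lens[p]
      avail <- 12:(L - 11)
      pos <- sample(avail, min(length(k), length(avail)))
      k <- k[seq_along(pos)]
      site_protein[k] <- prot_ids[p]
      site_position[k] <- pos
      chars[[p]][pos] <- "C"
      # planted flanking enrichment for low-occupancy-component sites
      enrich <- k[component[k] == "low" & runif(length(k)) < config$motif_enrich_prob]
      off <- config$motif_enrich_offset
      for (s in enrich) {
        at <- site_position[s] + off
        if (at >= 1 && at <= L && !(at %in% pos))
          chars[[p]][at] <- config$motif_enrich_residue
      }
    }
    # sites that could not be placed (protein saturated) go to fresh positions
    # on the least-used protein; with default sizes this never triggers
    unplaced <- which(site_protein == "")
    for (s in unplaced) {
      p <- which.max(lens)
      free <- setdiff(12:(lens[p] - 11), site_position[site_protein == prot_ids[p]])
      site_protein[s] <- prot_ids[p]
      site_position[s] <- free[1]
      chars[[p]][free[1]] <- "C"
    }
    seqs <- vapply(chars, paste, character(1), collapse = "")
    names(seqs) <- prot_ids
  }
  list(sequences = seqs, protein_ids = prot_ids,
       site_protein = site_protein, site_position = site_position)
}

build_protein_quant <- function(config, prot_ids, channels, loading) {
  np <- length(prot_ids)
  base <- 10^rnorm(np, mean = 6.5, sd = 0.6)
  ab <- list()
  for (st in REDOX_STATES) {
    m <- outer(base, loading[st, channels]) *
      matrix(rlnorm_cv(np * length(channels), config$noise_cv), nrow = np)
    dimnames(m) <- list(prot_ids, channels)
    ab[[st]] <- m
  }
  protein_quant(ab)
}

build_peptides <- function(config, prot_ids, design) {
  np <- length(prot_ids)
  n_pep <- sample(1:6, np, replace = TRUE)
  protein <- rep(prot_ids, n_pep)
  pep_ids <- paste0("pep_", seq_along(protein))
  is_unique <- runif(length(protein)) < 0.9
  share <- 10^rnorm(length(protein), mean = 5.5, sd = 0.5)
  sample_fac <- runif(nrow(design), 0.8, 1.2)
  vals <- outer(share, sample_fac) *
    matrix(rlnorm_cv(length(share) * nrow(design), config$noise_cv),
           nrow = length(share))
  colnames(vals) <- design$sample
  refs <- sapply(sort(unique(design$batch)), function(b)
    share * rlnorm_cv(length(share), config$noise_cv))
  colnames(refs) <- paste0("REF_", sort(unique(design$batch)))
  out <- data.frame(peptide_id = pep_ids, protein = protein,
                    is_unique = is_unique, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(vals, check.names = FALSE),
        as.data.frame(refs, check.names = FALSE))
}

build_metabolites <- function(config, design, z) {
  nm <- config$n_metabolites
  ns <- nrow(design)
  ids <- if (nm > 0) sprintf("met_%03d", seq_len(nm)) else character(0)
  # fixed counts of coupled metabolites, shuffled over positions; the
  # coupled set stays a minor share of the total ion current so the
  # correction-factor normalization does not transfer its group shift onto
  # the null metabolites
  n_sup <- round(config$frac_metab_suppressor * nm)
  n_pro <- round(config$frac_metab_promoter * nm)
  role <- sample(rep(c("suppressor", "promoter", "null"),
                     c(n_sup, n_pro, nm - n_sup - n_pro)))
  slope <- c(suppressor = -1, promoter = 1, null = 0)[role] * config$metab_slope
  unstable <- runif(nm) < config$frac_metab_unstable
  # stress-coupled metabolites sit in a lower abundance tier than the bulk
  # (signalling species, not TIC-dominating osmolytes), which keeps their
  # group-structured swing a small share of the per-sample total that the
  # correction-factor normalization divides out
  base <- rnorm(nm, mean = 5.5, sd = 0.30) - ifelse(role == "null", 0, 0.5)
  mode <- rep(c("pos", "neg"), length.out = nm)

  conc <- runif(ns, 0.8, 1.2)
  names(conc) <- design$sample
  tabs <- list()
  for (md in c("pos", "neg")) {
    keep <- mode == md
    nk <- sum(keep)
    tot_fac <- runif(ns, 0.7, 1.3)
    true_log <- outer(base[keep], rep(1, ns)) +
      outer(slope[keep], unname(z)) +
      matrix(rnorm(nk * ns, sd = 0.10), nrow = nk, ncol = ns)
    vals <- 10^true_log *
      matrix(rlnorm_cv(nk * ns, config$noise_cv), nrow = nk, ncol = ns)
    vals <- sweep(vals, 2, conc * tot_fac, "*")
    dimnames(vals) <- list(ids[keep], design$sample)
    qc_cv <- ifelse(unstable[keep], 0.5, config$noise_cv)
    qc <- matrix(NA_real_, nrow = nk, ncol = config$n_qc,
                 dimnames = list(ids[keep], paste0("QC_", seq_len(config$n_qc))))
    for (i in seq_len(nk))
      qc[i, ] <- 10^base[keep][i] * rlnorm_cv(config$n_qc, qc_cv[i])
    if (config$dropout && nk > 0) {
      p <- plogis(config$dropout_steepness * (config$dropout_midpoint - log10(vals)))
      vals[runif(length(vals)) < p] <- NA_real_
    }
    tabs[[md]] <- metabolite_table(vals, qc, conc, md)
  }
  list(tables = tabs,
       truth = data.frame(metabolite_id = ids, mode = mode, role = role,
                          slope = unname(slope), unstable = unstable,
                          base_log10 = base, stringsAsFactors = FALSE))
}
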