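---
title: "Methods: cysteine redoxome occupancy, regions and crosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cysteine redoxome occupancy, regions and crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxmap)
```

## The measurement model

redoxmap analyses multiplexed (TMT) cysteine redox proteomics in which each
tissue sample is profiled in five parallel plexes, one per redox state:
free thiol (SH), total oxidation (Sto, the TCEP-reducible pool), sulfenic
acid (SOH), S-nitrosylation (SNO) and S-glutathionylation (SSG). Every plex
carries one channel of a common reference: a pooled sample fully reduced
with TCEP, so its biotin-captured signal represents each cysteine's total
thiol content. The reference bridges plexes and batches.

Reporter intensities confound biology with per-channel loading. The
normalization chain mirrors standard practice for this design:

1. **Total-protein channel ratios.** From the unenriched aliquot of each
   channel, the summed protein abundance of the channel is divided by the
   summed abundance of the reference channel of the same plex
   (`compute_channel_ratios()`). Dividing a channel's reporter intensities
   by its ratio equalizes protein load exactly: after scaling, every
   channel's total equals the reference total by construction.
2. **Reference ratios.** Each site's channel-corrected intensity is then
   divided by the channel-corrected intensity of the same site in the same
   plex's reference channel (`normalize_redox()`), putting all plexes on a
   shared per-site scale.

### Occupancy

The occupancy (stoichiometry) of modification m on a site in a sample is

    occ_m = I_m / (I_Sto + I_SH)

the fraction of that cysteine's molecules carrying m. Two identities follow
and are enforced by tests: `occ_Sto + occ_SH = 1` wherever both terms
exist, and occupancy is invariant to multiplying all of a site-sample's
channels by a positive constant.

`compute_occupancy()` uses reference ratios rather than channel-corrected
intensities by default. The two modes give identical values when the
reference channels of the Sto and SH plexes carry the same effective
loading; when they do not (separate pipetting of the pooled reference into
each plex), only the reference-ratio mode cancels the per-plex reference
scale, so it is the default and the channel mode remains available via
`method = "channel"`. Occupancies above 1 arise from reporter noise; they
are clamped to 1 and flagged rather than dropped, preserving site coverage
while recording the anomaly. Clamping is monotone, so it never moves a site
across a region boundary.

## Bimodal regions and age transitions

Group medians are computed per site from samples of one age group, and only
where the site is quantified in at least `min_n = 3` samples of that group.
The distribution of median Sto occupancies is bimodal: a low-oxidation and
a high-oxidation population. `fit_density()` uses a Gaussian KDE
(Silverman's rule, 512-point grid on [0, 1], no boundary correction —
occupancies rarely pile up hard against 0 or 1 at these concentrations, and
the plain estimator matches how such distributions are routinely drawn).
`find_peaks_valley()` takes grid local maxima, discards baseline ripple
below 5% of the tallest peak, and pairs the tallest maximum with the
highest other maximum separated from it by a valley that dips at least 10%
below the lower of the two (`min_prominence`). Without such a pair the fit
raises a `redoxmap_unimodal_error` so callers can fall back to a fixed
boundary; a broad single mode whose KDE merely wiggles at the top is
correctly refused. The valley is the grid argmin strictly between the
peaks.

Sites at or below the valley belong to region 1 (low oxidation), above it
to region 2; a median exactly at the valley goes to region 1 (documented
tie rule — the boundary value is still "low"). The valley is fitted per
group from that group's own density, since the young and old distributions
shift; a shared boundary can be imposed by passing one group's model to
both calls. Transitions between the young and old regions (1→2: oxidation
gained with age; 2→1: lost) are counted by `count_transitions()`, with
sub-counts for sites whose absolute median change exceeds
`delta_min = 0.10` — i.e. more than 10 occupancy points, interpreting the
conventional ">10% change" as absolute occupancy difference since
occupancies are reported as percentages. Middle-aged samples inform the
trend labels but not the region models.

`modification_contribution()` attributes Sto occupancy to the measured
reversible modifications (fraction_m = occ_m / occ_Sto, capped at 1); the
residual covers states not separately measured (disulfides, SO2H/SO3H).
When noise pushes the sum of sub-fractions above 1 they are rescaled to sum
to 1 and flagged.

## Differential screens

Two rule systems, matching the two study designs:

* **Three groups** (`screen_redox_differential()`): sites detected in at
  least 3 samples of every age group get a classical one-way ANOVA
  (equal-variance F test via `oneway.test(var.equal = TRUE)`); significance
  is raw p < 0.05 with no multiplicity correction — the conventional screen
  in this literature; a BH-adjusted mode is available via `adjust = "BH"`
  but off by default. Sites failing the detection floor go to the
  presence/absence rule: differential iff at least one group has zero
  detections and every non-empty group is detected in at least half of its
  samples. The two rule sets are disjoint by construction. Trends order
  the group medians: `up_with_age` / `down_with_age` when the extremes
  disagree with the middle in between (inclusive), `up_in_M` / `down_in_M`
  when the middle group is strictly extreme; an exact old = young tie falls
  back to the middle group. For presence calls the non-empty groups define
  the direction (only-old = up with age; only-young = down; only-middle =
  up in M; young+old without middle = down in M).
* **Two groups** (`screen_two_group()`): on log2 values, a two-sided
  Student's t-test (equal variances, since that is the named test; Welch
  via `var_equal = FALSE`), significant iff p < 0.05 AND |log2 fold change|
  > 0.263 (fold change 1.2), both strict. One-sided detection (at least
  half of one group, none of the other) is differential by presence.
  Zero-variance ties give an undefined p and are flagged, not called.

"Detected" always means a non-missing positive intensity after ingest's
zero-to-missing conversion: a zero TMT reporter means the site was not
quantified in that channel, not that it was absent at abundance zero.

## Metabolite-redoxome crosstalk

Age-related metabolites are selected by the same ANOVA machinery
(raw p < 0.05). For every (differential Sto site, selected metabolite)
pair, `spearman_pairs()` computes Spearman's rho on pairwise-complete
samples with average ranks for ties; a pair is retained iff p < 0.05 AND
|rho| > 0.6, both strict. The Sto values entering the correlation are the
sites' normalized reference ratios ("Sto levels"), not occupancies —
levels are what the upstream differential screen operates on; an occupancy
mode is a one-line change since Spearman only needs monotonicity.

Two-sided p-values use the t approximation for n >= 10 complete pairs and
exact enumeration of all n! rank permutations below that (cached per n);
with the default `min_pairs = 8` floor — a conservative choice for a
24-sample design — the exact branch covers n of 8 and 9 where the t
approximation is least reliable.

`tally_features()` counts, per metabolite, the sites correlating
positively (n_pos) and negatively (n_neg). More negative than positive
partners makes a suppressor candidate (high metabolite, low oxidation),
the reverse a promoter candidate; equal counts or fewer than `min_total =
3` pairs are ambiguous. `top_k_overlap()` ranks sites per omics layer by
significant-correlation count and intersects the top-k sets; ties at the
k-th count are all included (deterministic and order-independent) and
flagged.

## Motif matrices

`extract_windows()` returns the ±10-residue window around each cysteine
(21 residues); positions beyond the protein termini are padded with `_`,
which is counted as its own symbol and excluded from enrichment
comparisons. `position_frequencies()` returns plain per-position relative
frequencies (the probability view of a sequence logo); a log-odds mode
against the cohort background is deliberately out of scope. Motif sets are
typically stratified by occupancy region; `sites_near_peak()` restricts to
sites within ±0.10 of a density peak for peak-centred motif sets.

## The synthetic cohort generator

`generate_cohort()` emulates the study design so every stage is testable
without raw MS data: 3 age groups × 2 colon locations × 4 animals (24
samples), five redox-state plexes plus reference, a proteinGroups-like
channel quantification, a peptide table for the proteome workflow, two
ion-mode metabolite tables with QC replicates, and protein sequences.
Ground truth for every site and metabolite is returned alongside.

Key defaults and why:

* **True occupancy**: a two-component Beta mixture parameterized by mode
  and concentration (modes 0.25 / 0.85, concentration 18, low-mode weight
  0.6) — peaks near the positions seen in primate colon without copying
  any dataset, with realistic spread.
* **Planted age effects**: 5% of sites shift up and 2% down by ±0.15
  occupancy in the extreme groups (middle intermediate), monotone in age.
  A further 5% of sites are driven by a per-sample latent stress factor
  (group mean increasing with age plus N(0, 0.5) individual variation),
  which also drives coupled metabolites — this shared factor is what makes
  metabolite-site correlations exist at all.
* **Reporter model**: site intensity T log-normal (median 1e6, 0.5 decades
  SD); state channels carry T·θ, T·(1−θ) and T·θ·c_m with per-site
  sub-fractions c_SSG ∈ (0.3, 0.6) > c_SOH, c_SNO ∈ (0.05, 0.2), so SSG
  dominates the reversible pool as observed in tissue; multiplicative
  log-normal noise with CV 0.2 (reporter-ion noise magnitudes are not
  published for this design; the CV is exposed in the configuration);
  per-channel loading multipliers in (0.7, 1.4).
* **Dropout** is logistic in log10 intensity (midpoint 4.2, steepness
  1.5): missing-not-at-random low-abundance loss, reproducing the observed
  ordering of state coverage (SH/Sto nearly complete, SSG high, SOH
  partial, SNO sparse) and giving the presence/absence rule structured
  missingness to detect.
* **Metabolites**: 8% suppressors and 8% promoters with log10 slope ∓0.4
  on the latent factor (site-metabolite |rho| ≈ 0.7 under the default
  noise), drawn from an abundance tier about 3-fold below the bulk.
  The tiering matters: the correction-factor normalization divides each
  sample by its total intensity, and if strongly age-coupled metabolites
  dominated that total, their group shift would be transferred with
  opposite sign onto every null metabolite — an artifact real data mostly
  avoids because age-responsive species are a minor share of the total ion
  current. 5% of metabolites get QC CV ≈ 0.5 so the CV filter has true
  positives.
* **Sequences**: random 20-letter backbones with C at each site position
  and a planted lysine enrichment (probability 0.4) at position −1 of
  low-occupancy-component sites, giving the motif module a known signal.
* **Streams**: each output block (sites, sequences, proteins, peptides,
  metabolites, loading, noise, dropout) draws from its own RNG stream
  derived from the master seed, so disabling one block never shifts
  another — and the whole cohort is a pure function of its configuration.

What the generator does **not** emulate: spectrum-level effects (isotope
impurity between TMT channels, co-isolation interference), retention-time
drift, correlated sites within one protein, peptide-level missingness
shared across states, or RNA-seq. Passing tests therefore demonstrate that
the statistical machinery is correct under the stated model, not that the
pipeline is robust to every artifact of real acquisitions.

## Numerical choices and degenerate inputs

* Localization-probability filtering is strict (> 0.75), matching the
  convention "probabilities greater than 0.75"; the threshold is exposed.
* `I_Sto + I_SH = 0` yields missing occupancy with a warning; constant
  density inputs and too-few values (< 50 by default) are errors rather
  than silent degenerate fits.
* Proteome totals are equalized to the mean of per-sample totals (the
  target level is unspecified in the field's descriptions; the mean is the
  least-surprising choice and is configurable).
* QC correlations require 3 pairwise-complete observations; constant
  columns give missing correlations with a warning.
* All thresholds are strict inequalities where the convention prints one
  (p < 0.05, |rho| > 0.6, fold change > 1.2, Δ > 10%).

## Problem sizes in the test suite

The packaged tests run the default cohort (3000 sites, 24 samples), a
10,000-site brute-force transition oracle, a null cohort (~2400 testable
sites) for ANOVA calibration, 1200-site cohorts across three effect sizes
for the power curve, and reduced cohorts (400-600 sites) for I/O, motif
and pipeline determinism checks — sizes chosen so the full suite exercises
every stage at statistically meaningful scale while staying quick enough
to run on every change.

## Known limitations

* The ANOVA/t-test screens assume approximately normal within-group
  values; occupancies near 0 or 1 are bounded and heteroskedastic, and no
  variance-stabilizing transform is applied (the screens mirror the
  field's convention rather than improve on it).
* Raw p-values without multiplicity correction overstate confidence for
  any single site; the screens are enrichment filters, not inference.
* The valley boundary is a point estimate; sites near it flip regions
  under resampling, which is why transition counts are paired with the
  Δ > 10% sub-counts.
* Channel-ratio normalization assumes the unenriched aliquot quantifies
  the same load as the enriched one; systematic enrichment-efficiency
  differences per channel are not modelled.
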