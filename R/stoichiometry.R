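# Stoichiometry: per-site redox-state occupancies, group medians, bimodal
# density region models, valley-based region assignment, age transitions
# with the >10% occupancy-change filter, and sub-modification contributions.

#' Per-site redox-state occupancies
#'
#' The occupancy (stoichiometry) of a modification m on a site in a sample
#' is I_m / (I_Sto + I_SH): the modified fraction of that cysteine's
#' molecules. By construction occ(Sto) + occ(SH) = 1 wherever both terms
#' are defined, and the value is invariant to rescaling all of a
#' site-sample's channels by a positive constant.
#'
#' Intensities enter as reference ratios (each site's channel-corrected
#' intensity relative to the same site in the plex's common reference),
#' which puts the five state plexes on a shared per-site scale; the
#' channel-corrected intensities can be used instead via
#' \code{method = "channel"} (the two agree exactly when the reference
#' channels of the Sto and SH plexes carry identical effective loadings).
#'
#' @param norm a \code{\link{normalize_redox}} result.
#' @param clamp clamp occupancies > 1 to 1 (raw values are retained in the
#'   \code{raw} element and flagged).
#' @param method \code{"reference_ratio"} (default) or \code{"channel"}.
#' @return Object of class \code{"occupancy_table"}: list with \code{occ}
#'   (per-state sites x samples matrices), \code{raw} (unclamped),
#'   \code{clamped} (logical matrices) and \code{annotation}.
#' @export
compute_occupancy <- function(norm, clamp = TRUE,
                              method = c("reference_ratio", "channel")) {
  stopifnot(inherits(norm, "normalized_redox"))
  method <- match.arg(method)
  samples <- attr(norm, "samples")
  vals <- if (method == "reference_ratio") norm$ref_ratio
          else lapply(norm$normalized, function(m) m[, samples, drop = FALSE])
  if (is.null(vals$Sto) || is.null(vals$SH))
    stop_schema("occupancy needs both 'Sto' and 'SH' states")
  denom <- vals$Sto + vals$SH
  zero_denom <- !is.na(denom) & denom == 0
  if (any(zero_denom)) {
    warning(sprintf("%d site-sample(s) with I_Sto + I_SH = 0 set to missing",
                    sum(zero_denom)))
    denom[zero_denom] <- NA_real_
  }
  occ <- list()
  raw <- list()
  clamped <- list()
  for (st in names(vals)) {
    r <- vals[[st]] / denom
    raw[[st]] <- r
    cl <- !is.na(r) & r > 1
    if (clamp) r[cl] <- 1
    occ[[st]] <- r
    clamped[[st]] <- cl
  }
  structure(list(annotation = norm$annotation, occ = occ, raw = raw,
                 clamped = clamped),
            samples = samples, method = method, class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat(sprintf("occupancy_table: %d sites, states [%s], %d samples (%s)\n",
              nrow(x$annotation), paste(names(x$occ), collapse = ", "),
              length(attr(x, "samples")), attr(x, "method")))
  invisible(x)
}

#' Group-median occupancy per site
#'
#' Sites quantified in at least \code{min_n} samples of a group get that
#' group's median occupancy; otherwise the median is missing there.
#'
#' @param mat sites x samples occupancy (or abundance) matrix.
#' @param design design data.frame with \code{sample} and \code{group}
#'   columns covering every column of \code{mat}.
#' @param min_n minimum quantified samples per group (default 3).
#' @return list with \code{median} and \code{n} (sites x groups matrices).
#' @export
group_median_occupancy <- function(mat, design, min_n = 3) {
  unknown <- setdiff(colnames(mat), design$sample)
  if (length(unknown) > 0)
    stop_schema(paste0("sample(s) not in design: ", paste(unknown, collapse = ", ")))
  design <- design[match(colnames(mat), design$sample), , drop = FALSE]
  groups <- if (is.factor(design$group)) levels(droplevels(design$group))
            else unique(design$group)
  med <- matrix(NA_real_, nrow = nrow(mat), ncol = length(groups),
                dimnames = list(rownames(mat), groups))
  nq <- med
  for (g in groups) {
    sub <- mat[, design$group == g, drop = FALSE]
    n <- rowSums(!is.na(sub))
    m <- apply(sub, 1, median, na.rm = TRUE)
    m[n < min_n] <- NA_real_
    med[, g] <- m
    nq[, g] <- n
  }
  list(median = med, n = nq)
}

#' Kernel density of an occupancy collection on [0, 1]
#'
#' Gaussian KDE (Silverman's rule by default) evaluated on an even grid
#' over the unit interval.
#'
#' @param values numeric occupancies (NAs dropped).
#' @param bw bandwidth rule or numeric bandwidth (see
#'   \code{\link[stats]{density}}).
#' @param n_grid grid size (default 512).
#' @param min_values minimum number of values required (default 50).
#' @return list of class \code{"occupancy_density"} with \code{x},
#'   \code{y}, \code{bw}, \code{n}.
#' @export
fit_density <- function(values, bw = "nrd0", n_grid = 512, min_values = 50) {
  values <- values[!is.na(values)]
  if (length(values) < min_values)
    stop_schema(sprintf(
      "only %d occupancy values (< %d); pool groups or locations before fitting",
      length(values), min_values))
  if (length(unique(values)) == 1)
    stop_schema("constant occupancy values: density is a degenerate spike")
  d <- density(values, bw = bw, n = n_grid, from = 0, to = 1)
  structure(list(x = d$x, y = d$y, bw = d$bw, n = length(values)),
            class = "occupancy_density")
}

#' Locate the two density peaks and the valley between them
#'
#' Local maxima are located on the grid; maxima whose density falls below
#' \code{min_peak_frac} of the global maximum are discarded as baseline
#' ripple. The two remaining maxima with the highest density are the
#' peaks, and the valley is the grid argmin strictly between them; the
#' valley must dip below both peaks. A density without two such peaks
#' raises a condition of class \code{"redoxmap_unimodal_error"} so callers
#' can fall back to a fixed boundary.
#'
#' @param dens a \code{\link{fit_density}} result.
#' @param min_peak_frac minimum height of a candidate peak as a fraction
#'   of the tallest peak (default 0.05).
#' @param min_prominence minimum relative dip of the valley below the
#'   lower of the two peaks (default 0.1); separates true bimodality from
#'   sampling ripple on a broad single peak.
#' @return Object of class \code{"region_model"}: list with \code{peaks}
#'   (increasing positions), \code{peak_density}, \code{valley},
#'   \code{valley_density}, \code{bw}.
#' @export
find_peaks_valley <- function(dens, min_peak_frac = 0.05,
                              min_prominence = 0.1) {
  stopifnot(inherits(dens, "occupancy_density"))
  y <- dens$y
  x <- dens$x
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  # grid-edge modes count too (mass piled at 0 or 1)
  if (y[1] > y[2]) is_max[1] <- TRUE
  if (y[n] > y[n - 1]) is_max[n] <- TRUE
  idx <- which(is_max & y >= min_peak_frac * max(y))
  if (length(idx) < 2)
    stop_unimodal(sprintf("density has %d substantial maximum(s); two peaks required",
                          length(idx)))
  # pair the tallest maximum with the highest other maximum from which it
  # is separated by a prominent dip; ripples on one broad mode fail this
  idx <- idx[order(y[idx], decreasing = TRUE)]
  first <- idx[1]
  top <- NULL
  for (j in idx[-1]) {
    lo <- min(first, j); hi <- max(first, j)
    between <- (lo + 1):(hi - 1)
    v <- between[which.min(y[between])]
    if (y[v] < (1 - min_prominence) * min(y[first], y[j])) {
      top <- c(lo, hi)
      break
    }
  }
  if (is.null(top))
    stop_unimodal("no prominent valley between density maxima; distribution is unimodal")
  between <- (top[1] + 1):(top[2] - 1)
  v <- between[which.min(y[between])]
  structure(list(peaks = x[top], peak_density = y[top],
                 valley = x[v], valley_density = y[v], bw = dens$bw),
            class = "region_model")
}

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf("region_model: peaks at %.3f / %.3f, valley at %.3f (bw %.4f)\n",
              x$peaks[1], x$peaks[2], x$valley, x$bw))
  invisible(x)
}

#' Fit a per-group region model
#'
#' @param medians named numeric vector of group-median occupancies.
#' @param ... passed to \code{\link{fit_density}}.
#' @return A \code{region_model}.
#' @export
fit_region_model <- function(medians, ...) {
  find_peaks_valley(fit_density(medians, ...))
}

#' Assign sites to occupancy regions at the valley boundary
#'
#' Sites with median occupancy below the valley go to region 1 (low
#' oxidation), above it to region 2 (high oxidation); a median exactly at
#' the valley goes to region 1 (documented tie rule).
#'
#' @param medians named numeric vector of group-median occupancies.
#' @param model a \code{region_model} for the same group.
#' @param prefix label prefix (e.g. \code{"Y"} or \code{"O"}).
#' @return Named character vector of labels (\code{NA} where the median is
#'   missing) with attribute \code{"region"} (integer 1/2).
#' @export
assign_regions <- function(medians, model, prefix = "R") {
  if (!inherits(model, "region_model")) stop_schema("missing or invalid region model")
  region <- ifelse(is.na(medians), NA_integer_,
                   ifelse(medians <= model$valley, 1L, 2L))
  labels <- ifelse(is.na(region), NA_character_, paste0(prefix, region))
  names(labels) <- names(medians)
  attr(labels, "region") <- region
  labels
}

#' Count region transitions between two groups
#'
#' Counts sites moving from the low region of the first group to the high
#' region of the second (1 -> 2, oxidation gain) and the reverse (2 -> 1),
#' plus the sub-counts whose absolute median occupancy change exceeds
#' \code{delta_min} (strict).
#'
#' @param median_a,median_b named group-median vectors for the two groups
#'   (e.g. young and old) over the same site universe.
#' @param region_a,region_b integer region assignments (1/2) for the two
#'   groups (as from \code{attr(assign_regions(...), "region")}).
#' @param delta_min occupancy-change threshold (default 0.10 = 10 points).
#' @return Object of class \code{"transition_report"}: counts, site ids and
#'   per-site delta (b - a) for both directions.
#' @export
count_transitions <- function(median_a, region_a, median_b, region_b,
                              delta_min = 0.10) {
  sites <- intersect(names(median_a), names(median_b))
  ok <- sites[!is.na(region_a[sites]) & !is.na(region_b[sites]) &
                !is.na(median_a[sites]) & !is.na(median_b[sites])]
  delta <- median_b[ok] - median_a[ok]
  up <- ok[region_a[ok] == 1L & region_b[ok] == 2L]
  down <- ok[region_a[ok] == 2L & region_b[ok] == 1L]
  structure(list(
    n_low_to_high = length(up),
    n_high_to_low = length(down),
    n_low_to_high_delta = sum(abs(delta[up]) > delta_min),
    n_high_to_low_delta = sum(abs(delta[down]) > delta_min),
    low_to_high = up, high_to_low = down,
    delta = delta, delta_min = delta_min, n_compared = length(ok)),
    class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf(paste0("transition_report: %d sites compared; 1->2: %d (%d with ",
                     "|delta| > %.2f); 2->1: %d (%d)\n"),
              x$n_compared, x$n_low_to_high, x$n_low_to_high_delta, x$delta_min,
              x$n_high_to_low, x$n_high_to_low_delta))
  invisible(x)
}

#' Contribution of SSG/SOH/SNO to total oxidation
#'
#' For each site the fraction of Sto occupancy attributed to each measured
#' reversible modification: fraction_m = occ_m / occ_Sto, capped at 1. The
#' residual max(0, 1 - sum) covers oxidation states not separately
#' measured (disulfide, SO2H/SO3H). When noise makes the sub-occupancies
#' sum above the Sto occupancy the fractions are rescaled to sum to 1 and
#' flagged.
#'
#' @param sto named vector of Sto occupancies (group medians).
#' @param ssg,soh,sno matching vectors of sub-modification occupancies
#'   (NA = not quantified).
#' @return data.frame with columns \code{site_id}, \code{SSG}, \code{SOH},
#'   \code{SNO}, \code{residual}, \code{rescaled}.
#' @export
modification_contribution <- function(sto, ssg, soh, sno) {
  sites <- names(sto)
  f <- cbind(SSG = ssg[sites] / sto, SOH = soh[sites] / sto,
             SNO = sno[sites] / sto)
  f[!is.na(f) & f > 1] <- 1
  f[is.na(sto) | sto == 0, ] <- NA_real_
  tot <- rowSums(f, na.rm = TRUE)
  tot[rowSums(!is.na(f)) == 0] <- NA_real_
  rescaled <- !is.na(tot) & tot > 1
  f[rescaled, ] <- f[rescaled, , drop = FALSE] / tot[rescaled]
  residual <- pmax(0, 1 - pmin(tot, 1))
  data.frame(site_id = sites, SSG = unname(f[, "SSG"]), SOH = unname(f[, "SOH"]),
             SNO = unname(f[, "SNO"]), residual = unname(residual),
             rescaled = unname(rescaled),
             row.names = NULL, stringsAsFactors = FALSE)
}
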