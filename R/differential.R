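# Differential screening: three-group one-way ANOVA with presence/absence
# fallback (primate ageing design) and two-group t-test + fold-change with
# its own presence rule (intervention designs), plus trend classification.

#' One-way ANOVA screen across age groups
#'
#' Sites detected in at least \code{min_n} samples of every group are
#' tested with a classical one-way ANOVA; they are called differential iff
#' the raw p-value is below \code{alpha} (no multiplicity correction — the
#' conventional screen in this field uses raw p < 0.05; set
#' \code{adjust = "BH"} for an FDR-adjusted call). Sites failing the
#' detection requirement are not tested here; their ids are attached as
#' attribute \code{"presence_candidates"} for the presence/absence screen.
#'
#' @param mat sites x samples value matrix (occupancies or normalized
#'   abundances; NA = not detected).
#' @param design design data.frame with \code{sample} and \code{group}.
#' @param alpha significance level on the (possibly adjusted) p-value.
#' @param min_n minimum detections per group for testability (default 3).
#' @param adjust \code{"none"} (default) or a \code{\link[stats]{p.adjust}}
#'   method applied across tested sites.
#' @return data.frame (rule \code{"anova"}): one row per tested site with
#'   per-group detection counts, group medians, \code{p_value},
#'   \code{significant} and \code{trend}.
#' @export
screen_anova <- function(mat, design, alpha = 0.05, min_n = 3,
                         adjust = "none") {
  design <- design[match(colnames(mat), design$sample), , drop = FALSE]
  if (anyNA(design$sample))
    stop_schema("matrix has samples missing from the design")
  groups <- if (is.factor(design$group)) levels(droplevels(design$group))
            else unique(as.character(design$group))
  if (length(groups) < 3)
    stop_schema("ANOVA screen needs >= 3 groups; use screen_two_group for two")
  g <- factor(as.character(design$group), levels = groups)

  det <- sapply(groups, function(gr)
    rowSums(!is.na(mat[, g == gr, drop = FALSE])))
  det <- matrix(det, nrow = nrow(mat), dimnames = list(rownames(mat), groups))
  testable <- rowSums(det >= min_n) == length(groups)

  meds <- sapply(groups, function(gr)
    apply(mat[, g == gr, drop = FALSE], 1, median, na.rm = TRUE))
  meds <- matrix(meds, nrow = nrow(mat), dimnames = list(rownames(mat), groups))

  idx <- which(testable)
  pvals <- vapply(idx, function(i) {
    v <- mat[i, ]
    ok <- !is.na(v)
    out <- tryCatch(
      oneway.test(v[ok] ~ g[ok], var.equal = TRUE)$p.value,
      error = function(e) NA_real_)
    # zero within- and between-group variance: no evidence of difference
    if (is.nan(out) || is.na(out)) out <- 1
    out
  }, numeric(1))
  padj <- if (identical(adjust, "none")) pvals else p.adjust(pvals, method = adjust)

  res <- data.frame(site_id = rownames(mat)[idx], rule = "anova",
                    p_value = pvals, p_adjusted = padj,
                    significant = padj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$trend <- NA_character_
  if (nrow(res) > 0 && length(groups) == 3) {
    m <- meds[idx, , drop = FALSE]
    res$trend <- classify_trend(m[, 1], m[, 2], m[, 3])
    res$trend[!res$significant] <- NA_character_
  }
  for (gr in groups) {
    res[[paste0("n_", gr)]] <- det[idx, gr]
    res[[paste0("median_", gr)]] <- meds[idx, gr]
  }
  attr(res, "presence_candidates") <- rownames(mat)[!testable]
  attr(res, "detections") <- det
  attr(res, "groups") <- groups
  res
}

#' Presence/absence differential screen
#'
#' A site undetected in one or two of the three groups but detected in at
#' least \code{min_frac} of the samples of every remaining group is called
#' differential; the set of non-empty groups determines the trend. By
#' construction this rule is disjoint from the ANOVA rule: any ANOVA-
#' testable site has detections in every group.
#'
#' @param det sites x groups detection-count matrix (columns ordered
#'   young, middle, old).
#' @param n_per_group named count of samples per group.
#' @param min_frac minimum detected fraction in non-empty groups
#'   (default 0.5, inclusive: "at least half").
#' @return data.frame (rule \code{"presence"}): per-site detection counts,
#'   \code{significant} and \code{trend}.
#' @export
screen_presence <- function(det, n_per_group, min_frac = 0.5) {
  groups <- colnames(det)
  n_per_group <- n_per_group[groups]
  if (nrow(det) == 0) {
    res0 <- data.frame(site_id = character(0), rule = character(0),
                       p_value = numeric(0), significant = logical(0),
                       trend = character(0), stringsAsFactors = FALSE)
    for (gr in groups) res0[[paste0("n_", gr)]] <- integer(0)
    return(res0)
  }
  empty <- det == 0
  n_empty <- rowSums(empty)
  full_enough <- det >= matrix(rep(ceiling(min_frac * n_per_group),
                                   each = nrow(det)), nrow = nrow(det))
  ok_nonempty <- rowSums(!empty & full_enough) == (length(groups) - n_empty)
  significant <- n_empty >= 1 & n_empty < length(groups) & ok_nonempty

  trend <- rep(NA_character_, nrow(det))
  if (length(groups) == 3) {
    pat <- paste0(as.integer(!empty[, 1]), as.integer(!empty[, 2]),
                  as.integer(!empty[, 3]))
    # non-empty groups define the direction (Y, M, O order)
    map <- c("001" = "up_with_age", "011" = "up_with_age",
             "100" = "down_with_age", "110" = "down_with_age",
             "010" = "up_in_M", "101" = "down_in_M")
    trend <- unname(map[pat])
  }
  trend[!significant] <- NA_character_
  res <- data.frame(site_id = rownames(det), rule = "presence",
                    p_value = NA_real_, significant = significant,
                    trend = trend, stringsAsFactors = FALSE, row.names = NULL)
  for (gr in groups) res[[paste0("n_", gr)]] <- det[, gr]
  res
}

#' Classify the age trend of three ordered group medians
#'
#' \code{up_with_age} if old > young with middle in between (inclusive);
#' \code{down_with_age} if old < young with middle in between;
#' \code{up_in_M} / \code{down_in_M} if the middle group is strictly the
#' largest / smallest. Exact O = Y ties fall back to comparing the middle
#' group (tie rule: O vs Y first, then M).
#'
#' @param y,m,o group medians (young, middle, old); vectorized.
#' @return character vector of trend labels (\code{NA} where fewer than two
#'   medians are available).
#' @export
classify_trend <- function(y, m, o) {
  n <- max(length(y), length(m), length(o))
  y <- rep_len(y, n); m <- rep_len(m, n); o <- rep_len(o, n)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    have <- c(!is.na(y[i]), !is.na(m[i]), !is.na(o[i]))
    if (sum(have) < 2) next
    yi <- y[i]; mi <- m[i]; oi <- o[i]
    if (is.na(mi)) {
      out[i] <- if (oi >= yi) "up_with_age" else "down_with_age"
    } else if (is.na(yi)) {
      out[i] <- if (oi >= mi) "up_with_age" else "down_with_age"
    } else if (is.na(oi)) {
      out[i] <- if (mi >= yi) "up_with_age" else "down_with_age"
    } else if (mi > yi && mi > oi) {
      out[i] <- "up_in_M"
    } else if (mi < yi && mi < oi) {
      out[i] <- "down_in_M"
    } else if (oi > yi) {
      out[i] <- "up_with_age"
    } else if (oi < yi) {
      out[i] <- "down_with_age"
    } else {
      # O = Y exactly: middle decides
      out[i] <- if (mi >= yi) "up_in_M" else "down_in_M"
    }
  }
  out
}

#' Combined three-group differential screen
#'
#' Runs \code{\link{screen_anova}} and forwards the untestable sites to
#' \code{\link{screen_presence}}; the two rule sets are disjoint.
#'
#' @inheritParams screen_anova
#' @param min_frac presence-rule detection fraction.
#' @return data.frame with both rules stacked.
#' @export
screen_redox_differential <- function(mat, design, alpha = 0.05, min_n = 3,
                                      min_frac = 0.5, adjust = "none") {
  an <- screen_anova(mat, design, alpha = alpha, min_n = min_n, adjust = adjust)
  det <- attr(an, "detections")
  cand <- attr(an, "presence_candidates")
  npg <- table(design$group)[attr(an, "groups")]
  pr <- screen_presence(det[cand, , drop = FALSE],
                        setNames(as.numeric(npg), names(npg)),
                        min_frac = min_frac)
  cols <- intersect(names(an), names(pr))
  out <- rbind(an[, cols, drop = FALSE], pr[, cols, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Two-group t-test + fold-change screen
#'
#' For sites detected in at least \code{min_n} samples of both groups a
#' two-sided Student's t-test (equal variances; Welch via
#' \code{var_equal = FALSE}) is applied to the log2 values; the site is
#' differential iff p < \code{alpha} AND |log2 fold change| >
#' \code{min_abs_log2fc} (both strict; 0.263 corresponds to a 1.2-fold
#' change). Sites detected in at least \code{min_frac} of one group and in
#' none of the other are differential by presence
#' (rule \code{"two_group_presence"}).
#'
#' @param mat sites x samples matrix of log2-transformed values.
#' @param group factor/character of length ncol(mat) with exactly two
#'   levels; fold change is level2 - level1.
#' @param alpha p-value threshold.
#' @param min_abs_log2fc fold-change threshold on |log2FC| (strict).
#' @param min_n minimum detections per group for the t-test.
#' @param min_frac presence-rule detection fraction.
#' @param var_equal classical Student's t-test (TRUE, default) or Welch.
#' @return data.frame: per site \code{rule}, \code{p_value},
#'   \code{log2_fold_change}, \code{significant}, \code{trend}
#'   (\code{"up"}/\code{"down"}), detection counts.
#' @export
screen_two_group <- function(mat, group, alpha = 0.05, min_abs_log2fc = 0.263,
                             min_n = 3, min_frac = 0.5, var_equal = TRUE) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2)
    stop_schema("screen_two_group needs exactly two groups")
  ga <- levels(group)[1]; gb <- levels(group)[2]
  a <- mat[, group == ga, drop = FALSE]
  b <- mat[, group == gb, drop = FALSE]
  na_ <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  n_a_tot <- ncol(a); n_b_tot <- ncol(b)

  testable <- na_ >= min_n & nb >= min_n
  pres_b <- na_ == 0 & nb >= ceiling(min_frac * n_b_tot)
  pres_a <- nb == 0 & na_ >= ceiling(min_frac * n_a_tot)

  res <- data.frame(site_id = rownames(mat),
                    rule = NA_character_, p_value = NA_real_,
                    log2_fold_change = NA_real_, significant = FALSE,
                    trend = NA_character_,
                    n_group1 = na_, n_group2 = nb,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in which(testable)) {
    va <- a[i, ][!is.na(a[i, ])]
    vb <- b[i, ][!is.na(b[i, ])]
    fc <- mean(vb) - mean(va)
    p <- tryCatch(t.test(vb, va, var.equal = var_equal)$p.value,
                  error = function(e) NA_real_)
    res$rule[i] <- "two_group"
    res$p_value[i] <- p
    res$log2_fold_change[i] <- fc
    res$significant[i] <- !is.na(p) && p < alpha && abs(fc) > min_abs_log2fc
    if (res$significant[i]) res$trend[i] <- if (fc > 0) "up" else "down"
  }
  pres <- pres_a | pres_b
  res$rule[pres] <- "two_group_presence"
  res$significant[pres] <- TRUE
  res$trend[pres_b] <- "up"
  res$trend[pres_a] <- "down"
  attr(res, "groups") <- c(ga, gb)
  res
}
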