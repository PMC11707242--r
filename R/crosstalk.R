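# Metabolite-redoxome crosstalk: age-related feature selection, site x
# feature Spearman correlation pairs with significance filtering, signed
# tallies with suppressor/promoter calls, and top-k multi-omics overlap.

#' Select age-related features by one-way ANOVA
#'
#' @param mat features x samples matrix.
#' @param design design with \code{sample} and \code{group} (3 groups).
#' @param alpha raw p-value threshold (default 0.05).
#' @param min_n minimum detections per group for testability.
#' @return Character vector of feature ids with ANOVA p < alpha; the full
#'   screen table is attached as attribute \code{"screen"}.
#' @export
select_age_related_features <- function(mat, design, alpha = 0.05, min_n = 3) {
  res <- screen_anova(mat, design, alpha = alpha, min_n = min_n)
  out <- res$site_id[res$significant]
  attr(out, "screen") <- res
  out
}

# exact permutation null of Spearman's rho for small n (cached per n):
# all n! permutations of one rank vector against 1..n
perm_rho_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    block <- sub
    block[block >= k] <- block[block >= k] + 1L
    rows <- ((k - 1L) * nrow(sub) + 1L):(k * nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- block
  }
  out
}

spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  key <- as.character(n)
  if (is.null(perm_rho_cache[[key]]))
    perm_rho_cache[[key]] <- all_permutations(n)
  perms <- perm_rho_cache[[key]]
  # rho against every permutation of ry's ordering
  ry_perm <- matrix(ry[perms], nrow = nrow(perms))
  rho_null <- as.numeric(cor(rx, t(ry_perm)))
  rho_obs <- cor(rx, ry)
  mean(abs(rho_null) >= abs(rho_obs) - 1e-12)
}

# Spearman rho (average ranks) with two-sided p: t approximation for
# n >= 10, exact permutation enumeration below that
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(c(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (sd(rx) == 0 || sd(ry) == 0) return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rx, ry)
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  } else {
    p <- spearman_exact_p(rx, ry)
  }
  c(rho = rho, p = p, n = n)
}

#' Site-feature Spearman correlation pairs
#'
#' Computes Spearman's rho (average ranks for ties) between every site row
#' and every feature row over shared samples, keeping pairs with at least
#' \code{min_pairs} complete observations that satisfy p < \code{p_max}
#' AND |rho| > \code{rho_min} (both strict). Two-sided p-values use the t
#' approximation for n >= 10 and exact permutation enumeration below that.
#'
#' @param sto sites x samples matrix of Sto levels (normalized reference
#'   ratios, or occupancies).
#' @param features features x samples matrix (e.g. metabolites).
#' @param p_max p-value threshold (strict <).
#' @param rho_min |rho| threshold (strict >).
#' @param min_pairs minimum complete observations per pair (default 8).
#' @return data.frame of retained pairs: \code{site_id},
#'   \code{feature_id}, \code{rho}, \code{p_value}, \code{n_pairs}; the
#'   number of evaluated pairs is attached as attribute \code{"n_tested"}.
#' @export
spearman_pairs <- function(sto, features, p_max = 0.05, rho_min = 0.6,
                           min_pairs = 8) {
  shared <- intersect(colnames(sto), colnames(features))
  if (length(shared) == 0) stop_schema("no shared samples between matrices")
  sto <- sto[, shared, drop = FALSE]
  features <- features[, shared, drop = FALSE]
  out <- vector("list", nrow(features))
  n_tested <- 0L
  for (j in seq_len(nrow(features))) {
    fv <- features[j, ]
    hits <- list()
    for (i in seq_len(nrow(sto))) {
      r <- spearman_test(sto[i, ], fv)
      if (is.na(r["rho"]) || r["n"] < min_pairs) next
      n_tested <- n_tested + 1L
      if (r["p"] < p_max && abs(r["rho"]) > rho_min)
        hits[[length(hits) + 1L]] <-
          data.frame(site_id = rownames(sto)[i],
                     feature_id = rownames(features)[j],
                     rho = unname(r["rho"]), p_value = unname(r["p"]),
                     n_pairs = unname(r["n"]), stringsAsFactors = FALSE)
    }
    if (length(hits) > 0) out[[j]] <- do.call(rbind, hits)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(site_id = character(0), feature_id = character(0),
                      rho = numeric(0), p_value = numeric(0),
                      n_pairs = integer(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  res
}

#' Tally signed correlations per feature and call its direction
#'
#' Counts, per feature, the sites whose Sto levels correlate positively
#' (n_pos) and negatively (n_neg) with it. A feature with more negative
#' than positive partners is a suppressor candidate (high levels go with
#' low oxidation), the reverse a promoter candidate; equal counts or fewer
#' than \code{min_total} total pairs are ambiguous.
#'
#' @param pairs a \code{\link{spearman_pairs}} result.
#' @param min_total minimum significant pairs for a directional call.
#' @return data.frame: \code{feature_id}, \code{n_pos}, \code{n_neg},
#'   \code{direction_score} = (n_neg - n_pos)/(n_neg + n_pos), \code{call}.
#' @export
tally_features <- function(pairs, min_total = 3) {
  if (nrow(pairs) == 0)
    return(data.frame(feature_id = character(0), n_pos = integer(0),
                      n_neg = integer(0), direction_score = numeric(0),
                      call = character(0), stringsAsFactors = FALSE))
  pos <- tapply(pairs$rho > 0, pairs$feature_id, sum)
  neg <- tapply(pairs$rho < 0, pairs$feature_id, sum)
  ids <- names(pos)
  n_pos <- as.integer(pos); n_neg <- as.integer(neg)
  score <- (n_neg - n_pos) / (n_neg + n_pos)
  call <- ifelse(n_pos + n_neg < min_total | n_neg == n_pos, "ambiguous",
                 ifelse(n_neg > n_pos, "suppressor_candidate",
                        "promoter_candidate"))
  data.frame(feature_id = ids, n_pos = n_pos, n_neg = n_neg,
             direction_score = score, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-k overlap of correlation-rich sites across omics layers
#'
#' Per omics layer, sites are ranked by their significant-correlation
#' count (descending) and the top k taken; sites tied with the k-th count
#' are all included (deterministic, order-independent) and flagged. The
#' result is the intersection across layers.
#'
#' @param counts named list of named count vectors (one per omics layer)
#'   over a shared site universe.
#' @param k top-list size (default 50).
#' @return Character vector of intersecting site ids; per-layer top sets as
#'   attribute \code{"top_sets"}, tie flag as attribute \code{"ties"}.
#' @export
top_k_overlap <- function(counts, k = 50) {
  if (length(counts) < 2) stop_schema("need >= 2 omics count vectors")
  universe <- Reduce(union, lapply(counts, names))
  ties <- logical(length(counts))
  tops <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    v <- counts[[i]][universe]
    v[is.na(v)] <- 0
    names(v) <- universe
    if (k >= length(v)) {
      warning(sprintf("k = %d >= universe size %d; using whole universe", k,
                      length(v)))
      tops[[i]] <- names(v)
      next
    }
    cutoff <- sort(v, decreasing = TRUE)[k]
    sel <- names(v)[v >= cutoff]
    ties[i] <- length(sel) > k
    tops[[i]] <- sel
  }
  names(tops) <- names(counts)
  out <- Reduce(intersect, tops)
  attr(out, "top_sets") <- tops
  attr(out, "ties") <- ties
  out
}
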