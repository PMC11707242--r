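# Crosstalk: age-related feature selection, Spearman pair filtering with a
# brute-force oracle, signed tallies, top-k overlap.

avg_rank <- function(v) {
  r <- rank(v)  # not used in oracle; see explicit version below
  r
}

# explicit average-rank + product-moment oracle, independent of the
# implementation's rank()/cor() path
oracle_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  rk <- function(v) {
    o <- order(v)
    r <- numeric(length(v)); r[o] <- seq_along(v)
    for (val in unique(v)) r[v == val] <- mean(r[v == val])
    r
  }
  rx <- rk(x); ry <- rk(y)
  am <- rx - mean(rx); bm <- ry - mean(ry)
  list(rho = sum(am * bm) / sqrt(sum(am^2) * sum(bm^2)), n = length(x))
}

test_that("age-related selection keeps shifted features, drops flat ones", {
  design <- data.frame(sample = paste0("s", 1:12),
                       group = factor(rep(c("young", "middle", "old"),
                                          each = 4),
                                      levels = c("young", "middle", "old")))
  set.seed(41)
  mat <- rbind(flat = rep(5, 12),
               shifted = rep(c(1, 2, 3), each = 4) + rnorm(12, sd = 0.1),
               noisy = rnorm(12))
  colnames(mat) <- design$sample
  sel <- select_age_related_features(mat, design, alpha = 0.05)
  expect_true("shifted" %in% sel)
  expect_false("flat" %in% sel)
  # alpha = 1 admits every feature with p < 1 (a perfectly flat feature has
  # the degenerate p = 1 and stays out under the strict inequality)
  expect_setequal(select_age_related_features(mat, design, alpha = 1),
                  c("shifted", "noisy"))
  # oracle p for the shifted feature
  v <- mat["shifted", ]; g <- design$group
  gm <- tapply(v, g, mean)
  ssb <- sum(4 * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  p_oracle <- stats::pf((ssb / 2) / (ssw / 9), 2, 9, lower.tail = FALSE)
  scr <- attr(sel, "screen")
  expect_equal(scr$p_value[scr$site_id == "shifted"], p_oracle,
               tolerance = 1e-12)
})

test_that("a perfect anti-monotone pair is retained with rho = -1", {
  sto <- matrix(1:8, nrow = 1, dimnames = list("site", paste0("s", 1:8)))
  feat <- matrix(8:1, nrow = 1, dimnames = list("met", paste0("s", 1:8)))
  pairs <- spearman_pairs(sto, feat, min_pairs = 8)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$rho, -1)
  # exact permutation p at n = 8: 2 of 8! orderings reach |rho| = 1
  expect_equal(pairs$p_value, 2 / factorial(8), tolerance = 1e-12)
})

test_that("the |rho| threshold is strict", {
  # ranks (1,2,3,4,5) vs (3,2,1,4,5): sum d^2 = 8, rho = 1 - 48/120 = 0.6
  sto <- matrix(1:5, nrow = 1, dimnames = list("site", paste0("s", 1:5)))
  feat <- matrix(c(3, 2, 1, 4, 5), nrow = 1,
                 dimnames = list("met", paste0("s", 1:5)))
  pairs <- spearman_pairs(sto, feat, p_max = 1, rho_min = 0.6, min_pairs = 5)
  expect_equal(nrow(pairs), 0)
  pairs2 <- spearman_pairs(sto, feat, p_max = 1, rho_min = 0.59, min_pairs = 5)
  expect_equal(pairs2$rho, 0.6, tolerance = 1e-12)
})

test_that("pair sets match the brute-force oracle bitwise", {
  set.seed(42)
  n <- 24
  sto <- matrix(rnorm(50 * n), nrow = 50,
                dimnames = list(paste0("site", 1:50), paste0("s", 1:n)))
  feat <- matrix(rnorm(10 * n), nrow = 10,
                 dimnames = list(paste0("met", 1:10), paste0("s", 1:n)))
  sto[sample(length(sto), 100)] <- NA
  feat[1:3, ] <- sto[1:3, ] * -1 + rnorm(n, sd = 0.1)  # strong couplings
  pairs <- spearman_pairs(sto, feat, p_max = 0.05, rho_min = 0.6,
                          min_pairs = 8)
  # oracle: full double loop with explicit ranks and t-distribution p
  expected <- 0
  for (i in 1:50) for (j in 1:10) {
    o <- oracle_rho(sto[i, ], feat[j, ])
    if (o$n < 8) next
    tt <- o$rho * sqrt((o$n - 2) / (1 - o$rho^2))
    p <- 2 * stats::pt(-abs(tt), o$n - 2)
    hit <- p < 0.05 && abs(o$rho) > 0.6
    if (hit) {
      expected <- expected + 1
      row <- pairs[pairs$site_id == rownames(sto)[i] &
                     pairs$feature_id == rownames(feat)[j], ]
      expect_equal(nrow(row), 1)
      expect_equal(row$rho, o$rho, tolerance = 1e-12)
    }
  }
  expect_equal(nrow(pairs), expected)
})

test_that("disjoint sample sets are an error", {
  a <- matrix(1, nrow = 1, dimnames = list("x", "s1"))
  b <- matrix(1, nrow = 1, dimnames = list("y", "s2"))
  expect_error(spearman_pairs(a, b), "no shared samples",
               class = "redoxmap_schema_error")
})

test_that("tallies count signs, score direction and respect min_total", {
  pairs <- data.frame(
    site_id = paste0("s", 1:40),
    feature_id = c(rep("supp", 32), rep("tie", 6), rep("rare", 2)),
    rho = c(rep(-0.8, 30), rep(0.8, 2),      # supp: 30 neg, 2 pos
            rep(c(0.7, -0.7), 3),            # tie: 3 + 3
            rep(0.9, 2)),                    # rare: below min_total
    p_value = 0.001, n_pairs = 24)
  tal <- tally_features(pairs, min_total = 3)
  rownames(tal) <- tal$feature_id
  expect_equal(tal["supp", "n_neg"], 30)
  expect_equal(tal["supp", "n_pos"], 2)
  expect_equal(tal["supp", "direction_score"], 28 / 32)
  expect_identical(tal["supp", "call"], "suppressor_candidate")
  expect_identical(tal["tie", "call"], "ambiguous")
  expect_identical(tal["rare", "call"], "ambiguous")
  # conservation: tallied pairs partition the pair set
  expect_equal(sum(tal$n_pos + tal$n_neg), nrow(pairs))
  expect_equal(nrow(tally_features(pairs[0, ])), 0)
})

test_that("top-k overlap intersects per-layer top sets with tie handling", {
  counts <- list(
    omA = c(a = 10, b = 9, c = 1, d = 0),
    omB = c(b = 7, c = 6, a = 2, d = 0),
    omC = c(b = 5, d = 4, a = 3, c = 0))
  ov <- top_k_overlap(counts, k = 2)
  expect_identical(sort(ov), "b")
  # identical count vectors: intersection is the whole top set
  same <- list(x = c(a = 3, b = 2, c = 1), y = c(a = 3, b = 2, c = 1))
  ov2 <- top_k_overlap(same, k = 2)
  expect_setequal(ov2, c("a", "b"))
  # ties at the k-th count are all included and flagged
  tied <- list(x = c(a = 5, b = 3, c = 3, d = 1),
               y = c(a = 5, b = 3, c = 3, d = 1))
  ov3 <- top_k_overlap(tied, k = 2)
  expect_setequal(ov3, c("a", "b", "c"))
  expect_true(all(attr(ov3, "ties")))
  w <- testthat::capture_warnings(top_k_overlap(same, k = 10))
  expect_match(w, "universe", all = TRUE)
})

test_that("latent-driven sites are enriched in the overlap", {
  set.seed(43)
  universe <- paste0("s", 1:500)
  driven <- sample(universe, 30)
  mk <- function() {
    v <- setNames(rpois(500, 1), universe)
    v[driven] <- v[driven] + rpois(30, 12)
    v
  }
  counts <- list(met = mk(), prot = mk(), rna = mk())
  ov <- top_k_overlap(counts, k = 50)
  hits <- sum(ov %in% driven)
  # exact hypergeometric: P(X >= hits) drawing |ov| from 30 driven / 500
  p_enrich <- stats::phyper(hits - 1, 30, 470, length(ov), lower.tail = FALSE)
  expect_lt(p_enrich, 1e-6)
})
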