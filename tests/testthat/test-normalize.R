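# Normalization: channel ratios, redox reference ratios, proteome and
# metabolome workflows, QC correlations (with a brute-force rank oracle).

test_that("channel ratios scale channel sums by the reference sum", {
  mat <- rbind(c(REF = 60, A = 120, B = 30), c(REF = 40, A = 80, B = 20))
  r <- channel_ratios(mat)
  expect_equal(r, c(REF = 1, A = 2, B = 0.5))
  same <- rbind(c(REF = 50, A = 50), c(REF = 50, A = 50))
  expect_equal(channel_ratios(same), c(REF = 1, A = 1))
  zero <- rbind(c(REF = 0, A = 10))
  expect_error(channel_ratios(zero), "non-positive",
               class = "redoxmap_schema_error")
})

test_that("redox normalization divides by ratios and forms reference ratios", {
  i <- list(Sto = rbind(s1 = c(a = 60, REF = 15)),
            SH = rbind(s1 = c(a = 10, REF = 15)))
  sites <- make_sites(i)
  ratios <- structure(list(Sto = c(a = 2, REF = 1), SH = c(a = 1, REF = 1)),
                      reference = "REF", class = "channel_ratio_set")
  nr <- normalize_redox(sites, ratios)
  expect_equal(nr$normalized$Sto["s1", "a"], 30)
  expect_equal(nr$ref_ratio$Sto["s1", "a"], 2)   # 30 / 15
  # identity ratios leave intensities unchanged
  id <- identity_ratios(c("Sto", "SH"), c("a", "REF"))
  nr2 <- normalize_redox(sites, id)
  expect_equal(nr2$normalized$Sto, i$Sto)
  # unmapped channel is an error naming it
  bad <- structure(list(Sto = c(a = 2)), reference = "REF",
                   class = "channel_ratio_set")
  expect_error(normalize_redox(make_sites(list(Sto = i$Sto)), bad), "REF",
               class = "redoxmap_schema_error")
})

test_that("missing reference intensity drops the ratio, not the intensity", {
  i <- list(Sto = rbind(s1 = c(a = 60, REF = NA)),
            SH = rbind(s1 = c(a = 10, REF = 5)))
  nr <- normalize_redox(make_sites(i), identity_ratios(c("Sto", "SH"),
                                                       c("a", "REF")))
  expect_true(is.na(nr$ref_ratio$Sto["s1", "a"]))
  expect_equal(nr$normalized$Sto["s1", "a"], 60)
})

test_that("channel normalization equalizes protein totals to the reference", {
  co <- default_cohort()
  ratios <- compute_channel_ratios(co$proteins)
  for (st in names(co$proteins$abundance)) {
    m <- sweep(co$proteins$abundance[[st]], 2, ratios[[st]], "/")
    tot <- colSums(m)
    expect_equal(unname(tot), rep(unname(tot["REF"]), length(tot)),
                 tolerance = 1e-12)
  }
})

test_that("reference self-ratios are identically one", {
  co <- clean_cohort()
  nr <- normalize_redox(co$sites, compute_channel_ratios(co$proteins))
  for (st in names(nr$normalized)) {
    self <- nr$normalized[[st]][, "REF"] / nr$normalized[[st]][, "REF"]
    expect_equal(unname(self), rep(1, length(self)))
  }
})

test_that("proteome workflow applies the unique-peptide and detection rules", {
  design <- data.frame(sample = c("x", "y"), group = c("g1", "g2"),
                       batch = c(1L, 1L))
  pep <- data.frame(peptide_id = paste0("p", 1:4),
                    protein = c("A", "A", "B", "C"),
                    is_unique = c(TRUE, TRUE, TRUE, FALSE),
                    x = c(10, 20, 5, 8), y = c(10, 20, 5, 8))
  # C has no unique peptide, B only one: both dropped
  m <- normalize_proteome(pep, design, min_unique = 2, min_detect_frac = 0,
                          log2_transform = FALSE)
  expect_identical(rownames(m), "A")
  # equal sample totals: scaling is identity, so A = 10 + 20
  expect_equal(unname(m["A", ]), c(30, 30))
  expect_warning(
    normalize_proteome(pep[pep$protein == "C", , drop = FALSE], design),
    "no unique peptides")
})

test_that("per-sample proteome totals are equalized before ref division", {
  co <- clean_cohort()
  pep <- co$peptides
  pep_noref <- pep[, !grepl("^REF_", names(pep))]
  m <- normalize_proteome(pep_noref, co$design, min_detect_frac = 0,
                          log2_transform = FALSE)
  tot <- colSums(m, na.rm = TRUE)
  expect_lt(diff(range(tot)) / mean(tot), 1e-9)
})

test_that("batch reference division brings both batches to one scale", {
  co <- clean_cohort()
  m <- normalize_proteome(co$peptides, co$design, min_detect_frac = 0.5)
  expect_true(all(is.finite(m[!is.na(m)])))
  expect_equal(sort(colnames(m)), sort(co$design$sample))
})

test_that("metabolome CV filter and correction factors follow the rules", {
  vals <- rbind(m1 = c(s1 = 30, s2 = 90), m2 = c(s1 = 70, s2 = 210))
  qc <- rbind(m1 = c(100, 100, 100), m2 = c(100, 200, 300))
  mt <- metabolite_table(vals, qc, c(s1 = 1, s2 = 1), "pos")
  expect_warning(out <- normalize_metabolome(list(mt), cv_max = 0.3), NA)
  # m2 has QC CV = sd/mean = 100/200 = 0.5 >= 0.3: excluded
  expect_identical(rownames(out), "m1")
  # totals were [30, 90], mean 60 -> factors [0.5, 1.5]; post totals equal
  expect_equal(unname(out["m1", ]), c(30 / 0.5, 90 / 1.5))
  expect_equal(sum(out[, 1]), sum(out[, 2]))
})

test_that("unit protein concentrations leave values unscaled", {
  vals <- rbind(m1 = c(s1 = 10, s2 = 10), m2 = c(s1 = 20, s2 = 20))
  qc <- rbind(m1 = c(5, 5), m2 = c(7, 7))
  mt <- metabolite_table(vals, qc, c(s1 = 1, s2 = 1), "neg")
  out <- normalize_metabolome(list(mt), cv_max = 0.3)
  # equal totals: correction factors are 1, so values pass through
  expect_equal(out, vals[rownames(out), ], ignore_attr = TRUE)
})

test_that("zero QC means are excluded with a warning", {
  vals <- rbind(m1 = c(s1 = 10, s2 = 10))
  qc <- rbind(m1 = c(0, 0))
  mt <- metabolite_table(vals, qc, c(s1 = 1, s2 = 1), "pos")
  expect_warning(out <- normalize_metabolome(list(mt)), "QC mean")
  expect_equal(nrow(out), 0)
})

test_that("QC correlation matrix has the contract properties", {
  set.seed(9)
  m <- matrix(rnorm(300), nrow = 50, ncol = 6,
              dimnames = list(NULL, paste0("q", 1:6)))
  m[, 2] <- m[, 1]           # duplicated column
  m[, 3] <- -m[, 1]          # anti-correlated column
  cc <- qc_correlation(m, method = "pearson")
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 6))
  expect_equal(cc["q1", "q2"], 1)
  expect_equal(cc["q1", "q3"], -1)
  expect_true(all(abs(cc) <= 1 + 1e-12))
  expect_warning(qc_correlation(cbind(m, const = 1)), "constant")
})

test_that("spearman QC correlations match a brute-force rank oracle", {
  set.seed(21)
  m <- matrix(rnorm(300)^3, nrow = 50, ncol = 6,
              dimnames = list(NULL, paste0("q", 1:6)))
  cc <- qc_correlation(m, method = "spearman")
  # oracle: explicit average ranks + product-moment formula
  avg_rank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    r[o] <- seq_along(v)
    for (val in unique(v)) r[v == val] <- mean(r[v == val])
    r
  }
  pm_cor <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  for (i in 1:6) for (j in 1:6) {
    expect_equal(cc[i, j], pm_cor(avg_rank(m[, i]), avg_rank(m[, j])),
                 tolerance = 1e-12)
  }
})
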