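# Stoichiometry: occupancy arithmetic and invariants, group medians,
# density/peak/valley models, region assignment, transitions, contributions.

make_norm <- function(intensity) {
  sites <- make_sites(intensity)
  normalize_redox(sites, identity_ratios(names(intensity),
                                         colnames(intensity[[1]])))
}

test_that("occupancy is each state's share of I_Sto + I_SH", {
  i <- list(Sto = rbind(s1 = c(a = 80, REF = 100)),
            SH = rbind(s1 = c(a = 20, REF = 100)),
            SSG = rbind(s1 = c(a = 25, REF = 100)))
  occ <- compute_occupancy(make_norm(i), method = "channel")
  expect_equal(occ$occ$SSG["s1", "a"], 0.25)
  expect_equal(occ$occ$Sto["s1", "a"], 0.80)
  expect_equal(occ$occ$Sto["s1", "a"] + occ$occ$SH["s1", "a"], 1)
  # reference-ratio mode agrees when the reference column is shared
  occ2 <- compute_occupancy(make_norm(i))
  expect_equal(occ2$occ$SSG["s1", "a"], 0.25)
})

test_that("boundary occupancies behave at 0 and full oxidation", {
  i <- list(Sto = rbind(s1 = c(a = 0.0001, REF = 1)),
            SH = rbind(s1 = c(a = 50, REF = 1)))
  i$Sto["s1", "a"] <- NA  # zero reporter would have been NA after ingest
  occ <- compute_occupancy(make_norm(i), method = "channel")
  expect_true(is.na(occ$occ$Sto["s1", "a"]))
  i2 <- list(Sto = rbind(s1 = c(a = 50, REF = 1)),
             SH = rbind(s1 = c(a = 50, REF = 1)))
  occ2 <- compute_occupancy(make_norm(i2), method = "channel")
  expect_equal(occ2$occ$Sto["s1", "a"], 0.5)
})

test_that("occupancies above one are clamped, flagged, raw kept", {
  i <- list(Sto = rbind(s1 = c(a = 80, REF = 1)),
            SH = rbind(s1 = c(a = 20, REF = 1)),
            SNO = rbind(s1 = c(a = 150, REF = 1)))
  occ <- compute_occupancy(make_norm(i), method = "channel")
  expect_equal(occ$occ$SNO["s1", "a"], 1)
  expect_equal(occ$raw$SNO["s1", "a"], 1.5)
  expect_true(occ$clamped$SNO["s1", "a"])
  expect_false(occ$clamped$Sto["s1", "a"])
})

test_that("occupancy is invariant to rescaling a site-sample's channels", {
  set.seed(4)
  base <- list(Sto = 80, SH = 20, SSG = 30, SOH = 5, SNO = 8)
  for (k in 1:20) {
    c1 <- runif(1, 0.01, 100)
    i <- lapply(base, function(v) rbind(s1 = c(a = v, b = v * c1, REF = 1)))
    occ <- compute_occupancy(make_norm(i), method = "channel")
    for (st in names(base))
      expect_equal(occ$occ[[st]]["s1", "a"], occ$occ[[st]]["s1", "b"],
                   tolerance = 1e-12)
  }
})

test_that("occ(Sto) + occ(SH) = 1 across a full noisy cohort", {
  ch <- occupancy_chain(default_cohort())
  s <- ch$occ$raw$Sto + ch$occ$raw$SH
  expect_lt(max(abs(s - 1), na.rm = TRUE), 1e-9)
})

test_that("zero Sto+SH denominators give missing occupancy with warning", {
  i <- list(Sto = rbind(s1 = c(a = 0, REF = 1)),
            SH = rbind(s1 = c(a = 0, REF = 1)))
  i$Sto["s1", "a"] <- 0; i$SH["s1", "a"] <- 0
  expect_warning(occ <- compute_occupancy(make_norm(i), method = "channel"),
                 "I_Sto \\+ I_SH = 0")
  expect_true(is.na(occ$occ$Sto["s1", "a"]))
})

test_that("group medians require the minimum per-group detection count", {
  design <- data.frame(sample = paste0("s", 1:6),
                       group = rep(c("young", "old"), each = 3))
  mat <- rbind(site1 = c(0.2, 0.3, 0.4, 0.5, 0.5, 0.5),
               site2 = c(0.2, 0.3, NA, 0.1, 0.1, 0.1),
               site3 = rep(0.7, 6))
  colnames(mat) <- design$sample
  gm <- group_median_occupancy(mat, design, min_n = 3)
  expect_equal(gm$median["site1", "young"], 0.3)
  expect_true(is.na(gm$median["site2", "young"]))   # only 2 of 3 quantified
  expect_equal(gm$median["site2", "old"], 0.1)
  expect_equal(unname(gm$median["site3", ]), c(0.7, 0.7))
  expect_error(group_median_occupancy(
    rbind(x = 1:2) |> `colnames<-`(c("s1", "zz")), design), "zz",
    class = "redoxmap_schema_error")
})

test_that("density fit recovers a single Beta mode and integrates to one", {
  set.seed(12)
  kappa <- 18
  x <- rbeta(2000, 0.5 * (kappa - 2) + 1, 0.5 * (kappa - 2) + 1)
  d <- fit_density(x)
  # analytic mode of Beta(9, 9) is 0.5
  expect_lt(abs(d$x[which.max(d$y)] - 0.5), 0.05)
  grid_int <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
  expect_gt(grid_int, 0.98)
  expect_lt(grid_int, 1.02)
  expect_error(fit_density(rep(0.4, 100)), "constant",
               class = "redoxmap_schema_error")
  expect_error(fit_density(runif(10)), "pool",
               class = "redoxmap_schema_error")
})

test_that("peaks and valley of a Beta mixture match the analytic density", {
  set.seed(13)
  n <- 3000
  kappa <- 18
  shapes <- function(m) c(m * (kappa - 2) + 1, (1 - m) * (kappa - 2) + 1)
  lo <- shapes(0.25); hi <- shapes(0.85)
  comp <- runif(n) < 0.6
  x <- ifelse(comp, rbeta(n, lo[1], lo[2]), rbeta(n, hi[1], hi[2]))
  d <- fit_density(x)
  model <- find_peaks_valley(d)
  # oracle: argmax/argmin of the exact mixture density on the same grid
  fx <- 0.6 * dbeta(d$x, lo[1], lo[2]) + 0.4 * dbeta(d$x, hi[1], hi[2])
  lo_idx <- d$x < 0.5
  peak1 <- d$x[lo_idx][which.max(fx[lo_idx])]
  peak2 <- d$x[!lo_idx][which.max(fx[!lo_idx])]
  mid <- d$x > peak1 & d$x < peak2
  valley <- d$x[mid][which.min(fx[mid])]
  expect_lt(abs(model$peaks[1] - peak1), 0.05)
  expect_lt(abs(model$peaks[2] - peak2), 0.05)
  expect_lt(abs(model$valley - valley), 0.1)
  expect_true(model$peaks[1] < model$valley && model$valley < model$peaks[2])
})

test_that("a symmetric two-spike sample puts the valley near the centre", {
  set.seed(14)
  x <- c(rnorm(1000, 0.2, 0.02), rnorm(1000, 0.8, 0.02))
  model <- find_peaks_valley(fit_density(x))
  expect_lt(abs(model$valley - 0.5), 0.05)
})

test_that("unimodal densities raise the dedicated condition", {
  set.seed(15)
  x <- rbeta(2000, 9, 9)
  expect_error(find_peaks_valley(fit_density(x)),
               class = "redoxmap_unimodal_error")
})

test_that("region assignment splits at the valley with region-1 ties", {
  model <- structure(list(peaks = c(0.25, 0.85), valley = 0.55, bw = 0.05),
                     class = "region_model")
  med <- c(a = 0.2, b = 0.9, c = 0.55, d = NA)
  lab <- assign_regions(med, model, prefix = "Y")
  expect_equal(unname(lab[c("a", "b", "c")]), c("Y1", "Y2", "Y1"))
  expect_true(is.na(lab["d"]))
  expect_error(assign_regions(med, NULL), class = "redoxmap_schema_error")
})

test_that("transitions and delta sub-counts match a hand-worked example", {
  my <- c(a = 0.2, b = 0.3, c = 0.9)
  mo <- c(a = 0.85, b = 0.4, c = 0.2)
  ry <- setNames(c(1L, 1L, 2L), names(my))
  ro <- setNames(c(2L, 1L, 1L), names(mo))
  tr <- count_transitions(my, ry, mo, ro, delta_min = 0.10)
  expect_equal(tr$n_low_to_high, 1)   # a: Y1 -> O2
  expect_equal(tr$n_high_to_low, 1)   # c: Y2 -> O1
  expect_equal(tr$n_low_to_high_delta, 1)  # |0.85 - 0.2| = 0.65 > 0.10
  expect_equal(tr$low_to_high, "a")
  expect_equal(tr$high_to_low, "c")
})

test_that("transition counts equal a brute-force per-site loop", {
  set.seed(16)
  n <- 2000
  ids <- paste0("s", seq_len(n))
  my <- setNames(runif(n), ids); mo <- setNames(runif(n), ids)
  vy <- 0.55; vo <- 0.6
  ry <- setNames(ifelse(my <= vy, 1L, 2L), ids)
  ro <- setNames(ifelse(mo <= vo, 1L, 2L), ids)
  # drop some sites from one side
  keep_o <- sample(ids, n - 100)
  tr <- count_transitions(my, ry, mo[keep_o], ro[keep_o], delta_min = 0.10)
  # independent loop
  n12 <- n21 <- d12 <- d21 <- 0
  for (s in intersect(ids, keep_o)) {
    if (ry[s] == 1 && ro[s] == 2) {
      n12 <- n12 + 1
      if (abs(mo[s] - my[s]) > 0.10) d12 <- d12 + 1
    }
    if (ry[s] == 2 && ro[s] == 1) {
      n21 <- n21 + 1
      if (abs(mo[s] - my[s]) > 0.10) d21 <- d21 + 1
    }
  }
  expect_equal(tr$n_low_to_high, n12)
  expect_equal(tr$n_high_to_low, n21)
  expect_equal(tr$n_low_to_high_delta, d12)
  expect_equal(tr$n_high_to_low_delta, d21)
})

test_that("clamping never reorders sites across the valley", {
  set.seed(17)
  raw <- runif(50, 0, 1.4)
  clamped <- pmin(raw, 1)
  valley <- 0.55
  expect_identical(raw <= valley, clamped <= valley)
})

test_that("modification contributions split Sto occupancy as stated", {
  sto <- c(a = 0.25, b = 0.30, c = 0.20, d = 0)
  ssg <- c(a = 0.10, b = 0.30, c = 0.18, d = 0.1)
  soh <- c(a = 0.02, b = NA, c = 0.08, d = NA)
  sno <- c(a = 0.03, b = NA, c = 0.02, d = NA)
  ct <- modification_contribution(sto, ssg, soh, sno)
  rownames(ct) <- ct$site_id
  expect_equal(ct["a", "SSG"], 0.40)
  expect_equal(ct["a", "SOH"], 0.08)
  expect_equal(ct["a", "SNO"], 0.12)
  expect_equal(ct["a", "residual"], 0.40)
  # SSG alone accounts for all oxidation
  expect_equal(ct["b", "SSG"], 1)
  expect_equal(ct["b", "residual"], 0)
  # overshoot (0.9 + 0.4 + 0.1 = 1.4) is rescaled to sum one and flagged
  expect_true(ct["c", "rescaled"])
  expect_equal(sum(ct["c", c("SSG", "SOH", "SNO")]), 1)
  expect_equal(ct["c", "residual"], 0)
  # zero Sto occupancy: contribution undefined
  expect_true(is.na(ct["d", "SSG"]))
})
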