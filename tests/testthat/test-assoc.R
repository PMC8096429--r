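test_that("allelic counts match hand enumeration and exclude missing", {
  d <- matrix(c(2L, 1L, NA, 0L, 1L, 0L), nrow = 3)
  gm <- toy_gm(d)
  cohort <- toy_cohort(2, 1)
  ac <- allelic_counts(gm, cohort, 1)
  expect_equal(unname(ac$table["CASE", ]), c(3L, 1L))   # 2 + 1 of 4
  expect_equal(unname(ac$table["CONTROL", ]), c(0L, 0L))  # only a missing call
  expect_equal(ac$freq_case, 0.75)

  # 81 cases carrying 90 of 162 alt alleles -> frequency 0.556
  d2 <- matrix(c(rep(2L, 9), rep(1L, 72), rep(0L, 36)), ncol = 1)
  gm2 <- toy_gm(d2)
  co2 <- toy_cohort(81, 36)
  expect_equal(round(allelic_counts(gm2, co2, 1)$freq_case, 3), 0.556)
})

test_that("logistic association reduces to the sample log-OR without covariates", {
  set.seed(41)
  g <- rbinom(200, 1, 0.4)
  y <- rbinom(200, 1, plogis(-0.5 + 1.2 * g))
  ids <- sprintf("s%03d", 1:200)
  gm <- toy_gm(matrix(as.integer(g), ncol = 1))
  rownames(gm$dosage) <- ids
  cohort <- cohort_table(ids, ifelse(y == 1, "CASE", "CONTROL"))
  res <- logistic_assoc(gm, cohort, covariates = character(0))
  a <- sum(g == 1 & y == 1); b <- sum(g == 1 & y == 0)
  cc <- sum(g == 0 & y == 1); dd <- sum(g == 0 & y == 0)
  expect_equal(res$or, (a / b) / (cc / dd), tolerance = 1e-6)

  # identical genotype distributions: OR near 1, p large
  g2 <- rep(c(0L, 1L, 2L), length.out = 200)
  gm2 <- toy_gm(matrix(g2, ncol = 1)); rownames(gm2$dosage) <- ids
  null_res <- logistic_assoc(gm2, cohort_table(ids, rep(c("CASE", "CONTROL"),
                                                        each = 100)),
                             covariates = character(0))
  expect_equal(null_res$or, 1, tolerance = 0.35)
  expect_gt(null_res$p, 0.2)
})

test_that("separation and monomorphism are flagged, not silently reported", {
  ids <- sprintf("s%02d", 1:20)
  sep <- toy_gm(matrix(as.integer(rep(c(1L, 0L), each = 10)), ncol = 1))
  rownames(sep$dosage) <- ids
  cohort <- cohort_table(ids, rep(c("CASE", "CONTROL"), each = 10))
  res <- logistic_assoc(sep, cohort, covariates = character(0))
  expect_false(res$converged)
  expect_true(is.na(res$p))

  mono <- toy_gm(matrix(1L, nrow = 20, ncol = 1))
  rownames(mono$dosage) <- ids
  res2 <- logistic_assoc(mono, cohort, covariates = character(0))
  expect_false(res2$converged)
})

test_that("Wald CI covers a planted odds ratio at its nominal rate", {
  set.seed(42)
  hits <- 0; reps <- 120
  for (r in 1:reps) {
    sim <- simulate_cohort(n_case = 1500, n_ctrl = 1500, n_variants = 1,
                           maf_range = c(0.25, 0.25),
                           effect_loci = data.frame(index = 1, or = 5))
    res <- logistic_assoc(sim$genotypes, sim$cohort,
                          covariates = character(0))
    if (!is.na(res$ci_low) && res$ci_low <= 5 && res$ci_high >= 5) {
      hits <- hits + 1
    }
  }
  cover <- hits / reps
  mc_se <- sqrt(cover * (1 - cover) / reps)
  expect_gte(cover, 0.94 - 2 * mc_se)
})

test_that("permutation adjustment is monotone, bounded, and calibrated", {
  set.seed(43)
  sim <- simulate_cohort(n_case = 50, n_ctrl = 50, n_variants = 25,
                         effect_loci = data.frame(index = 1, or = 12),
                         seed = 44)
  adj <- permutation_adjust(sim$genotypes, sim$cohort, n_perm = 400,
                            seed = 45)
  expect_true(all(adj$p_adjusted >= adj$p_nominal))
  expect_true(all(adj$p_adjusted >= 1 / 401))
  expect_lte(adj$p_adjusted[1], 3 / 401)  # strong planted signal

  # single variant: adjusted ~ nominal within Monte Carlo error
  one <- subset_variants(sim$genotypes, 5)
  a1 <- permutation_adjust(one, sim$cohort, n_perm = 2000, seed = 46)
  mc <- 3 * sqrt(a1$p_nominal * (1 - a1$p_nominal) / 2000)
  expect_lt(abs(a1$p_adjusted - a1$p_nominal), mc + 1 / 2001)
  expect_error(permutation_adjust(one, sim$cohort, n_perm = 50), "100")
})

test_that("permutation adjustment controls the family-wise error rate", {
  set.seed(47)
  reps <- 300
  fam_hits <- 0
  for (r in 1:reps) {
    sim <- simulate_cohort(n_case = 30, n_ctrl = 30, n_variants = 15)
    adj <- permutation_adjust(sim$genotypes, sim$cohort, n_perm = 100)
    if (any(adj$p_adjusted <= 0.1)) fam_hits <- fam_hits + 1
  }
  rate <- fam_hits / reps
  expect_lte(rate, 0.1 + 2 * sqrt(0.1 * 0.9 / reps))
})

test_that("allele-frequency trajectories carry the U-shape rule", {
  mk <- function(freq, n = 50) {
    d <- matrix(as.integer(rbinom(n, 2, freq)), ncol = 1)
    gm <- toy_gm(d, rsid = "rs_target")
    gm
  }
  set.seed(48)
  traj <- af_trajectory("rs_target", list(
    oldest = mk(0.55), old = mk(0.2), mid = mk(0.25), young = mk(0.3)
  ))
  expect_equal(nrow(traj), 4)
  expect_true(attr(traj, "u_shape"))

  flat <- af_trajectory("rs_target", list(a = mk(0.3), b = mk(0.9)))
  expect_false(attr(flat, "u_shape"))
})
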