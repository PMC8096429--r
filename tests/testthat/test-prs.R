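grs_fixture <- function() {
  d <- rbind(s1 = c(0L, 0L), s2 = c(2L, 1L), s3 = c(1L, 2L), s4 = c(NA, 1L))
  gm <- toy_gm(d, ref = c("A", "C"), alt = c("G", "T"),
               rsid = c("rs_a", "rs_b"))
  gm
}

test_that("the risk score is the effect-allele dosage dot product", {
  gm <- grs_fixture()
  w1 <- data.frame(snp = c("rs_a", "rs_b"), effect_allele = c("G", "T"),
                   beta = c(0.5, -1))
  res <- compute_grs(gm, w1)
  expect_equal(res$score[res$sample_id == "s1"], 0)        # all dosages 0
  expect_equal(res$score[res$sample_id == "s2"], 0)        # 2*0.5 + 1*(-1)
  w2 <- data.frame(snp = c("rs_a", "rs_b"), effect_allele = c("G", "T"),
                   beta = c(0.2, 0.3))
  expect_equal(compute_grs(gm, w2)$score[3], 0.8)          # 1*0.2 + 2*0.3
})

test_that("score computation is linear in the weights (exact)", {
  gm <- grs_fixture()
  w1 <- data.frame(snp = c("rs_a", "rs_b"), effect_allele = c("G", "T"),
                   beta = c(0.4, -0.7))
  w2 <- data.frame(snp = c("rs_a", "rs_b"), effect_allele = c("G", "T"),
                   beta = c(-0.1, 1.3))
  wsum <- w1; wsum$beta <- w1$beta + w2$beta
  expect_equal(compute_grs(gm, wsum)$score,
               compute_grs(gm, w1)$score + compute_grs(gm, w2)$score,
               tolerance = 1e-12)
})

test_that("flipping the effect allele maps dosage A to 2 - A exactly", {
  gm <- grs_fixture()
  walt <- data.frame(snp = "rs_a", effect_allele = "G", beta = 0.6)
  wref <- data.frame(snp = "rs_a", effect_allele = "A", beta = 0.6)
  salt <- compute_grs(gm, walt)$score
  sref <- compute_grs(gm, wref)$score
  d <- gm$dosage[, 1]
  ok <- !is.na(d)
  expect_equal(sref[ok], unname(0.6 * (2 - d[ok])))
  expect_equal(salt[ok] + sref[ok], rep(1.2, sum(ok)))
})

test_that("missing-genotype policies bookkeep n_used + n_missing", {
  gm <- grs_fixture()
  w <- data.frame(snp = c("rs_a", "rs_b", "rs_absent"),
                  effect_allele = c("G", "T", "A"), beta = c(1, 1, 1))
  skip <- compute_grs(gm, w, missing_policy = "skip")
  expect_true(all(skip$n_snps_used + skip$n_missing == 3))
  expect_equal(skip$n_missing[skip$sample_id == "s4"], 2)  # NA + absent SNP
  meanp <- compute_grs(gm, w, missing_policy = "mean")
  expect_equal(meanp$n_missing[meanp$sample_id == "s4"], 1)
  expect_error(compute_grs(gm, w, missing_policy = "fail"), "missing")
  wbad <- data.frame(snp = "rs_a", effect_allele = "T", beta = 1)
  expect_error(compute_grs(gm, wbad), "neither record allele")
})

ld_fixture <- function(seed = 81) {
  set.seed(seed)
  n <- 300
  target <- rbinom(n, 2, 0.4)
  noisy <- function(q) ifelse(runif(n) < q, target,
                              rbinom(n, 2, 0.4))
  d <- cbind(target, p_strong = noisy(0.97), p_weak = noisy(0.6),
             p_unrelated = rbinom(n, 2, 0.4))
  rownames(d) <- sprintf("r%03d", 1:n)
  storage.mode(d) <- "integer"
  toy_gm(d, rsid = c("rs_target", "rs_strong", "rs_weak", "rs_far"))
}

test_that("proxy search takes the highest r2 above threshold", {
  ref <- ld_fixture()
  # cohort carries the candidate proxies but not the target
  cohort_gm <- subset_variants(ref, 2:4)
  w <- data.frame(snp = "rs_target", effect_allele = "G", beta = 0.3)
  pd <- find_proxies("rs_target", ref, cohort_gm, w)
  expect_true(pd$accepted)
  expect_equal(pd$proxy, "rs_strong")
  expect_gt(pd$r2, 0.8)

  # no candidate above 0.8: rejected with the threshold reason
  weak_ref <- subset_variants(ref, c(1, 3, 4))
  pd2 <- find_proxies("rs_target", weak_ref, subset_variants(ref, 3:4), w)
  expect_false(pd2$accepted)
  expect_equal(pd2$reason, "r2_below_threshold")

  pd3 <- find_proxies("rs_missing", ref, cohort_gm, w)
  expect_equal(pd3$reason, "target_not_in_reference")
})

test_that("accepted proxies enter the score and never lower n_snps_used", {
  ref <- ld_fixture()
  cohort_gm <- subset_variants(ref, 2:4)
  w <- data.frame(snp = c("rs_target", "rs_far"),
                  effect_allele = c("G", "G"), beta = c(0.3, 0.1))
  pd <- find_proxies("rs_target", ref, cohort_gm, w)
  without <- compute_grs(cohort_gm, w)
  with_p <- compute_grs(cohort_gm, w, proxies = pd)
  expect_true(all(with_p$n_snps_used >= without$n_snps_used))
  expect_true(all(with_p$n_proxied == 1))
  expect_true(all(with_p$n_snps_used + with_p$n_missing == 2))
})

test_that("score comparison gates between t-test and Wilcoxon", {
  set.seed(83)
  ids <- sprintf("s%03d", 1:160)
  cohort <- toy_cohort(80, 80, ids = ids)
  normal <- data.frame(sample_id = ids,
                       score = c(rnorm(80, 1), rnorm(80, 0)))
  res <- compare_scores(normal, cohort)
  expect_equal(res$location_test, "t-test")
  expect_lt(res$location_p, 1e-4)
  expect_lt(res$logistic_p, 1e-3)

  skewed <- data.frame(sample_id = ids,
                       score = c(rexp(80)^3, rexp(80)^3))
  res2 <- compare_scores(skewed, cohort)
  expect_equal(res2$location_test, "wilcoxon")
  expect_gt(res2$location_p, 0.001)

  same <- data.frame(sample_id = ids, score = rep(rnorm(80), 2))
  res3 <- compare_scores(same, cohort)
  expect_gt(res3$location_p, 0.9)

  flat <- data.frame(sample_id = ids, score = rep(1, 160))
  res4 <- compare_scores(flat, cohort)
  expect_true(is.na(res4$location_p))
})
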