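test_that("coverage quantile normalization matches distributions", {
  x <- c(80, 90, 100, 110, 120)
  expect_equal(quantile_normalize_coverage(x, x), x)        # identity
  expect_equal(quantile_normalize_coverage(2 * x, x), x)    # same shape, 2x
  expect_equal(quantile_normalize_coverage(c(120, 120, 120), 60),
               c(60, 60, 60))                               # constant control

  set.seed(71)
  case <- rnbinom(10000, mu = 120, size = 20)
  ctrl <- rnbinom(10000, mu = 60, size = 35)
  mapped <- quantile_normalize_coverage(case, ctrl)
  ks <- suppressWarnings(stats::ks.test(mapped, ctrl))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("count recomputation uses half-to-even rounding and is consistent", {
  expect_equal(recompute_counts(0.2, 50), data.frame(alt = 10L, ref = 40L,
                                                     coverage = 50L))
  expect_equal(recompute_counts(1 / 3, 10)$alt, 3L)
  expect_equal(recompute_counts(1 / 3, 10)$ref, 7L)
  half <- recompute_counts(0.5, 9)
  expect_equal(half$alt, 4L)  # round(4.5) -> 4 under half-to-even
  expect_equal(half$ref, 5L)
  rc <- recompute_counts(runif(50), runif(50, 0, 200))
  expect_true(all(rc$alt + rc$ref == rc$coverage))
})

test_that("heterozygous mean estimation is the in-band median", {
  expect_equal(estimate_het_mean(c(0.3, 0.47, 0.5, 0.9)), 0.47)
  expect_equal(estimate_het_mean(c(0.4, 0.5, 0.6)), 0.5)
  expect_error(estimate_het_mean(c(0.05, 0.95)), "het_mean_override")
})

test_that("site classification follows the filter-then-test pipeline", {
  cfg <- somatic_config()
  hm <- c(CASE = 0.4643, CONTROL = 0.4713)
  cls <- function(...) classify_site(..., config = cfg, het_means = hm)

  het <- cls("C", "T", 42 / 90, 42L, 90L, "CASE")
  expect_equal(het$classification, "GERMLINE_HET")

  som <- cls("C", "T", 14 / 90, 14L, 90L, "CASE")
  expect_equal(som$classification, "SOMATIC")
  expect_true(som$putative_flag)

  low <- cls("C", "T", 3 / 8, 3L, 8L, "CASE")
  expect_equal(low$reason, "low_coverage")

  indel <- cls("C", "TA", 0.3, 30L, 100L, "CASE")
  expect_equal(indel$reason, "indel")

  fixed <- cls("C", "T", 1, 90L, 90L, "CASE")
  expect_equal(fixed$reason, "fixed")

  hom <- cls("C", "T", 89 / 90, 89L, 90L, "CASE")
  expect_equal(hom$classification, "GERMLINE_HOM")

  lowaf <- cls("C", "T", 0.08, 8L, 100L, "CASE")
  expect_equal(lowaf$reason, "low_af")
})

test_that("classification is monotone in evidence toward the het mean", {
  cfg <- somatic_config()
  hm <- c(CASE = 0.4643, CONTROL = 0.4713)
  cov <- 120L
  states <- vapply(10:56, function(alt) {
    classify_site("C", "T", alt / cov, as.integer(alt), cov, "CASE",
                  config = cfg, het_means = hm)$classification
  }, character(1))
  # once the trajectory has left SOMATIC it never returns before the mean
  som_idx <- which(states == "SOMATIC")
  expect_true(length(som_idx) > 0)
  expect_true(all(diff(som_idx) == 1))  # a contiguous block
  expect_false(any(states == "EXCLUDED" & c(FALSE, head(states, -1) ==
                                              "SOMATIC")))
})

test_that("cohort calling applies recurrence and requires controls", {
  cohort <- toy_cohort(5, 3)
  ids <- cohort$sample_id
  mk_row <- function(s, pos, cov, alt) {
    data.frame(sample = s, chrom = "2", pos = pos, ref = "C", alt = "T",
               gene = "DNMT3A", coverage = cov, alt_count = alt)
  }
  # one variant carried by 3 cases (recurrent), one private clone
  tab <- rbind(mk_row(ids[1], 1000, 100, 20), mk_row(ids[2], 1000, 100, 22),
               mk_row(ids[3], 1000, 100, 25), mk_row(ids[4], 2000, 100, 20),
               mk_row(ids[6], 3000, 100, 48), mk_row(ids[7], 3500, 100, 47))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- read_site_counts(path)
  cfg <- somatic_config(het_mean_override = c(CASE = 0.47, CONTROL = 0.47))
  calls <- call_cohort(counts, cohort, cfg)
  rec <- calls[calls$pos == 1000, ]
  expect_true(all(rec$classification == "EXCLUDED"))
  expect_true(all(rec$reason == "recurrent"))
  expect_equal(calls$classification[calls$pos == 2000], "SOMATIC")

  case_only <- cohort_table(ids[1:5], rep("CASE", 5))
  expect_error(call_cohort(counts[1:3, ], case_only, cfg), "control")
})

test_that("population-frequency annotation excludes common variants", {
  cohort <- toy_cohort(2, 2)
  ids <- cohort$sample_id
  tab <- data.frame(sample = ids[c(1, 2, 3)], chrom = "2",
                    pos = c(1000, 2000, 3000),
                    ref = "C", alt = "T", gene = "TET2",
                    coverage = 100, alt_count = c(20, 20, 50))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- read_site_counts(path)
  cfg <- somatic_config(het_mean_override = c(CASE = 0.47, CONTROL = 0.47))
  annot <- data.frame(chrom = "2", pos = c(1000, 2000), ref = "C", alt = "T",
                      population_af = c(0.01, 1e-5))
  calls <- call_cohort(counts, cohort, cfg, annotations = annot)
  expect_equal(calls$reason[calls$pos == 1000], "common_population")
  expect_equal(calls$classification[calls$pos == 2000], "SOMATIC")
})

test_that("the default simulation yields no false-positive somatic calls", {
  sim <- simulate_cohort(n_variants = 10, seed = 72)
  rc <- simulate_read_counts(sim$cohort, seed = 73)
  calls <- call_cohort(rc$counts, sim$cohort)
  som <- calls[calls$classification == "SOMATIC", ]
  truth_key <- with(rc$truth[rc$truth$state == "SOMATIC", ],
                    paste(sample_id, chrom, pos))
  call_key <- with(som, paste(sample_id, chrom, pos))
  expect_true(all(call_key %in% truth_key))
  # determinism
  calls2 <- call_cohort(rc$counts, sim$cohort)
  expect_identical(calls$classification, calls2$classification)
})

test_that("clones well below the heterozygous band are recovered with high power", {
  sim <- simulate_cohort(n_variants = 10, seed = 74)
  cfg <- counts_config(clone_vaf_range = c(0.15, 0.30))
  rc <- simulate_read_counts(sim$cohort, cfg, seed = 75)
  calls <- call_cohort(rc$counts, sim$cohort)
  truth <- rc$truth[rc$truth$state == "SOMATIC", ]
  cov <- rc$counts$coverage[rc$truth$state == "SOMATIC"]
  truth <- truth[cov >= 60, ]
  som_key <- with(calls[calls$classification == "SOMATIC", ],
                  paste(sample_id, chrom, pos))
  sens <- mean(with(truth, paste(sample_id, chrom, pos)) %in% som_key)
  expect_gt(sens, 0.9)
})

test_that("burden comparison matches exact Mann-Whitney and Fisher oracles", {
  cohort <- toy_cohort(3, 2)
  ids <- cohort$sample_id
  calls <- data.frame(
    sample_id = c(ids[3], ids[4], ids[4], ids[5], ids[5]),
    chrom = "2", pos = 1:5, ref = "C", alt = "T", gene = "DNMT3A",
    classification = "SOMATIC", stringsAsFactors = FALSE
  )
  gg <- gene_group_comparison(calls, cohort, genes = "DNMT3A")
  # cases {0,0,1} vs controls {2,2}: exact enumeration gives p = 0.2
  expect_equal(gg$per_gene$mwu_p, 0.2)
  expect_equal(gg$per_gene$median_case, 0)
  expect_equal(gg$per_gene$median_ctrl, 2)

  # identical count multisets -> p = 1
  calls2 <- calls[c(1, 4), ]
  calls2$sample_id <- c(ids[1], ids[4])
  cohort2 <- toy_cohort(2, 2, ids = ids[1:4])
  gg2 <- gene_group_comparison(calls2, cohort2, genes = "DNMT3A")
  expect_equal(gg2$per_gene$mwu_p, 1)
})

test_that("prevalence comparison reproduces the study-shaped Fisher table", {
  cohort <- toy_cohort(79, 31)
  ids <- cohort$sample_id
  calls <- data.frame(
    sample_id = ids[1:8], chrom = "2", pos = 1:8, ref = "C", alt = "T",
    gene = "DNMT3A", classification = "SOMATIC", impact = "HIGH",
    stringsAsFactors = FALSE
  )
  dis <- disruptive_subset(calls, cohort)
  expect_equal(round(dis$prevalence_case, 4), 0.1013)
  expect_equal(dis$prevalence_ctrl, 0)
  expect_equal(round(dis$fisher_p, 4), 0.1025)
})

test_that("disruptive subset keeps moderate/high impact only", {
  cohort <- toy_cohort(2, 2)
  ids <- cohort$sample_id
  calls <- data.frame(
    sample_id = ids[1:3], chrom = "2", pos = 1:3, ref = "C", alt = "T",
    gene = "TP53", classification = "SOMATIC",
    impact = c("HIGH", "LOW", "MODERATE"), stringsAsFactors = FALSE
  )
  dis <- disruptive_subset(calls, cohort)
  expect_setequal(dis$subset$impact, c("HIGH", "MODERATE"))

  calls$impact[2] <- NA
  expect_warning(disruptive_subset(calls, cohort), "unannotated")
})

test_that("substitution spectrum collapses onto pyrimidine classes", {
  calls <- data.frame(ref = c("C", "G", "A"), alt = c("T", "A", "G"))
  sp <- spectrum(calls)
  expect_equal(unname(sp["C>T"]), 2L)  # G>A complements to C>T
  expect_equal(unname(sp["T>C"]), 1L)  # A>G complements to T>C
  expect_equal(sum(sp), nrow(calls))
  expect_equal(sum(spectrum(calls[0, ])), 0L)
  expect_error(spectrum(data.frame(ref = "CA", alt = "T")), "single")
})

test_that("candidate-driver flags follow the report-count rule", {
  calls <- data.frame(chrom = "2", pos = 1:3, ref = "C", alt = "T",
                      stringsAsFactors = FALSE)
  cosmic <- data.frame(chrom = "2", pos = 1:2, ref = "C", alt = "T",
                       cosmic_heme_count = c(7L, 6L))
  flagged <- cosmic_driver_flags(calls, cosmic)
  expect_equal(flagged$cosmic_driver, c(TRUE, FALSE, FALSE))
})
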