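#' Weighted-allele genetic risk score
#'
#' `GRS = sum_i A_i * beta_i` where `A_i` counts copies of the effect
#' allele (0/1/2). Weight rows are matched to cohort variants by rsid
#' first, then by `chrom:pos:ref:alt` key; when the effect allele is the
#' record's reference allele the dosage is flipped to `2 - A`. An effect
#' allele matching neither record allele is an error listing the
#' offenders. Missing genotypes follow `missing_policy`: `"skip"` drops
#' the term for that sample, `"mean"` substitutes the cohort mean
#' effect-allele dosage, `"fail"` errors. Weight-table SNPs absent from
#' the cohort can be rescued through accepted [find_proxies()] decisions,
#' which contribute the proxy's dosage with the original beta.
#'
#' @param gm a [genotype_matrix()].
#' @param weights a [read_weights()] table.
#' @param missing_policy `"skip"` (default), `"mean"` or `"fail"`.
#' @param proxies optional [find_proxies()] output; accepted rows
#'   substitute missing weight SNPs.
#' @return `data.frame(sample_id, score, n_snps_used, n_missing,
#'   n_proxied)`; `n_snps_used + n_missing` equals the weight-table size
#'   for every sample.
#' @export
compute_grs <- function(gm, weights,
                        missing_policy = c("skip", "mean", "fail"),
                        proxies = NULL) {
  missing_policy <- match.arg(missing_policy)
  ids <- rownames(gm$dosage)
  n <- length(ids)
  score <- numeric(n)
  used <- missing <- proxied <- integer(n)
  offenders <- character(0)
  accepted <- if (is.null(proxies)) NULL else
    proxies[proxies$accepted, , drop = FALSE]
  for (i in seq_len(nrow(weights))) {
    snp <- weights$snp[i]
    j <- match(snp, gm$variants$rsid)
    if (is.na(j)) j <- match(snp, variant_id(gm$variants))
    eff <- weights$effect_allele[i]
    via_proxy <- FALSE
    if (is.na(j) && !is.null(accepted) && snp %in% accepted$target) {
      prow <- accepted[match(snp, accepted$target), ]
      j <- match(prow$proxy, gm$variants$rsid)
      if (is.na(j)) j <- match(prow$proxy, variant_id(gm$variants))
      eff <- prow$proxy_effect_allele
      via_proxy <- !is.na(j)
    }
    if (is.na(j)) {
      missing <- missing + 1L
      next
    }
    ref <- gm$variants$ref[j]; alt <- gm$variants$alt[j]
    if (!eff %in% c(ref, alt)) {
      offenders <- c(offenders, sprintf("%s (effect %s vs %s/%s)",
                                        snp, eff, ref, alt))
      next
    }
    d <- gm$dosage[, j]
    if (eff == ref) d <- 2L - d
    miss <- is.na(d)
    if (any(miss)) {
      if (missing_policy == "fail") {
        stop("missing genotype for ", snp, " under missing_policy = 'fail'")
      }
      if (missing_policy == "mean") {
        d[miss] <- mean(d, na.rm = TRUE)
        miss <- rep(FALSE, n)
      }
    }
    term <- ifelse(miss, 0, d) * weights$beta[i]
    score <- score + term
    used <- used + as.integer(!miss)
    missing <- missing + as.integer(miss)
    if (via_proxy) proxied <- proxied + as.integer(!miss)
  }
  if (length(offenders)) {
    stop("effect allele matches neither record allele for: ",
         paste(offenders, collapse = "; "))
  }
  data.frame(sample_id = ids, score = score, n_snps_used = used,
             n_missing = missing, n_proxied = proxied,
             stringsAsFactors = FALSE)
}

#' Search an LD reference panel for proxy SNPs
#'
#' For each missing weight-table SNP, candidate proxies are the reference
#' panel variants (other than the target) that are also present in the
#' cohort; candidates are ranked by squared dosage correlation with the
#' target in the reference panel and the best is accepted only when its
#' r-squared strictly exceeds `r2_min` (ties broken toward the lower
#' genomic position). The accepted proxy inherits the target's original
#' effect size; its effect allele is oriented so that its dosage
#' correlates positively with the target's effect-allele dosage.
#'
#' @param missing_snps character vector of weight-table SNP ids (rsid or
#'   key) absent from the cohort.
#' @param ld_reference reference-panel [genotype_matrix()].
#' @param cohort_gm the cohort [genotype_matrix()] the proxy must be
#'   present in.
#' @param weights the [read_weights()] table (effect alleles of the
#'   targets).
#' @param r2_min acceptance threshold (default 0.8, strict `>`).
#' @return `data.frame(target, proxy, r2, accepted, reason,
#'   proxy_effect_allele)`, one row per missing SNP.
#' @export
find_proxies <- function(missing_snps, ld_reference, cohort_gm, weights,
                         r2_min = 0.8) {
  ref_ids <- gm_all_ids(ld_reference)
  coh_ids <- gm_all_ids(cohort_gm)
  rows <- lapply(missing_snps, function(snp) {
    none <- function(reason) data.frame(
      target = snp, proxy = NA_character_, r2 = NA_real_, accepted = FALSE,
      reason = reason, proxy_effect_allele = NA_character_,
      stringsAsFactors = FALSE
    )
    t_idx <- match_either(snp, ld_reference)
    if (is.na(t_idx)) return(none("target_not_in_reference"))
    cand <- which(seq_len(n_variants(ld_reference)) != t_idx &
                    (ref_ids$key %in% coh_ids$key |
                       (!is.na(ref_ids$rsid) & ref_ids$rsid %in% coh_ids$rsid)))
    if (!length(cand)) return(none("none_found"))
    eff <- weights$effect_allele[match(snp, weights$snp)]
    td <- ld_reference$dosage[, t_idx]
    if (!is.na(eff) && eff == ld_reference$variants$ref[t_idx]) td <- 2L - td
    r <- suppressWarnings(stats::cor(td, ld_reference$dosage[, cand],
                                     use = "pairwise.complete.obs"))
    r <- as.vector(r)
    r[is.na(r)] <- 0
    r2 <- r^2
    best <- cand[order(-r2, ld_reference$variants$pos[cand])][1]
    b_r <- r[match(best, cand)]
    b_r2 <- r2[match(best, cand)]
    if (b_r2 <= r2_min) {
      out <- none("r2_below_threshold")
      out$proxy <- ref_ids$label[best]; out$r2 <- b_r2
      return(out)
    }
    data.frame(
      target = snp, proxy = ref_ids$label[best], r2 = b_r2, accepted = TRUE,
      reason = "ok",
      proxy_effect_allele = if (b_r >= 0) ld_reference$variants$alt[best]
        else ld_reference$variants$ref[best],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @keywords internal
gm_all_ids <- function(gm) {
  key <- variant_id(gm$variants)
  rsid <- gm$variants$rsid
  list(key = key, rsid = rsid,
       label = ifelse(is.na(rsid), key, rsid))
}

#' @keywords internal
match_either <- function(snp, gm) {
  j <- match(snp, gm$variants$rsid)
  if (is.na(j)) j <- match(snp, variant_id(gm$variants))
  j
}

#' Compare risk-score distributions between groups
#'
#' Assumption-gated location test: when Shapiro-Wilk normality holds in
#' both groups and Levene's test (mean-centered) finds homogeneous
#' variances, both at significance `alpha`, the Student t-test is used;
#' otherwise the Wilcoxon rank-sum test. The Levene variance p-value and
#' a logistic-regression (group on score) Wald p-value are always
#' reported alongside.
#'
#' @param scores [compute_grs()] output (or any `data.frame` with
#'   `sample_id` and `score`).
#' @param cohort a [cohort_table()].
#' @param alpha significance level of the assumption gates (default
#'   0.05).
#' @return list with `location_test` (name of the test chosen),
#'   `location_p`, `variance_p` (Levene), `logistic_p`, and the per-group
#'   Shapiro p-values.
#' @export
compare_scores <- function(scores, cohort, alpha = 0.05) {
  grp <- group_of(cohort, scores$sample_id)
  x <- scores$score[grp == "CASE"]
  y <- scores$score[grp == "CONTROL"]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 samples per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(list(location_test = "undefined (zero variance)",
                location_p = NA_real_, variance_p = NA_real_,
                logistic_p = NA_real_,
                shapiro_p = c(CASE = NA_real_, CONTROL = NA_real_)))
  }
  shap <- vapply(list(x, y), function(v) {
    if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000) {
      return(NA_real_)
    }
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  g <- factor(c(rep("CASE", length(x)), rep("CONTROL", length(y))))
  lev <- car::leveneTest(c(x, y) ~ g, center = "mean")
  lev_p <- lev[["Pr(>F)"]][1]
  normal_ok <- all(is.na(shap) | shap > alpha) && !all(is.na(shap))
  var_ok <- !is.na(lev_p) && lev_p > alpha
  if (normal_ok && var_ok) {
    loc <- stats::t.test(x, y, var.equal = TRUE)
    test <- "t-test"
  } else {
    loc <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    test <- "wilcoxon"
  }
  fit <- suppressWarnings(stats::glm((g == "CASE") ~ c(x, y),
                                     family = stats::binomial()))
  log_p <- summary(fit)$coefficients[2, 4]
  list(location_test = test, location_p = loc$p.value,
       variance_p = lev_p, logistic_p = log_p,
       shapiro_p = c(CASE = shap[1], CONTROL = shap[2]))
}
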