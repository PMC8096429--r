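#' Allelic 2x2 counts for one variant
#'
#' Allele counts (2 x homozygotes + heterozygotes) per group; missing
#' genotypes are excluded from the denominators.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a [cohort_table()].
#' @param variant variant id (`chrom:pos:ref:alt`), rsid, or column index.
#' @return list with `table` (2x2 matrix, rows CASE/CONTROL, columns
#'   ALT/REF), `freq_case`, `freq_ctrl`.
#' @export
allelic_counts <- function(gm, cohort, variant) {
  j <- resolve_variant(gm, variant)
  d <- gm$dosage[, j]
  grp <- group_of(cohort, rownames(gm$dosage))
  counts <- function(g) {
    x <- d[grp == g & !is.na(d)]
    c(alt = sum(x), ref = 2L * length(x) - sum(x))
  }
  ca <- counts("CASE"); co <- counts("CONTROL")
  tab <- rbind(CASE = ca, CONTROL = co)
  colnames(tab) <- c("ALT", "REF")
  list(table = tab,
       freq_case = unname(ca["alt"] / sum(ca)),
       freq_ctrl = unname(co["alt"] / sum(co)))
}

#' @keywords internal
resolve_variant <- function(gm, variant) {
  if (is.numeric(variant)) return(as.integer(variant))
  j <- match(variant, variant_id(gm$variants))
  if (is.na(j)) j <- match(variant, gm$variants$rsid)
  if (is.na(j)) stop("variant not found: ", variant)
  j
}

#' Per-variant logistic association with covariates
#'
#' Additive-dosage logistic regression of case status, fitted by
#' iteratively reweighted least squares (at most 50 iterations, deviance
#' tolerance 1e-8), reporting the Wald odds ratio, 95% CI and p-value per
#' variant. Non-convergence or separation (|beta| > 15) is flagged, with
#' the p-value left absent rather than reported silently.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a [cohort_table()]; samples with unknown sex are dropped
#'   when sex is a covariate.
#' @param covariates character vector of `cohort` columns to adjust for
#'   (default `"sex"`; use `character(0)` for the crude model).
#' @return `data.frame`, one row per variant: variant key columns, `or`,
#'   `ci_low`, `ci_high`, `p`, `freq_case`, `freq_ctrl`, `converged`.
#' @export
logistic_assoc <- function(gm, cohort, covariates = "sex") {
  assert_two_groups(cohort)
  ids <- rownames(gm$dosage)
  grp <- group_of(cohort, ids)
  y <- as.integer(grp == "CASE")
  covs <- NULL
  keep <- rep(TRUE, length(ids))
  if (length(covariates)) {
    covs <- cohort[match(ids, cohort$sample_id), covariates, drop = FALSE]
    if ("sex" %in% covariates) {
      keep <- covs$sex %in% c("M", "F")
      covs$sex <- as.integer(covs$sex == "F")
    }
    covs <- as.data.frame(lapply(covs, as.numeric))
  }
  res <- vector("list", n_variants(gm))
  for (j in seq_len(n_variants(gm))) {
    g <- gm$dosage[, j]
    ok <- keep & !is.na(g)
    df <- data.frame(y = y[ok], g = g[ok])
    if (!is.null(covs)) df <- cbind(df, covs[ok, , drop = FALSE])
    or <- ci_lo <- ci_hi <- p <- NA_real_
    conv <- FALSE
    if (stats::var(df$g) > 0 && length(unique(df$y)) == 2) {
      fit <- suppressWarnings(stats::glm(
        y ~ ., data = df, family = stats::binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 50)
      ))
      co <- summary(fit)$coefficients
      if ("g" %in% rownames(co)) {
        beta <- co["g", "Estimate"]
        se <- co["g", "Std. Error"]
        conv <- fit$converged && abs(beta) <= 15
        if (conv) {
          or <- exp(beta)
          ci_lo <- exp(beta - stats::qnorm(0.975) * se)
          ci_hi <- exp(beta + stats::qnorm(0.975) * se)
          p <- co["g", "Pr(>|z|)"]
        }
      }
    }
    fc <- allelic_counts(gm, cohort, j)
    res[[j]] <- data.frame(or = or, ci_low = ci_lo, ci_high = ci_hi, p = p,
                           freq_case = fc$freq_case,
                           freq_ctrl = fc$freq_ctrl, converged = conv)
  }
  cbind(gm$variants, do.call(rbind, res))
}

#' Permutation-based family-wise multiplicity adjustment (max-T)
#'
#' Case/control labels are permuted; the adjusted p-value of variant `j`
#' is the smoothed proportion of permutations whose genome-wide minimum
#' nominal p-value is at most the observed nominal p of `j`:
#' `(1 + #perm) / (n_perm + 1)`. The per-variant statistic is the allelic
#' trend chi-square (`n * r^2` of dosage against status, 1 df) on
#' mean-imputed dosages, so the scan is fully vectorized. This is a
#' transparent, seed-controlled stand-in for sliding-window adjustment
#' tools; it controls the family-wise error rate but does not model local
#' LD windows.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a [cohort_table()].
#' @param n_perm number of permutations (at least 100).
#' @param seed optional integer seed.
#' @return `data.frame` with the variant keys, `p_nominal` and
#'   `p_adjusted`.
#' @export
permutation_adjust <- function(gm, cohort, n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  assert_two_groups(cohort)
  y <- as.integer(group_of(cohort, rownames(gm$dosage)) == "CASE")
  d <- gm$dosage
  mu <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mu[j]
  trend_p <- function(yy) {
    r <- suppressWarnings(stats::cor(yy, d))
    r[is.na(r)] <- 0
    stats::pchisq(length(yy) * r^2, df = 1, lower.tail = FALSE)
  }
  p_obs <- as.vector(trend_p(y))
  min_p <- replicate(n_perm, min(trend_p(sample(y))))
  p_adj <- vapply(p_obs, function(p) (1 + sum(min_p <= p)) / (n_perm + 1),
                  numeric(1))
  cbind(gm$variants,
        data.frame(p_nominal = p_obs, p_adjusted = pmax(p_adj, p_obs)))
}

#' Allele-frequency trajectory of a variant across cohorts
#'
#' Reports the alternate-allele frequency of one variant in each supplied
#' cohort, ordered as given with the extreme-age cohort first. The
#' U-shape flag is true when the extreme-age cohort's frequency strictly
#' exceeds the frequency in every younger cohort.
#'
#' @param variant variant id or rsid.
#' @param cohorts named list of [genotype_matrix()] objects, the
#'   extreme-age cohort first; names are the cohort labels.
#' @return `data.frame(label, af, present)` with attribute `"u_shape"`.
#' @export
af_trajectory <- function(variant, cohorts) {
  if (is.null(names(cohorts))) stop("cohorts must be a named list")
  rows <- lapply(names(cohorts), function(lab) {
    gm <- cohorts[[lab]]
    j <- tryCatch(resolve_variant(gm, variant), error = function(e) NA)
    af <- if (is.na(j)) NA_real_ else unname(allele_freq(gm)[j])
    data.frame(label = lab, af = af, present = !is.na(j),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  u <- if (nrow(out) > 1 && all(!is.na(out$af))) {
    out$af[1] > max(out$af[-1])
  } else NA
  attr(out, "u_shape") <- u
  out
}
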