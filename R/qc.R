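#' Quality-control configuration
#'
#' Defaults follow standard case-control GWAS practice for
#' deep-sequencing cohorts: variants with call rate below 98% are removed,
#' common-variant analyses keep minor allele frequency strictly above 5%,
#' LD pruning scans windows of 50 SNPs advanced by 5 removing one of any
#' pair with r-squared above 0.2, and samples are excluded when a
#' displayed principal component (or heterozygosity / missingness) lies
#' more than 3 standard deviations from the cohort mean.
#'
#' @param min_variant_call_rate minimum call rate to retain a variant.
#' @param ld_window,ld_step,ld_r2_max LD-pruning window (SNPs), step
#'   (SNPs) and maximum pairwise r-squared.
#' @param pc_sd_threshold principal-component outlier threshold in SDs.
#' @param maf_min_common MAF threshold of the common-variant filter
#'   (strictly greater retained).
#' @param het_sd_threshold heterozygosity / missingness outlier threshold
#'   in SDs.
#' @param x_het_max_male X-chromosome heterozygosity above which a sample
#'   is called genetically female (no published threshold exists for the
#'   check; 0.2 is configurable).
#' @return list of validated settings.
#' @export
qc_config <- function(min_variant_call_rate = 0.98, ld_window = 50,
                      ld_step = 5, ld_r2_max = 0.2, pc_sd_threshold = 3,
                      maf_min_common = 0.05, het_sd_threshold = 3,
                      x_het_max_male = 0.2) {
  stopifnot(min_variant_call_rate > 0, min_variant_call_rate <= 1,
            ld_window >= 2, ld_step >= 1, ld_r2_max > 0,
            pc_sd_threshold > 0, het_sd_threshold > 0)
  list(min_variant_call_rate = min_variant_call_rate, ld_window = ld_window,
       ld_step = ld_step, ld_r2_max = ld_r2_max,
       pc_sd_threshold = pc_sd_threshold, maf_min_common = maf_min_common,
       het_sd_threshold = het_sd_threshold, x_het_max_male = x_het_max_male)
}

#' Variant-level filters: call rate and minor allele frequency
#'
#' Variants with call rate strictly below the threshold are removed. When
#' `maf_filter` is given, only variants with minor allele frequency
#' strictly greater than the threshold are retained (so MAF exactly at the
#' threshold is removed, the literal reading of "MAF > 5%"). A variant
#' with no missingness is never removed unless a MAF filter applies.
#'
#' @param gm a [genotype_matrix()].
#' @param qc a [qc_config()].
#' @param maf_filter optional MAF threshold (e.g. `0.05` for the
#'   common-variant analysis).
#' @return list with `genotypes` (the filtered matrix) and `report`
#'   (`data.frame(variant, reason)` of removals).
#' @export
filter_variants <- function(gm, qc = qc_config(), maf_filter = NULL) {
  if (n_variants(gm) == 0) stop("empty genotype matrix")
  cr <- call_rate(gm)
  low_cr <- cr < qc$min_variant_call_rate
  reason <- ifelse(low_cr, "call_rate", NA_character_)
  if (!is.null(maf_filter)) {
    low_maf <- minor_af(gm) <= maf_filter
    reason[is.na(reason) & low_maf] <- "maf"
  }
  drop <- !is.na(reason)
  report <- data.frame(variant = variant_id(gm$variants)[drop],
                       reason = reason[drop], stringsAsFactors = FALSE)
  list(genotypes = subset_variants(gm, !drop), report = report)
}

#' Sample-level quality control
#'
#' Flags samples whose heterozygosity rate or genotype missingness lies
#' more than `het_sd_threshold` standard deviations from the cohort mean,
#' and checks reported sex against X-chromosome heterozygosity when
#' X-linked variants are present (het rate at or below
#' `x_het_max_male` is called male, above it female).
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a [cohort_table()].
#' @param qc a [qc_config()].
#' @return list with `kept` (sample ids passing) and `report` (per-sample
#'   statistics, flags, and sex concordance).
#' @export
sample_qc <- function(gm, cohort, qc = qc_config()) {
  if (n_samples(gm) < 3) stop("need at least 3 samples for outlier SDs")
  d <- gm$dosage
  het <- rowMeans(d == 1L, na.rm = TRUE)
  miss <- rowMeans(is.na(d))
  zof <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  het_z <- zof(het)
  miss_z <- zof(miss)
  flagged <- abs(het_z) > qc$het_sd_threshold |
    abs(miss_z) > qc$het_sd_threshold
  x_idx <- gm$variants$chrom %in% c("X", "chrX", "23")
  sex_discordant <- rep(NA, n_samples(gm))
  x_het <- rep(NA_real_, n_samples(gm))
  if (any(x_idx)) {
    x_het <- rowMeans(d[, x_idx, drop = FALSE] == 1L, na.rm = TRUE)
    inferred <- ifelse(x_het <= qc$x_het_max_male, "M", "F")
    reported <- cohort$sex[match(rownames(d), cohort$sample_id)]
    sex_discordant <- reported %in% c("M", "F") & reported != inferred
  }
  report <- data.frame(
    sample_id = rownames(d), het_rate = het, miss_rate = miss,
    het_z = het_z, miss_z = miss_z, x_het = x_het,
    flagged = flagged, sex_discordant = sex_discordant,
    stringsAsFactors = FALSE
  )
  list(kept = rownames(d)[!flagged & !(sex_discordant %in% TRUE)],
       report = report)
}

#' Windowed LD pruning
#'
#' Greedy scan per chromosome over position-sorted variants: within each
#' window of `ld_window` SNPs every still-retained pair is examined and,
#' when the squared Pearson correlation of dosages exceeds `ld_r2_max`,
#' the later-positioned member is removed (a deterministic tie-break);
#' the window then advances by `ld_step` SNPs. The LD measure is the
#' composite genotypic r-squared, which requires no phase.
#'
#' @param gm a [genotype_matrix()].
#' @param qc a [qc_config()].
#' @return character vector of retained variant ids, in position order.
#' @export
ld_prune <- function(gm, qc = qc_config()) {
  ids <- variant_id(gm$variants)
  ord <- order(gm$variants$chrom, gm$variants$pos)
  keep <- rep(TRUE, length(ids))
  for (chr in unique(gm$variants$chrom)) {
    idx <- ord[gm$variants$chrom[ord] == chr]
    n <- length(idx)
    if (n < 2) next
    d <- gm$dosage[, idx, drop = FALSE]
    starts <- seq(1L, max(1L, n - 1L), by = qc$ld_step)
    for (s in starts) {
      win <- s:min(s + qc$ld_window - 1L, n)
      act <- win[keep[idx[win]]]
      if (length(act) < 2) next
      cm <- suppressWarnings(stats::cor(d[, act, drop = FALSE],
                                        use = "pairwise.complete.obs"))
      cm[is.na(cm)] <- 0
      for (i in seq_along(act)[-length(act)]) {
        if (!keep[idx[act[i]]]) next
        for (j in (i + 1):length(act)) {
          if (!keep[idx[act[j]]]) next
          if (cm[i, j]^2 > qc$ld_r2_max) {
            # variants are position-sorted: act[j] is the later one
            keep[idx[act[j]]] <- FALSE
          }
        }
      }
      if (win[length(win)] == n) break
    }
  }
  ids[ord][keep[ord]]
}

#' Principal-component outlier exclusion
#'
#' PCA is run on mean-imputed, unit-variance-standardized dosages (the
#' matrix should already be LD-pruned and MAF-filtered). A sample is
#' excluded when, on either of the first `n_pcs` components, its score
#' lies strictly more than `pc_sd_threshold` standard deviations from the
#' mean. When `strata` is given (e.g. sampling location), means and SDs
#' are computed within each stratum; the default uses the whole cohort.
#' Exactly one exclusion pass is performed.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a [cohort_table()].
#' @param qc a [qc_config()].
#' @param n_pcs number of displayed components screened (default 2).
#' @param strata optional character vector naming a `cohort` column (such
#'   as `"region"`) to stratify the outlier statistics.
#' @return list with `excluded` (sample ids) and `scores` (PC score
#'   matrix).
#' @export
pc_outliers <- function(gm, cohort, qc = qc_config(), n_pcs = 2,
                        strata = NULL) {
  d <- gm$dosage
  if (n_pcs > min(dim(d)) - 1) stop("more PCs requested than the data rank")
  mu <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mu[j]
  sds <- apply(d, 2, stats::sd)
  ok <- sds > 0
  z <- scale(d[, ok, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  strat <- if (is.null(strata)) rep("all", nrow(scores)) else
    as.character(cohort[[strata]][match(rownames(scores),
                                        cohort$sample_id)])
  out <- rep(FALSE, nrow(scores))
  for (g in unique(strat)) {
    rows <- strat == g
    for (k in seq_len(n_pcs)) {
      x <- scores[rows, k]
      s <- stats::sd(x)
      if (is.na(s) || s == 0) next
      out[rows] <- out[rows] | abs(x - mean(x)) > qc$pc_sd_threshold * s
    }
  }
  list(excluded = rownames(scores)[out], scores = scores)
}
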