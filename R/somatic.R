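#' Somatic-caller configuration
#'
#' Defaults reproduce the clonal-hematopoiesis calling rules over the
#' seven-gene panel: single-nucleotide variants only, alternate allele
#' fraction strictly above 10% after normalization, normalized coverage of
#' at least 10 reads and normalized alternate count of at least 3 reads,
#' recurrence at most one control carrier and at most two case carriers,
#' a population allele-frequency ceiling of 0.025% (applied only when the
#' annotation is supplied), germline exclusion by equal-tail binomial
#' tests at significance 0.05 against the group heterozygous mean
#' (estimated as the median in-band allele fraction, band 0.2-0.8, unless
#' overridden) and against homozygous means 1% / 99%, and a separately
#' recorded putative-somatic screen against mean 50% at designed false
#' positive rate 1e-5.
#'
#' @param genes panel gene names.
#' @param af_min minimum (strict) normalized allele fraction.
#' @param min_norm_coverage,min_norm_alt minimum normalized coverage and
#'   alternate reads.
#' @param max_ctrl_carriers,max_case_carriers recurrence ceilings per
#'   group.
#' @param designed_fpr false positive rate of the putative-somatic screen.
#' @param alpha_germline significance threshold of the germline exclusion
#'   tests.
#' @param het_band allele-fraction band used to estimate the heterozygous
#'   mean.
#' @param hom_means binomial means of the homozygous-reference and
#'   homozygous-alternate nulls.
#' @param pop_af_max population allele-frequency ceiling.
#' @param het_mean_override optional named vector
#'   `c(CASE = , CONTROL = )` fixing the heterozygous means instead of
#'   estimating them (the study-scale reference values are 0.4643 for
#'   cases and 0.4713 for controls).
#' @return list of validated settings.
#' @export
somatic_config <- function(genes = c("ASXL1", "DNMT3A", "JAK2", "PPM1D",
                                     "TET2", "TP53", "SF3B1"),
                           af_min = 0.10, min_norm_coverage = 10,
                           min_norm_alt = 3, max_ctrl_carriers = 1,
                           max_case_carriers = 2, designed_fpr = 1e-5,
                           alpha_germline = 0.05, het_band = c(0.2, 0.8),
                           hom_means = c(0.01, 0.99), pop_af_max = 0.00025,
                           het_mean_override = NULL) {
  stopifnot(af_min > 0, af_min < 0.5, designed_fpr < alpha_germline,
            het_band[1] > 0, het_band[2] < 1, het_band[1] < het_band[2])
  list(genes = genes, af_min = af_min,
       min_norm_coverage = min_norm_coverage, min_norm_alt = min_norm_alt,
       max_ctrl_carriers = max_ctrl_carriers,
       max_case_carriers = max_case_carriers, designed_fpr = designed_fpr,
       alpha_germline = alpha_germline, het_band = het_band,
       hom_means = hom_means, pop_af_max = pop_af_max,
       het_mean_override = het_mean_override)
}

#' Quantile-normalize case coverage onto the control distribution
#'
#' The case coverage distribution is transformed so that its cumulative
#' distribution matches the control one: each case value is replaced by
#' the control empirical quantile at its own ECDF position, with linear
#' interpolation between control order statistics (ECDF positions
#' `(rank - 1) / (n - 1)` with average ranks for ties, so identical
#' distributions map to themselves exactly). Control coverages pass
#' through unchanged downstream.
#'
#' @param case_cov numeric vector of case coverages.
#' @param ctrl_cov numeric vector of control coverages (a single-valued
#'   control distribution yields a constant map).
#' @return numeric vector of normalized case coverages, parallel to
#'   `case_cov`.
#' @export
quantile_normalize_coverage <- function(case_cov, ctrl_cov) {
  if (!length(case_cov) || !length(ctrl_cov)) {
    stop("both coverage vectors must be non-empty")
  }
  n <- length(case_cov)
  p <- if (n == 1L) 0.5 else (rank(case_cov, ties.method = "average") - 1) /
    (n - 1)
  unname(stats::quantile(ctrl_cov, probs = p, type = 7, names = FALSE))
}

#' Recompute alternate/reference counts at normalized coverage
#'
#' `alt = round(frequency * normalized coverage)` with banker's
#' (half-to-even) rounding, which is unbiased over many sites;
#' `ref = round(normalized coverage) - alt`, so the two counts always sum
#' to the rounded coverage.
#'
#' @param frequency alternate allele fraction in `[0, 1]`.
#' @param norm_coverage normalized coverage (non-negative real).
#' @return `data.frame(alt, ref, coverage)` of integer counts.
#' @export
recompute_counts <- function(frequency, norm_coverage) {
  stopifnot(all(frequency >= 0 & frequency <= 1, na.rm = TRUE),
            all(norm_coverage >= 0))
  cov_r <- as.integer(round(norm_coverage))
  alt <- as.integer(round(frequency * norm_coverage))
  alt <- pmin(alt, cov_r)
  data.frame(alt = alt, ref = cov_r - alt, coverage = cov_r)
}

#' Estimate the heterozygous binomial mean
#'
#' The median alternate-allele fraction of sites whose fraction lies in
#' the heterozygous band (default `[0.2, 0.8]`, inclusive). Computed per
#' group by the caller. An empty band is an error: supply
#' `het_mean_override` in [somatic_config()] instead.
#'
#' @param frequencies numeric vector of allele fractions (or a
#'   `site_read_counts` table, whose `frequency` column is used).
#' @param band inclusive lower/upper band bounds.
#' @return the median in-band fraction.
#' @export
estimate_het_mean <- function(frequencies, band = c(0.2, 0.8)) {
  if (is.data.frame(frequencies)) frequencies <- frequencies$frequency
  inband <- frequencies[!is.na(frequencies) & frequencies >= band[1] &
                          frequencies <= band[2]]
  if (!length(inband)) {
    stop("no sites in the heterozygous band; use het_mean_override")
  }
  stats::median(inband)
}

#' @keywords internal
#' Vectorized site classification given normalized counts.
#' `recurrent` and `pop_af` are precomputed by the cohort-level caller.
classify_rows <- function(is_snv, frequency, alt_n, cov_n, group, config,
                          het_means, recurrent = FALSE, pop_af = NA_real_) {
  n <- length(frequency)
  recurrent <- rep_len(recurrent, n)
  pop_af <- rep_len(pop_af, n)
  cls <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  p_het <- p_lo <- p_hi <- rep(NA_real_, n)
  put <- rep(NA, n)

  excl <- function(cond, why) {
    hit <- is.na(cls) & cond
    cls[hit] <<- "EXCLUDED"
    reason[hit] <<- why
  }
  excl(!is_snv, "indel")
  excl(is.na(frequency), "zero_coverage")
  excl(frequency %in% c(0, 1), "fixed")
  excl(cov_n < config$min_norm_coverage, "low_coverage")
  excl(alt_n < config$min_norm_alt, "low_alt")
  excl(frequency <= config$af_min, "low_af")
  excl(recurrent, "recurrent")
  excl(!is.na(pop_af) & pop_af >= config$pop_af_max, "common_population")

  open <- which(is.na(cls))
  if (length(open)) {
    hm <- het_means[group[open]]
    if (anyNA(hm)) stop("missing group heterozygous mean")
    p_lo[open] <- binom_two_sided(alt_n[open], cov_n[open],
                                  config$hom_means[1])
    p_hi[open] <- binom_two_sided(alt_n[open], cov_n[open],
                                  config$hom_means[2])
    p_het[open] <- binom_two_sided(alt_n[open], cov_n[open], hm)
    put[open] <- putative_flag(alt_n[open], cov_n[open],
                               config$designed_fpr)
    a <- config$alpha_germline
    hom <- p_lo[open] >= a | p_hi[open] >= a
    cls[open[hom]] <- "GERMLINE_HOM"
    het <- !hom & p_het[open] >= a
    cls[open[het]] <- "GERMLINE_HET"
    cls[open[!hom & !het]] <- "SOMATIC"
  }
  data.frame(classification = cls, reason = reason, p_het = p_het,
             p_hom_low = p_lo, p_hom_high = p_hi, putative_flag = put,
             stringsAsFactors = FALSE)
}

#' Classify a single site observation
#'
#' One-site convenience wrapper around the caller's classification
#' pipeline: filters (SNV, fixed allele fraction, normalized depth,
#' normalized alternate reads, allele fraction), then binomial exclusion
#' of homozygous (means 1%/99%) and heterozygous (group mean) germline
#' hypotheses at `alpha_germline`; what survives is SOMATIC, with the
#' designed-FPR putative flag recorded alongside. Recurrence and
#' population-frequency exclusion require cohort context and are applied
#' by [call_cohort()].
#'
#' @param ref,alt allele strings (SNV check).
#' @param frequency alternate allele fraction.
#' @param alt_n,cov_n normalized alternate reads and coverage (integers,
#'   see [recompute_counts()]).
#' @param group `"CASE"` or `"CONTROL"`.
#' @param config a [somatic_config()].
#' @param het_means named vector `c(CASE = , CONTROL = )`.
#' @return one-row `data.frame` with `classification`, `reason` and the
#'   germline-test p-values.
#' @export
classify_site <- function(ref, alt, frequency, alt_n, cov_n, group,
                          config = somatic_config(), het_means) {
  classify_rows(nchar(ref) == 1L & nchar(alt) == 1L, frequency, alt_n,
                cov_n, group, config, het_means)
}

#' Call somatic mutations across a cohort
#'
#' The full caller: restricts to the panel genes, quantile-normalizes the
#' pooled case coverage distribution onto the control one (one global
#' map; control coverages pass through), recomputes alternate/reference
#' counts at normalized coverage, estimates per-group heterozygous means
#' (unless overridden), applies the cohort recurrence filter (a variant
#' with alternate evidence in more than `max_ctrl_carriers` controls or
#' more than `max_case_carriers` cases is excluded everywhere), then
#' classifies every (sample, site) observation. Deterministic given its
#' inputs.
#'
#' @param counts a [site_read_counts()] table.
#' @param cohort a [cohort_table()]; at least one control is required
#'   (the normalization target).
#' @param config a [somatic_config()].
#' @param annotations optional `data.frame` keyed by `chrom`, `pos`,
#'   `ref`, `alt` with any of `population_af`, `impact`,
#'   `cosmic_heme_count`.
#' @return `data.frame`, one row per observation, with normalized counts,
#'   classification, exclusion reason, germline-test p-values and the
#'   putative flag; attribute `"het_means"` records the means used.
#' @export
call_cohort <- function(counts, cohort, config = somatic_config(),
                        annotations = NULL) {
  grp <- group_of(cohort, counts$sample_id)
  if (anyNA(grp)) stop("count rows for samples missing from the cohort")
  if (!any(grp == "CONTROL")) {
    stop("no control samples: coverage normalization undefined")
  }
  panel <- counts$gene %in% config$genes
  counts <- counts[panel, , drop = FALSE]
  grp <- grp[panel]

  is_case <- grp == "CASE"
  norm_cov <- as.numeric(counts$coverage)
  if (any(is_case)) {
    norm_cov[is_case] <- quantile_normalize_coverage(
      counts$coverage[is_case], counts$coverage[!is_case]
    )
  }
  rc <- recompute_counts(ifelse(is.na(counts$frequency), 0,
                                counts$frequency), norm_cov)
  freq <- counts$frequency

  het_means <- config$het_mean_override
  if (is.null(het_means)) {
    fr <- ifelse(rc$coverage > 0, rc$alt / rc$coverage, NA_real_)
    het_means <- c(
      CASE = estimate_het_mean(fr[is_case], config$het_band),
      CONTROL = estimate_het_mean(fr[!is_case], config$het_band)
    )
  }

  # recurrence: count samples per variant with alternate evidence passing
  # the site-level depth/fraction filters
  snv <- nchar(counts$ref) == 1L & nchar(counts$alt) == 1L
  evid <- snv & !is.na(freq) & freq > config$af_min & freq < 1 &
    rc$alt >= config$min_norm_alt & rc$coverage >= config$min_norm_coverage
  vid <- paste(counts$chrom, counts$pos, counts$ref, counts$alt, sep = ":")
  case_n <- tapply(evid & is_case, vid, sum)
  ctrl_n <- tapply(evid & !is_case, vid, sum)
  recurrent <- unname(
    case_n[vid] > config$max_case_carriers |
      ctrl_n[vid] > config$max_ctrl_carriers
  )

  pop_af <- rep(NA_real_, nrow(counts))
  impact <- cosmic <- NULL
  if (!is.null(annotations)) {
    akey <- paste(annotations$chrom, annotations$pos, annotations$ref,
                  annotations$alt, sep = ":")
    m <- match(vid, akey)
    if (!is.null(annotations$population_af)) {
      pop_af <- annotations$population_af[m]
    }
    if (!is.null(annotations$impact)) impact <- annotations$impact[m]
    if (!is.null(annotations$cosmic_heme_count)) {
      cosmic <- annotations$cosmic_heme_count[m]
    }
  }

  cls <- classify_rows(snv, freq, rc$alt, rc$coverage, grp, config,
                       het_means, recurrent = recurrent, pop_af = pop_af)
  out <- data.frame(
    sample_id = counts$sample_id, group = grp, chrom = counts$chrom,
    pos = counts$pos, ref = counts$ref, alt = counts$alt,
    gene = counts$gene, coverage = counts$coverage,
    norm_coverage = rc$coverage, norm_alt = rc$alt, frequency = freq,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, cls)
  if (!is.null(impact)) out$impact <- impact
  if (!is.null(cosmic)) out$cosmic_heme_count <- cosmic
  attr(out, "het_means") <- het_means
  out
}

#' Per-gene and overall group comparison of somatic burden
#'
#' Per-individual somatic mutation counts (zero-filled for
#' mutation-free individuals) are compared between groups with the
#' two-sided Mann-Whitney U test ([mwu_test()]: exact enumeration for
#' small groups, tie-corrected normal approximation otherwise), per gene
#' and overall; per-gene prevalence (fraction of individuals with at
#' least one call) is compared with the Fisher exact test.
#'
#' @param calls output of [call_cohort()].
#' @param cohort a [cohort_table()]; all its samples enter the
#'   denominators.
#' @param genes genes to compare (default: panel genes present in the
#'   calls).
#' @return list with `per_gene` (`data.frame`: gene, medians, MWU p,
#'   prevalences, Fisher p) and `overall` (the same quantities across all
#'   genes together).
#' @export
gene_group_comparison <- function(calls, cohort, genes = NULL) {
  som <- calls[calls$classification == "SOMATIC", , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(calls$gene))
  grp <- as.character(cohort$group)
  count_of <- function(sub) {
    n <- table(factor(sub$sample_id, levels = cohort$sample_id))
    as.integer(n)
  }
  one <- function(sub, label) {
    cnt <- count_of(sub)
    x <- cnt[grp == "CASE"]; y <- cnt[grp == "CONTROL"]
    mwu <- mwu_test(x, y)
    prev_case <- mean(x > 0); prev_ctrl <- mean(y > 0)
    fp <- fisher_exact_2x2(sum(x > 0), sum(x == 0),
                           sum(y > 0), sum(y == 0))$p
    data.frame(gene = label, median_case = stats::median(x),
               median_ctrl = stats::median(y), mwu_p = mwu$p,
               prevalence_case = prev_case, prevalence_ctrl = prev_ctrl,
               prevalence_fisher_p = fp, stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    one(som[som$gene == g, , drop = FALSE], g)
  }))
  list(per_gene = per_gene, overall = one(som, "ALL"))
}

#' Pyrimidine-referenced substitution spectrum
#'
#' Each single-nucleotide substitution is collapsed onto its
#' pyrimidine-referenced representative (`G>A` becomes `C>T`, etc.) and
#' counted over the six classes; counts sum to the number of input calls.
#'
#' @param calls `data.frame` with `ref` and `alt` columns (typically the
#'   SOMATIC subset of [call_cohort()] output).
#' @return named integer vector over `C>A, C>G, C>T, T>A, T>C, T>G`.
#' @export
spectrum <- function(calls) {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  if (!nrow(calls)) {
    return(stats::setNames(integer(length(classes)), classes))
  }
  ref <- calls$ref; alt <- calls$alt
  if (any(nchar(ref) != 1 | nchar(alt) != 1)) {
    stop("spectrum requires single-nucleotide substitutions")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  sub <- factor(paste(ref, alt, sep = ">"), levels = classes)
  if (anyNA(sub)) stop("invalid substitution in input")
  table_out <- table(sub)
  stats::setNames(as.integer(table_out), classes)
}

#' Disruptive (moderate/high-impact) subset and prevalence comparison
#'
#' Keeps SOMATIC calls whose annotated impact is MODERATE or HIGH (the
#' classes likely to disrupt protein function) and recomputes per-group
#' carrier prevalence with a Fisher exact comparison. Unannotated calls
#' are excluded with a warning.
#'
#' @param calls output of [call_cohort()] (must carry an `impact` column,
#'   or supply `annotations`).
#' @param cohort a [cohort_table()].
#' @param annotations optional annotation table (see [call_cohort()]).
#' @return list with `subset` (the kept calls), `prevalence_case`,
#'   `prevalence_ctrl` and `fisher_p`.
#' @export
disruptive_subset <- function(calls, cohort, annotations = NULL) {
  som <- calls[calls$classification == "SOMATIC", , drop = FALSE]
  if (!is.null(annotations)) som <- join_annotations(som, annotations)
  if (is.null(som$impact)) stop("calls carry no impact annotation")
  if (anyNA(som$impact)) {
    warning(sum(is.na(som$impact)), " unannotated call(s) excluded")
    som <- som[!is.na(som$impact), , drop = FALSE]
  }
  keep <- som[som$impact %in% c("MODERATE", "HIGH"), , drop = FALSE]
  grp <- as.character(cohort$group)
  carrier <- cohort$sample_id %in% keep$sample_id
  cc <- sum(carrier & grp == "CASE"); nc <- sum(grp == "CASE")
  cn <- sum(carrier & grp == "CONTROL"); nn <- sum(grp == "CONTROL")
  list(subset = keep,
       prevalence_case = cc / nc, prevalence_ctrl = cn / nn,
       fisher_p = fisher_exact_2x2(cc, nc - cc, cn, nn - cn)$p)
}

#' Candidate-driver flags from haematopoietic malignancy report counts
#'
#' Flags calls reported at least `min_count` times in haematopoietic and
#' lymphoid malignancies; optionally also flags disruptive
#' (MODERATE/HIGH impact) calls when `include_disruptive` is set.
#' Variants absent from the table are never flagged by count.
#'
#' @param calls output of [call_cohort()].
#' @param cosmic_table `data.frame(chrom, pos, ref, alt,
#'   cosmic_heme_count)`.
#' @param min_count flag threshold (default 7).
#' @param include_disruptive also flag MODERATE/HIGH-impact calls.
#' @return the calls with a logical `cosmic_driver` column.
#' @export
cosmic_driver_flags <- function(calls, cosmic_table, min_count = 7,
                                include_disruptive = FALSE) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  cnt <- cosmic_table$cosmic_heme_count[match(key(calls),
                                              key(cosmic_table))]
  flag <- !is.na(cnt) & cnt >= min_count
  if (include_disruptive && !is.null(calls$impact)) {
    flag <- flag | calls$impact %in% c("MODERATE", "HIGH")
  }
  calls$cosmic_driver <- flag
  calls
}
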