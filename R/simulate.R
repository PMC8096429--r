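#' Simulate a two-group genotype cohort
#'
#' Control genotypes are drawn under Hardy-Weinberg equilibrium at minor
#' allele frequencies sampled from `maf_range`; at each planted effect
#' locus the case allele odds equal the control odds times the allelic
#' odds ratio, and case genotypes are drawn under Hardy-Weinberg at the
#' resulting frequency. Default cohort composition mirrors the study
#' design this package targets: 81 cases (18 M, 63 F) aged 105+ and 36
#' younger controls (13 M, 23 F).
#'
#' @param n_case,n_ctrl group sizes (defaults 81 / 36).
#' @param n_variants number of simulated variants.
#' @param maf_range length-2 numeric, uniform sampling range of the control
#'   allele frequency.
#' @param effect_loci optional `data.frame(index, or)` of planted allelic
#'   odds ratios; all other loci are null (`OR = 1`).
#' @param sex_case,sex_ctrl named integer vectors `c(M = ..., F = ...)`;
#'   scaled proportionally when group sizes differ from the defaults.
#' @param chrom chromosome label for the simulated variants.
#' @param seed optional integer seed; identical seeds reproduce the cohort
#'   exactly.
#' @return list with `genotypes` ([genotype_matrix()]), `cohort`
#'   ([cohort_table()]) and `truth` (`data.frame` of per-variant true
#'   control/case allele frequencies and odds ratios).
#' @export
simulate_cohort <- function(n_case = 81, n_ctrl = 36, n_variants = 1000,
                            maf_range = c(0.05, 0.5), effect_loci = NULL,
                            sex_case = c(M = 18, F = 63),
                            sex_ctrl = c(M = 13, F = 23),
                            chrom = "1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  af_ctrl <- stats::runif(n_variants, maf_range[1], maf_range[2])
  or <- rep(1, n_variants)
  if (!is.null(effect_loci)) {
    idx <- as.integer(effect_loci$index)
    if (any(idx < 1 | idx > n_variants)) stop("effect locus index out of range")
    if (any(effect_loci$or <= 0)) stop("odds ratios must be positive")
    or[idx] <- effect_loci$or
  }
  if (any((af_ctrl %in% c(0, 1)) & or != 1)) {
    stop("cannot plant an effect at a fixed locus (allele frequency 0 or 1)")
  }
  odds_case <- or * af_ctrl / (1 - af_ctrl)
  af_case <- odds_case / (1 + odds_case)
  d_case <- matrix(stats::rbinom(n_case * n_variants, 2L,
                                 rep(af_case, each = n_case)),
                   nrow = n_case)
  d_ctrl <- matrix(stats::rbinom(n_ctrl * n_variants, 2L,
                                 rep(af_ctrl, each = n_ctrl)),
                   nrow = n_ctrl)
  dosage <- rbind(d_case, d_ctrl)
  ids <- c(sprintf("case_%03d", seq_len(n_case)),
           sprintf("ctrl_%03d", seq_len(n_ctrl)))
  rownames(dosage) <- ids
  variants <- data.frame(
    chrom = chrom, pos = seq_len(n_variants) * 1000L,
    ref = "A", alt = "G",
    rsid = sprintf("sim%d", seq_len(n_variants)),
    stringsAsFactors = FALSE
  )
  cohort <- cohort_table(
    sample_id = ids,
    group = rep(c("CASE", "CONTROL"), c(n_case, n_ctrl)),
    sex = c(scaled_sexes(sex_case, n_case), scaled_sexes(sex_ctrl, n_ctrl))
  )
  truth <- data.frame(index = seq_len(n_variants), af_ctrl = af_ctrl,
                      af_case = af_case, or = or)
  list(genotypes = genotype_matrix(dosage, variants),
       cohort = cohort, truth = truth)
}

#' @keywords internal
scaled_sexes <- function(counts, n) {
  m <- round(n * counts[["M"]] / sum(counts))
  rep(c("M", "F"), c(m, n - m))
}

#' Construct a phased-haplotype set
#'
#' @param alleles character matrix, haplotypes in rows, markers in columns.
#' @param haplotype_id,sample_id,group parallel vectors, one per haplotype;
#'   each diploid sample must contribute exactly two haplotypes.
#' @param markers `data.frame(chrom, pos, ref, alt, rsid)`, one row per
#'   marker.
#' @return object of class `phased_haplotypes`.
#' @export
phased_haplotypes <- function(alleles, haplotype_id, sample_id, group,
                              markers) {
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != length(haplotype_id)) stop("haplotype count mismatch")
  if (ncol(alleles) != nrow(markers)) stop("marker count mismatch")
  if (anyDuplicated(haplotype_id)) stop("duplicate haplotype ids")
  per_sample <- table(sample_id)
  if (any(per_sample != 2L)) {
    stop("each diploid sample must contribute exactly two haplotypes")
  }
  rownames(alleles) <- haplotype_id
  out <- list(alleles = alleles, haplotype_id = as.character(haplotype_id),
              sample_id = as.character(sample_id),
              group = as.character(group), markers = markers)
  class(out) <- "phased_haplotypes"
  out
}

#' @export
print.phased_haplotypes <- function(x, ...) {
  cat(sprintf("phased_haplotypes: %d haplotypes x %d markers\n",
              nrow(x$alleles), ncol(x$alleles)))
  invisible(x)
}

#' Simulate phased haplotypes with a planted carrier haplotype
#'
#' One designated carrier allele sequence over the marker window appears
#' with the configured frequency in each group (independent Bernoulli draws
#' per haplotype); non-carriers receive random sequences guaranteed to
#' differ from the carrier sequence in at least one marker. Defaults mirror
#' the haplotype analysis the package targets: 162 case and 72 control
#' haplotypes, carrier frequencies 0.35 / 0.75 over 13 markers.
#'
#' @param n_case_hap,n_ctrl_hap haplotype counts per group (must be even).
#' @param carrier_freq_case,carrier_freq_ctrl carrier-haplotype frequencies
#'   in `[0, 1]`.
#' @param n_markers number of biallelic markers in the window.
#' @param chrom chromosome label.
#' @param seed optional integer seed.
#' @return list with `haplotypes` ([phased_haplotypes()]) and `truth`
#'   (`data.frame(haplotype_id, carrier)` plus the carrier sequence as
#'   attribute `"carrier_sequence"`).
#' @export
simulate_haplotypes <- function(n_case_hap = 162, n_ctrl_hap = 72,
                                carrier_freq_case = 0.35,
                                carrier_freq_ctrl = 0.75,
                                n_markers = 13, chrom = "7", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_markers < 1) stop("n_markers must be >= 1")
  freqs <- c(carrier_freq_case, carrier_freq_ctrl)
  if (any(freqs < 0 | freqs > 1)) stop("carrier frequency outside [0, 1]")
  if (n_case_hap %% 2L || n_ctrl_hap %% 2L) {
    stop("haplotype counts must be even (two per diploid sample)")
  }
  n_h <- n_case_hap + n_ctrl_hap
  group <- rep(c("CASE", "CONTROL"), c(n_case_hap, n_ctrl_hap))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_markers, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  carrier_seq <- ifelse(stats::runif(n_markers) < 0.5, ref, alt)
  carrier <- stats::runif(n_h) < ifelse(group == "CASE", carrier_freq_case,
                                        carrier_freq_ctrl)
  alleles <- matrix(NA_character_, nrow = n_h, ncol = n_markers)
  for (i in seq_len(n_h)) {
    if (carrier[i]) {
      alleles[i, ] <- carrier_seq
    } else {
      repeat {
        s <- ifelse(stats::runif(n_markers) < 0.5, ref, alt)
        if (any(s != carrier_seq)) break
      }
      alleles[i, ] <- s
    }
  }
  sample_id <- rep(c(sprintf("case_%03d", seq_len(n_case_hap / 2)),
                     sprintf("ctrl_%03d", seq_len(n_ctrl_hap / 2))),
                   each = 2)
  hap_id <- paste(sample_id, rep(1:2, n_h / 2), sep = "_")
  markers <- data.frame(
    chrom = chrom, pos = seq_len(n_markers) * 500L, ref = ref, alt = alt,
    rsid = sprintf("hsim%d", seq_len(n_markers)), stringsAsFactors = FALSE
  )
  haps <- phased_haplotypes(alleles, hap_id, sample_id, group, markers)
  truth <- data.frame(haplotype_id = hap_id, carrier = carrier,
                      stringsAsFactors = FALSE)
  attr(truth, "carrier_sequence") <- paste(carrier_seq, collapse = "")
  list(haplotypes = haps, truth = truth)
}

#' Read-count simulation configuration
#'
#' Defaults emulate the sequencing conditions of the targeted study: a
#' seven-gene clonal-hematopoiesis panel, negative-binomial coverage with
#' group means 110x (cases) and 90x (controls), heterozygous allele
#' fraction 0.47 (reference bias pulls observed het fractions slightly
#' below one half), homozygous-alternate fraction 0.99, sequencing error
#' 0.01, and per-individual per-gene somatic clones at uniform VAF in
#' [0.15, 0.4] with prevalence 0.15 in cases and 0.30 in controls (the
#' younger controls carry the heavier clone burden).
#'
#' @param genes panel gene names.
#' @param sites_per_gene germline variant sites simulated per gene.
#' @param germline_af_range uniform range of germline population allele
#'   frequencies at panel sites.
#' @param coverage_mean named vector `c(CASE = , CONTROL = )` of
#'   negative-binomial coverage means.
#' @param coverage_size negative-binomial size (inverse overdispersion).
#' @param p_het,p_hom_alt binomial means of heterozygous and
#'   homozygous-alternate read draws.
#' @param error_rate sequencing error rate in `[0, 0.05]` (binomial mean at
#'   homozygous-reference sites).
#' @param clone_prevalence named vector of per-individual per-gene clone
#'   probabilities.
#' @param clone_vaf_range uniform VAF range of planted clones, within
#'   `(0, 0.5]`.
#' @return list of validated settings.
#' @export
counts_config <- function(genes = c("ASXL1", "DNMT3A", "JAK2", "PPM1D",
                                    "TET2", "TP53", "SF3B1"),
                          sites_per_gene = 5,
                          germline_af_range = c(0.1, 0.5),
                          coverage_mean = c(CASE = 110, CONTROL = 90),
                          coverage_size = 30,
                          p_het = 0.47, p_hom_alt = 0.99,
                          error_rate = 0.01,
                          clone_prevalence = c(CASE = 0.15, CONTROL = 0.30),
                          clone_vaf_range = c(0.15, 0.4)) {
  if (any(clone_vaf_range <= 0) || any(clone_vaf_range > 0.5)) {
    stop("clone VAF bounds must lie within (0, 0.5]")
  }
  if (error_rate < 0 || error_rate > 0.05) {
    stop("error rate must lie in [0, 0.05]")
  }
  list(genes = genes, sites_per_gene = sites_per_gene,
       germline_af_range = germline_af_range,
       coverage_mean = coverage_mean, coverage_size = coverage_size,
       p_het = p_het, p_hom_alt = p_hom_alt, error_rate = error_rate,
       clone_prevalence = clone_prevalence,
       clone_vaf_range = clone_vaf_range)
}

#' Simulate per-site read counts over the gene panel
#'
#' Germline sites draw alternate read counts from a binomial at the mean
#' of the sample's true state (heterozygous `p_het`, homozygous-alternate
#' `p_hom_alt`, homozygous-reference `error_rate`); each individual
#' carries a somatic clone in a gene with the configured per-group
#' prevalence, contributing an individual-unique site whose alternate
#' counts are binomial at the clone's true VAF. Group coverage
#' distributions may differ, which is what the caller's coverage
#' normalization has to undo.
#'
#' @param cohort a [cohort_table()].
#' @param config a [counts_config()].
#' @param seed optional integer seed.
#' @return list with `counts` (a [site_read_counts()] table) and `truth`
#'   (`data.frame` with the true state and VAF of every row).
#' @export
simulate_read_counts <- function(cohort, config = counts_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- config$genes
  n_g <- length(genes)
  spg <- config$sites_per_gene
  bases <- c("A", "C", "G", "T")
  site_gene <- rep(genes, each = spg)
  site_chrom <- rep(as.character(seq_len(n_g) + 10L), each = spg)
  site_pos <- as.integer(1e6 * rep(seq_len(n_g), each = spg) +
                           rep(seq_len(spg), n_g) * 100L)
  site_ref <- sample(bases, n_g * spg, replace = TRUE)
  site_alt <- vapply(site_ref, function(b) sample(setdiff(bases, b), 1),
                     character(1))
  site_af <- stats::runif(n_g * spg, config$germline_af_range[1],
                          config$germline_af_range[2])
  n_s <- nrow(cohort)
  grp <- as.character(cohort$group)

  # germline rows: every sample at every panel site
  geno <- matrix(stats::rbinom(n_s * n_g * spg, 2L, rep(site_af, each = n_s)),
                 nrow = n_s)
  state <- matrix(c("HOM_REF", "HET", "HOM_ALT")[geno + 1L], nrow = n_s)
  pmat <- matrix(config$error_rate, nrow = n_s, ncol = n_g * spg)
  pmat[state == "HET"] <- config$p_het
  pmat[state == "HOM_ALT"] <- config$p_hom_alt
  cov_mu <- config$coverage_mean[grp]
  cov <- matrix(stats::rnbinom(n_s * n_g * spg,
                               mu = rep(cov_mu, n_g * spg),
                               size = config$coverage_size), nrow = n_s)
  alt <- matrix(stats::rbinom(length(cov), as.vector(cov), as.vector(pmat)),
                nrow = n_s)
  germ <- data.frame(
    sample_id = rep(cohort$sample_id, n_g * spg),
    chrom = rep(site_chrom, each = n_s), pos = rep(site_pos, each = n_s),
    ref = rep(site_ref, each = n_s), alt_allele = rep(site_alt, each = n_s),
    gene = rep(site_gene, each = n_s),
    coverage = as.vector(cov), alt_count = as.vector(alt),
    state = as.vector(state), vaf = NA_real_, stringsAsFactors = FALSE
  )

  # somatic clones: per individual per gene, individual-unique positions
  clone_draw <- matrix(stats::runif(n_s * n_g) <
                         config$clone_prevalence[grp], nrow = n_s)
  ci <- which(clone_draw, arr.ind = TRUE)
  if (nrow(ci)) {
    vaf <- stats::runif(nrow(ci), config$clone_vaf_range[1],
                        config$clone_vaf_range[2])
    ref <- sample(bases, nrow(ci), replace = TRUE)
    altb <- vapply(ref, function(b) sample(setdiff(bases, b), 1),
                   character(1))
    ccov <- stats::rnbinom(nrow(ci), mu = cov_mu[ci[, 1]],
                           size = config$coverage_size)
    calt <- stats::rbinom(nrow(ci), ccov, vaf)
    som <- data.frame(
      sample_id = cohort$sample_id[ci[, 1]],
      chrom = as.character(ci[, 2] + 10L),
      pos = as.integer(1e6 * ci[, 2] + 50000L + ci[, 1] * 10L),
      ref = ref, alt_allele = altb, gene = genes[ci[, 2]],
      coverage = ccov, alt_count = calt,
      state = "SOMATIC", vaf = vaf, stringsAsFactors = FALSE
    )
    germ <- rbind(germ, som)
  }
  counts <- site_read_counts(
    sample_id = germ$sample_id, chrom = germ$chrom, pos = germ$pos,
    ref = germ$ref, alt = germ$alt_allele, gene = germ$gene,
    coverage = germ$coverage, alt_count = germ$alt_count
  )
  truth <- germ[, c("sample_id", "chrom", "pos", "state", "vaf")]
  list(counts = counts, truth = truth)
}
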