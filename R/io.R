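#' Read genotypes from VCF or a genotype-matrix TSV
#'
#' VCF input is parsed with \pkg{vcfR}; dosages are alternate-allele counts
#' taken from the `GT` field (`./.` becomes missing). Multi-allelic records
#' are rejected by default because every downstream analysis is biallelic;
#' `multiallelic = "split"` instead expands them into one biallelic record
#' per alternate allele.
#'
#' The matrix TSV format has one row per variant: columns `chrom`, `pos`,
#' `ref`, `alt`, `rsid`, then one column per sample holding dosage 0/1/2 or
#' `NA`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"matrix_tsv"`.
#' @param multiallelic `"reject"` (default) or `"split"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix_tsv"),
                           multiallelic = c("reject", "split")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix_tsv"
  }
  if (format == "vcf") {
    read_genotypes_vcf(path, multiallelic)
  } else {
    read_genotypes_tsv(path)
  }
}

#' @keywords internal
read_genotypes_vcf <- function(path, multiallelic) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  multi <- grepl(",", fix$ALT)
  if (any(multi) && multiallelic == "reject") {
    stop(sprintf(
      "%d multi-allelic record(s) (first at %s:%s); rerun with multiallelic = 'split'",
      sum(multi), fix$CHROM[which(multi)[1]], fix$POS[which(multi)[1]]
    ))
  }
  samples <- colnames(gt)
  rows <- list()
  dose <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    calls <- strsplit(gt[i, ], "[/|]")
    for (j in seq_along(alts)) {
      d <- vapply(calls, function(al) {
        if (length(al) == 0 || anyNA(al) || any(al == ".")) {
          return(NA_integer_)
        }
        sum(al == as.character(j))
      }, integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j],
        rsid = ifelse(is.na(fix$ID[i]) | fix$ID[i] == ".", NA_character_, fix$ID[i]),
        stringsAsFactors = FALSE
      )
      dose[[length(rows)]] <- d
    }
  }
  variants <- do.call(rbind, rows)
  dosage <- do.call(cbind, dose)
  rownames(dosage) <- samples
  genotype_matrix(dosage, variants)
}

#' @keywords internal
read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  meta <- c("chrom", "pos", "ref", "alt", "rsid")
  if ("rsid" %in% names(tab)) tab$rsid[tab$rsid == "NA"] <- NA_character_
  for (s in setdiff(names(tab), meta)) {
    tab[[s]] <- suppressWarnings(as.integer(tab[[s]]))
  }
  if (!all(meta[1:4] %in% names(tab))) {
    stop("matrix TSV must start with columns chrom, pos, ref, alt[, rsid]")
  }
  samples <- setdiff(names(tab), meta)
  if (!length(samples)) stop("matrix TSV has no sample columns")
  dosage <- t(as.matrix(tab[, samples, drop = FALSE]))
  variants <- tab[, intersect(meta, names(tab)), drop = FALSE]
  genotype_matrix(dosage, variants)
}

#' Write a genotype matrix as TSV
#'
#' Inverse of [read_genotypes()] with `format = "matrix_tsv"`; the
#' read-write-read round trip reproduces the matrix exactly.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @export
write_genotypes <- function(gm, path) {
  tab <- cbind(gm$variants[, c("chrom", "pos", "ref", "alt", "rsid")],
               as.data.frame(t(gm$dosage)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-site read counts
#'
#' Expects a TSV with columns `sample`, `chrom`, `pos`, `ref`, `alt`,
#' `gene`, `coverage`, `alt_count`. The alternate-allele frequency is
#' recomputed as `alt_count / coverage`; zero-coverage rows are kept but
#' flagged (`zero_coverage`) with an undefined frequency, and rows where
#' `alt_count > coverage` are rejected with a message.
#'
#' @param path file path.
#' @return a `data.frame` of class `site_read_counts`.
#' @export
read_site_counts <- function(path) {
  # allele columns must never be type-guessed ("T" is not logical TRUE)
  tab <- utils::read.delim(path, colClasses = "character")
  for (col in c("pos", "coverage", "alt_count")) {
    if (col %in% names(tab)) tab[[col]] <- as.integer(tab[[col]])
  }
  need <- c("sample", "chrom", "pos", "ref", "alt", "gene",
            "coverage", "alt_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("count table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- tab$alt_count > tab$coverage
  if (any(bad)) {
    message(sprintf("rejecting %d row(s) with alt_count > coverage", sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
  }
  site_read_counts(
    sample_id = tab$sample, chrom = tab$chrom, pos = tab$pos,
    ref = tab$ref, alt = tab$alt, gene = tab$gene,
    coverage = tab$coverage, alt_count = tab$alt_count
  )
}

#' Assemble a site read-count table
#'
#' @param sample_id,chrom,pos,ref,alt,gene,coverage,alt_count parallel
#'   vectors, one entry per (sample, site) observation.
#' @return `data.frame` of class `site_read_counts` with the derived
#'   `frequency` and `zero_coverage` columns.
#' @export
site_read_counts <- function(sample_id, chrom, pos, ref, alt, gene,
                             coverage, alt_count) {
  coverage <- as.integer(coverage)
  alt_count <- as.integer(alt_count)
  if (any(coverage < 0) || any(alt_count < 0)) stop("counts must be >= 0")
  if (any(alt_count > coverage)) stop("alt_count exceeds coverage")
  out <- data.frame(
    sample_id = as.character(sample_id), chrom = as.character(chrom),
    pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt),
    gene = as.character(gene), coverage = coverage, alt_count = alt_count,
    stringsAsFactors = FALSE
  )
  out$frequency <- ifelse(out$coverage > 0, out$alt_count / out$coverage,
                          NA_real_)
  out$zero_coverage <- out$coverage == 0L
  class(out) <- c("site_read_counts", "data.frame")
  out
}

#' Read a polygenic-score weight table
#'
#' TSV with columns `snp`, `effect_allele`, `beta` and optionally `chrom`,
#' `pos`, `ref`, `alt`. Duplicate SNP entries and non-finite effect sizes
#' are errors; negative betas (protective effects) are accepted.
#'
#' @param path file path.
#' @return `data.frame` of class `weight_table`.
#' @export
read_weights <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp", "effect_allele", "beta")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("weight table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$snp)) {
    stop("duplicate snp entries: ",
         paste(unique(tab$snp[duplicated(tab$snp)]), collapse = ", "))
  }
  tab$beta <- suppressWarnings(as.numeric(tab$beta))
  if (any(!is.finite(tab$beta))) stop("non-numeric or non-finite beta values")
  class(tab) <- c("weight_table", "data.frame")
  tab
}

#' Write a result table as TSV
#'
#' Columns are written in their given order; floating-point columns are
#' serialized with 10 significant digits so that a write-read round trip is
#' stable to that precision. An empty table produces a header-only file.
#'
#' @param table a `data.frame`.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  out <- as.data.frame(table)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], digits = 10, format = "g"))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phased haplotypes from a phased VCF
#'
#' Every `GT` call must use the phased separator `|`; unphased input is
#' rejected (phasing is consumed, never performed here). Each diploid sample
#' contributes two haplotypes, labelled `<sample>_1` and `<sample>_2`.
#'
#' @param path phased VCF path.
#' @param cohort optional [cohort_table()] supplying group labels.
#' @return a [phased_haplotypes()] object.
#' @export
read_phased_vcf <- function(path, cohort = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("genotypes are not phased ('/' separator found); phased input required")
  }
  if (any(grepl(",", fix$ALT))) stop("multi-allelic records not supported")
  samples <- colnames(gt)
  n_mark <- nrow(fix)
  alleles <- matrix(NA_character_, nrow = 2L * length(samples), ncol = n_mark)
  hap_id <- character(2L * length(samples))
  hap_sample <- character(2L * length(samples))
  for (s in seq_along(samples)) {
    calls <- strsplit(gt[, s], "|", fixed = TRUE)
    h1 <- vapply(calls, `[`, character(1), 1L)
    h2 <- vapply(calls, `[`, character(1), 2L)
    alleles[2L * s - 1L, ] <- ifelse(h1 == "0", fix$REF, fix$ALT)
    alleles[2L * s, ] <- ifelse(h2 == "0", fix$REF, fix$ALT)
    hap_id[c(2L * s - 1L, 2L * s)] <- paste(samples[s], 1:2, sep = "_")
    hap_sample[c(2L * s - 1L, 2L * s)] <- samples[s]
  }
  group <- if (is.null(cohort)) rep(NA_character_, length(hap_sample)) else
    group_of(cohort, hap_sample)
  phased_haplotypes(
    alleles = alleles, haplotype_id = hap_id, sample_id = hap_sample,
    group = group,
    markers = data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         rsid = ifelse(fix$ID == "." | is.na(fix$ID),
                                       NA_character_, fix$ID),
                         stringsAsFactors = FALSE)
  )
}
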