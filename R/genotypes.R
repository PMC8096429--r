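#' Construct a genotype matrix
#'
#' Dosages are counts of the record's alternate allele (0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternate, `NA` = missing);
#' the coding is strand-free and never complemented. Coordinates are 1-based
#' and fully closed, as in VCF.
#'
#' @param dosage integer matrix, samples in rows, variants in columns, values
#'   in `{0, 1, 2, NA}`. Row names are sample identifiers.
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `rsid`, one row per column of `dosage`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` and `variants`; columns of `dosage` are named
#'   `chrom:pos:ref:alt`.
#' @export
genotype_matrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variants must have columns chrom, pos, ref, alt")
  }
  if (ncol(dosage) != nrow(variants)) {
    stop("ncol(dosage) must equal nrow(variants)")
  }
  if (is.null(rownames(dosage))) {
    stop("dosage must carry sample ids as row names")
  }
  if (anyDuplicated(rownames(dosage))) stop("duplicate sample ids")
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- as.character(variants$ref)
  variants$alt <- as.character(variants$alt)
  if (is.null(variants$rsid)) variants$rsid <- NA_character_
  if (any(variants$pos < 1L)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must lie in {0, 1, 2} or be missing")
  }
  colnames(dosage) <- variant_id(variants)
  rownames(variants) <- NULL
  out <- list(dosage = dosage, variants = variants)
  class(out) <- "genotype_matrix"
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants (%.1f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage), 100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @keywords internal
variant_id <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Number of samples / variants in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$dosage)

#' @rdname n_samples
#' @export
n_variants <- function(gm) ncol(gm$dosage)

#' Per-variant summaries
#'
#' `allele_freq` is the alternate-allele frequency among non-missing
#' genotypes, `minor_af` folds it onto `[0, 0.5]`, `call_rate` is the
#' fraction of non-missing genotypes, and `is_snv` is true when both alleles
#' have length one.
#'
#' @param gm a `genotype_matrix`.
#' @param samples optional character vector restricting the computation to a
#'   subset of samples.
#' @return numeric (or logical) vector, one entry per variant.
#' @export
allele_freq <- function(gm, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[rownames(d) %in% samples, , drop = FALSE]
  colMeans(d, na.rm = TRUE) / 2
}

#' @rdname allele_freq
#' @export
minor_af <- function(gm, samples = NULL) {
  af <- allele_freq(gm, samples)
  pmin(af, 1 - af)
}

#' @rdname allele_freq
#' @export
call_rate <- function(gm) {
  colMeans(!is.na(gm$dosage))
}

#' @rdname allele_freq
#' @export
is_snv <- function(gm) {
  nchar(gm$variants$ref) == 1L & nchar(gm$variants$alt) == 1L
}

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param keep logical, integer or character index of variants (samples).
#' @return a new `genotype_matrix`.
#' @export
subset_variants <- function(gm, keep) {
  if (is.character(keep)) keep <- match(keep, variant_id(gm$variants))
  genotype_matrix(gm$dosage[, keep, drop = FALSE],
                  gm$variants[keep, , drop = FALSE])
}

#' @rdname subset_variants
#' @export
subset_samples <- function(gm, keep) {
  if (is.logical(keep) || is.numeric(keep)) {
    keep <- rownames(gm$dosage)[keep]
  }
  genotype_matrix(gm$dosage[match(keep, rownames(gm$dosage)), , drop = FALSE],
                  gm$variants)
}
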