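#' Case-private mutations
#'
#' Under the default `"singleton"` rule a variant is private when its
#' alternate allele is carried by exactly one case sample and by no
#' control; the looser `"absent_controls"` rule only requires absence
#' from controls (any number of case carriers). Annotations (damaging
#' votes, population allele frequency, ClinVar flag) are joined when
#' supplied.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a [cohort_table()].
#' @param rule `"singleton"` (default) or `"absent_controls"`.
#' @param annotations optional `data.frame` with variant key columns
#'   (`chrom`, `pos`, `ref`, `alt`) plus any of `damaging_votes`,
#'   `population_af`, `clinvar_pathogenic`, `impact`.
#' @return `data.frame`, one row per private variant, with the carrier
#'   case sample id (comma-separated under the looser rule).
#' @export
find_private <- function(gm, cohort, rule = c("singleton", "absent_controls"),
                         annotations = NULL) {
  rule <- match.arg(rule)
  grp <- group_of(cohort, rownames(gm$dosage))
  carrier <- !is.na(gm$dosage) & gm$dosage >= 1L
  case_n <- colSums(carrier[grp == "CASE", , drop = FALSE])
  ctrl_n <- colSums(carrier[grp == "CONTROL", , drop = FALSE])
  keep <- if (rule == "singleton") case_n == 1L & ctrl_n == 0L else
    case_n >= 1L & ctrl_n == 0L
  idx <- which(keep)
  carriers <- vapply(idx, function(j) {
    paste(rownames(gm$dosage)[carrier[, j] & grp == "CASE"], collapse = ",")
  }, character(1))
  out <- cbind(gm$variants[idx, , drop = FALSE],
               data.frame(carrier_sample = carriers,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  if (!is.null(annotations)) out <- join_annotations(out, annotations)
  out
}

#' @keywords internal
join_annotations <- function(tab, annotations) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  m <- match(key(tab), key(annotations))
  for (col in setdiff(names(annotations), c("chrom", "pos", "ref", "alt"))) {
    tab[[col]] <- annotations[[col]][m]
  }
  tab
}

#' Damaging-predictor vote rule
#'
#' A variant counts as damaging when it is predicted damaging in more
#' than 4 of the 6 predictors, i.e. at least 5 votes. A missing vote
#' count yields `FALSE` with a warning (missing predictions count as
#' non-damaging votes).
#'
#' @param votes integer vector of damaging votes in 0..6 (or a
#'   `data.frame` with a `damaging_votes` column).
#' @return logical vector.
#' @export
damaging_vote <- function(votes) {
  if (is.data.frame(votes)) votes <- votes$damaging_votes
  if (any(stats::na.omit(votes) < 0 | stats::na.omit(votes) > 6)) {
    stop("votes must lie in 0..6")
  }
  if (anyNA(votes)) {
    warning("missing damaging votes treated as non-damaging")
  }
  !is.na(votes) & votes >= 5
}

#' Rare-variant filter
#'
#' Keeps variants whose minor allele frequency is strictly below
#' `maf_max` in the cases AND in the controls (a variant rare in one
#' group but common in the other is removed). Idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a [cohort_table()].
#' @param maf_max MAF threshold (default 0.01, strict `<`).
#' @return the filtered [genotype_matrix()].
#' @export
rare_filter <- function(gm, cohort, maf_max = 0.01) {
  grp <- group_of(cohort, rownames(gm$dosage))
  case_ids <- rownames(gm$dosage)[grp == "CASE"]
  ctrl_ids <- rownames(gm$dosage)[grp == "CONTROL"]
  keep <- minor_af(gm, case_ids) < maf_max & minor_af(gm, ctrl_ids) < maf_max
  keep[is.na(keep)] <- FALSE
  subset_variants(gm, keep)
}

#' Collapsing burden test per gene
#'
#' For each gene, samples are collapsed to carrier (at least one rare
#' alternate allele among the gene's variants) versus non-carrier, and
#' carrier status is tested against case/control status with the
#' two-sided Fisher exact test. This carrier-collapsing test is a
#' transparent substitute for variance-component rare-variant tests: it
#' preserves the pipeline role (per-gene rare-variant association) while
#' being exactly computable and calibrated, at the cost of power against
#' mixed-direction effects.
#'
#' @param gm_rare a rare-filtered [genotype_matrix()].
#' @param gene_map `data.frame(chrom, start, end, gene)` (BED-like, 1-based
#'   closed intervals) assigning variants to genes.
#' @param cohort a [cohort_table()].
#' @return `data.frame`, one row per gene with at least one variant,
#'   ordered by p-value: `gene`, `n_variants`, `carriers_case`,
#'   `carriers_ctrl`, `n_case`, `n_ctrl`, `p`.
#' @export
burden_collapse <- function(gm_rare, gene_map, cohort) {
  assert_two_groups(cohort)
  grp <- group_of(cohort, rownames(gm_rare$dosage))
  rows <- list()
  for (i in seq_len(nrow(gene_map))) {
    in_gene <- gm_rare$variants$chrom == gene_map$chrom[i] &
      gm_rare$variants$pos >= gene_map$start[i] &
      gm_rare$variants$pos <= gene_map$end[i]
    if (!any(in_gene)) {
      message("gene with zero variants skipped: ", gene_map$gene[i])
      next
    }
    carrier <- rowSums(gm_rare$dosage[, in_gene, drop = FALSE] >= 1L,
                       na.rm = TRUE) > 0
    cc <- sum(carrier & grp == "CASE"); nc <- sum(grp == "CASE")
    cn <- sum(carrier & grp == "CONTROL"); nn <- sum(grp == "CONTROL")
    p <- fisher_exact_2x2(cc, nc - cc, cn, nn - cn)$p
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene_map$gene[i], n_variants = sum(in_gene),
      carriers_case = cc, carriers_ctrl = cn, n_case = nc, n_ctrl = nn,
      p = p, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
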