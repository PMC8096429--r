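#' Cluster haplotypes by exact allele-sequence match over a marker window
#'
#' Haplotypes sharing the identical allele sequence across the window form
#' one cluster (every member carries the cluster's defining sequence at
#' every window marker). Clusters are returned sorted by size descending,
#' ties broken by the defining sequence alphabetically, so the output is
#' deterministic. This replaces HMM-based localized haplotype clustering
#' with its degenerate exact-match limit, which is the form in which
#' significant clusters are reported (all members carrying the same allele
#' at every window marker).
#'
#' @param haps a [phased_haplotypes()] object.
#' @param interval integer vector of marker column indices (a contiguous
#'   window, but any non-empty index set is accepted).
#' @return list of clusters; each is a list with `interval`, `sequence`
#'   (alleles pasted in marker order) and `members` (haplotype ids).
#' @export
window_clusters <- function(haps, interval) {
  interval <- as.integer(interval)
  if (!length(interval)) stop("empty marker interval")
  if (any(interval < 1 | interval > ncol(haps$alleles))) {
    stop("interval markers outside the marker list")
  }
  seqs <- apply(haps$alleles[, interval, drop = FALSE], 1, paste,
                collapse = "")
  split_ids <- split(haps$haplotype_id, seqs)
  sizes <- lengths(split_ids)
  ord <- order(-sizes, names(split_ids))
  lapply(ord, function(i) {
    list(interval = range(interval), sequence = names(split_ids)[i],
         members = unname(split_ids[[i]]))
  })
}

#' Pseudomarker coding of a haplotype cluster
#'
#' The cluster becomes a diallelic pseudomarker: a haplotype is coded 2
#' when it belongs to the cluster and 1 when it does not, so cluster
#' membership can be tested exactly like any other diallelic marker.
#'
#' @param cluster one element of [window_clusters()] output.
#' @param haps the [phased_haplotypes()] the cluster was built from.
#' @return named integer vector (2 = member, 1 = non-member), one entry
#'   per haplotype.
#' @export
pseudomarker_of <- function(cluster, haps) {
  if (!all(cluster$members %in% haps$haplotype_id)) {
    stop("cluster members not found among haplotypes")
  }
  code <- ifelse(haps$haplotype_id %in% cluster$members, 2L, 1L)
  names(code) <- haps$haplotype_id
  code
}

#' Case/control association of a haplotype cluster
#'
#' Builds the carrier/non-carrier by case/control 2x2 table and delegates
#' to [fisher_exact_2x2()]; carrier frequencies are carriers divided by
#' group haplotype totals.
#'
#' @param carriers_case,carriers_ctrl carrier haplotype counts per group.
#' @param n_case_hap,n_ctrl_hap total haplotypes per group.
#' @return list with `or`, `ci`, `p`, `freq_case`, `freq_ctrl`, `table`.
#' @examples
#' hap_association(57, 162, 54, 72)  # OR 0.18, p 1.84e-8
#' @export
hap_association <- function(carriers_case, n_case_hap,
                            carriers_ctrl, n_ctrl_hap) {
  if (n_case_hap == 0 || n_ctrl_hap == 0) stop("zero haplotypes in a group")
  if (carriers_case > n_case_hap || carriers_ctrl > n_ctrl_hap) {
    stop("carrier counts exceed group totals")
  }
  ft <- fisher_exact_2x2(carriers_case, n_case_hap - carriers_case,
                         carriers_ctrl, n_ctrl_hap - carriers_ctrl)
  list(or = ft$or, ci = ft$ci, p = ft$p,
       freq_case = carriers_case / n_case_hap,
       freq_ctrl = carriers_ctrl / n_ctrl_hap,
       table = ft$table)
}

#' Scan marker windows for associated haplotype clusters
#'
#' Every cluster in every window is tested; the result table carries the
#' window coordinates, defining sequence, cluster size, odds ratio,
#' confidence interval, p-value and per-group carrier frequencies, with a
#' flag for the largest cluster of each window and a genome-wide
#' significance flag (`p < 5e-8`, applied as a column only — all rows are
#' reported unadjusted).
#'
#' @param haps a [phased_haplotypes()] with group labels.
#' @param windows list of marker-index vectors, one per window.
#' @return `data.frame`, one row per (window, cluster).
#' @export
scan_region <- function(haps, windows) {
  if (any(is.na(haps$group))) stop("haplotypes carry no group labels")
  n_case <- sum(haps$group == "CASE")
  n_ctrl <- sum(haps$group == "CONTROL")
  rows <- list()
  for (w in seq_along(windows)) {
    clusters <- window_clusters(haps, windows[[w]])
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      member <- haps$haplotype_id %in% cl$members
      cc <- sum(member & haps$group == "CASE")
      cn <- sum(member & haps$group == "CONTROL")
      ha <- hap_association(cc, n_case, cn, n_ctrl)
      rows[[length(rows) + 1L]] <- data.frame(
        window = w,
        start = haps$markers$pos[cl$interval[1]],
        end = haps$markers$pos[cl$interval[2]],
        sequence = cl$sequence, n_members = length(cl$members),
        or = ha$or, ci_low = ha$ci[1], ci_high = ha$ci[2], p = ha$p,
        freq_case = ha$freq_case, freq_ctrl = ha$freq_ctrl,
        largest = ci == 1L, genomewide = ha$p < 5e-8,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
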