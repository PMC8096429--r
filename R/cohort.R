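#' Build a cohort table
#'
#' A cohort table carries the per-sample metadata used by every two-group
#' analysis in the package: the group label (`CASE` for the long-lived
#' subjects, `CONTROL` for the younger comparison group), sex, and optional
#' age and sampling-region columns.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group character or factor, one of `"CASE"`/`"CONTROL"` per sample.
#' @param sex character, one of `"M"`, `"F"`, `"unknown"` (default).
#' @param age optional numeric vector of ages in years.
#' @param region optional character vector of sampling locations.
#' @return A `data.frame` of class `cohort_table` with one row per sample.
#' @examples
#' cohort_table(c("s1", "s2"), c("CASE", "CONTROL"), sex = c("F", "M"))
#' @export
cohort_table <- function(sample_id, group, sex = "unknown",
                         age = NULL, region = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("sample_id values must be unique")
  }
  group <- as.character(group)
  if (!all(group %in% c("CASE", "CONTROL"))) {
    stop("group must be 'CASE' or 'CONTROL'")
  }
  sex <- rep_len(as.character(sex), length(sample_id))
  if (!all(sex %in% c("M", "F", "unknown"))) {
    stop("sex must be 'M', 'F' or 'unknown'")
  }
  out <- data.frame(
    sample_id = sample_id,
    group = factor(group, levels = c("CASE", "CONTROL")),
    sex = sex,
    stringsAsFactors = FALSE
  )
  if (!is.null(age)) out$age <- as.numeric(rep_len(age, nrow(out)))
  if (!is.null(region)) out$region <- as.character(rep_len(region, nrow(out)))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @keywords internal
assert_two_groups <- function(cohort) {
  tab <- table(cohort$group)
  if (any(tab[c("CASE", "CONTROL")] == 0) || length(tab) < 2) {
    stop("cohort must contain at least one CASE and one CONTROL sample")
  }
  invisible(cohort)
}

#' @keywords internal
group_of <- function(cohort, sample_id) {
  as.character(cohort$group[match(sample_id, cohort$sample_id)])
}
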