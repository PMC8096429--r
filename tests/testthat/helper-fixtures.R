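# small in-code fixtures shared across test files

toy_gm <- function(dosage, chrom = "1", pos = NULL, ref = "A", alt = "G",
                   rsid = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  }
  nv <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  genotype_matrix(dosage, data.frame(
    chrom = rep_len(chrom, nv), pos = pos, ref = rep_len(ref, nv),
    alt = rep_len(alt, nv),
    rsid = if (is.null(rsid)) sprintf("rs%d", seq_len(nv)) else rsid,
    stringsAsFactors = FALSE
  ))
}

toy_cohort <- function(n_case, n_ctrl, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n_case + n_ctrl))
  cohort_table(ids, rep(c("CASE", "CONTROL"), c(n_case, n_ctrl)),
               sex = rep("F", n_case + n_ctrl))
}

# a tiny VCF written to a temp file
write_tiny_vcf <- function(path, phased = FALSE, multiallelic = FALSE) {
  sep <- if (phased) "|" else "/"
  gt <- function(a, b) paste(a, b, sep = sep)
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsA\tsB\tsC",
    paste("7", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          gt(0, 1), gt(0, 0), gt(1, 1), sep = "\t"),
    paste("7", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          gt(0, 0), if (phased) gt(0, 1) else "./.", gt(0, 1), sep = "\t")
  )
  if (multiallelic) {
    lines <- c(lines, paste("7", "300", "rs3", "G", "A,C", ".", "PASS", ".",
                            "GT", gt(0, 1), gt(0, 2), gt(0, 0), sep = "\t"))
  }
  writeLines(lines, path)
  path
}
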