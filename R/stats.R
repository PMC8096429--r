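#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value sums, over all tables with the observed margins,
#' the hypergeometric probabilities no larger than that of the observed
#' table (the convention of classical conditional exact testing; a relative
#' tolerance of 1e-7 guards against ties lost to floating point). The
#' reported odds ratio is the sample (cross-product) ratio `(a/b)/(c/d)`
#' with a Woolf log-odds 95% confidence interval; when any cell is zero the
#' OR and CI are undefined (`NA`) while the p-value remains valid.
#'
#' @param a,b,c,d non-negative integer cell counts: rows are groups, columns
#'   carrier/non-carrier (or allele counts). A 2x2 matrix may be given as
#'   `a`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   referring to the upper-left cell.
#' @return list with `p`, `or`, `ci` (length-2), and the input `table`.
#' @examples
#' fisher_exact_2x2(8, 71, 0, 31)$p   # 0.1025
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL,
                             alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) stop("cell counts must be >= 0")
  if (sum(cells) == 0) stop("all-zero table")
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    less = stats::phyper(a, m, n, k),
    greater = stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
  )
  p <- min(1, p)
  if (all(cells > 0)) {
    or <- (a / b) / (c / d)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  } else {
    or <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  list(p = p, or = or, ci = ci,
       table = matrix(c(a, b, c, d), 2, 2, byrow = TRUE,
                      dimnames = list(c("CASE", "CONTROL"), NULL)))
}

#' Combine p-values by Fisher's method
#'
#' `X = -2 * sum(log(p))` is referred to a chi-square distribution with
#' `2k` degrees of freedom. Zero p-values (log undefined) and empty input
#' are errors; a single p-value is returned unchanged.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return the combined p-value.
#' @examples
#' fisher_combine(c(8.40e-5, 1e-6))  # 2.03e-9
#' @export
fisher_combine <- function(pvalues) {
  if (!length(pvalues)) stop("no p-values to combine")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  x <- -2 * sum(log(pvalues))
  stats::pchisq(x, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Genomic inflation factor
#'
#' The median of the association chi-square statistics (obtained by
#' back-transforming the p-values through the 1-df chi-square quantile
#' function) divided by the null median 0.4549364.
#'
#' @param pvalues numeric vector of p-values.
#' @return lambda, the genomic inflation factor.
#' @export
inflation_lambda <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) stop("no p-values")
  chisq <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Equal-tail two-sided exact binomial test
#'
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))` under `Binomial(n, p0)`.
#' The equal-tail (doubling) convention is used rather than the
#' minimum-likelihood convention of [stats::binom.test()]: it is
#' reproducible across implementations and conservative. Vectorized over
#' `k` and `n`.
#'
#' @param k observed successes (alternate read count).
#' @param n trials (coverage); must be positive.
#' @param p0 null success probability in (0, 1).
#' @return vector of p-values.
#' @export
binom_two_sided <- function(k, n, p0) {
  if (any(n == 0)) stop("n must be positive")
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must lie in (0, 1)")
  if (any(k < 0 | k > n)) stop("k must lie in 0..n")
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Designed-false-positive-rate flag for clone-like allele counts
#'
#' Builds the equal-tail rejection region of `Binomial(n, 0.5)` whose tail
#' masses are each at most `fpr / 2` (so the achieved size is at most
#' `fpr` by construction) and reports whether `k` falls inside it. This is
#' the screening test for putative somatic mutations: a germline
#' heterozygous site (allele fraction near one half) is flagged at most at
#' rate `fpr`. Vectorized over `k` and `n`.
#'
#' @param k observed alternate read count.
#' @param n coverage.
#' @param fpr designed false positive rate (default `1e-5`).
#' @return logical vector.
#' @export
putative_flag <- function(k, n, fpr = 1e-5) {
  if (any(k < 0 | k > n)) stop("k must lie in 0..n")
  q <- stats::qbinom(fpr / 2, n, 0.5)
  k_lo <- ifelse(stats::pbinom(q, n, 0.5) <= fpr / 2, q, q - 1)
  k <= k_lo | k >= n - k_lo
}

#' Two-sided Mann-Whitney U test
#'
#' For group sizes of at most `exact_max` per group the two-sided p-value
#' is computed by full enumeration of all assignments of the pooled values
#' to the two groups (ties handled exactly):
#' `p = P(|W - E[W]| >= |W_obs - E[W]|)` for the rank-sum `W` of the first
#' group. Larger samples use the normal approximation with tie correction
#' and continuity correction.
#'
#' @param x,y numeric samples for the two groups.
#' @param exact_max per-group size up to which full enumeration is used
#'   (default 8).
#' @return list with `p`, `u` (Mann-Whitney U of `x`) and `method`.
#' @export
mwu_test <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  u_obs <- w_obs - nx * (nx + 1) / 2
  ew <- nx * (nx + ny + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    combos <- utils::combn(nx + ny, nx)
    ws <- colSums(matrix(r[combos], nrow = nx))
    p <- mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    ties <- table(pooled)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(p = 1, u = u_obs, method = "degenerate"))
    z <- u_obs - nx * ny / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(p = min(1, p), u = u_obs, method = method)
}
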