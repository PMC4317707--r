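#' Hardy-Weinberg exact test for a biallelic locus
#'
#' Conditional exact test: given the observed allele counts, every
#' heterozygote count with the same parity as the minor-allele count is a
#' possible genotype configuration; each has a hypergeometric-form
#' conditional probability under random mating. The p-value is the sum of
#' the probabilities of all configurations no more probable than the
#' observed one (plain tail definition, no mid-p correction).
#' Probabilities are built by a stable multiplicative recurrence from the
#' modal configuration and normalized, so no factorials overflow.
#'
#' Degenerate loci (fewer than one copy of either allele) admit a single
#' configuration and return p = 1 with `degenerate = TRUE`.
#'
#' @param counts A [locus_counts] object.
#' @return List of class `hwe_result`: `locus_id`, `p_value`, `method`,
#'   `het_observed`, `het_expected` (HWE expectation at the observed allele
#'   frequency) and `degenerate`.
#' @examples
#' hwe_exact(locus_counts(1, 0, 1))   # p = 1/3
#' @export
hwe_exact <- function(counts) {
  stopifnot(inherits(counts, "locus_counts"))
  n <- counts$n
  n_del <- 2L * counts$n_dd + counts$n_di
  n_ins <- 2L * counts$n_ii + counts$n_di
  het_expected <- 2 * (n_del / (2 * n)) * (n_ins / (2 * n)) * n
  res <- function(p, degen) {
    structure(list(locus_id = counts$locus_id, p_value = p, method = "exact",
                   het_observed = counts$n_di, het_expected = het_expected,
                   degenerate = degen),
              class = "hwe_result")
  }
  minor <- min(n_del, n_ins)
  if (minor < 1L) return(res(1, TRUE))
  hets <- seq.int(minor %% 2L, minor, by = 2L)
  # unnormalized probabilities via the recurrence
  #   P(h + 2) / P(h) = 4 n_dd(h) n_ii(h) / ((h + 2)(h + 1)),
  # accumulated in log space from the smallest feasible h
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1L]) {
    h <- hets[k - 1L]
    ndd <- (n_del - h) / 2
    nii <- (n_ins - h) / 2
    lp[k] <- lp[k - 1L] + log(4 * ndd * nii) - log((h + 2) * (h + 1))
  }
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  p_obs <- pr[hets == counts$n_di]
  p <- sum(pr[pr <= p_obs * (1 + 1e-12)])
  res(min(p, 1), FALSE)
}

#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' One-degree-of-freedom test of the observed genotype counts against the
#' HWE expectations `n p^2, 2npq, n q^2` at the observed allele frequency.
#' Provided for comparison with [hwe_exact()]; no continuity correction.
#'
#' @param counts A [locus_counts] object.
#' @return List of class `hwe_result` with an extra `statistic` element.
#'   Monomorphic loci return p = 1 with `degenerate = TRUE`.
#' @examples
#' hwe_chi2(locus_counts(25, 50, 25))  # statistic 0, p = 1
#' @export
hwe_chi2 <- function(counts) {
  stopifnot(inherits(counts, "locus_counts"))
  n <- counts$n
  p <- (2 * counts$n_dd + counts$n_di) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  degenerate <- p == 0 || p == 1
  if (degenerate) {
    stat <- 0
    pval <- 1
  } else {
    observed <- c(counts$n_dd, counts$n_di, counts$n_ii)
    stat <- sum((observed - expected)^2 / expected)
    pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(locus_id = counts$locus_id, p_value = pval, method = "chi2",
                 statistic = stat, het_observed = counts$n_di,
                 het_expected = expected[2L], degenerate = degenerate),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE %s test%s: p = %.4g (het observed %d, expected %.2f)%s\n",
              x$method,
              if (is.na(x$locus_id)) "" else paste0(" at ", x$locus_id),
              x$p_value, x$het_observed, x$het_expected,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}
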