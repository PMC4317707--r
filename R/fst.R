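# Weir-Cockerham variance components for two populations at a biallelic
# locus, from (n, p_del, het proportion) per population. Returns c(a, b, c).
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c(a = a, b = b, c = hbar / 2)
}

counts_stats <- function(cnt) {
  c(n = cnt$n, p = (2 * cnt$n_dd + cnt$n_di) / (2 * cnt$n), h = cnt$n_di / cnt$n)
}

#' Pairwise Weir-Cockerham Fst at one biallelic locus
#'
#' Moment estimator theta of Weir & Cockerham (1984) for two populations
#' from diploid genotype counts, using the observed heterozygosities in the
#' within-individual variance component. Negative estimates are returned
#' as-is (they are informative small-divergence outcomes, distinct from
#' zero). A locus monomorphic in the pooled sample has no defined estimate
#' and raises an error rather than returning 0.
#'
#' @param c1,c2 [locus_counts] for the two populations (each `n >= 2`).
#' @return Numeric theta with attribute `"components"` = c(a, b, c), the
#'   among-population, among-individual-within-population and
#'   within-individual variance components; theta = a / (a + b + c).
#' @examples
#' pairwise_fst(locus_counts(50, 0, 0), locus_counts(0, 0, 50))  # 1
#' @export
pairwise_fst <- function(c1, c2) {
  stopifnot(inherits(c1, "locus_counts"), inherits(c2, "locus_counts"))
  if (c1$n < 2 || c2$n < 2) stop("each population needs n >= 2")
  s1 <- counts_stats(c1); s2 <- counts_stats(c2)
  pooled <- (2 * s1[["n"]] * s1[["p"]] + 2 * s2[["n"]] * s2[["p"]]) /
    (2 * (s1[["n"]] + s2[["n"]]))
  if (pooled <= 0 || pooled >= 1)
    stop("locus is monomorphic in the pooled sample; Fst is undefined",
         if (!is.na(c1$locus_id)) paste0(" (", c1$locus_id, ")") else "")
  comp <- wc_components(s1[["n"]], s1[["p"]], s1[["h"]],
                        s2[["n"]], s2[["p"]], s2[["h"]])
  denom <- sum(comp)
  theta <- if (denom == 0) 0 else comp[["a"]] / denom
  attr(theta, "components") <- comp
  theta
}

#' Multi-locus Weir-Cockerham Fst
#'
#' Ratio-of-sums estimator: variance components are summed over loci before
#' taking theta = sum(a) / sum(a + b + c). Loci monomorphic in the pooled
#' sample carry no information and are skipped.
#'
#' @param counts1,counts2 Lists of [locus_counts] (parallel, same loci).
#' @return Numeric multi-locus theta; attribute `"n_loci_used"` gives the
#'   number of polymorphic loci that entered the sums.
#' @export
multilocus_fst <- function(counts1, counts2) {
  stopifnot(length(counts1) == length(counts2), length(counts1) >= 1)
  acc <- c(a = 0, b = 0, c = 0)
  used <- 0L
  for (i in seq_along(counts1)) {
    theta <- tryCatch(pairwise_fst(counts1[[i]], counts2[[i]]),
                      error = function(e) NULL)
    if (is.null(theta)) next
    acc <- acc + attr(theta, "components")
    used <- used + 1L
  }
  if (used == 0L) stop("all loci monomorphic in the pooled sample")
  out <- acc[["a"]] / sum(acc)
  attr(out, "n_loci_used") <- used
  out
}

calls_to_counts <- function(calls, locus_id = NA_character_) {
  calls <- calls[!is.na(calls)]
  locus_counts(sum(calls == "DD"), sum(calls == "DI"), sum(calls == "II"),
               locus_id = locus_id)
}

#' Permutation test of pairwise Fst at one locus
#'
#' Whole individuals (their full genotypes) are shuffled between the two
#' population labels, preserving group sizes; theta is recomputed for each
#' permuted partition. The p-value is
#' `(#\{permuted theta >= observed theta\} + 1) / (n_perm + 1)`, so it is
#' never zero and is exactly reproducible given the seed.
#'
#' @param calls1,calls2 Character vectors of genotype calls (`"DD"`, `"DI"`,
#'   `"II"`; `NA` dropped) for the two populations at one locus.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param locus_id Optional label carried into the result.
#' @return List of class `fst_perm_result`: `locus_id`, `fst`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
fst_permutation <- function(calls1, calls2, n_perm = 1000L, seed,
                            locus_id = NA_character_) {
  if (missing(seed)) stop("seed is mandatory for the permutation test")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  calls1 <- calls1[!is.na(calls1)]
  calls2 <- calls2[!is.na(calls2)]
  obs <- pairwise_fst(calls_to_counts(calls1, locus_id),
                      calls_to_counts(calls2, locus_id))
  pooled <- c(calls1, calls2)
  n1 <- length(calls1)
  # encode each individual once; a permutation only re-tallies counts
  het <- pooled == "DI"
  ndel <- (pooled == "DD") * 2L + het
  n2 <- length(pooled) - n1
  # seed a private stream; restore the caller's RNG state on exit so the
  # permutation test never perturbs surrounding simulations
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), n1)
    h1 <- sum(het[idx]); d1 <- sum(ndel[idx])
    h2 <- sum(het) - h1; d2 <- sum(ndel) - d1
    comp <- wc_components(n1, d1 / (2 * n1), h1 / n1,
                          n2, d2 / (2 * n2), h2 / n2)
    th <- if (sum(comp) == 0) 0 else comp[["a"]] / sum(comp)
    if (th >= as.numeric(obs)) exceed <- exceed + 1L
  }
  structure(list(locus_id = locus_id, fst = as.numeric(obs),
                 p_value = (exceed + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "fst_perm_result")
}

ref_to_calls <- function(ref, locus) {
  if (inherits(ref, "genotype_matrix")) {
    if (!locus %in% colnames(ref$calls)) return(NULL)
    ref$calls[, locus]
  } else {
    # frequency + sample size reference: expand HWE-expected counts
    if (!locus %in% names(ref$freq)) return(NULL)
    p <- ref$freq[[locus]]
    n <- ref$n
    ndd <- round(p^2 * n); ndi <- round(2 * p * (1 - p) * n)
    nii <- max(n - ndd - ndi, 0)
    rep(c("DD", "DI", "II"), times = c(ndd, ndi, nii))
  }
}

#' Locus-by-locus differentiation table against reference populations
#'
#' For every locus shared between the target genotype matrix and each
#' reference, computes the pairwise Weir-Cockerham theta and its permutation
#' p-value, flagging loci with p below `alpha`. References may be genotype
#' matrices or frequency-only summaries supplied as
#' `list(freq = <named p_del vector>, n = <diploid sample size>)`; the
#' latter are expanded to HWE-expected genotype counts and marked
#' approximate. Loci absent from a reference yield `NA` rows (no result),
#' mirroring published comparison tables with incomplete reference data.
#'
#' @param target A [genotype_matrix].
#' @param references Named list of references (see above).
#' @param n_perm Permutations per locus-pair test.
#' @param seed Integer seed; each locus-by-reference cell uses a distinct
#'   sub-seed derived deterministically from it.
#' @param alpha Significance level for the flags (default 0.05).
#' @param bonferroni If `TRUE`, divide `alpha` by the number of tested loci
#'   per reference before flagging.
#' @return Data frame in long format with columns `locus_id`, `reference`,
#'   `fst`, `p_value`, `significant`, `approx_reference`; attribute
#'   `"n_significant"` holds the per-reference count of flagged loci.
#' @export
differentiation_table <- function(target, references, n_perm = 1000L, seed,
                                  alpha = 0.05, bonferroni = FALSE) {
  stopifnot(inherits(target, "genotype_matrix"))
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop("references must be a named list")
  loci <- colnames(target$calls)
  shared_any <- vapply(references, function(ref) {
    ref_loci <- if (inherits(ref, "genotype_matrix")) colnames(ref$calls)
                else names(ref$freq)
    length(intersect(loci, ref_loci)) > 0
  }, logical(1L))
  if (!all(shared_any))
    stop("no shared loci with reference: ",
         paste(names(references)[!shared_any], collapse = ", "))
  rows <- list()
  cell <- 0L
  for (ref_name in names(references)) {
    ref <- references[[ref_name]]
    approx <- !inherits(ref, "genotype_matrix")
    alpha_ref <- alpha
    if (bonferroni) {
      n_tested <- sum(vapply(loci, function(l) !is.null(ref_to_calls(ref, l)),
                             logical(1L)))
      alpha_ref <- alpha / max(n_tested, 1L)
    }
    for (locus in loci) {
      cell <- cell + 1L
      ref_calls <- ref_to_calls(ref, locus)
      if (is.null(ref_calls)) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = locus, reference = ref_name, fst = NA_real_,
          p_value = NA_real_, significant = NA, approx_reference = approx,
          stringsAsFactors = FALSE)
        next
      }
      res <- tryCatch(
        fst_permutation(target$calls[, locus], ref_calls, n_perm = n_perm,
                        seed = (as.integer(seed) + cell) %% .Machine$integer.max,
                        locus_id = locus),
        error = function(e) NULL)  # pooled-monomorphic locus: no result
      rows[[length(rows) + 1L]] <- if (is.null(res)) data.frame(
        locus_id = locus, reference = ref_name, fst = NA_real_,
        p_value = NA_real_, significant = NA, approx_reference = approx,
        stringsAsFactors = FALSE)
      else data.frame(
        locus_id = locus, reference = ref_name, fst = res$fst,
        p_value = res$p_value, significant = res$p_value < alpha_ref,
        approx_reference = approx, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  n_sig <- tapply(out$significant, out$reference, sum, na.rm = TRUE)
  attr(out, "n_significant") <- n_sig[names(references)]
  out
}
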