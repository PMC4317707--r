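#' Sample diploid genotypes under Hardy-Weinberg equilibrium
#'
#' Draws `n` independent genotypes with probabilities `(p^2, 2pq, q^2)` for
#' (DD, DI, II) at deletion-allele frequency `p`. A single RNG stream is
#' seeded once at entry, so output is bit-reproducible given `(p_del, n,
#' seed)`.
#'
#' @param p_del Deletion-allele frequency in \[0, 1\].
#' @param n Number of diploid individuals.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List with `calls` (character vector of `"DD"/"DI"/"II"`) and
#'   `counts` (a [locus_counts]).
#' @export
sample_hwe_genotypes <- function(p_del, n, seed = NULL) {
  sample_inbred_genotypes(p_del, f = 0, n = n, seed = seed)
}

#' Sample genotypes with an inbreeding departure from HWE
#'
#' Genotype probabilities `(p^2 + f p q, 2 p q (1 - f), q^2 + f p q)`: the
#' inbreeding coefficient `f` moves heterozygotes into both homozygote
#' classes, giving calibrated HWE-violating input for power studies of the
#' equilibrium tests. `f = 0` is exact HWE; `f = 1` produces no
#' heterozygotes.
#'
#' @param p_del Deletion-allele frequency in \[0, 1\].
#' @param f Inbreeding coefficient in \[0, 1\].
#' @param n Number of diploid individuals.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return As [sample_hwe_genotypes()].
#' @export
sample_inbred_genotypes <- function(p_del, f, n, seed = NULL) {
  stopifnot(p_del >= 0, p_del <= 1, f >= 0, f <= 1, n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  q <- 1 - p_del
  pr <- c(p_del^2 + f * p_del * q, 2 * p_del * q * (1 - f), q^2 + f * p_del * q)
  calls <- sample(c("DD", "DI", "II"), n, replace = TRUE, prob = pr)
  list(calls = calls, counts = calls_to_counts(calls))
}

#' Balding-Nichols allele-frequency divergence
#'
#' Draws per-population deletion-allele frequencies for `k` populations
#' diverged at level `fst` from an ancestral frequency `p`:
#' independent draws from `Beta(p (1-F)/F, (1-p)(1-F)/F)`, whose mean is
#' `p` and variance `F p (1-p)`. `fst = 0` is handled explicitly and
#' returns the ancestral frequency for every population.
#'
#' @param p Ancestral deletion-allele frequency, strictly in (0, 1) when
#'   `fst > 0`.
#' @param fst Divergence level in \[0, 1).
#' @param k Number of populations.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of length `k`.
#' @export
balding_nichols <- function(p, fst, k, seed = NULL) {
  stopifnot(fst >= 0, fst < 1, k >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (fst == 0) return(rep(p, k))
  stopifnot(p > 0, p < 1)
  stats::rbeta(k, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Simulate a multi-population InDel study
#'
#' Emulates the design of a forensic InDel population survey: `k`
#' populations diverged from ancestral deletion-allele frequencies under
#' the Balding-Nichols model (optionally in two hierarchical clades), then
#' `n` diploid individuals per population genotyped at every locus under
#' HWE (or with inbreeding `f`) at that population's derived frequencies.
#'
#' A single RNG stream is seeded once; draws occur in a documented order
#' (clade frequencies locus by locus, then population frequencies locus by
#' locus, then genotypes population by population, locus by locus), so
#' adding populations or individuals does not silently change earlier
#' draws of the same run and every run is bit-reproducible.
#'
#' @param loci Named numeric vector of ancestral deletion-allele
#'   frequencies (default: the published 30-locus Xibe panel frequencies).
#' @param n Diploid individuals per population (default 223, the survey's
#'   sample size).
#' @param k Number of populations.
#' @param fst Balding-Nichols divergence of each population from the
#'   ancestor (ignored when `clades` is given).
#' @param clades Optional integer vector of length `k` with values 1 or 2
#'   assigning populations to two clades; clade ancestors diverge from the
#'   common ancestor at `fst_between`, populations from their clade
#'   ancestor at `fst_within`.
#' @param fst_within,fst_between Hierarchical divergence levels used when
#'   `clades` is given.
#' @param inbreeding_f Within-population inbreeding coefficient.
#' @param seed Integer seed (mandatory).
#' @return List of class `indel_simulation`: `populations` (named list of
#'   [genotype_matrix]), `true_freqs` (populations x loci matrix),
#'   `ancestral` (the input frequencies), `clades`, `fst`, `seed`.
#' @export
simulate_study <- function(loci = NULL, n = 223L, k = 1L, fst = 0,
                           clades = NULL, fst_within = 0.01,
                           fst_between = 0.15, inbreeding_f = 0, seed) {
  if (missing(seed)) stop("seed is mandatory for simulation")
  if (is.null(loci)) {
    panel <- xibe_panel()
    loci <- stats::setNames(panel$p_del, panel$locus_id)
  }
  stopifnot(!is.null(names(loci)), all(loci >= 0 & loci <= 1), n >= 1, k >= 1)
  if (!is.null(clades)) stopifnot(length(clades) == k, all(clades %in% 1:2))
  set.seed(as.integer(seed))
  n_loci <- length(loci)
  pop_names <- sprintf("pop%02d", seq_len(k))
  true_freqs <- matrix(NA_real_, k, n_loci,
                       dimnames = list(pop_names, names(loci)))
  for (l in seq_len(n_loci)) {
    p_anc <- loci[[l]]
    if (is.null(clades)) {
      true_freqs[, l] <- balding_nichols(p_anc, fst, k)
    } else {
      clade_p <- balding_nichols(p_anc, fst_between, 2L)
      for (pop in seq_len(k))
        true_freqs[pop, l] <- balding_nichols(clade_p[clades[pop]],
                                              fst_within, 1L)
    }
  }
  populations <- lapply(seq_len(k), function(pop) {
    calls <- matrix(NA_character_, n, n_loci,
                    dimnames = list(sprintf("%s_s%04d", pop_names[pop],
                                            seq_len(n)),
                                    names(loci)))
    for (l in seq_len(n_loci))
      calls[, l] <- sample_inbred_genotypes(true_freqs[pop, l],
                                            f = inbreeding_f, n = n)$calls
    genotype_matrix(calls)
  })
  structure(list(populations = stats::setNames(populations, pop_names),
                 true_freqs = true_freqs, ancestral = loci, clades = clades,
                 fst = if (is.null(clades)) fst
                       else c(within = fst_within, between = fst_between),
                 seed = as.integer(seed)),
            class = "indel_simulation")
}

#' Observed allele-frequency table of simulated (or real) populations
#'
#' @param populations Named list of [genotype_matrix] objects sharing loci.
#' @return Populations x loci matrix of observed deletion-allele
#'   frequencies, ready for [nei_da()], [pca_from_frequencies()] etc.
#' @export
population_frequency_table <- function(populations) {
  stopifnot(length(populations) >= 1, !is.null(names(populations)))
  loci <- colnames(populations[[1L]]$calls)
  out <- matrix(NA_real_, length(populations), length(loci),
                dimnames = list(names(populations), loci))
  for (i in seq_along(populations)) {
    cnts <- panel_counts(populations[[i]])
    out[i, ] <- vapply(cnts[loci], function(cnt)
      allele_frequencies(cnt)[["p_del"]], numeric(1L))
  }
  out
}
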