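#' Per-locus forensic efficiency parameters
#'
#' The standard forensic descriptors of a biallelic InDel locus, written
#' with `p` the deletion-allele frequency, `q = 1 - p`, `h` the observed
#' heterozygosity and `H = 1 - h`:
#'
#' * observed heterozygosity `Ho = n_di / n`;
#' * expected heterozygosity `He = 2pq` (no small-sample correction);
#' * polymorphic information content `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`
#'   (Botstein's biallelic form);
#' * power of exclusion `PE = h^2 (1 - 2 h H^2)` driven by the observed
#'   heterozygosity;
#' * discrimination power `DP = 1 - sum(g_i^2)` over the three *observed*
#'   genotype class frequencies `g_i` (not their HWE expectations);
#' * typical paternity index `TPI = 1 / (2 (1 - h))`.
#'
#' @param counts A [locus_counts] object.
#' @param p_del Deletion-allele frequency in \[0, 1\].
#' @param ho Observed heterozygosity in \[0, 1\]; any heterozygosity may be
#'   supplied to `power_of_exclusion()` (feeding `He` gives the
#'   HWE-expectation variant of PE instead of the observed-heterozygosity
#'   default).
#' @return A single numeric value.
#' @name forensic_parameters
NULL

#' @rdname forensic_parameters
#' @export
observed_heterozygosity <- function(counts) {
  stopifnot(inherits(counts, "locus_counts"))
  counts$n_di / counts$n
}

#' @rdname forensic_parameters
#' @export
expected_heterozygosity <- function(p_del) {
  stopifnot(p_del >= 0, p_del <= 1)
  2 * p_del * (1 - p_del)
}

#' @rdname forensic_parameters
#' @export
pic <- function(p_del) {
  stopifnot(p_del >= 0, p_del <= 1)
  q <- 1 - p_del
  1 - (p_del^2 + q^2) - 2 * p_del^2 * q^2
}

#' @rdname forensic_parameters
#' @export
power_of_exclusion <- function(ho) {
  stopifnot(ho >= 0, ho <= 1)
  H <- 1 - ho
  ho^2 * (1 - 2 * ho * H^2)
}

#' @rdname forensic_parameters
#' @export
discrimination_power <- function(counts) {
  stopifnot(inherits(counts, "locus_counts"))
  g <- c(counts$n_dd, counts$n_di, counts$n_ii) / counts$n
  1 - sum(g^2)
}

#' @rdname forensic_parameters
#' @export
typical_paternity_index <- function(ho) {
  stopifnot(ho >= 0, ho <= 1)
  if (ho == 1) stop("typical paternity index is undefined at ho = 1")
  1 / (2 * (1 - ho))
}

#' Combined powers of a multi-locus panel
#'
#' Treating loci as independent, the cumulative power of exclusion is
#' `CPE = 1 - prod(1 - PE_i)` and the combined discrimination power
#' `CPD = 1 - prod(1 - DP_i)`. The products of complements are accumulated
#' directly (in log space) so that panel-level complements of order 1e-12
#' remain accurate.
#'
#' @param pe Numeric vector of per-locus powers of exclusion.
#' @param dp Numeric vector of per-locus discrimination powers (same length).
#' @return List with `cpe`, `cpd`, `cpd_complement` (`prod(1 - DP_i)`, exact
#'   on the complement scale) and `n_loci`.
#' @examples
#' combined_powers(pe = c(0.5, 0.5), dp = c(0.5, 0.5))  # cpe = cpd = 0.75
#' @export
combined_powers <- function(pe, dp) {
  if (!length(pe)) stop("combined powers need at least one locus")
  stopifnot(length(pe) == length(dp),
            all(pe >= 0 & pe <= 1), all(dp >= 0 & dp <= 1))
  cpe_complement <- exp(sum(log1p(-pe)))
  cpd_complement <- exp(sum(log1p(-dp)))
  list(cpe = 1 - cpe_complement, cpd = 1 - cpd_complement,
       cpd_complement = cpd_complement, n_loci = length(pe))
}

#' Summarize a panel: per-locus forensic parameters and combined powers
#'
#' Accepts either a [genotype_matrix] (counts tallied per locus, missing
#' calls dropped) or a summary data frame with columns `locus_id`, `p_del`,
#' `ho`, `n` (as from [xibe_panel()] or [read_summary_table()]), in which
#' case integer genotype counts are first reconstructed with
#' [counts_from_summary()]. All statistics are computed at full precision
#' from the integer counts; [format_panel_report()] renders them at the
#' conventional four decimals.
#'
#' @param x A [genotype_matrix] or summary data frame.
#' @param hwe_method Hardy-Weinberg test reported in the `p_hwe` column:
#'   `"exact"` (default), `"chi2"`, or `"none"`.
#' @return Data frame with one row per locus and columns `locus_id`, `rs_id`,
#'   `n`, `n_dd`, `n_di`, `n_ii`, `p_del`, `p_ins`, `ho`, `he`, `p_hwe`,
#'   `pic`, `pe`, `dp`, `tpi`; the [combined_powers()] list is attached as
#'   attribute `"panel_powers"`.
#' @export
summarize_panel <- function(x, hwe_method = c("exact", "chi2", "none")) {
  hwe_method <- match.arg(hwe_method)
  counts <- if (inherits(x, "genotype_matrix")) {
    panel_counts(x)
  } else if (is.data.frame(x)) {
    need <- c("locus_id", "p_del", "ho", "n")
    if (!all(need %in% names(x)))
      stop("summary data frame needs columns: ", paste(need, collapse = ", "))
    if (!nrow(x)) stop("empty panel: no loci to summarize")
    rs <- if ("rs_id" %in% names(x)) x$rs_id else rep(NA_character_, nrow(x))
    stats::setNames(
      lapply(seq_len(nrow(x)), function(i)
        counts_from_summary(x$p_del[i], x$ho[i], x$n[i],
                            locus_id = x$locus_id[i], rs_id = rs[i])),
      x$locus_id)
  } else {
    stop("x must be a genotype_matrix or a summary data frame")
  }
  if (!length(counts)) stop("empty panel: no loci to summarize")
  rows <- lapply(counts, function(cnt) {
    p <- allele_frequencies(cnt)
    ho <- observed_heterozygosity(cnt)
    p_hwe <- switch(hwe_method,
                    exact = hwe_exact(cnt)$p_value,
                    chi2  = hwe_chi2(cnt)$p_value,
                    none  = NA_real_)
    data.frame(locus_id = cnt$locus_id, rs_id = cnt$rs_id, n = cnt$n,
               n_dd = cnt$n_dd, n_di = cnt$n_di, n_ii = cnt$n_ii,
               p_del = p[["p_del"]], p_ins = p[["p_ins"]],
               ho = ho, he = expected_heterozygosity(p[["p_del"]]),
               p_hwe = p_hwe, pic = pic(p[["p_del"]]),
               pe = power_of_exclusion(ho),
               dp = discrimination_power(cnt),
               tpi = typical_paternity_index(ho),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "panel_powers") <- combined_powers(out$pe, out$dp)
  out
}

#' Render a panel summary at four-decimal report precision
#'
#' Rounds the frequency-scale columns of a [summarize_panel()] result
#' half-up to four decimals, the convention of published forensic panel
#' tables; the input keeps full precision.
#'
#' @param summary A data frame from [summarize_panel()].
#' @return Data frame with columns `locus_id`, `rs_id`, `p_del`, `p_ins`,
#'   `ho`, `he`, `p_hwe`, `pic`, `pe`, `dp`, `tpi` rounded to 4 decimals.
#' @export
format_panel_report <- function(summary) {
  cols <- c("p_del", "p_ins", "ho", "he", "p_hwe", "pic", "pe", "dp", "tpi")
  out <- summary[, c("locus_id", "rs_id", cols)]
  out[cols] <- lapply(out[cols], round_half_up, digits = 4L)
  out
}

# round half away from zero, the convention of spreadsheet-era reports
# (base round() rounds half to even: round(0.00005, 4) == 0)
round_half_up <- function(x, digits = 4L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
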