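#' Genotype counts at one biallelic InDel locus
#'
#' Container for the integer genotype counts at a single deletion/insertion
#' polymorphism: deletion homozygotes (`n_dd`), heterozygotes (`n_di`) and
#' insertion homozygotes (`n_ii`). The deletion allele is the short (DIP-)
#' allele, the insertion allele the long (DIP+) allele; the canonical class
#' order is always DD, DI, II.
#'
#' @param n_dd,n_di,n_ii Non-negative integer counts of the three genotype
#'   classes. At least one individual in total is required.
#' @param locus_id Optional locus label (e.g. `"HLD92"`).
#' @param rs_id Optional dbSNP-style identifier.
#' @return An object of class `locus_counts`: a list with elements `n_dd`,
#'   `n_di`, `n_ii`, `n` (their sum), `locus_id` and `rs_id`.
#' @examples
#' locus_counts(57, 117, 49, locus_id = "HLD92")
#' @export
locus_counts <- function(n_dd, n_di, n_ii, locus_id = NA_character_,
                         rs_id = NA_character_) {
  cnt <- c(n_dd, n_di, n_ii)
  if (length(cnt) != 3L || anyNA(cnt) || !is.numeric(cnt))
    stop("n_dd, n_di and n_ii must be single non-missing numbers")
  if (any(cnt < 0) || any(abs(cnt - round(cnt)) > 1e-8))
    stop("genotype counts must be non-negative integers")
  cnt <- as.integer(round(cnt))
  n <- sum(cnt)
  if (n < 1L) stop("at least one genotyped individual is required (n >= 1)")
  structure(
    list(n_dd = cnt[1L], n_di = cnt[2L], n_ii = cnt[3L], n = n,
         locus_id = as.character(locus_id), rs_id = as.character(rs_id)),
    class = "locus_counts"
  )
}

#' @export
print.locus_counts <- function(x, ...) {
  id <- if (is.na(x$locus_id)) "" else paste0(" [", x$locus_id, "]")
  cat(sprintf("locus_counts%s: DD=%d DI=%d II=%d (n=%d, p_del=%.4f)\n",
              id, x$n_dd, x$n_di, x$n_ii, x$n, allele_frequencies(x)[["p_del"]]))
  invisible(x)
}

#' Allele frequencies from genotype counts
#'
#' The deletion (short, DIP-) allele frequency is
#' `p_del = (2 n_dd + n_di) / (2 n)`; the insertion (long, DIP+) frequency is
#' its complement, never stored independently, so the two always sum to one
#' exactly.
#'
#' @param counts A [locus_counts] object.
#' @return Named numeric vector `c(p_del = , p_ins = )`.
#' @examples
#' allele_frequencies(locus_counts(57, 117, 49))  # p_del = 231/446
#' @export
allele_frequencies <- function(counts) {
  stopifnot(inherits(counts, "locus_counts"))
  p <- (2 * counts$n_dd + counts$n_di) / (2 * counts$n)
  c(p_del = p, p_ins = 1 - p)
}

#' Reconstruct integer genotype counts from a published summary row
#'
#' Population surveys typically print, per locus, the deletion-allele
#' frequency, the observed heterozygosity and the sample size, each rounded
#' to four decimals. Because the underlying counts are integers, the triple
#' can be inverted exactly: the heterozygote count is `round(ho * n)` and the
#' deletion-allele count is `round(p_del * 2n)`. When rounding leaves the two
#' with incompatible parity (the deletion-homozygote count must be an
#' integer), the allele count is nudged by one in the direction that best
#' matches the printed frequency (ties resolved downward) and the result is
#' flagged.
#'
#' The reconstruction is verified by round-trip: re-deriving `p_del` and `ho`
#' from the integer counts must match the inputs to within `tol` (default
#' half a unit in the fourth printed decimal).
#'
#' @param p_del Printed deletion (DIP-) allele frequency in \[0, 1\].
#' @param ho Printed observed heterozygosity in \[0, 1\].
#' @param n Diploid sample size.
#' @param locus_id,rs_id Optional labels carried through.
#' @param tol Round-trip tolerance on the reconstructed frequencies.
#' @return A [locus_counts] object with attribute `parity_adjusted` (logical).
#' @examples
#' counts_from_summary(0.5179, 0.5247, 223)  # DD=57 DI=117 II=49
#' @export
counts_from_summary <- function(p_del, ho, n, locus_id = NA_character_,
                                rs_id = NA_character_, tol = 5e-4) {
  stopifnot(p_del >= 0, p_del <= 1, ho >= 0, ho <= 1, n >= 1)
  n <- as.integer(n)
  n_di <- as.integer(round(ho * n))
  a <- as.integer(round(p_del * 2 * n))          # deletion-allele count
  adjusted <- FALSE
  if ((a - n_di) %% 2L != 0L) {
    cand <- c(a - 1L, a + 1L)
    err <- abs(p_del - cand / (2 * n))
    a <- if (err[2L] < err[1L]) cand[2L] else cand[1L]  # tie -> subtract 1
    adjusted <- TRUE
  }
  n_dd <- (a - n_di) %/% 2L
  n_ii <- n - n_di - n_dd
  if (n_dd < 0L || n_ii < 0L || n_di < 0L)
    stop(sprintf("inconsistent summary row%s: reconstructed counts (%d, %d, %d) are negative",
                 if (is.na(locus_id)) "" else paste0(" at ", locus_id),
                 n_dd, n_di, n_ii))
  cnt <- locus_counts(n_dd, n_di, n_ii, locus_id = locus_id, rs_id = rs_id)
  p_back <- allele_frequencies(cnt)[["p_del"]]
  ho_back <- cnt$n_di / cnt$n
  if (abs(p_back - p_del) > tol)
    stop(sprintf("round-trip mismatch in p_del%s: printed %.4f, reconstructed %.6f",
                 if (is.na(locus_id)) "" else paste0(" at ", locus_id), p_del, p_back))
  if (abs(ho_back - ho) > tol)
    stop(sprintf("round-trip mismatch in ho%s: printed %.4f, reconstructed %.6f",
                 if (is.na(locus_id)) "" else paste0(" at ", locus_id), ho, ho_back))
  attr(cnt, "parity_adjusted") <- adjusted
  cnt
}

#' Published 30-locus InDel panel summary for the Chinese Xibe population
#'
#' Per-locus summary statistics (deletion-allele frequency, observed
#' heterozygosity, sample size) of the Investigator DIPplex 30-locus InDel
#' panel from a published population survey of 223 unrelated Chinese Xibe
#' individuals. These rows are the package's default emulation profile for
#' the synthetic-data generator and the input from which exact integer
#' genotype counts can be reconstructed with [counts_from_summary()].
#'
#' @return Data frame with columns `locus_id`, `rs_id`, `p_del`, `ho`, `n`
#'   (30 rows).
#' @examples
#' head(xibe_panel())
#' @export
xibe_panel <- function() {
  path <- system.file("extdata", "xibe_indel_panel.csv", package = "indelpop",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a summary table of published per-locus rows
#'
#' CSV with columns `locus_id`, `rs_id`, `p_del`, `ho`, `n` (extra columns
#' are ignored), one row per locus.
#'
#' @param path File path.
#' @return Data frame in the same layout as [xibe_panel()].
#' @export
read_summary_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "p_del", "ho", "n")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("summary table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"rs_id" %in% names(df)) df$rs_id <- NA_character_
  if (anyDuplicated(df$locus_id))
    stop("duplicate locus_id in summary table")
  df[, c("locus_id", "rs_id", "p_del", "ho", "n")]
}
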