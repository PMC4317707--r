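test_that("per-locus parameters reproduce the published headline values", {
  # heterozygosities
  expect_equal(round(observed_heterozygosity(locus_counts(57, 117, 49)), 4),
               0.5247)
  expect_equal(round(expected_heterozygosity(38 / 446), 4), 0.1559)
  expect_equal(round(expected_heterozygosity(228 / 446), 4), 0.4997)
  expect_equal(expected_heterozygosity(0.5), 0.5)
  # polymorphic information content
  expect_equal(round(pic(228 / 446), 4), 0.3749)
  expect_equal(round(pic(38 / 446), 4), 0.1437)
  expect_equal(pic(0.5), 0.375)
  # power of exclusion
  expect_equal(round(power_of_exclusion(117 / 223), 4), 0.2100)
  expect_equal(round(power_of_exclusion(38 / 223), 4), 0.0222)
  expect_equal(power_of_exclusion(0), 0)
  # discrimination power
  expect_equal(round(discrimination_power(locus_counts(0, 38, 185)), 4), 0.2827)
  expect_equal(round(discrimination_power(locus_counts(60, 108, 55)), 4), 0.6322)
  expect_equal(discrimination_power(locus_counts(10, 0, 0)), 0)
  # typical paternity index
  expect_equal(round(typical_paternity_index(117 / 223), 4), 1.0519)
  expect_equal(round(typical_paternity_index(38 / 223), 4), 0.6027)
  expect_equal(typical_paternity_index(0.5), 1)
  expect_error(typical_paternity_index(1), "undefined")
})

test_that("PIC is strictly below He on (0,1) and both peak at p = 0.5", {
  p <- seq(0.01, 0.99, by = 0.01)
  he <- vapply(p, expected_heterozygosity, numeric(1))
  pv <- vapply(p, pic, numeric(1))
  expect_true(all(pv < he))
  expect_equal(p[which.max(he)], 0.5)
  expect_equal(p[which.max(pv)], 0.5)
})

test_that("DP stays below 1 and is 0 only for a single genotype class", {
  set.seed(5)
  for (i in 1:50) {
    cnt <- as.vector(stats::rmultinom(1, 100, runif(3)))
    if (sum(cnt) == 0) next
    dp <- discrimination_power(locus_counts(cnt[1], cnt[2], cnt[3]))
    expect_lt(dp, 1)
    expect_identical(dp == 0, sum(cnt > 0) == 1L)
  }
})

test_that("TPI is strictly increasing in observed heterozygosity", {
  ho <- seq(0, 0.99, by = 0.01)
  tpi <- vapply(ho, typical_paternity_index, numeric(1))
  expect_true(all(diff(tpi) > 0))
  expect_true(all(tpi >= 0.5))
})

test_that("combined powers multiply complements and behave monotonically", {
  expect_equal(combined_powers(0.5, 0.5)$cpe, 0.5)   # single locus: identity
  expect_equal(combined_powers(c(0.5, 0.5), c(0.2, 0.2))$cpe, 0.75)
  pe <- c(0.1, 0.2, 0.05)
  dp <- c(0.6, 0.3, 0.4)
  pw <- combined_powers(pe, dp)
  perm <- c(3, 1, 2)
  expect_equal(combined_powers(pe[perm], dp[perm]), pw)  # order-invariant
  grown <- combined_powers(c(pe, 0.01), c(dp, 0.01))
  expect_gte(grown$cpe, pw$cpe)                          # monotone
  expect_gte(grown$cpd, pw$cpd)
  expect_gte(pw$cpe, max(pe))
  expect_gte(pw$cpd, max(dp))
  expect_error(combined_powers(numeric(0), numeric(0)), "at least one locus")
})

test_that("panel summary from summary rows carries all columns coherently", {
  s <- summarize_panel(xibe_panel(), hwe_method = "none")
  expect_equal(nrow(s), 30)
  expect_equal(s$n_dd + s$n_di + s$n_ii, s$n)
  expect_equal(s$ho, s$n_di / s$n)
  expect_true(all(s$he <= 0.5 + 1e-12))
  expect_true(all(s$pic < s$he))
  expect_true(all(s$tpi >= 0.5))
  pw <- attr(s, "panel_powers")
  expect_equal(pw$n_loci, 30)
  expect_gte(pw$cpe, max(s$pe))
})

test_that("a simulated study at panel frequencies lands in the sampling envelope", {
  sim <- simulate_study(n = 223, k = 1, fst = 0, seed = 91)
  s <- summarize_panel(sim$populations[[1]], hwe_method = "none")
  panel <- published_panel_table()
  panel <- panel[match(s$locus_id, panel$locus_id), ]
  expect_true(all(abs(s$he - panel$he) <= 0.05))
})

test_that("empty input is refused", {
  expect_error(summarize_panel(xibe_panel()[0, ]), "empty panel")
  expect_error(summarize_panel(1:3), "genotype_matrix or a summary")
})

test_that("report rendering rounds half away from zero at four decimals", {
  s <- summarize_panel(data.frame(locus_id = "L1", p_del = 0.5179,
                                  ho = 0.5247, n = 223),
                       hwe_method = "none")
  r <- format_panel_report(s)
  expect_equal(r$pe, 0.2100)
  expect_equal(r$tpi, 1.0519)
  # 117/223 * something landing exactly on .xxxx5 must round up, not to even
  expect_equal(indelpop:::round_half_up(0.00005, 4), 1e-4)
  expect_equal(indelpop:::round_half_up(-0.00005, 4), -1e-4)
})
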