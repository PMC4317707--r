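test_that("theta matches the variance-component oracle and its bounds", {
  # equal sample frequencies force a non-positive among-population component
  c1 <- locus_counts(60, 108, 55)
  th <- pairwise_fst(c1, c1)
  expect_lte(as.numeric(th), 0)
  expect_equal(as.numeric(th), wc_theta_oracle(c1, c1), tolerance = 1e-12)
  # complete fixation for opposite alleles
  expect_equal(as.numeric(pairwise_fst(locus_counts(50, 0, 0),
                                       locus_counts(0, 0, 50))), 1)
  # random pairs agree with the direct component evaluation
  set.seed(21)
  for (rep in 1:20) {
    a <- as.vector(stats::rmultinom(1, 150, runif(3, 0.05, 1)))
    b <- as.vector(stats::rmultinom(1, 90, runif(3, 0.05, 1)))
    ca <- locus_counts(a[1], a[2], a[3]); cb <- locus_counts(b[1], b[2], b[3])
    expect_equal(as.numeric(pairwise_fst(ca, cb)), wc_theta_oracle(ca, cb),
                 tolerance = 1e-12)
    expect_lte(as.numeric(pairwise_fst(ca, cb)), 1)
  }
})

test_that("theta is invariant to population order and allele relabeling", {
  set.seed(22)
  for (rep in 1:15) {
    a <- as.vector(stats::rmultinom(1, 120, runif(3, 0.05, 1)))
    b <- as.vector(stats::rmultinom(1, 80, runif(3, 0.05, 1)))
    ca <- locus_counts(a[1], a[2], a[3]); cb <- locus_counts(b[1], b[2], b[3])
    ca_m <- locus_counts(a[3], a[2], a[1]); cb_m <- locus_counts(b[3], b[2], b[1])
    th <- as.numeric(pairwise_fst(ca, cb))
    expect_equal(as.numeric(pairwise_fst(cb, ca)), th, tolerance = 1e-12)
    expect_equal(as.numeric(pairwise_fst(ca_m, cb_m)), th, tolerance = 1e-12)
  }
})

test_that("a pooled-monomorphic locus is an error, not a zero", {
  expect_error(pairwise_fst(locus_counts(10, 0, 0), locus_counts(20, 0, 0)),
               "monomorphic")
  expect_error(pairwise_fst(locus_counts(1, 0, 0), locus_counts(0, 0, 5)),
               "n >= 2")
})

test_that("permutation p-values are deterministic given the seed", {
  set.seed(23)
  g1 <- sample_hwe_genotypes(0.4, 60)$calls
  g2 <- sample_hwe_genotypes(0.6, 60)$calls
  r1 <- fst_permutation(g1, g2, n_perm = 200, seed = 99)
  r2 <- fst_permutation(g1, g2, n_perm = 200, seed = 99)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$fst, r2$fst)
  expect_error(fst_permutation(g1, g2, n_perm = 200), "seed is mandatory")
  expect_error(fst_permutation(g1, g2, n_perm = 50, seed = 1), "at least 100")
})

test_that("opposite fixation attains the minimum possible p-value", {
  g1 <- rep("DD", 40)
  g2 <- rep("II", 40)
  res <- fst_permutation(g1, g2, n_perm = 199, seed = 7)
  expect_equal(res$p_value, 1 / 200)
})

test_that("under the null the permutation test rarely rejects", {
  set.seed(24)
  pv <- vapply(1:100, function(i) {
    g1 <- sample_hwe_genotypes(0.5, 50)$calls
    g2 <- sample_hwe_genotypes(0.5, 50)$calls
    fst_permutation(g1, g2, n_perm = 100, seed = 1000 + i)$p_value
  }, numeric(1))
  expect_gte(mean(pv > 0.05), 0.9)
})

test_that("a population compared with itself flags no locus", {
  sim <- simulate_study(n = 120, k = 1, fst = 0, seed = 25,
                        loci = c(HLD1 = 0.3, HLD2 = 0.5, HLD3 = 0.7))
  gm <- sim$populations[[1]]
  tab <- differentiation_table(gm, list(self = gm), n_perm = 199, seed = 8)
  expect_true(all(tab$significant == FALSE))
  expect_equal(unname(attr(tab, "n_significant")["self"]), 0)
})

test_that("loci absent from a reference yield no-result rows", {
  sim <- simulate_study(n = 80, k = 2, fst = 0.02, seed = 26,
                        loci = c(HLD1 = 0.3, HLD2 = 0.5, HLD3 = 0.7))
  target <- sim$populations[[1]]
  ref <- sim$populations[[2]]
  ref_sub <- genotype_matrix(ref$calls[, c("HLD1", "HLD3")])
  tab <- differentiation_table(target, list(partial = ref_sub),
                               n_perm = 199, seed = 9)
  expect_equal(nrow(tab), 3)
  expect_true(is.na(tab$fst[tab$locus_id == "HLD2"]))
  expect_equal(sum(!is.na(tab$fst)), 2)
})

test_that("significant-locus counts grow with the generating divergence", {
  panel <- xibe_panel()
  loci <- stats::setNames(panel$p_del, panel$locus_id)
  target <- simulate_study(loci = loci, n = 223, k = 1, fst = 0,
                           seed = 261)$populations[[1]]
  refs <- list(
    null = simulate_study(loci = loci, n = 200, k = 1, fst = 0,
                          seed = 262)$populations[[1]],
    mild = simulate_study(loci = loci, n = 200, k = 1, fst = 0.02,
                          seed = 263)$populations[[1]],
    strong = simulate_study(loci = loci, n = 200, k = 1, fst = 0.2,
                            seed = 264)$populations[[1]])
  tab <- differentiation_table(target, refs, n_perm = 199, seed = 265)
  n_sig <- attr(tab, "n_significant")
  expect_true(n_sig[["null"]] <= n_sig[["mild"]])
  expect_true(n_sig[["mild"]] <= n_sig[["strong"]])
  expect_gte(n_sig[["strong"]], 15)  # Fst = 0.2 is detected at most loci
})

test_that("frequency-only references are usable and flagged approximate", {
  sim <- simulate_study(n = 100, k = 1, fst = 0, seed = 27,
                        loci = c(HLD1 = 0.3, HLD2 = 0.6))
  ref <- list(freq = c(HLD1 = 0.31, HLD2 = 0.58), n = 150)
  tab <- differentiation_table(sim$populations[[1]], list(pub = ref),
                               n_perm = 199, seed = 10)
  expect_true(all(tab$approx_reference))
  expect_true(all(is.finite(tab$fst)))
  expect_error(
    differentiation_table(sim$populations[[1]],
                          list(far = list(freq = c(OTHER = 0.5), n = 50)),
                          n_perm = 199, seed = 11),
    "no shared loci")
})
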