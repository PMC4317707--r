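freqs2 <- function(x, y) {
  m <- rbind(X = x, Y = y)
  colnames(m) <- sprintf("L%d", seq_len(ncol(m)))
  m
}

test_that("Nei DA distance matches hand-evaluated cases and its bounds", {
  m <- freqs2(c(0.2, 0.6), c(0.2, 0.6))
  expect_equal(unname(nei_da(m)["X", "Y"]), 0)
  m2 <- freqs2(c(1, 1, 0), c(0, 0, 1))
  expect_equal(unname(nei_da(m2)["X", "Y"]), 1)
  # hand evaluation: 1 - mean(sqrt(.2*.4)+sqrt(.8*.6), sqrt(.6*.6)+sqrt(.4*.4))
  m3 <- freqs2(c(0.2, 0.6), c(0.4, 0.6))
  expect_equal(unname(nei_da(m3)["X", "Y"]), 0.012168482248915, tolerance = 1e-9)
  d <- nei_da(m3)
  expect_equal(d, t(d))
  expect_equal(diag(d), c(X = 0, Y = 0))
})

test_that("Nei standard distance matches hand evaluation and flags Jxy = 0", {
  m <- freqs2(c(0.2, 0.6), c(0.2, 0.6))
  expect_equal(unname(nei_ds(m)["X", "Y"]), 0)
  m3 <- freqs2(c(0.2, 0.6), c(0.4, 0.6))
  # Jx = 0.6, Jy = 0.52, Jxy = 0.54 -> -log(0.54 / sqrt(0.312))
  expect_equal(unname(nei_ds(m3)["X", "Y"]), 0.0338100938374896, tolerance = 1e-9)
  m2 <- freqs2(c(1, 1), c(0, 0))
  expect_warning(d <- nei_ds(m2), "infinite")
  expect_equal(unname(d["X", "Y"]), Inf)
})

test_that("pairs without shared loci are refused; NA loci are masked per pair", {
  m <- rbind(X = c(0.2, NA), Y = c(NA, 0.6))
  colnames(m) <- c("L1", "L2")
  expect_error(nei_da(m), "no shared loci")
  m2 <- rbind(X = c(0.2, NA, 0.5), Y = c(0.4, 0.9, 0.5))
  colnames(m2) <- c("L1", "L2", "L3")
  # only L1 and L3 are shared; L2 must not contribute
  expect_equal(unname(nei_da(m2)["X", "Y"]),
               unname(nei_da(rbind(X = c(0.2, 0.5), Y = c(0.4, 0.5)))["X", "Y"]))
})

test_that("UPGMA on forced topologies yields the expected Newick text", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(d)
  expect_identical(write_newick(tree), "((A:1,B:1):1,C:2);")
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_identical(write_newick(upgma(d2)), "(A:1.5,B:1.5);")
})

test_that("UPGMA input validation rejects broken matrices", {
  d <- matrix(c(0, -1, -1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(upgma(d), "non-negative")
  d2 <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(upgma(d2), "not symmetric")
  expect_error(upgma(matrix(0, 1, 1, dimnames = list("A", "A"))), "two taxa")
})

test_that("UPGMA reproduces ultrametric matrices exactly", {
  set.seed(61)
  for (rep in 1:8) {
    n_tip <- sample(4:10, 1)
    ref <- ape::rcoal(n_tip)                 # random ultrametric tree
    d <- ape::cophenetic.phylo(ref)
    tree <- upgma(d)
    coph <- cophenetic_distances(tree)[rownames(d), colnames(d)]
    expect_lt(max(abs(coph - d)), 1e-9)
  }
})

test_that("UPGMA agrees with average-linkage hclust on generic matrices", {
  set.seed(62)
  for (rep in 1:8) {
    n <- sample(4:9, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- sprintf("T%02d", seq_len(n))
    d <- as.matrix(stats::dist(x))
    tree <- upgma(d)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(cophenetic_distances(tree)[rownames(d), colnames(d)],
                 as.matrix(stats::cophenetic(hc))[rownames(d), colnames(d)],
                 tolerance = 1e-9)
    # merge heights never decrease, and root-to-tip depths are all equal
    expect_true(all(diff(sort(unique(ape::branching.times(tree)))) >= -1e-12))
    depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
    expect_lt(diff(range(depths)), 1e-9)
  }
})

test_that("tied merges resolve by smallest label pair, stable across runs", {
  lab <- c("B", "A", "D", "C")
  d <- matrix(1, 4, 4, dimnames = list(lab, lab))
  diag(d) <- 0
  nwk1 <- write_newick(upgma(d))
  nwk2 <- write_newick(upgma(d[c(3, 1, 4, 2), c(3, 1, 4, 2)]))
  expect_identical(nwk1, nwk2)
  expect_match(nwk1, "\\(A:0.5,B:0.5\\)", fixed = FALSE)
})

test_that("Newick output round-trips through a parser", {
  set.seed(63)
  ref <- ape::rcoal(7)
  tree <- upgma(ape::cophenetic.phylo(ref))
  back <- read_newick(write_newick(tree))
  expect_equal(sort(back$tip.label), sort(tree$tip.label))
  expect_lt(max(abs(cophenetic_distances(back)[tree$tip.label, tree$tip.label] -
                    cophenetic_distances(tree))), 1e-9)
})
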