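# Independent oracles and small fixture builders used across the suite.

# Brute-force HWE exact test: probability of every heterozygote count with
# the right parity via the closed-form log-factorial expression (independent
# of the package's normalized recurrence).
hwe_enum_oracle <- function(n_dd, n_di, n_ii) {
  n <- n_dd + n_di + n_ii
  na <- 2 * n_dd + n_di
  nb <- 2 * n_ii + n_di
  minor <- min(na, nb)
  if (minor < 1) return(1)
  hets <- seq(minor %% 2, minor, by = 2)
  lp <- vapply(hets, function(h) {
    d <- (na - h) / 2
    i <- (nb - h) / 2
    lfactorial(n) - lfactorial(d) - lfactorial(h) - lfactorial(i) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp)
  p_obs <- pr[hets == n_di]
  min(sum(pr[pr <= p_obs * (1 + 1e-12)]), 1)
}

# Literal transcription of the Weir-Cockerham (1984) two-population variance
# components, kept separate from the package's implementation.
wc_theta_oracle <- function(c1, c2) {
  n <- c(c1$n, c2$n)
  p <- c((2 * c1$n_dd + c1$n_di) / (2 * c1$n),
         (2 * c2$n_dd + c2$n_di) / (2 * c2$n))
  h <- c(c1$n_di / c1$n, c2$n_di / c2$n)
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# Mean 1-D silhouette of a two-group labelling along a single score axis.
silhouette_1d <- function(score, group) {
  stopifnot(length(score) == length(group))
  mean(vapply(seq_along(score), function(i) {
    same <- group == group[i]
    same[i] <- FALSE
    a <- mean(abs(score[i] - score[same]))
    b <- mean(abs(score[i] - score[!same]))
    (b - a) / max(a, b)
  }, numeric(1)))
}

# Tip labels on each side of the deepest (root) split of a rooted tree.
root_split <- function(tree) {
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  lapply(kids, function(k) {
    if (k <= length(tree$tip.label)) tree$tip.label[k]
    else ape::extract.clade(tree, k)$tip.label
  })
}

split_matches_clades <- function(tree, clade_of) {
  sides <- root_split(tree)
  if (length(sides) != 2) return(FALSE)
  g1 <- unique(clade_of[sides[[1]]])
  g2 <- unique(clade_of[sides[[2]]])
  length(g1) == 1 && length(g2) == 1 && g1 != g2
}

# Quick genotype_matrix from a list of per-locus call vectors.
gm_from_calls <- function(...) {
  loci <- list(...)
  calls <- do.call(cbind, loci)
  rownames(calls) <- sprintf("s%03d", seq_len(nrow(calls)))
  genotype_matrix(calls)
}

# The published 30-locus panel with its printed derived statistics, used to
# check full-table reproduction (inputs p_del/ho/n ship with the package;
# the derived columns are the printed reference values).
published_panel_table <- function() {
  derived <- read.csv(text = 'locus_id,he,pic,pe,dp,tpi
HLD6,0.4964,0.3732,0.1741,0.6288,0.9696
HLD39,0.2584,0.2250,0.0453,0.4150,0.6677
HLD40,0.4696,0.3593,0.1895,0.5935,1.0045
HLD45,0.4650,0.3569,0.1462,0.6118,0.9065
HLD48,0.4831,0.3664,0.1895,0.6070,1.0045
HLD56,0.4805,0.3651,0.1495,0.6258,0.9139
HLD58,0.4204,0.3320,0.1107,0.5814,0.8259
HLD64,0.3600,0.2952,0.0796,0.5267,0.7534
HLD67,0.4073,0.3244,0.1367,0.5585,0.8849
HLD70,0.4728,0.3610,0.1367,0.6240,0.8849
HLD77,0.4995,0.3748,0.1895,0.6234,1.0045
HLD81,0.2646,0.2296,0.0423,0.4188,0.6598
HLD83,0.4823,0.3660,0.1704,0.6167,0.9612
HLD84,0.3168,0.2666,0.0549,0.4788,0.6925
HLD88,0.4877,0.3688,0.1529,0.6313,0.9215
HLD92,0.4994,0.3747,0.2100,0.6111,1.0519
HLD93,0.4707,0.3599,0.1855,0.5968,0.9955
HLD97,0.4685,0.3587,0.1189,0.6268,0.8447
HLD99,0.2646,0.2296,0.0367,0.4134,0.6445
HLD101,0.4997,0.3749,0.1741,0.6322,0.9696
HLD111,0.2162,0.1928,0.0381,0.3665,0.6483
HLD114,0.4357,0.3408,0.1430,0.5840,0.8992
HLD118,0.1559,0.1437,0.0222,0.2827,0.6027
HLD122,0.3974,0.3185,0.1004,0.5613,0.8022
HLD124,0.4847,0.3672,0.1975,0.6039,1.0229
HLD125,0.4831,0.3664,0.1668,0.6195,0.9530
HLD128,0.4614,0.3549,0.1305,0.6151,0.8711
HLD131,0.4307,0.3380,0.1107,0.5918,0.8259
HLD133,0.4823,0.3660,0.1632,0.6206,0.9449
HLD136,0.4964,0.3732,0.2058,0.6107,1.0421',
    stringsAsFactors = FALSE)
  merge(xibe_panel(), derived, by = "locus_id", sort = FALSE)
}
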