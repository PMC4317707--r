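freq_matrix_check <- function(freqs) {
  if (!is.matrix(freqs) || !is.numeric(freqs))
    stop("freqs must be a numeric populations x loci matrix of p_del")
  if (is.null(rownames(freqs))) stop("freqs needs population names as rownames")
  if (nrow(freqs) < 2L) stop("at least two populations are required")
  rng <- range(freqs, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("allele frequencies must lie in [0, 1]")
  freqs
}

pairwise_over_loci <- function(freqs, f) {
  pops <- rownames(freqs)
  k <- length(pops)
  d <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    shared <- !is.na(freqs[i, ]) & !is.na(freqs[j, ])
    if (!any(shared))
      stop("no shared loci between populations ", pops[i], " and ", pops[j])
    d[i, j] <- d[j, i] <- f(freqs[i, shared], freqs[j, shared])
  }
  d
}

#' Nei DA genetic distance between populations
#'
#' Allele-sharing distance of Nei, Tajima & Tateno (1983):
#' `DA = 1 - (1/L) * sum over loci of sum over alleles of sqrt(x_a * y_a)`,
#' here with the two alleles (deletion, insertion) per biallelic locus. DA
#' lies in \[0, 1\]; it is 0 for identical frequency profiles and 1 for
#' populations fixed for opposite alleles at every locus. Loci missing
#' (`NA`) in either population of a pair are masked for that pair.
#'
#' @param freqs Numeric populations x loci matrix of deletion-allele
#'   frequencies with population names as rownames.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
nei_da <- function(freqs) {
  freqs <- freq_matrix_check(freqs)
  pairwise_over_loci(freqs, function(x, y)
    1 - mean(sqrt(x * y) + sqrt((1 - x) * (1 - y))))
}

#' Nei standard genetic distance between populations
#'
#' `Ds = -log(Jxy / sqrt(Jx * Jy))` with gene identities
#' `Jx = mean(x^2 + (1-x)^2)`, `Jy` likewise and
#' `Jxy = mean(x*y + (1-x)*(1-y))`, averaged over loci. Populations fixed
#' for opposite alleles at every shared locus have `Jxy = 0` and infinite
#' distance; `Inf` is returned with a warning.
#'
#' @inheritParams nei_da
#' @return Symmetric distance matrix with zero diagonal (possibly `Inf`
#'   off-diagonal).
#' @export
nei_ds <- function(freqs) {
  freqs <- freq_matrix_check(freqs)
  pairwise_over_loci(freqs, function(x, y) {
    jx <- mean(x^2 + (1 - x)^2)
    jy <- mean(y^2 + (1 - y)^2)
    jxy <- mean(x * y + (1 - x) * (1 - y))
    if (jxy == 0) {
      warning("zero cross-population gene identity; Ds is infinite")
      return(Inf)
    }
    -log(jxy / sqrt(jx * jy))
  })
}

#' UPGMA tree from a distance matrix
#'
#' Unweighted pair-group agglomeration with arithmetic means: repeatedly
#' merge the closest pair of clusters; the distance from the merged cluster
#' to any other is the size-weighted mean of its members' distances, and the
#' merge node sits at height (merge distance)/2 so branch lengths are in
#' distance units and the tree is ultrametric. Ties are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest leaf), and within each merge the cluster with the smaller
#' label is listed first, so the topology and Newick output are
#' deterministic.
#'
#' @param d Symmetric numeric distance matrix with labels, zero diagonal,
#'   no negative or missing entries.
#' @return A rooted ultrametric tree of class `phylo` (ape).
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' write_newick(upgma(d))  # ((A:1,B:1):1,C:2);
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) stop("d must be a numeric matrix")
  labels <- rownames(d)
  if (is.null(labels)) stop("d needs labels as dimnames")
  n <- nrow(d)
  if (n < 2L) stop("at least two taxa are required")
  if (anyNA(d) || any(d < 0)) stop("distances must be non-negative and non-missing")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")

  # active clusters: id < 0 is leaf -id (hclust convention), id > 0 a merge row
  active <- as.list(-seq_len(n))
  key <- labels                 # lexicographic key: smallest leaf label
  size <- rep(1L, n)
  dm <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  idx <- seq_len(n)             # live row/col indices of dm
  for (step in seq_len(n - 1L)) {
    m <- length(idx)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      dij <- dm[idx[i], idx[j]]
      ki <- key[idx[i]]; kj <- key[idx[j]]
      pair_key <- if (ki <= kj) c(ki, kj) else c(kj, ki)
      if (is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
           (pair_key[1L] < best$key[1L] ||
            (pair_key[1L] == best$key[1L] && pair_key[2L] < best$key[2L])))) {
        best <- list(i = idx[i], j = idx[j], d = dij, key = pair_key)
      }
    }
    i <- best$i; j <- best$j
    # list the cluster whose key is smaller first
    first <- if (key[i] <= key[j]) i else j
    second <- if (first == i) j else i
    merge[step, ] <- c(active[[first]], active[[second]])
    height[step] <- best$d
    # weighted-average update into slot i; retire slot j
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      newd <- (size[i] * dm[i, others] + size[j] * dm[j, others]) /
        (size[i] + size[j])
      dm[i, others] <- newd
      dm[others, i] <- newd
    }
    active[[i]] <- step
    key[i] <- min(key[i], key[j])
    size[i] <- size[i] + size[j]
    idx <- setdiff(idx, j)
  }
  hc <- structure(list(merge = merge, height = height,
                       order = hclust_order(merge), labels = labels,
                       method = "average", call = match.call(),
                       dist.method = "user"),
                  class = "hclust")
  tree <- ape::as.phylo(hc)   # node heights become height/2 branch lengths
  tree
}

# leaf order consistent with the merge matrix (required by the hclust class)
hclust_order <- function(merge) {
  expand <- function(row) {
    unlist(lapply(merge[row, ], function(x)
      if (x < 0) -x else expand(x)))
  }
  expand(nrow(merge))
}

#' Serialize a tree to Newick text
#'
#' Standard parenthesis notation with branch lengths, terminated by `";"`.
#' Child order is whatever the tree encodes; trees built by [upgma()] are
#' deterministic, so the text is byte-stable across runs.
#'
#' @param tree A `phylo` tree.
#' @param digits Significant digits for branch lengths.
#' @return Single Newick string.
#' @export
write_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

#' Parse Newick text to a tree
#'
#' @param text A Newick string.
#' @return A `phylo` tree.
#' @export
read_newick <- function(text) {
  ape::read.tree(text = text)
}

#' Cophenetic distances implied by a tree
#'
#' For an ultrametric UPGMA tree the cophenetic distance between two leaves
#' is twice the height of their most recent common ancestor; on an input
#' matrix that is itself ultrametric, UPGMA reproduces it exactly.
#'
#' @param tree A `phylo` tree.
#' @return Symmetric matrix of leaf-to-leaf path lengths.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  m <- ape::cophenetic.phylo(tree)
  m[tree$tip.label, tree$tip.label]
}
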