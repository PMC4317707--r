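#' Principal component analysis of a population allele-frequency table
#'
#' Column-centers the populations x loci matrix of deletion-allele
#' frequencies (no unit-variance scaling: frequencies already share a
#' common scale) and eigendecomposes its covariance via the singular value
#' decomposition. Per-component explained variance is reported as a
#' percentage of the total; component signs are fixed by making the
#' largest-magnitude loading of each component positive, so results are
#' reproducible across platforms.
#'
#' @param freqs Numeric populations x loci matrix with population rownames.
#' @param n_components Number of components to retain (default: all
#'   `min(n_pops - 1, n_loci)` nonzero-capable components).
#' @return List of class `freq_pca`: `scores` (populations x components,
#'   centered), `loadings` (loci x components), `explained_pct`
#'   (percentages, non-increasing, summing to 100 over all components),
#'   `center` (column means), `n_components`.
#' @export
pca_from_frequencies <- function(freqs, n_components = NULL) {
  freqs <- freq_matrix_check(freqs)
  if (anyNA(freqs)) stop("PCA input must have no missing frequencies")
  centered <- scale(freqs, center = TRUE, scale = FALSE)
  if (sum(centered^2) < 1e-24)
    stop("degenerate input: all populations have identical frequency profiles")
  fit <- stats::prcomp(freqs, center = TRUE, scale. = FALSE)
  total_var <- sum(fit$sdev^2)
  explained <- 100 * fit$sdev^2 / total_var
  k_all <- length(fit$sdev)
  if (is.null(n_components)) n_components <- k_all
  if (n_components < 1L || n_components > k_all)
    stop("n_components must be between 1 and ", k_all)
  scores <- fit$x
  loadings <- fit$rotation
  for (k in seq_len(ncol(loadings))) {
    flip <- sign(loadings[which.max(abs(loadings[, k])), k])
    if (flip < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(
    list(scores = scores[, seq_len(n_components), drop = FALSE],
         loadings = loadings[, seq_len(n_components), drop = FALSE],
         explained_pct = explained,
         center = fit$center,
         n_components = as.integer(n_components)),
    class = "freq_pca")
}

#' @export
print.freq_pca <- function(x, ...) {
  k <- min(x$n_components, length(x$explained_pct))
  cat(sprintf("PCA of %d populations: first %d component(s) explain %s%%\n",
              nrow(x$scores), k,
              paste(sprintf("%.2f", x$explained_pct[seq_len(k)]),
                    collapse = " + ")))
  invisible(x)
}
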