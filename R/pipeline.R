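#' Run the full InDel population study pipeline
#'
#' Chains the four analysis stages on a target population and a set of
#' reference populations: (1) per-locus forensic parameters and combined
#' powers of the target panel; (2) locus-by-locus Weir-Cockerham Fst with
#' permutation significance against every reference; (3) PCA of the
#' population allele-frequency table; (4) Nei distance and UPGMA tree.
#' Writes four artifacts plus a JSON manifest into `out_dir`:
#' `forensic_parameters.csv`, `differentiation.csv`, `pca_scores.csv`,
#' `tree.nwk`, `manifest.json`. Reports are rendered at four decimals;
#' `manifest.json` records the seed and settings, input dimensions, MD5
#' hashes of every written artifact, per-stage timings and the package
#' version. If any stage fails, partial outputs are removed and the error
#' names the stage.
#'
#' @param target A [genotype_matrix] for the study population.
#' @param references Named list of reference populations
#'   ([genotype_matrix] objects, or `list(freq =, n =)` frequency
#'   summaries as in [differentiation_table()]).
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed (mandatory; drives the permutation tests).
#' @param target_name Label of the target population in tree/PCA outputs.
#' @param n_perm Permutations per Fst test.
#' @param alpha Significance level for differentiation flags.
#' @param distance `"da"` (Nei DA, default) or `"ds"` (Nei standard).
#' @param n_components PCA components written to `pca_scores.csv`.
#' @param overwrite Allow overwriting existing artifacts (default `FALSE`).
#' @return Invisibly, a list with the in-memory results of the four stages
#'   and the manifest.
#' @export
run_full_study <- function(target, references, out_dir, seed,
                           target_name = "target", n_perm = 1000L,
                           alpha = 0.05, distance = c("da", "ds"),
                           n_components = 2L, overwrite = FALSE) {
  stopifnot(inherits(target, "genotype_matrix"))
  if (missing(seed)) stop("seed is mandatory")
  distance <- match.arg(distance)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c("forensic_parameters.csv",
                                "differentiation.csv", "pca_scores.csv",
                                "tree.nwk", "manifest.json"))
  names(files) <- c("forensic", "differentiation", "pca", "tree", "manifest")
  if (!overwrite && any(file.exists(files)))
    stop("output files already exist in ", out_dir,
         " (use overwrite = TRUE): ",
         paste(basename(files[file.exists(files)]), collapse = ", "))
  written <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      file.remove(written[file.exists(written)])
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  panel <- stage("forensic", {
    s <- summarize_panel(target)
    utils::write.csv(format_panel_report(s), files[["forensic"]],
                     row.names = FALSE)
    written <- c(written, files[["forensic"]])
    s
  })

  diff_tab <- stage("differentiation", {
    d <- differentiation_table(target, references, n_perm = n_perm,
                               seed = seed, alpha = alpha)
    out <- d
    out$fst <- round_half_up(out$fst, 4L)
    out$p_value <- round_half_up(out$p_value, 4L)
    utils::write.csv(out, files[["differentiation"]], row.names = FALSE)
    written <- c(written, files[["differentiation"]])
    d
  })

  freq_tab <- stage("frequencies", {
    pops <- list()
    pops[[target_name]] <- population_frequency_table(
      stats::setNames(list(target), target_name))[1L, , drop = TRUE]
    for (nm in names(references)) {
      ref <- references[[nm]]
      pops[[nm]] <- if (inherits(ref, "genotype_matrix"))
        population_frequency_table(stats::setNames(list(ref), nm))[1L, , drop = TRUE]
      else {
        v <- rep(NA_real_, ncol(target$calls))
        names(v) <- colnames(target$calls)
        shared <- intersect(names(v), names(ref$freq))
        v[shared] <- ref$freq[shared]
        v
      }
    }
    loci <- colnames(target$calls)
    do.call(rbind, lapply(pops, function(v) v[loci]))
  })

  pca_res <- stage("pca", {
    complete <- colSums(is.na(freq_tab)) == 0L
    res <- pca_from_frequencies(freq_tab[, complete, drop = FALSE],
                                n_components = min(n_components,
                                                   nrow(freq_tab) - 1L))
    out <- data.frame(population = rownames(res$scores),
                      round(res$scores, 6), check.names = FALSE)
    utils::write.csv(out, files[["pca"]], row.names = FALSE)
    written <- c(written, files[["pca"]])
    res
  })

  tree <- stage("tree", {
    dmat <- if (distance == "da") nei_da(freq_tab) else nei_ds(freq_tab)
    tr <- upgma(dmat)
    writeLines(write_newick(tr), files[["tree"]])
    written <- c(written, files[["tree"]])
    tr
  })

  manifest <- stage("manifest", {
    m <- list(
      package = "indelpop",
      version = as.character(utils::packageVersion("indelpop")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = as.integer(seed), n_perm = as.integer(n_perm), alpha = alpha,
      distance = distance,
      target = list(name = target_name, n_samples = nrow(target$calls),
                    n_loci = ncol(target$calls)),
      references = names(references),
      outputs = stats::setNames(
        as.list(unname(tools::md5sum(written))), basename(written)),
      timings_sec = timings)
    jsonlite::write_json(m, files[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <- c(written, files[["manifest"]])
    m
  })

  invisible(list(panel = panel, differentiation = diff_tab,
                 frequencies = freq_tab, pca = pca_res, tree = tree,
                 manifest = manifest, files = files))
}
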