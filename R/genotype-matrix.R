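#' Sample-by-locus diploid genotype matrix
#'
#' Calls are stored as a character matrix with values `"DD"`, `"DI"`, `"II"`
#' or `NA` (missing), sample ids as row names and locus ids as column names.
#' Missing genotypes are excluded per locus (pairwise deletion), never
#' imputed.
#'
#' @param calls Character matrix of calls, values in `c("DD","DI","II", NA)`.
#' @param loci Optional data frame with columns `locus_id` and `rs_id`
#'   describing the columns; defaults to the column names with unknown rs ids.
#' @return Object of class `genotype_matrix`: list with elements `calls`
#'   (the matrix) and `loci` (the locus data frame).
#' @export
genotype_matrix <- function(calls, loci = NULL) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("calls must be a character matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls must have sample ids as rownames and locus ids as colnames")
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(calls))) stop("duplicate locus ids")
  bad <- !(calls %in% c("DD", "DI", "II") | is.na(calls))
  if (any(bad)) {
    i <- which(bad)[1L]
    rc <- arrayInd(i, dim(calls))
    stop(sprintf("invalid genotype call '%s' at sample %s, locus %s",
                 calls[i], rownames(calls)[rc[1L]], colnames(calls)[rc[2L]]))
  }
  non_missing <- colSums(!is.na(calls))
  if (any(non_missing == 0L))
    stop("no data at locus ", colnames(calls)[which(non_missing == 0L)[1L]])
  if (is.null(loci))
    loci <- data.frame(locus_id = colnames(calls), rs_id = NA_character_,
                       stringsAsFactors = FALSE)
  stopifnot(identical(loci$locus_id, colnames(calls)))
  structure(list(calls = calls, loci = loci), class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d missing calls)\n",
              nrow(x$calls), ncol(x$calls), sum(is.na(x$calls))))
  invisible(x)
}

.default_tokens <- c("D/D" = "DD", "D/I" = "DI", "I/D" = "DI", "I/I" = "II")

#' Read a delimited genotype table
#'
#' First column holds sample ids, remaining columns one locus each (named in
#' the header). Genotype tokens default to the `"D/D"`, `"D/I"`, `"I/I"`
#' dialect; empty cells and `"NA"` are missing. The delimiter is
#' auto-detected (comma vs tab) unless forced.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) auto-detects `","` vs `"\t"`
#'   from the header line.
#' @param tokens Named character vector mapping file tokens to canonical
#'   calls `"DD"`, `"DI"`, `"II"`.
#' @param missing_tokens Tokens treated as missing genotypes.
#' @return A [genotype_matrix].
#' @export
read_genotype_table <- function(path, sep = NULL,
                                tokens = .default_tokens,
                                missing_tokens = c("", "NA")) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("genotype table needs a header and at least one sample row")
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  loci_ids <- trimws(header[-1L])
  if (anyDuplicated(loci_ids))
    stop("duplicate locus name in header: ",
         loci_ids[duplicated(loci_ids)][1L])
  ncol_expected <- length(header)
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    f <- strsplit(lines[i], sep, fixed = TRUE)[[1L]]
    # strsplit drops a trailing empty field; restore it
    if (endsWith(lines[i], sep)) f <- c(f, "")
    if (length(f) != ncol_expected)
      stop(sprintf("malformed row at line %d: %d fields, expected %d",
                   i, length(f), ncol_expected))
    trimws(f)
  })
  sample_ids <- vapply(rows, `[`, character(1L), 1L)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  calls <- matrix(NA_character_, length(rows), length(loci_ids),
                  dimnames = list(sample_ids, loci_ids))
  for (r in seq_along(rows)) {
    tok <- rows[[r]][-1L]
    is_missing <- tok %in% missing_tokens
    known <- tok %in% names(tokens)
    bad <- !is_missing & !known
    if (any(bad)) {
      j <- which(bad)[1L]
      stop(sprintf("unknown genotype token '%s' at row %d, %s",
                   tok[j], r, loci_ids[j]))
    }
    calls[r, !is_missing] <- unname(tokens[tok[!is_missing]])
  }
  genotype_matrix(calls)
}

#' Write a genotype table in the same dialect the reader accepts
#'
#' @param gm A [genotype_matrix].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @param tokens Named map from canonical calls to file tokens (inverse of
#'   the reader's default dialect).
#' @param missing_token Token written for missing calls.
#' @export
write_genotype_table <- function(gm, path, sep = ",",
                                 tokens = c(DD = "D/D", DI = "D/I", II = "I/I"),
                                 missing_token = "") {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- gm$calls
  out[] <- ifelse(is.na(gm$calls), missing_token, unname(tokens[gm$calls]))
  header <- paste(c("sample_id", colnames(out)), collapse = sep)
  body <- vapply(seq_len(nrow(out)), function(r)
    paste(c(rownames(out)[r], out[r, ]), collapse = sep), character(1L))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Tally genotype counts at one locus of a genotype matrix
#'
#' Missing calls are dropped, so `n` is the per-locus effective sample size.
#'
#' @param gm A [genotype_matrix].
#' @param locus Locus id (must be a column of `gm`).
#' @return A [locus_counts] object.
#' @export
counts_from_matrix <- function(gm, locus) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!locus %in% colnames(gm$calls))
    stop("locus not present in genotype matrix: ", locus)
  v <- gm$calls[, locus]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no data at locus ", locus)
  rs <- gm$loci$rs_id[match(locus, gm$loci$locus_id)]
  locus_counts(sum(v == "DD"), sum(v == "DI"), sum(v == "II"),
               locus_id = locus, rs_id = rs)
}

#' Tally genotype counts at every locus
#'
#' @param gm A [genotype_matrix].
#' @return Named list of [locus_counts], one per locus.
#' @export
panel_counts <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  stats::setNames(lapply(colnames(gm$calls), counts_from_matrix, gm = gm),
                  colnames(gm$calls))
}
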