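#' TPM from a counts table
#'
#' Per sample: `rate_i = count_i / length_i`, `TPM_i = 1e6 * rate_i / sum(rates)`.
#' Every column of the result sums to one million whenever the sample has any
#' reads.
#'
#' @param counts Non-negative matrix, features x samples.
#' @param lengths Effective feature lengths in bp (positive; recycled by
#'   name when named).
#' @param assay Optional character vector tagging each sample with its assay
#'   (`total_rna`, `polya_rna`, `pro_seq`).
#' @return Object of class `ExpressionMatrix`: list with `tpm` (matrix) and
#'   `assay` (named by sample).
#' @export
tpm_from_counts <- function(counts, lengths, assay = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  stopifnot(length(lengths) == nrow(counts))
  if (any(lengths <= 0)) stop("effective lengths must be positive", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  rate <- counts / lengths
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  if (!is.null(assay)) {
    stopifnot(length(assay) == ncol(counts))
    assay <- setNames(assay, colnames(counts))
  }
  structure(list(tpm = tpm, assay = assay), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$tpm), "features x", ncol(x$tpm),
      "samples\n")
  invisible(x)
}

#' Count reads per window with multi-overlap semantics
#'
#' A read increments *every* window it overlaps by at least 1 bp, so reads
#' spanning two overlapping windows are counted in both; window widths serve
#' as effective lengths for TPM.
#'
#' @param reads Named list of GRanges, one per sample (read/fragment
#'   intervals).
#' @param windows Promoter windows ([extract_promoters()]).
#' @return List with `counts` (windows x samples integer matrix, rownames =
#'   gene ids) and `lengths` (window widths).
#' @export
quantify_window <- function(reads, windows) {
  ids <- mcols(windows)$gene_id
  counts <- vapply(reads, function(gr)
    countOverlaps(windows, gr, minoverlap = 1L, ignore.strand = TRUE),
    integer(length(windows)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(windows))
  dimnames(counts) <- list(ids, names(reads))
  list(counts = counts, lengths = setNames(width(windows), ids))
}

#' Classify a TPM value into expression bins
#'
#' Quartile-motivated bins on the TPM scale: off `< 0.001`, low
#' `(0.001, 0.137]` read together with the off rule so that exactly 0.001
#' falls in low, medium `(0.137, 3]`, high `> 3`. The bins partition
#' `[0, Inf)`.
#'
#' @param tpm Non-negative numeric vector.
#' @param edges Bin edges (off/low, low/medium, medium/high), strictly
#'   increasing.
#' @return Ordered factor with levels `off < low < medium < high`.
#' @export
classify_expression_bin <- function(tpm, edges = c(0.001, 0.137, 3)) {
  if (any(tpm < 0, na.rm = TRUE)) stop("negative TPM", call. = FALSE)
  stopifnot(length(edges) == 3, all(diff(edges) > 0))
  lev <- c("off", "low", "medium", "high")
  out <- ifelse(tpm < edges[1], "off",
                ifelse(tpm <= edges[2], "low",
                       ifelse(tpm <= edges[3], "medium", "high")))
  factor(out, levels = lev, ordered = TRUE)
}

#' Correlation between promoter binding events and expression
#'
#' Pearson correlation of `log10(tpm + pseudocount)` against the number of
#' DBPs bound, plus the Spearman rank correlation (which needs no
#' transform), with two-sided p-values.
#'
#' @param n_dbps Binding events per promoter.
#' @param tpm Expression per promoter (same order).
#' @param pseudocount Added before the log; defaults to the off threshold
#'   0.001.
#' @return List with `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `n`.
#' @export
binding_expression_correlation <- function(n_dbps, tpm, pseudocount = 0.001) {
  stopifnot(length(n_dbps) == length(tpm))
  if (length(n_dbps) < 3L) stop("need at least 3 promoters", call. = FALSE)
  y <- log10(tpm + pseudocount)
  if (var(n_dbps) == 0 || var(y) == 0)
    stop("zero variance in binding or expression", call. = FALSE)
  pe <- cor.test(n_dbps, y, method = "pearson")
  sp <- suppressWarnings(cor.test(n_dbps, tpm, method = "spearman",
                                  exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(n_dbps))
}

#' Average TPM across the replicates of one assay
#' @param expr An `ExpressionMatrix`.
#' @param assay Assay tag to average over.
#' @return Named numeric vector (one value per feature).
#' @export
average_assay_tpm <- function(expr, assay) {
  if (is.null(expr$assay)) stop("expression matrix has no assay tags",
                                call. = FALSE)
  cols <- names(expr$assay)[expr$assay == assay]
  if (!length(cols)) stop("no samples tagged ", assay, call. = FALSE)
  rowMeans(expr$tpm[, cols, drop = FALSE])
}
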