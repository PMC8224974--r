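#' Count features overlapped by a consensus peak set
#'
#' Returns the number of *features* touched by at least one consensus peak
#' (>= 1 bp). This is the feature-unit overlap statistic used for the
#' peak-count versus promoter-overlap trend; the peak-unit statistic lives in
#' the permutation test.
#'
#' @param set A `ConsensusPeakSet` (or a plain GRanges of peaks).
#' @param features GRanges of features (may overlap each other).
#' @return Integer count of overlapped features.
#' @export
count_feature_overlaps <- function(set, features) {
  peaks <- if (inherits(set, "ConsensusPeakSet")) set$peaks else set
  sum(overlapsAny(features, peaks, minoverlap = 1L, ignore.strand = TRUE))
}

#' Build the binary promoter-by-DBP occupancy matrix
#'
#' Entry (g, d) is 1 when DBP d has at least 1 bp of consensus peak anywhere
#' in promoter g's window, else 0; multiple peaks in one window still count
#' once. A promoter's number of "binding events" is its row sum.
#'
#' @param sets List of `ConsensusPeakSet` objects (one per DBP).
#' @param promoters Promoter windows from [extract_promoters()].
#' @return An object of class `OccupancyMatrix`: list with `m` (binary
#'   integer matrix, promoters x DBPs, dimnames set), `n_dbps` (named row
#'   sums) and `biotype` (named per-promoter biotype when available).
#' @export
build_occupancy_matrix <- function(sets, promoters) {
  ids <- mcols(promoters)$gene_id
  if (is.null(ids)) stop("promoters must carry gene_id metadata", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  dbps <- vapply(sets, function(s) as.character(s$dbp), "")
  if (anyDuplicated(dbps)) stop("duplicate DBP name(s)", call. = FALSE)
  m <- vapply(sets, function(s)
    as.integer(overlapsAny(promoters, s$peaks, minoverlap = 1L,
                           ignore.strand = TRUE)),
    integer(length(promoters)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(promoters))
  dimnames(m) <- list(ids, dbps)
  bt <- mcols(promoters)$biotype
  structure(list(m = m, n_dbps = setNames(rowSums(m), ids),
                 biotype = if (!is.null(bt)) setNames(bt, ids) else NULL),
            class = "OccupancyMatrix")
}

#' @export
print.OccupancyMatrix <- function(x, ...) {
  cat("OccupancyMatrix:", nrow(x$m), "promoters x", ncol(x$m), "DBPs;",
      "median binding events per promoter:", stats::median(x$n_dbps), "\n")
  invisible(x)
}

#' Ordinary least-squares fit of feature overlaps on peak counts
#'
#' Fits `n_overlapping_features ~ n_peaks` across DBPs with an intercept and
#' reports the slope, Pearson correlation and the two-sided p-value for a
#' non-zero slope.
#'
#' @param n_peaks Per-DBP consensus peak counts (x).
#' @param n_features Per-DBP overlapped-feature counts (y).
#' @return Object of class `RegressionFit`: list with `slope`, `intercept`,
#'   `r`, `p`, `n`.
#' @export
fit_peaknum_regression <- function(n_peaks, n_features) {
  stopifnot(length(n_peaks) == length(n_features))
  n <- length(n_peaks)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (var(n_peaks) == 0) stop("zero variance in peak counts", call. = FALSE)
  fit <- lm(n_features ~ n_peaks)
  co <- summary(fit)$coefficients
  structure(list(slope = unname(co["n_peaks", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 r = unname(cor(n_peaks, n_features)),
                 p = unname(co["n_peaks", "Pr(>|t|)"]),
                 n = n),
            class = "RegressionFit")
}

#' @export
print.RegressionFit <- function(x, ...) {
  cat(sprintf("RegressionFit: slope = %.4g, intercept = %.4g, r = %.3f, p = %.3g (n = %d)\n",
              x$slope, x$intercept, x$r, x$p, x$n))
  invisible(x)
}

#' Assign each peak to one genomic feature class
#'
#' Each peak is classified by the position of its midpoint with a fixed
#' precedence: promoter/TSS window > TTS window > exon > intron > intergenic.
#' The TTS is the strand-aware 3' end of the gene span. When no exon models
#' are supplied the whole gene body counts as intron.
#'
#' @param peaks GRanges of peaks with a `dbp` metadata column (or a list of
#'   `ConsensusPeakSet`).
#' @param genes Gene models ([read_gtf_genes()]).
#' @param promoter_flank Promoter window half-width (default 3000).
#' @param tts_flank TTS window half-width (default 1000).
#' @param exons Optional GRanges of exon intervals.
#' @return Object of class `FeatureAnnotationSummary`: list with `fractions`
#'   (DBP x class matrix of per-DBP fractions summing to 1) and `counts`.
#' @export
annotate_peak_features <- function(peaks, genes, promoter_flank = 3000,
                                   tts_flank = 1000, exons = NULL) {
  if (is.list(peaks) && all(vapply(peaks, inherits, TRUE, "ConsensusPeakSet"))) {
    peaks <- do.call(c, lapply(unname(peaks), function(s) {
      gr <- s$peaks
      mcols(gr)$dbp <- s$dbp
      gr
    }))
  }
  dbp <- mcols(peaks)$dbp
  if (is.null(dbp)) stop("peaks must carry a dbp metadata column", call. = FALSE)
  mid <- floor((start(peaks) + end(peaks)) / 2)
  midgr <- GRanges(seqnames(peaks), IRanges(mid, mid))
  minus <- as.character(strand(genes)) == "-"
  tss <- ifelse(minus, end(genes), start(genes))
  tts <- ifelse(minus, start(genes), end(genes))
  prom <- GRanges(seqnames(genes),
                  IRanges(pmax(1, tss - promoter_flank), tss + promoter_flank - 1))
  ttsw <- GRanges(seqnames(genes),
                  IRanges(pmax(1, tts - tts_flank), tts + tts_flank - 1))
  body <- GRanges(seqnames(genes), ranges(genes))
  classes <- c("promoter_tss", "tts", "exon", "intron", "intergenic")
  cls <- rep("intergenic", length(midgr))
  in_body <- overlapsAny(midgr, body, ignore.strand = TRUE)
  cls[in_body] <- "intron"
  if (!is.null(exons)) {
    cls[in_body & overlapsAny(midgr, exons, ignore.strand = TRUE)] <- "exon"
  } else {
    cls[in_body] <- "intron"
  }
  cls[overlapsAny(midgr, ttsw, ignore.strand = TRUE)] <- "tts"
  cls[overlapsAny(midgr, prom, ignore.strand = TRUE)] <- "promoter_tss"
  tab <- table(factor(dbp), factor(cls, levels = classes))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  fractions <- counts / pmax(1L, rowSums(counts))
  structure(list(fractions = fractions, counts = counts),
            class = "FeatureAnnotationSummary")
}

#' Hierarchically cluster binary binding profiles
#'
#' Euclidean distance on the binary vectors with complete linkage (both
#' configurable); deterministic given the input.
#'
#' @param occ An `OccupancyMatrix`.
#' @param over Cluster `"dbps"` (columns) or `"promoters"` (rows).
#' @param h Optional cut height for flat cluster labels.
#' @param dist_method,linkage Distance and linkage passed to [stats::dist()]
#'   and [stats::hclust()].
#' @return List with `tree` (hclust), `labels` (flat clusters at `h`, or
#'   `NULL`), and `metadata` recording distance and linkage.
#' @export
cluster_binary_profiles <- function(occ, over = c("dbps", "promoters"),
                                    h = NULL, dist_method = "euclidean",
                                    linkage = "complete") {
  over <- match.arg(over)
  m <- if (over == "dbps") t(occ$m) else occ$m
  if (nrow(m) < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  tree <- hclust(dist(m, method = dist_method), method = linkage)
  labels <- if (!is.null(h)) cutree(tree, h = h) else NULL
  list(tree = tree, labels = labels,
       metadata = list(distance = dist_method, linkage = linkage, over = over))
}

#' Write an occupancy matrix as TSV (promoters as rows)
#' @param occ An `OccupancyMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(occ, path) {
  df <- data.frame(gene_id = rownames(occ$m), occ$m, n_dbps = occ$n_dbps,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
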