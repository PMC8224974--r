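#' Binding-event count threshold for reservoir calling
#'
#' The per-promoter binding-event distribution is bimodal; the default is
#' the fixed threshold 7 (promoters with *more than* 7 events fall in the
#' high mode). The `"valley"` mode instead scans a kernel-smoothed density
#' for the deepest minimum between its two largest modes; when the
#' distribution is not bimodal it warns and falls back to the fixed value.
#'
#' @param n_dbps Per-promoter binding-event counts.
#' @param mode `"fixed"` (default) or `"valley"`.
#' @param fixed The fixed threshold (default 7).
#' @param bw Bandwidth for the density in valley mode.
#' @return The threshold (numeric).
#' @export
find_count_threshold <- function(n_dbps, mode = c("fixed", "valley"),
                                 fixed = 7, bw = "nrd0") {
  mode <- match.arg(mode)
  if (!length(n_dbps)) stop("empty distribution", call. = FALSE)
  if (mode == "fixed") return(fixed)
  d <- density(n_dbps, bw = bw)
  y <- d$y
  ## interior local maxima of the smoothed density
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(pk) < 2L) {
    warning("density is not bimodal; falling back to fixed threshold ", fixed)
    return(fixed)
  }
  top2 <- sort(pk[order(y[pk], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  d$x[valley]
}

#' Call reservoir promoters
#'
#' A reservoir is a promoter with *more than* `min_dbps` binding events
#' (strict inequality) whose total RNA-seq output is *below* `tpm_off`
#' (strict inequality) - heavily bound yet producing no steady-state RNA.
#'
#' @param occ An `OccupancyMatrix`.
#' @param tpm_total Named numeric vector of total RNA-seq TPM (replicate
#'   average) per gene; every promoter in `occ` must be present.
#' @param min_dbps Binding-event threshold (default 7).
#' @param tpm_off Expression-off threshold in TPM (default 0.001).
#' @return A data.frame of class `ReservoirCalls`: one row per promoter
#'   with `gene_id`, `biotype` (when available), `n_dbps`, `tpm_total`,
#'   `is_reservoir`, and `subclass`/`neighbor_class`/`se_overlap`/
#'   `conservative`/`polII_bound` columns initialised for the downstream
#'   steps.
#' @export
call_reservoirs <- function(occ, tpm_total, min_dbps = 7, tpm_off = 0.001) {
  ids <- rownames(occ$m)
  miss <- setdiff(ids, names(tpm_total))
  if (length(miss))
    stop(length(miss), " promoter(s) missing from expression input (e.g. ",
         miss[1], ")", call. = FALSE)
  tpm <- unname(tpm_total[ids])
  n <- unname(occ$n_dbps[ids])
  res <- n > min_dbps & tpm < tpm_off
  out <- data.frame(gene_id = ids,
                    biotype = if (!is.null(occ$biotype))
                      unname(occ$biotype[ids]) else NA_character_,
                    n_dbps = n, tpm_total = tpm, is_reservoir = res,
                    subclass = "none", neighbor_class = NA_character_,
                    se_overlap = NA, conservative = NA, polII_bound = NA,
                    stringsAsFactors = FALSE)
  class(out) <- c("ReservoirCalls", "data.frame")
  out
}

#' @export
print.ReservoirCalls <- function(x, ...) {
  cat("ReservoirCalls:", nrow(x), "promoters;", sum(x$is_reservoir),
      "reservoirs")
  if (any(x$subclass != "none"))
    cat(" (", sum(x$subclass == "ghost"), "ghost /",
        sum(x$subclass == "zombie"), "zombie )")
  cat("\n")
  invisible(x)
}

#' Flag reservoir promoters overlapping super-enhancers
#'
#' Overlap is >= 1 bp between the promoter window and any super-enhancer
#' interval. Overlapping reservoirs are flagged, not removed; the
#' neighborhood window analysis excludes them.
#'
#' @param calls `ReservoirCalls`.
#' @param promoters Promoter windows matching `calls$gene_id`.
#' @param se GRanges of super-enhancer intervals (already in the working
#'   assembly).
#' @return `calls` with `se_overlap` filled; the number of SE-overlapping
#'   reservoirs is stored in `attr(, "n_se_reservoirs")`.
#' @export
flag_superenhancer_overlap <- function(calls, promoters, se) {
  idx <- match(calls$gene_id, mcols(promoters)$gene_id)
  if (anyNA(idx)) stop("promoter window(s) missing for some calls",
                       call. = FALSE)
  ov <- overlapsAny(promoters[idx], se, minoverlap = 1L, ignore.strand = TRUE)
  calls$se_overlap <- ov
  attr(calls, "n_se_reservoirs") <- sum(ov & calls$is_reservoir)
  calls
}

#' Classify a promoter's neighborhood
#'
#' TSS-to-TSS distances with strict `<= distance`. Categories are evaluated
#' with a fixed precedence so every promoter gets exactly one label:
#' `multiple_nearby` (two or more other TSSs within `distance`, any strand)
#' beats `bidirectional` (an opposite-strand TSS within `distance` upstream
#' of the query TSS, upstream taken against the query's orientation), which
#' beats `same_strand_nearby` (a same-strand TSS upstream within
#' `distance`), else `none`.
#'
#' @param promoters Promoter windows (or any GRanges with `gene_id`, `tss`
#'   and strand) for the full annotation.
#' @param query Gene id(s) to classify; default all.
#' @param distance Distance cutoff in bp (default 1000).
#' @return Named character vector of classes for the queried genes.
#' @export
classify_neighbor <- function(promoters, query = NULL, distance = 1000) {
  ids <- mcols(promoters)$gene_id
  tss <- mcols(promoters)$tss
  if (is.null(ids) || is.null(tss))
    stop("promoters must carry gene_id and tss metadata", call. = FALSE)
  if (is.null(query)) query <- ids
  if (!all(query %in% ids))
    stop("query gene(s) absent from annotation: ",
         paste(setdiff(query, ids), collapse = ", "), call. = FALSE)
  chrom <- as.character(seqnames(promoters))
  str <- as.character(strand(promoters))
  out <- setNames(rep("none", length(query)), query)
  for (k in seq_along(query)) {
    q <- match(query[k], ids)
    same_chr <- which(chrom == chrom[q])
    same_chr <- same_chr[same_chr != q]
    d <- abs(tss[same_chr] - tss[q])
    near <- same_chr[d <= distance]
    if (length(near) >= 2L) { out[k] <- "multiple_nearby"; next }
    if (!length(near)) next
    delta <- tss[near] - tss[q]
    upstream <- if (str[q] == "-") delta > 0 else delta < 0
    if (upstream && str[near] != str[q]) out[k] <- "bidirectional"
    else if (upstream && str[near] == str[q]) out[k] <- "same_strand_nearby"
  }
  out
}

#' Expressed-neighbor status of reservoirs versus other promoters
#'
#' A promoter has an expressed neighbor when any other TSS within `distance`
#' belongs to a gene with TPM at or above `tpm_off`. Reports the fraction of
#' reservoirs (among those with any neighbor) whose neighbor is expressed,
#' and a chi-squared test of the 2x2 reservoir-status by
#' expressed-neighbor-status table over all promoters with neighbors.
#'
#' @param calls `ReservoirCalls`.
#' @param promoters Promoter annotation GRanges.
#' @param tpm Named TPM vector per gene.
#' @param distance Neighbor distance in bp (default 1000).
#' @param tpm_off Expression threshold (default 0.001).
#' @return List with `fraction_reservoir`, `fraction_nonreservoir`,
#'   `statistic`, `p`, `table`.
#' @export
neighbor_expression_status <- function(calls, promoters, tpm,
                                       distance = 1000, tpm_off = 0.001) {
  ids <- mcols(promoters)$gene_id
  tss <- mcols(promoters)$tss
  chrom <- as.character(seqnames(promoters))
  expressed <- tpm[ids] >= tpm_off
  has_nb <- expr_nb <- logical(length(ids))
  for (i in seq_along(ids)) {
    j <- which(chrom == chrom[i] & abs(tss - tss[i]) <= distance)
    j <- j[j != i]
    has_nb[i] <- length(j) > 0
    expr_nb[i] <- any(expressed[j])
  }
  names(has_nb) <- names(expr_nb) <- ids
  idx <- match(calls$gene_id, ids)
  res <- calls$is_reservoir
  keep <- has_nb[idx]
  tab <- table(reservoir = res[keep], expressed_neighbor = expr_nb[idx][keep])
  fr <- function(r) {
    sel <- keep & res == r
    if (!any(sel)) return(NA_real_)
    mean(expr_nb[idx][sel])
  }
  ct <- if (all(dim(tab) == c(2, 2)))
    suppressWarnings(chisq.test(tab, correct = FALSE)) else NULL
  list(fraction_reservoir = fr(TRUE), fraction_nonreservoir = fr(FALSE),
       statistic = if (!is.null(ct)) unname(ct$statistic) else NA_real_,
       p = if (!is.null(ct)) ct$p.value else NA_real_, table = tab)
}

#' Mean expression of the 4 genes flanking each gene (5-gene windows)
#'
#' Genes are ordered by TSS within each chromosome; for every full window of
#' `k` genes (2 on each side at the default `k = 5`) the mean TPM of the
#' flanking genes is computed, excluding the center gene. Two-sided Wilcoxon
#' rank-sum tests compare windows centered on reservoirs (SE-overlapping
#' reservoirs removed) against non-reservoir centers, and SE-overlapping
#' centers against the rest.
#'
#' @param promoters Promoter annotation (gene order comes from `tss`).
#' @param tpm Named TPM per gene.
#' @param calls `ReservoirCalls` (with `se_overlap` filled for the SE
#'   comparison; NA treated as no overlap).
#' @param k Window size in genes (odd, default 5).
#' @return List with `records` (data.frame: `gene_id`, `window_mean`,
#'   `group` flags), `reservoir_test` and `se_test` (each: group means and
#'   Wilcoxon p).
#' @export
window_neighborhood_expression <- function(promoters, tpm, calls, k = 5) {
  stopifnot(k >= 3, k %% 2 == 1)
  half <- (k - 1L) %/% 2L
  ids <- mcols(promoters)$gene_id
  tss <- mcols(promoters)$tss
  chrom <- as.character(seqnames(promoters))
  recs <- list()
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (length(i) < k) next
    i <- i[order(tss[i])]
    v <- unname(tpm[ids[i]])
    for (c0 in (half + 1L):(length(i) - half)) {
      nb <- c((c0 - half):(c0 - 1L), (c0 + 1L):(c0 + half))
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = ids[i][c0], window_mean = mean(v[nb]))
    }
  }
  if (!length(recs)) stop("no chromosome has at least ", k, " genes",
                          call. = FALSE)
  records <- do.call(rbind, recs)
  m <- match(records$gene_id, calls$gene_id)
  se <- calls$se_overlap[m]
  se[is.na(se)] <- FALSE
  res <- calls$is_reservoir[m]
  records$center_reservoir <- res & !se
  records$center_se <- se
  wtest <- function(a, b) {
    if (!length(a) || !length(b))
      return(list(mean_in = NA_real_, mean_out = NA_real_, p = NA_real_))
    p <- if (length(unique(c(a, b))) == 1L) 1 else
      suppressWarnings(wilcox.test(a, b)$p.value)
    list(mean_in = mean(a), mean_out = mean(b), p = p)
  }
  list(records = records,
       reservoir_test = wtest(records$window_mean[records$center_reservoir],
                              records$window_mean[!records$center_reservoir & !se]),
       se_test = wtest(records$window_mean[records$center_se],
                       records$window_mean[!records$center_se]))
}

#' Split reservoirs into ghosts and zombies by nascent transcription
#'
#' Ghosts are reservoirs whose PRO-seq TPM over the promoter window is below
#' `ghost_tpm` (no nascent transcription at all); zombies have detectable
#' nascent transcription but still no mature RNA. Non-reservoirs keep
#' subclass `none`.
#'
#' @param calls `ReservoirCalls`.
#' @param proseq_tpm Named PRO-seq window TPM per gene (replicate average).
#' @param ghost_tpm Threshold (default 0.001).
#' @return `calls` with `subclass` filled.
#' @export
classify_ghost_zombie <- function(calls, proseq_tpm, ghost_tpm = 0.001) {
  miss <- setdiff(calls$gene_id[calls$is_reservoir], names(proseq_tpm))
  if (length(miss))
    stop("missing PRO-seq value for ", length(miss), " reservoir(s)",
         call. = FALSE)
  v <- proseq_tpm[calls$gene_id]
  calls$subclass <- ifelse(!calls$is_reservoir, "none",
                           ifelse(v < ghost_tpm, "ghost", "zombie"))
  calls$tpm_proseq_window <- unname(v)
  calls
}

#' Conservative reservoir set
#'
#' A reservoir is conservative when its promoter window shows TPM below
#' `tpm_off` in *every* steady-state RNA sample (total and polyA), i.e. no
#' expression anywhere within the window, not merely none attributed to its
#' own gene model.
#'
#' @param calls `ReservoirCalls`.
#' @param window_tpm Matrix of window TPM, genes x RNA samples (total +
#'   polyA).
#' @param tpm_off Threshold (default 0.001).
#' @return `calls` with `conservative` filled (FALSE for non-reservoirs).
#' @export
conservative_set <- function(calls, window_tpm, tpm_off = 0.001) {
  idx <- match(calls$gene_id, rownames(window_tpm))
  if (anyNA(idx[calls$is_reservoir]))
    stop("window TPM missing for some reservoirs", call. = FALSE)
  allow <- rowSums(window_tpm >= tpm_off) == 0
  calls$conservative <- calls$is_reservoir & allow[idx]
  calls$conservative[is.na(calls$conservative)] <- FALSE
  calls
}

#' Flag promoters bound by Pol II machinery
#' @param calls `ReservoirCalls`.
#' @param occ An `OccupancyMatrix`.
#' @param polII_dbps Character vector of DBP names counted as Pol II
#'   machinery.
#' @return `calls` with `polII_bound` filled.
#' @export
flag_polII <- function(calls, occ, polII_dbps) {
  cols <- intersect(polII_dbps, colnames(occ$m))
  bound <- if (length(cols))
    rowSums(occ$m[, cols, drop = FALSE]) > 0 else
      rep(FALSE, nrow(occ$m))
  calls$polII_bound <- unname(bound[match(calls$gene_id, rownames(occ$m))])
  calls
}

#' Association of a chromatin mark with nascent transcription
#'
#' Splits promoters by >= 1 bp overlap of the mark's peaks with the promoter
#' window and compares PRO-seq TPM between the two groups: group means,
#' their ratio (with/without), and a two-sided Wilcoxon rank-sum p-value.
#'
#' @param promoters Promoter windows.
#' @param mark_peaks GRanges of the mark's peaks.
#' @param proseq_tpm Named PRO-seq window TPM per gene.
#' @param subset Optional logical vector or gene ids restricting the
#'   comparison (e.g. reservoirs only).
#' @return List with `mean_with`, `mean_without`, `ratio`, `p`, `n_with`,
#'   `n_without`; all NA (with a warning) when either group is empty.
#' @export
chromatin_association <- function(promoters, mark_peaks, proseq_tpm,
                                  subset = NULL) {
  ids <- mcols(promoters)$gene_id
  marked <- overlapsAny(promoters, mark_peaks, minoverlap = 1L,
                        ignore.strand = TRUE)
  keep <- rep(TRUE, length(ids))
  if (!is.null(subset)) {
    keep <- if (is.logical(subset)) subset else ids %in% subset
  }
  v <- proseq_tpm[ids]
  a <- v[keep & marked]; b <- v[keep & !marked]
  if (!length(a) || !length(b)) {
    warning("one group is empty; comparison undefined")
    return(list(mean_with = NA_real_, mean_without = NA_real_,
                ratio = NA_real_, p = NA_real_,
                n_with = length(a), n_without = length(b)))
  }
  p <- if (length(unique(c(a, b))) == 1L) 1 else
    suppressWarnings(wilcox.test(a, b)$p.value)
  list(mean_with = mean(a), mean_without = mean(b),
       ratio = mean(a) / mean(b), p = p,
       n_with = length(a), n_without = length(b))
}
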