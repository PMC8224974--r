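#' Read a bedGraph file into a coverage track
#'
#' A coverage track is a per-chromosome run-length encoded vector of
#' non-negative values over every base (absent intervals are 0) - any
#' coverage works (read pileup, peak indicator): the metaprofile arithmetic
#' is agnostic to what the values mean.
#'
#' @param path bedGraph file.
#' @param genome A `GenomeAssembly` (fixes chromosome universe and lengths).
#' @return An [IRanges::RleList], one numeric Rle per chromosome.
#' @export
read_bedgraph <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track_from_intervals(gr, genome, score = mcols(gr)$score)
}

#' Build a coverage track from scored intervals
#' @param gr GRanges (overlaps add up).
#' @param genome A `GenomeAssembly`.
#' @param score Numeric weights (default 1 per interval).
#' @return An [IRanges::RleList].
#' @export
track_from_intervals <- function(gr, genome, score = NULL) {
  if (is.null(score)) score <- rep(1, length(gr))
  if (any(score < 0)) stop("coverage values must be non-negative", call. = FALSE)
  seqlevels(gr) <- names(genome$sizes)
  GenomeInfoDb::seqinfo(gr) <- assembly_seqinfo(genome)
  cov <- GenomicRanges::coverage(gr, weight = score)
  methods::as(cov, "RleList")
}

## Extract oriented per-bp window slices as a matrix (rows = anchors).
## Windows must be fully inside the chromosome (caller filters).
window_slices <- function(track, chrom, start, end, minus) {
  n <- length(chrom)
  wlen <- end[1] - start[1] + 1L
  out <- matrix(0, n, wlen)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- IRanges::Views(track[[ch]], start = start[i], end = end[i])
    out[i, ] <- as.matrix(v)
  }
  if (any(minus)) out[minus, ] <- out[minus, wlen:1, drop = FALSE]
  out
}

#' TSS-centered coverage metaprofile
#'
#' Averages an oriented coverage slice (`tss - flank .. tss + flank - 1`,
#' minus-strand windows reversed so downstream always means
#' transcription-downstream) over a set of promoters. The confidence band is
#' the normal 95% interval of the per-offset mean,
#' `mean +/- 1.96 * sqrt(var / n)`.
#'
#' @param track Coverage track ([read_bedgraph()]).
#' @param promoters Promoter windows ([extract_promoters()]; `tss` metadata
#'   and strand are used).
#' @param flank Half-width in bp (default 3000).
#' @param clipped `"exclude"` (default) drops windows truncated by chromosome
#'   ends; `"zero_pad"` keeps them padded with zeros.
#' @param genome Required for `clipped` handling when promoters lack seqinfo.
#' @return Object of class `MetaProfile`: list with `offsets`
#'   (-flank .. flank-1), `mean`, `var`, `lower`, `upper`, `n_anchors`,
#'   `anchor_set`.
#' @export
compute_tss_profile <- function(track, promoters, flank = 3000,
                                clipped = c("exclude", "zero_pad"),
                                genome = NULL) {
  clipped <- match.arg(clipped)
  if (length(promoters) == 0L) stop("zero anchors", call. = FALSE)
  chrom <- as.character(seqnames(promoters))
  tss <- mcols(promoters)$tss
  if (is.null(tss)) stop("promoters must carry tss metadata", call. = FALSE)
  lens <- if (!is.null(genome)) genome$sizes[chrom] else
    seqlengths(promoters)[chrom]
  if (any(is.na(lens))) stop("chromosome lengths unavailable", call. = FALSE)
  minus <- as.character(strand(promoters)) == "-"
  ## strand-aware slice: offset j in [-flank, flank) sits at tss + j on the
  ## plus strand and tss - j on the minus strand, so the window is
  ## [tss - flank, tss + flank - 1] (+) or [tss - flank + 1, tss + flank] (-)
  ## and reversing the genome leaves the profile exactly unchanged
  s <- ifelse(minus, tss - flank + 1L, tss - flank)
  e <- ifelse(minus, tss + flank, tss + flank - 1L)
  inside <- s >= 1 & e <= lens
  wlen <- 2L * flank
  if (clipped == "exclude") {
    if (!any(inside)) stop("zero anchors after excluding clipped windows",
                           call. = FALSE)
    m <- window_slices(track, chrom[inside], as.integer(s[inside]),
                       as.integer(e[inside]), minus[inside])
  } else {
    m <- matrix(0, length(promoters), wlen)
    if (any(inside))
      m[inside, ] <- window_slices(track, chrom[inside], as.integer(s[inside]),
                                   as.integer(e[inside]), minus[inside])
    for (i in which(!inside)) {
      cs <- max(1L, as.integer(s[i])); ce <- min(as.integer(lens[i]),
                                                 as.integer(e[i]))
      if (cs > ce) next
      v <- as.numeric(IRanges::Views(track[[chrom[i]]], cs, ce)[[1L]])
      m[i, (cs - s[i] + 1L):(ce - s[i] + 1L)] <- v
      if (minus[i]) m[i, ] <- rev(m[i, ])
    }
  }
  n <- nrow(m)
  mu <- colMeans(m)
  v <- if (n > 1) colSums(sweep(m, 2, mu)^2) / (n - 1) else rep(0, wlen)
  half <- 1.96 * sqrt(v / n)
  structure(list(anchor_set = "tss", offsets = seq(-flank, flank - 1L),
                 mean = mu, var = v, lower = mu - half, upper = mu + half,
                 n_anchors = n),
            class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat("MetaProfile over", x$n_anchors, "anchors;",
      length(x$offsets), "offsets; mean range",
      sprintf("[%.3g, %.3g]\n", min(x$mean), max(x$mean)))
  invisible(x)
}

#' Cluster per-DBP metaprofile shapes
#'
#' Hierarchical clustering (Euclidean distance, complete linkage) of the
#' per-DBP mean profile vectors, cut at a fixed height. Labels are renumbered
#' in order of first appearance so the labelling is deterministic.
#'
#' @param profiles Numeric matrix, one row per DBP (rownames = DBP names).
#' @param cut_height Dendrogram cut height (default 65; meaningful only when
#'   profiles share a scale).
#' @param normalize Divide each profile by its maximum before clustering
#'   (default FALSE).
#' @return List with `labels` (named integer vector) and `tree` (hclust).
#' @export
cluster_profile_shapes <- function(profiles, cut_height = 65,
                                   normalize = FALSE) {
  if (nrow(profiles) < 2L) stop("need at least 2 profiles", call. = FALSE)
  if (normalize) {
    mx <- apply(profiles, 1, max)
    profiles <- profiles / ifelse(mx > 0, mx, 1)
  }
  tree <- hclust(dist(profiles), method = "complete")
  raw <- cutree(tree, h = cut_height)
  labels <- match(raw, unique(raw))
  names(labels) <- rownames(profiles)
  list(labels = labels, tree = tree)
}

#' Element-centered scaled metaprofile
#'
#' Profiles coverage around variable-length elements: fixed-width flanks at
#' binned bp resolution plus the element body rescaled to a fixed number of
#' bins. Body bin values are linear interpolations of the per-bp coverage at
#' the bin-center fractional positions (so elements shorter than the bin
#' count are handled smoothly); flank bins are plain means over equal bp
#' windows. Minus-strand elements are flipped so bins run 5' to 3'.
#'
#' @param track Coverage track.
#' @param elements GRanges of elements (e.g. one repeat family).
#' @param flank Flank width in bp (default 5000).
#' @param body_bins Number of body bins (default 100).
#' @param flank_bins Number of bins per flank (default 100; `flank` must be
#'   divisible by `flank_bins`).
#' @param genome Optional `GenomeAssembly` for bounds; elements whose flanks
#'   leave the chromosome are dropped.
#' @return Object of class `ScaledMetaProfile`: list with `flank5`, `body`,
#'   `flank3` (mean per bin), `n_elements` and the bin configuration.
#' @export
compute_element_profile <- function(track, elements, flank = 5000,
                                    body_bins = 100, flank_bins = 100,
                                    genome = NULL) {
  if (length(elements) == 0L) stop("zero elements", call. = FALSE)
  if (flank %% flank_bins != 0L)
    stop("flank must be divisible by flank_bins", call. = FALSE)
  chrom <- as.character(seqnames(elements))
  lens <- if (!is.null(genome)) genome$sizes[chrom] else
    seqlengths(elements)[chrom]
  ok <- (start(elements) - flank) >= 1 & (end(elements) + flank) <= lens
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) stop("zero elements after bounds filtering", call. = FALSE)
  elements <- elements[ok]
  chrom <- chrom[ok]
  minus <- as.character(strand(elements)) == "-"
  bw <- flank %/% flank_bins
  bin_means <- function(v) colMeans(matrix(v, nrow = bw))
  f5 <- f3 <- matrix(0, length(elements), flank_bins)
  bod <- matrix(0, length(elements), body_bins)
  for (i in seq_along(elements)) {
    s <- start(elements)[i]; e <- end(elements)[i]
    left <- as.numeric(IRanges::Views(track[[chrom[i]]], s - flank, s - 1L)[[1L]])
    right <- as.numeric(IRanges::Views(track[[chrom[i]]], e + 1L, e + flank)[[1L]])
    body <- as.numeric(IRanges::Views(track[[chrom[i]]], s, e)[[1L]])
    L <- length(body)
    x <- (seq_len(L) - 0.5) / L
    xout <- (seq_len(body_bins) - 0.5) / body_bins
    bvals <- if (L == 1L) rep(body, body_bins) else
      approx(x, body, xout = xout, rule = 2)$y
    if (minus[i]) {
      f5[i, ] <- bin_means(rev(right))
      f3[i, ] <- bin_means(rev(left))
      bod[i, ] <- rev(bvals)
    } else {
      f5[i, ] <- bin_means(left)
      f3[i, ] <- bin_means(right)
      bod[i, ] <- bvals
    }
  }
  structure(list(flank5 = colMeans(f5), body = colMeans(bod),
                 flank3 = colMeans(f3), n_elements = length(elements),
                 flank = flank, body_bins = body_bins,
                 flank_bins = flank_bins),
            class = "ScaledMetaProfile")
}

#' @export
print.ScaledMetaProfile <- function(x, ...) {
  cat("ScaledMetaProfile over", x$n_elements, "elements;",
      x$flank_bins, "+", x$body_bins, "+", x$flank_bins, "bins; body mean",
      sprintf("%.3g\n", mean(x$body)))
  invisible(x)
}

#' Add two coverage tracks
#' @param a,b RleLists over the same chromosomes.
#' @return Their per-base sum.
#' @export
add_tracks <- function(a, b) {
  stopifnot(identical(names(a), names(b)))
  methods::as(mapply(function(x, y) x + y, a, b, SIMPLIFY = FALSE),
              "RleList")
}
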