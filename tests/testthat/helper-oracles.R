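## Brute-force oracles and toy-data builders shared across test files.
## Oracles deliberately use naive O(n^2) algorithms and plain loops,
## independent of the package's implementations.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

toy_genome <- function(sizes = c(chr1 = 100000, chr2 = 50000), canonical = NULL)
  genome_assembly(sizes, canonical = canonical)

## GRanges from 0-based half-open triples (test-side convenience)
gr0 <- function(chrom, start0, end0, strand = "*")
  GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)

## Connected-component consensus oracle: all-pairs overlap matrix + BFS;
## a component emits [min start, max end] iff every replicate is present.
oracle_consensus <- function(reps) {
  df <- do.call(rbind, lapply(seq_along(reps), function(i) {
    gr <- reps[[i]]
    if (length(gr) == 0L) return(NULL)
    data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
               end = end(gr), rep = i)
  }))
  if (is.null(df) || length(unique(df$rep)) < length(reps))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  n <- nrow(df)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- df$chrom[i] == df$chrom[j] &&
      df$start[i] <= df$end[j] && df$start[j] <= df$end[i]
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  out <- do.call(rbind, lapply(seq_len(k), function(cc) {
    idx <- which(comp == cc)
    if (length(unique(df$rep[idx])) < length(reps)) return(NULL)
    data.frame(chrom = df$chrom[idx][1L], start = min(df$start[idx]),
               end = max(df$end[idx]))
  }))
  if (is.null(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer()))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

consensus_as_df <- function(set) {
  gr <- set$peaks
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
                   end = end(gr))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_gr <- function(n, chrom_len = 10000, chroms = "chr1",
                      max_width = 500) {
  ch <- sample(chroms, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i)
    sample.int(chrom_len - w[i], 1L), 1L)
  GRanges(ch, IRanges(s, width = w))
}

## Nested-loop feature-overlap oracle (>= 1 bp)
oracle_overlap_count <- function(peaks, features) {
  hit <- logical(length(features))
  for (j in seq_along(features)) for (i in seq_along(peaks)) {
    if (as.character(seqnames(features))[j] == as.character(seqnames(peaks))[i] &&
        start(features)[j] <= end(peaks)[i] &&
        start(peaks)[i] <= end(features)[j]) {
      hit[j] <- TRUE
      break
    }
  }
  sum(hit)
}

## Toy promoter annotation: GRanges with gene_id/tss/flank metadata
toy_promoters <- function(tss, strand, chrom = "chr1", flank = 3000,
                          ids = sprintf("g%02d", seq_along(tss)),
                          biotype = NULL, chrom_len = 1e6) {
  g <- genome_assembly(setNames(rep(chrom_len, length(unique(chrom))),
                                unique(chrom)))
  gr <- GRanges(rep(chrom, length.out = length(tss)),
                IRanges(pmax(1, tss - flank), tss + flank - 1),
                strand = strand)
  mcols(gr)$gene_id <- ids
  if (!is.null(biotype)) mcols(gr)$biotype <- biotype
  mcols(gr)$tss <- as.integer(tss)
  mcols(gr)$flank <- as.integer(flank)
  GenomeInfoDb::seqlevels(gr) <- names(g$sizes)
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- Seqinfo(names(g$sizes),
                                                        unname(g$sizes)))
  gr
}

## Small-but-complete simulation config for fast end-to-end tests
small_sim_config <- function(seed = 7, ...)
  sim_config(seed = seed, n_genes = 120, n_chromosomes = 2,
             chrom_length = 1.2e6, n_dbps = 10, n_low_affinity = 2,
             n_reservoirs = 8, bg_peaks_per_dbp = 40,
             repeat_family_copies = 25, n_superenhancers = 4, ...)
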