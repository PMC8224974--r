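#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Mixes the master seed with a label string through a djb2-style string
#' hash, modulo 2^31 - 1. Every randomized operation takes its own sub-seed
#' from the master seed and the names of the objects involved, so results do
#' not depend on execution order.
#'
#' @param seed Master integer seed.
#' @param ... Label components (coerced to character, joined by "/").
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 5381
  for (code in utf8ToInt(lab)) h <- (h * 33 + code) %% 2147483647
  as.integer(h)
}

#' Constrained genome shuffle of a peak set
#'
#' Randomly relocates peaks while preserving (i) the number of peaks, (ii)
#' the multiset of peak widths, and (iii) the number of peaks on each
#' chromosome. Each start is uniform on `[0, L - w]`; shuffled peaks may
#' overlap one another (no rejection). Deterministic given the seed.
#'
#' @param set A `ConsensusPeakSet` or GRanges.
#' @param genome A `GenomeAssembly`.
#' @param seed Integer seed.
#' @return GRanges of shuffled intervals.
#' @export
shuffle_peaks <- function(set, genome, seed) {
  peaks <- if (inherits(set, "ConsensusPeakSet")) set$peaks else set
  out <- shuffle_starts(peaks, genome, seed, n_draws = 1L)
  out$gr
}

## Vectorized engine shared by shuffle_peaks and the permutation null:
## generates n_draws independent shuffles at once; returns a GRanges with a
## `perm` metadata column. Uses one runif() call per chromosome so a single
## draw reproduces shuffle_peaks exactly.
shuffle_starts <- function(peaks, genome, seed, n_draws) {
  chrom <- as.character(seqnames(peaks))
  w <- width(peaks)
  L <- genome$sizes[chrom]
  if (any(w > L)) stop("peak wider than its chromosome", call. = FALSE)
  set.seed(seed)
  parts <- lapply(unique(chrom), function(ch) {
    i <- which(chrom == ch)
    n <- length(i) * n_draws
    ## 0-based start uniform on {0, ..., L - w}; 1-based = value + 1
    wi <- rep(w[i], n_draws)
    s0 <- floor(runif(n) * (genome$sizes[ch] - wi + 1))
    GRanges(ch, IRanges(as.integer(s0) + 1L, width = wi),
            perm = rep(seq_len(n_draws), each = length(i)))
  })
  gr <- suppressWarnings(do.call(c, parts))
  list(gr = gr)
}

#' Permutation enrichment of a peak set against a feature set
#'
#' The observed statistic is, by default, the number of *peaks* overlapping
#' at least one feature (so the Fisher table rows sum to the peak count); the
#' feature-unit statistic (number of features hit) is also available. The
#' null is `n_perm` constrained shuffles ([shuffle_peaks()]); the Z-score is
#' `(obs - null mean)/null sd`; the empirical p-value is two-sided with an
#' add-one correction (twice the smaller tail, capped at 1), so it is never
#' exactly zero. Draws tying the observed value count half into each tail
#' (the mid-p correction): the overlap count is discrete, and full-weight
#' ties would make the p-value conservative rather than calibrated under the
#' null. A Fisher exact p-value is reported alongside, built from the
#' 2x2 table `[obs, n - obs; round(null mean), n - round(null mean)]` - a
#' documented construction, not a substitute for the empirical p.
#'
#' @param set `ConsensusPeakSet` or GRanges of peaks.
#' @param features GRanges of features.
#' @param genome A `GenomeAssembly`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the effective seed is derived from `seed`, the
#'   DBP name and `feature_set` via [derive_seed()].
#' @param feature_set Label for the feature set (used in the RNG substream
#'   and in reports).
#' @param unit `"peaks"` (default) or `"features"`: the unit of the overlap
#'   statistic.
#' @param alpha Significance level used only to label `direction`.
#' @return Object of class `PermutationNull`; see Details.
#' @export
permutation_enrichment <- function(set, features, genome, n_perm = 1000,
                                   seed = 1, feature_set = "features",
                                   unit = c("peaks", "features"),
                                   alpha = 0.05) {
  unit <- match.arg(unit)
  stopifnot(n_perm >= 1)
  peaks <- if (inherits(set, "ConsensusPeakSet")) set$peaks else set
  dbp <- if (inherits(set, "ConsensusPeakSet")) set$dbp else NA_character_
  n_peaks <- length(peaks)
  count_stat <- function(gr, perm = NULL) {
    if (is.null(perm)) {
      if (unit == "peaks")
        sum(overlapsAny(gr, features, ignore.strand = TRUE))
      else
        sum(overlapsAny(features, gr, ignore.strand = TRUE))
    } else {
      if (unit == "peaks") {
        ov <- overlapsAny(gr, features, ignore.strand = TRUE)
        tabulate(perm[ov], nbins = n_perm)
      } else {
        hits <- findOverlaps(gr, features, ignore.strand = TRUE)
        key <- unique((as.numeric(perm[queryHits(hits)]) - 1) *
                        length(features) + subjectHits(hits))
        pid <- floor((key - 1) / length(features)) + 1
        tabulate(pid, nbins = n_perm)
      }
    }
  }
  observed <- count_stat(peaks)
  sub <- derive_seed(seed, dbp, feature_set)
  sh <- shuffle_starts(peaks, genome, sub, n_draws = n_perm)
  draws <- count_stat(sh$gr, perm = mcols(sh$gr)$perm)
  null_mean <- mean(draws)
  null_sd <- sd(draws)
  if (is.na(null_sd)) null_sd <- 0
  z <- if (null_sd > 0) (observed - null_mean) / null_sd else NA_real_
  ties <- sum(draws == observed)
  p_lo <- (1 + sum(draws < observed) + 0.5 * ties) / (n_perm + 1)
  p_hi <- (1 + sum(draws > observed) + 0.5 * ties) / (n_perm + 1)
  p_emp <- min(1, 2 * min(p_lo, p_hi))
  m <- round(null_mean)
  p_fisher <- if (n_peaks > 0)
    fisher.test(matrix(c(observed, n_peaks - observed, m, n_peaks - m), 2))$p.value
  else NA_real_
  direction <- if (null_sd == 0) "undefined"
  else if (p_emp < alpha && observed > null_mean) "enriched"
  else if (p_emp < alpha && observed < null_mean) "depleted"
  else "ns"
  structure(list(dbp = dbp, feature_set = feature_set, observed = observed,
                 draws = draws, null_mean = null_mean, null_sd = null_sd,
                 z = z, p_empirical = p_emp, p_fisher = p_fisher,
                 direction = direction, n_perm = n_perm, n_peaks = n_peaks,
                 unit = unit),
            class = "PermutationNull")
}

#' @export
print.PermutationNull <- function(x, ...) {
  cat(sprintf("PermutationNull: %s vs %s - obs %d, null %.1f +/- %.2f, z = %s, p_emp = %.3g (%s)\n",
              x$dbp, x$feature_set, x$observed, x$null_mean, x$null_sd,
              ifelse(is.na(x$z), "undefined", sprintf("%.2f", x$z)),
              x$p_empirical, x$direction))
  invisible(x)
}

#' Permutation Z-score matrix for DBPs against repeat groups
#'
#' Runs [permutation_enrichment()] for every (DBP, repeat class or family)
#' pair and collects Z-scores and p-values into matrices ready for heat-map
#' plotting. Each pair uses its own RNG substream so the matrix is identical
#' whatever the iteration order.
#'
#' @param sets List of `ConsensusPeakSet`.
#' @param repeats GRanges from [read_repeats()].
#' @param genome A `GenomeAssembly`.
#' @param by Group repeats by `"family"` or `"class"`.
#' @param groups Optional subset of group names; an unknown name errors.
#' @param n_perm,seed Passed to [permutation_enrichment()].
#' @return List with matrices `z`, `p_empirical`, `p_fisher` (DBP x group)
#'   and `results` (nested list of `PermutationNull`).
#' @export
repeat_enrichment_matrix <- function(sets, repeats, genome,
                                     by = c("family", "class"),
                                     groups = NULL, n_perm = 1000, seed = 1) {
  by <- match.arg(by)
  key <- if (by == "family") mcols(repeats)$rep_family else mcols(repeats)$rep_class
  avail <- unique(key)
  if (is.null(groups)) groups <- sort(avail)
  miss <- setdiff(groups, avail)
  if (length(miss))
    stop("repeat ", by, " absent from annotation: ",
         paste(miss, collapse = ", "), call. = FALSE)
  dbps <- vapply(sets, function(s) as.character(s$dbp), "")
  z <- pe <- pf <- matrix(NA_real_, length(sets), length(groups),
                          dimnames = list(dbps, groups))
  results <- list()
  for (g in groups) {
    feat <- repeats[key == g]
    for (i in seq_along(sets)) {
      r <- permutation_enrichment(sets[[i]], feat, genome, n_perm = n_perm,
                                  seed = seed,
                                  feature_set = paste0(by, ":", g))
      z[i, g] <- r$z
      pe[i, g] <- r$p_empirical
      pf[i, g] <- r$p_fisher
      results[[paste(dbps[i], g, sep = "|")]] <- r
    }
  }
  list(z = z, p_empirical = pe, p_fisher = pf, results = results, by = by)
}

#' Chi-squared test of DBP binding bias between lncRNA and mRNA promoters
#'
#' For each DBP, a 2x2 contingency table of bound/unbound by lncRNA/mRNA is
#' tested with the textbook chi-squared statistic (no continuity correction);
#' the reported effect is log2(observed/expected) on the bound-lncRNA cell.
#'
#' @param occ An `OccupancyMatrix` whose promoters carry biotypes, or supply
#'   `biotypes` explicitly.
#' @param biotypes Named character vector (`mRNA`/`lncRNA`) per promoter.
#' @return data.frame with one row per DBP: bound/unbound counts per biotype,
#'   `log2_obs_exp`, `statistic`, `p` (NA rows for DBPs bound nowhere).
#' @export
biotype_bias_test <- function(occ, biotypes = NULL) {
  if (is.null(biotypes)) biotypes <- occ$biotype
  if (is.null(biotypes)) stop("biotypes are required", call. = FALSE)
  biotypes <- biotypes[rownames(occ$m)]
  if (!all(c("lncRNA", "mRNA") %in% biotypes))
    stop("both biotypes must be present", call. = FALSE)
  is_lnc <- biotypes == "lncRNA"
  res <- lapply(colnames(occ$m), function(d) {
    b <- occ$m[, d] == 1L
    tab <- matrix(c(sum(b & is_lnc), sum(b & !is_lnc),
                    sum(!b & is_lnc), sum(!b & !is_lnc)), 2, byrow = TRUE,
                  dimnames = list(c("bound", "unbound"), c("lncRNA", "mRNA")))
    if (sum(b) == 0L)
      return(data.frame(dbp = d, bound_lncRNA = 0L, bound_mRNA = 0L,
                        unbound_lncRNA = tab[2, 1], unbound_mRNA = tab[2, 2],
                        log2_obs_exp = NA_real_, statistic = NA_real_,
                        p = NA_real_))
    expected <- sum(b) * sum(is_lnc) / length(b)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    data.frame(dbp = d, bound_lncRNA = tab[1, 1], bound_mRNA = tab[1, 2],
               unbound_lncRNA = tab[2, 1], unbound_mRNA = tab[2, 2],
               log2_obs_exp = log2(tab[1, 1] / expected),
               statistic = unname(ct$statistic), p = unname(ct$p.value))
  })
  do.call(rbind, res)
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` successes in `n` draws without replacement from a population
#' of `N` containing `K` successes.
#'
#' @param k Successes drawn.
#' @param K Successes in the population.
#' @param n Number of draws.
#' @param N Population size.
#' @return The upper-tail p-value.
#' @export
hypergeometric_overrepresentation <- function(k, K, n, N) {
  if (!(0 <= k && k <= min(K, n) && min(K, n) <= N && n <= N && K <= N))
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n) <= N",
         call. = FALSE)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' DBPs enriched or depleted on reservoir promoters
#'
#' Per DBP, a 2x2 table (bound/unbound by reservoir/non-reservoir) is tested
#' with the chi-squared statistic, and the fold change is the ratio of
#' binding rates. DBPs passing both the p-value and fold thresholds are
#' reported with their direction.
#'
#' @param occ An `OccupancyMatrix`.
#' @param is_reservoir Logical vector (named by gene id, or aligned to the
#'   matrix rows).
#' @param p_threshold P-value cutoff (default 0.001).
#' @param fold Fold-change cutoff (default 2): enriched when rate ratio
#'   > `fold`, depleted when < `1/fold`.
#' @return List with `enriched`, `depleted` (character vectors of DBPs) and
#'   `table` (per-DBP data.frame with counts, fold change and p).
#' @export
reservoir_dbp_bias <- function(occ, is_reservoir, p_threshold = 0.001,
                               fold = 2) {
  if (!is.null(names(is_reservoir))) is_reservoir <- is_reservoir[rownames(occ$m)]
  stopifnot(length(is_reservoir) == nrow(occ$m))
  if (!any(is_reservoir) || all(is_reservoir))
    stop("both reservoir and non-reservoir promoters are required",
         call. = FALSE)
  n_res <- sum(is_reservoir); n_non <- sum(!is_reservoir)
  rows <- lapply(colnames(occ$m), function(d) {
    b <- occ$m[, d] == 1L
    br <- sum(b & is_reservoir); bn <- sum(b & !is_reservoir)
    tab <- matrix(c(br, bn, n_res - br, n_non - bn), 2, byrow = TRUE)
    p <- if (sum(b) == 0L) NA_real_ else
      suppressWarnings(chisq.test(tab, correct = FALSE))$p.value
    fc <- (br / n_res) / (bn / n_non)
    data.frame(dbp = d, bound_reservoir = br, bound_nonreservoir = bn,
               fold_change = fc, p = p)
  })
  tab <- do.call(rbind, rows)
  sig <- !is.na(tab$p) & tab$p < p_threshold
  list(enriched = tab$dbp[sig & tab$fold_change > fold & is.finite(tab$fold_change)],
       depleted = tab$dbp[sig & tab$fold_change < 1 / fold],
       table = tab)
}

#' Write a list of permutation results as a TSV table
#' @param results List of `PermutationNull`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(dbp = r$dbp, feature_set = r$feature_set, observed = r$observed,
               null_mean = r$null_mean, null_sd = r$null_sd, z = r$z,
               p_empirical = r$p_empirical, p_fisher = r$p_fisher,
               direction = r$direction)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
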