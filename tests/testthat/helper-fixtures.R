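## Shared expensive fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

## Full-scale synthetic study: default generator conditions, written to disk
## and pushed through the pipeline up to the reservoir report.
full_study <- function(seed = 101) {
  key <- paste0("study", seed)
  if (is.null(.fixture_env[[key]])) {
    ds <- file.path(tempdir(), paste0("reservoiR_ds_", seed))
    out <- file.path(tempdir(), paste0("reservoiR_out_", seed))
    sim <- write_synthetic_dataset(sim_config(seed = seed), ds,
                                   coverage = FALSE)
    res <- run_pipeline(ds, out, thresholds = analysis_thresholds(),
                        stages = c("reservoirs", "report"))
    .fixture_env[[key]] <- list(sim = sim, res = res, ds = ds, out = out)
  }
  .fixture_env[[key]]
}

## Uniform-null calibration fixture: feature sets and peak sets drawn from
## the same uniform placement the shuffle uses, sized so the overlap count
## statistic has wide support (see the methods vignette).
calibration_run <- function(seed = 7, n_dbps = 40, n_sets = 5,
                            n_perm = 200, n_features = 400,
                            feature_width = 3000, n_peaks = 500) {
  g <- genome_assembly(c(chr1 = 1e7, chr2 = 1e7))
  set.seed(derive_seed(seed, "calibration-features"))
  featsets <- lapply(seq_len(n_sets), function(k) {
    ch <- sample(names(g$sizes), n_features, replace = TRUE)
    GRanges(ch, IRanges(floor(runif(n_features) *
                                (g$sizes[ch] - feature_width)) + 1,
                        width = feature_width))
  })
  pvals <- zs <- numeric()
  for (d in seq_len(n_dbps)) {
    set.seed(derive_seed(seed, "calibration-peaks", d))
    w <- pmin(pmax(round(rlnorm(n_peaks, log(300), 0.4)), 150), 2500)
    ch <- sample(names(g$sizes), n_peaks, replace = TRUE)
    pk <- GRanges(ch, IRanges(floor(runif(n_peaks) *
                                      (g$sizes[ch] - w + 1)) + 1, width = w))
    set <- structure(list(dbp = paste0("D", d), peaks = pk,
                          n_replicates = 2, n_peaks = n_peaks),
                     class = "ConsensusPeakSet")
    for (k in seq_len(n_sets)) {
      r <- permutation_enrichment(set, featsets[[k]], g, n_perm = n_perm,
                                  seed = seed,
                                  feature_set = paste0("fs", k))
      pvals <- c(pvals, r$p_empirical)
      zs <- c(zs, r$z)
    }
  }
  list(pvals = pvals, z = zs)
}
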