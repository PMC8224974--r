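test_that("constrained shuffle preserves widths and per-chromosome counts", {
  g <- toy_genome(c(chr1 = 50000, chr2 = 20000))
  set.seed(5)
  pk <- suppressWarnings(c(random_gr(30, 49000, "chr1"),
                           random_gr(10, 19000, "chr2")))
  sh <- shuffle_peaks(pk, g, seed = 123)
  for (ch in c("chr1", "chr2")) {
    expect_equal(sort(width(sh[seqnames(sh) == ch])),
                 sort(width(pk[seqnames(pk) == ch])))
  }
  expect_true(all(start(sh) >= 1))
  expect_true(all(end(sh) <= g$sizes[as.character(seqnames(sh))]))
  ## deterministic given the seed, different otherwise
  expect_identical(sh, shuffle_peaks(pk, g, seed = 123))
  expect_false(identical(start(sh), start(shuffle_peaks(pk, g, seed = 124))))
  wide <- GRanges("chr2", IRanges(1, 30000))
  expect_error(shuffle_peaks(wide, g, seed = 1), "wider")
})

test_that("planted overlap is detected and the z-score matches a plain-loop re-implementation", {
  g <- toy_genome(c(chr1 = 100000))
  features <- GRanges("chr1", IRanges(seq(1000, 9000, by = 2000), width = 500))
  ## peaks copied onto features: every peak overlaps
  pk <- features
  set <- structure(list(dbp = "TFX", peaks = pk, n_replicates = 2,
                        n_peaks = length(pk)), class = "ConsensusPeakSet")
  r <- permutation_enrichment(set, features, g, n_perm = 200, seed = 99,
                              feature_set = "toy")
  expect_equal(r$observed, length(pk))
  expect_lt(r$p_empirical, 0.01)
  expect_equal(r$direction, "enriched")
  expect_gt(r$z, 3)

  ## independent oracle: replay the same substream with plain loops
  sub <- derive_seed(99, "TFX", "toy")
  set.seed(sub)
  n <- length(pk)
  w <- width(pk)
  u <- runif(n * 200)
  draws <- integer(200)
  for (p in 1:200) {
    s0 <- floor(u[(p - 1) * n + seq_len(n)] * (100000 - rep(w, 1) + 1))
    s1 <- s0 + 1
    e1 <- s0 + w
    cnt <- 0L
    for (i in seq_len(n)) {
      hit <- FALSE
      for (j in seq_along(features))
        if (s1[i] <= end(features)[j] && start(features)[j] <= e1[i]) {
          hit <- TRUE
          break
        }
      cnt <- cnt + hit
    }
    draws[p] <- cnt
  }
  expect_equal(r$draws, draws)
  expect_equal(r$z, (r$observed - mean(draws)) / sd(draws))
  ties <- sum(draws == r$observed)
  expect_equal(r$p_empirical,
               min(1, 2 * min((1 + sum(draws > r$observed) + ties / 2) / 201,
                              (1 + sum(draws < r$observed) + ties / 2) / 201)))
})

test_that("degenerate feature sets give sd-zero or all-zero nulls", {
  g <- toy_genome(c(chr1 = 10000))
  pk <- GRanges("chr1", IRanges(c(100, 5000), width = 50))
  set <- structure(list(dbp = "d", peaks = pk, n_replicates = 2, n_peaks = 2),
                   class = "ConsensusPeakSet")
  tiling <- GRanges("chr1", IRanges(1, 10000))
  r <- permutation_enrichment(set, tiling, g, n_perm = 50, seed = 1)
  expect_equal(r$null_sd, 0)
  expect_true(is.na(r$z))
  expect_equal(r$direction, "undefined")
  r0 <- permutation_enrichment(set, GRanges(), g, n_perm = 50, seed = 1)
  expect_equal(r0$observed, 0L)
  expect_true(all(r0$draws == 0))
})

test_that("repeat enrichment matrix recovers planted family preference", {
  g <- toy_genome(c(chr1 = 200000))
  fam <- GRanges("chr1", IRanges(seq(10000, 190000, by = 10000), width = 800))
  other <- GRanges("chr1", IRanges(seq(5000, 185000, by = 20000), width = 300))
  reps <- c(fam, other)
  mcols(reps)$rep_name <- sprintf("r%02d", seq_along(reps))
  mcols(reps)$rep_class <- rep(c("Retroposon", "SINE"),
                               c(length(fam), length(other)))
  mcols(reps)$rep_family <- rep(c("SVA", "Alu"), c(length(fam), length(other)))
  binder <- structure(list(dbp = "B", peaks = GenomicRanges::resize(fam, 400,
                                                                    fix = "center"),
                           n_replicates = 2, n_peaks = length(fam)),
                      class = "ConsensusPeakSet")
  m <- repeat_enrichment_matrix(list(binder), reps, g, by = "family",
                                n_perm = 100, seed = 4)
  expect_gt(m$z["B", "SVA"], 3)
  expect_equal(colnames(m$z)[which.max(m$z["B", ])], "SVA")
  expect_error(repeat_enrichment_matrix(list(binder), reps, g, by = "family",
                                        groups = "L1", n_perm = 10, seed = 1),
               "absent")
})

test_that("lncRNA/mRNA bias chi-squared matches the textbook 2x2 computation", {
  ## 60 of 100 lncRNA bound, 20 of 100 mRNA bound
  m <- cbind(D1 = c(rep(1, 60), rep(0, 40), rep(1, 20), rep(0, 80)),
             D0 = rep(0, 200),
             DP = c(rep(1, 10), rep(0, 90), rep(1, 10), rep(0, 90)))
  rownames(m) <- sprintf("g%03d", 1:200)
  bt <- setNames(rep(c("lncRNA", "mRNA"), each = 100), rownames(m))
  occ <- structure(list(m = m, n_dbps = rowSums(m), biotype = bt),
                   class = "OccupancyMatrix")
  res <- biotype_bias_test(occ)
  d1 <- res[res$dbp == "D1", ]
  ## E = [40,40;60,60]; X^2 = 2*400/40 + 2*400/60
  expect_equal(d1$statistic, 2 * 400 / 40 + 2 * 400 / 60)
  expect_equal(d1$log2_obs_exp, log2(60 / 40))
  ## proportional binding (10% each) -> log2 obs/exp = 0
  expect_equal(res[res$dbp == "DP", "log2_obs_exp"], 0)
  ## unbound DBP -> NA
  expect_true(is.na(res[res$dbp == "D0", "p"]))
})

test_that("hypergeometric over-representation matches enumeration", {
  expect_equal(hypergeometric_overrepresentation(0, 3, 2, 10), 1)
  ## N=5, K=2, n=2, k=2: C(2,2) C(3,0) / C(5,2) = 1/10
  expect_equal(hypergeometric_overrepresentation(2, 2, 2, 5), 0.1)
  expect_equal(hypergeometric_overrepresentation(4, 4, 4, 4), 1)
  ## full enumeration oracle at N=6, K=3, n=3, k=2: P[X>=2]
  p_enum <- (choose(3, 2) * choose(3, 1) + choose(3, 3) * choose(3, 0)) /
    choose(6, 3)
  expect_equal(hypergeometric_overrepresentation(2, 3, 3, 6), p_enum)
  expect_error(hypergeometric_overrepresentation(5, 2, 2, 5), "bounds")
})

test_that("reservoir DBP bias applies both the p and fold thresholds", {
  set.seed(21)
  n_res <- 100; n_non <- 400
  res_flag <- c(rep(TRUE, n_res), rep(FALSE, n_non))
  ## planted 4x denser on reservoirs; a balanced DBP; an empty DBP
  m <- cbind(ENR = c(rbinom(n_res, 1, 0.8), rbinom(n_non, 1, 0.2)),
             BAL = rbinom(n_res + n_non, 1, 0.5),
             NONE = 0L)
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  occ <- structure(list(m = m, n_dbps = rowSums(m)), class = "OccupancyMatrix")
  b <- reservoir_dbp_bias(occ, res_flag, p_threshold = 0.001, fold = 2)
  expect_true("ENR" %in% b$enriched)
  expect_false("BAL" %in% c(b$enriched, b$depleted))
  binf <- reservoir_dbp_bias(occ, res_flag, p_threshold = 0.001, fold = Inf)
  expect_length(binf$enriched, 0L)
  expect_length(binf$depleted, 0L)
})

test_that("adding features never decreases the observed overlap", {
  g <- toy_genome(c(chr1 = 50000))
  set.seed(8)
  pk <- random_gr(40, 49000)
  f1 <- random_gr(10, 49000)
  f2 <- c(f1, random_gr(10, 49000))
  s <- structure(list(dbp = "d", peaks = pk, n_replicates = 2,
                      n_peaks = length(pk)), class = "ConsensusPeakSet")
  o1 <- permutation_enrichment(s, f1, g, n_perm = 5, seed = 1)$observed
  o2 <- permutation_enrichment(s, f2, g, n_perm = 5, seed = 1)$observed
  expect_gte(o2, o1)
})
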