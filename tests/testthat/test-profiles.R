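flat_track <- function(value, g) {
  gr <- GRanges(names(g$sizes), IRanges(1, unname(g$sizes)))
  track_from_intervals(gr, g, score = rep(value, length(gr)))
}

random_track <- function(g, n = 60) {
  gr <- do.call(c, lapply(names(g$sizes), function(ch)
    GRanges(ch, IRanges(sample.int(g$sizes[ch] - 500, n), width = 500))))
  track_from_intervals(gr, g)
}

test_that("TSS profiles average oriented slices with a variance band", {
  g <- toy_genome(c(chr1 = 100000))
  prom <- toy_promoters(tss = c(20000, 50000), strand = c("+", "-"),
                        flank = 100, chrom_len = 1e5)
  ## constant coverage -> flat profile, zero variance
  p <- compute_tss_profile(flat_track(2, g), prom, flank = 100, genome = g)
  expect_equal(p$mean, rep(2, 200))
  expect_equal(p$var, rep(0, 200))
  expect_equal(p$lower, p$mean)
  expect_equal(p$n_anchors, 2L)
  expect_equal(p$offsets, -100:99)

  ## single anchor: profile is exactly the oriented coverage slice
  tr <- track_from_intervals(GRanges("chr1", IRanges(19950, 20010)), g)
  one <- compute_tss_profile(tr, prom[1], flank = 100, genome = g)
  slice <- as.numeric(IRanges::Views(tr[["chr1"]], 19900, 20099)[[1]])
  expect_equal(one$mean, slice)

  ## two anchors: per-offset arithmetic mean of the two oriented slices
  tr2 <- track_from_intervals(GRanges("chr1", IRanges(c(19950, 50040),
                                                      width = 20)), g)
  both <- compute_tss_profile(tr2, prom, flank = 100, genome = g)
  s1 <- as.numeric(IRanges::Views(tr2[["chr1"]], 19900, 20099)[[1]])
  s2 <- rev(as.numeric(IRanges::Views(tr2[["chr1"]], 49901, 50100)[[1]]))
  expect_equal(both$mean, (s1 + s2) / 2)
  expect_true(all(both$lower <= both$mean & both$mean <= both$upper))

  ## clipped windows are excluded by default, zero-padded on request
  edge <- toy_promoters(tss = c(50, 20000), strand = c("+", "+"),
                        flank = 100, chrom_len = 1e5)
  pexc <- compute_tss_profile(flat_track(1, g), edge, flank = 100, genome = g)
  expect_equal(pexc$n_anchors, 1L)
  ppad <- compute_tss_profile(flat_track(1, g), edge, flank = 100,
                              clipped = "zero_pad", genome = g)
  expect_equal(ppad$n_anchors, 2L)
  expect_lt(ppad$mean[1], 1)
  expect_error(compute_tss_profile(flat_track(1, g), edge[0], flank = 100,
                                   genome = g), "zero anchors")
})

test_that("metaprofiles are invariant under genome mirroring", {
  set.seed(14)
  g <- toy_genome(c(chr1 = 40000))
  L <- 40000
  tr <- random_track(g, n = 40)
  prom <- toy_promoters(tss = c(9000, 17000, 30000),
                        strand = c("+", "-", "+"), flank = 500,
                        chrom_len = 4e4)
  ## mirrored genome: position x -> L + 1 - x, strands flipped
  mtr <- methods::as(list(chr1 = rev(tr[["chr1"]])), "RleList")
  mprom <- toy_promoters(tss = L + 1 - c(9000, 17000, 30000),
                         strand = c("-", "+", "-"), flank = 500,
                         chrom_len = 4e4)
  p1 <- compute_tss_profile(tr, prom, flank = 500, genome = g)
  p2 <- compute_tss_profile(mtr, mprom, flank = 500, genome = g)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-12)
  expect_equal(p1$var, p2$var, tolerance = 1e-12)

  ## element profiles mirror too
  el <- GRanges("chr1", IRanges(c(12000, 22000), width = c(700, 1300)),
                strand = c("+", "-"))
  mel <- GRanges("chr1", IRanges(L + 1 - c(12000 + 699, 22000 + 1299),
                                 width = c(700, 1300)),
                 strand = c("-", "+"))
  e1 <- compute_element_profile(tr, el, flank = 1000, body_bins = 50,
                                flank_bins = 20, genome = g)
  e2 <- compute_element_profile(mtr, mel, flank = 1000, body_bins = 50,
                                flank_bins = 20, genome = g)
  expect_equal(e1$body, e2$body, tolerance = 1e-12)
  expect_equal(e1$flank5, e2$flank5, tolerance = 1e-12)
  expect_equal(e1$flank3, e2$flank3, tolerance = 1e-12)
})

test_that("profiles are additive over tracks", {
  set.seed(15)
  g <- toy_genome(c(chr1 = 30000))
  t1 <- random_track(g, 30)
  t2 <- random_track(g, 30)
  prom <- toy_promoters(tss = c(8000, 21000), strand = c("+", "-"),
                        flank = 400, chrom_len = 3e4)
  ps <- compute_tss_profile(add_tracks(t1, t2), prom, flank = 400, genome = g)
  pa <- compute_tss_profile(t1, prom, flank = 400, genome = g)
  pb <- compute_tss_profile(t2, prom, flank = 400, genome = g)
  expect_equal(ps$mean, pa$mean + pb$mean, tolerance = 1e-9)
  el <- GRanges("chr1", IRanges(c(5000, 15000), width = c(300, 900)))
  es <- compute_element_profile(add_tracks(t1, t2), el, flank = 1000,
                                body_bins = 40, flank_bins = 10, genome = g)
  ea <- compute_element_profile(t1, el, flank = 1000, body_bins = 40,
                                flank_bins = 10, genome = g)
  eb <- compute_element_profile(t2, el, flank = 1000, body_bins = 40,
                                flank_bins = 10, genome = g)
  expect_equal(es$body, ea$body + eb$body, tolerance = 1e-9)
  expect_equal(es$flank5, ea$flank5 + eb$flank5, tolerance = 1e-9)
})

test_that("element bodies rescale by bin-center interpolation", {
  g <- toy_genome(c(chr1 = 100000))
  ## indicator coverage: 1 inside every element, 0 outside
  el <- GRanges("chr1", IRanges(c(20000, 50000), width = c(400, 1000)))
  ind <- track_from_intervals(el, g)
  e <- compute_element_profile(ind, el, flank = 1000, body_bins = 20,
                               flank_bins = 10, genome = g)
  expect_equal(e$body, rep(1, 20))
  expect_equal(e$flank5, rep(0, 10))
  expect_equal(e$flank3, rep(0, 10))

  ## linear-gradient coverage over two different lengths vs hand resampling
  grad <- function(s, w) GRanges("chr1", IRanges(s + seq_len(w) - 1, width = 1))
  w1 <- 40; w2 <- 100
  gsc <- c(seq_len(w1), seq_len(w2))
  tr <- track_from_intervals(c(grad(20000, w1), grad(50000, w2)), g,
                             score = gsc)
  el2 <- GRanges("chr1", IRanges(c(20000, 50000), width = c(w1, w2)))
  e2 <- compute_element_profile(tr, el2, flank = 100, body_bins = 10,
                                flank_bins = 10, genome = g)
  hand_one <- function(w) {
    x <- (seq_len(w) - 0.5) / w
    stats::approx(x, seq_len(w), xout = (seq_len(10) - 0.5) / 10, rule = 2)$y
  }
  expect_equal(e2$body, (hand_one(w1) + hand_one(w2)) / 2)
  expect_error(compute_element_profile(tr, el2[0], genome = g),
               "zero elements")
})

test_that("profile-shape clustering separates distinct families deterministically", {
  x <- seq(-3, 3, length.out = 61)
  narrow <- exp(-x^2 / 0.1)
  well <- 1 - exp(-x^2 / 0.5)
  set.seed(2)
  prof <- rbind(t(replicate(4, narrow + rnorm(61, 0, 0.01))),
                t(replicate(4, well + rnorm(61, 0, 0.01))))
  rownames(prof) <- sprintf("D%d", 1:8)
  cl <- cluster_profile_shapes(prof, cut_height = 1)
  expect_equal(unname(cl$labels), rep(c(1L, 2L), each = 4))
  ## duplicated profiles share a label; cut height 0 splits distinct profiles
  dup <- rbind(a = narrow, b = narrow, c = well)
  cld <- cluster_profile_shapes(dup, cut_height = 0.5)
  expect_equal(cld$labels[["a"]], cld$labels[["b"]])
  cl0 <- cluster_profile_shapes(rbind(a = narrow, b = well), cut_height = 0)
  expect_equal(unname(cl0$labels), c(1L, 2L))
  expect_error(cluster_profile_shapes(prof[1, , drop = FALSE]), "at least 2")
})
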