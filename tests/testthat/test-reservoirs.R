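mk_occ <- function(n_dbps, ids = names(n_dbps), biotype = NULL) {
  ## materialize a binary matrix with the requested row sums over 30 columns
  m <- t(vapply(n_dbps, function(k) {
    v <- integer(30)
    if (k > 0) v[seq_len(k)] <- 1L
    v
  }, integer(30)))
  dimnames(m) <- list(ids, sprintf("DBP%02d", 1:30))
  structure(list(m = m, n_dbps = setNames(rowSums(m), ids),
                 biotype = if (!is.null(biotype)) setNames(biotype, ids)),
            class = "OccupancyMatrix")
}

test_that("reservoir calling uses strict inequalities on both axes", {
  occ <- mk_occ(c(a = 8, b = 7, c = 20, d = 9))
  tpm <- c(a = 0, b = 0, c = 0.5, d = 0.0009)
  calls <- call_reservoirs(occ, tpm)
  expect_equal(calls$is_reservoir, c(TRUE, FALSE, FALSE, TRUE))
  ## exactly the off threshold is not a reservoir (strict <)
  expect_false(call_reservoirs(occ, c(a = 0.001, b = 0, c = 0, d = 0)
                               )$is_reservoir[1])
  expect_error(call_reservoirs(occ, tpm[1:2]), "missing")
})

test_that("count threshold default is fixed and valley mode finds the gap", {
  expect_equal(find_count_threshold(rpois(100, 3)), 7)
  set.seed(40)
  bim <- c(rnorm(400, 2, 1), rnorm(400, 40, 5))
  th <- find_count_threshold(bim, mode = "valley")
  expect_gt(th, 5)
  expect_lt(th, 35)
  uni <- rnorm(300, 10, 2)
  expect_warning(thu <- find_count_threshold(uni, mode = "valley", fixed = 7),
                 "not bimodal")
  expect_equal(thu, 7)
})

test_that("super-enhancer overlap flags match a nested-loop oracle", {
  prom <- toy_promoters(tss = seq(5000, 45000, by = 10000),
                        strand = rep("+", 5), flank = 1000)
  occ <- mk_occ(setNames(c(10, 10, 10, 2, 10), mcols(prom)$gene_id))
  calls <- call_reservoirs(occ, setNames(rep(0, 5), mcols(prom)$gene_id))
  se <- gr0(c("chr1", "chr1", "chr2"), c(4500, 30000, 1000),
            c(4700, 36000, 2000))
  calls <- flag_superenhancer_overlap(calls, prom, se)
  oracle <- vapply(seq_along(prom), function(g)
    any(as.character(seqnames(se)) == "chr1" &
          start(se) <= end(prom)[g] & start(prom)[g] <= end(se)), TRUE)
  expect_equal(calls$se_overlap, oracle)
  expect_equal(attr(calls, "n_se_reservoirs"),
               sum(oracle & calls$is_reservoir))
})

test_that("neighbor classification matches an exhaustive truth table", {
  flank <- 200
  offsets <- c(250, 999, 1000, 1001)
  ## independent truth function, written straight from the rules
  truth <- function(q_strand, nb) {
    near <- nb[abs(nb$off) <= 1000, , drop = FALSE]
    if (nrow(near) >= 2) return("multiple_nearby")
    if (nrow(near) == 0) return("none")
    upstream <- if (q_strand == "+") near$off < 0 else near$off > 0
    if (upstream && near$strand != q_strand) return("bidirectional")
    if (upstream && near$strand == q_strand) return("same_strand_nearby")
    "none"
  }
  pool <- expand.grid(off = c(offsets, -offsets), strand = c("+", "-"),
                      stringsAsFactors = FALSE)   # 16 candidate neighbors
  combos <- list(data.frame(off = numeric(), strand = character()))
  for (n_nb in 1:3) {
    sel <- utils::combn(nrow(pool), n_nb, simplify = FALSE)
    sel <- Filter(function(s) !anyDuplicated(pool$off[s]), sel)
    ## keep the full 1- and 2-neighbor enumerations; thin the 3-neighbor set
    if (n_nb == 3) sel <- sel[seq(1, length(sel), by = 7)]
    combos <- c(combos, lapply(sel, function(s) pool[s, , drop = FALSE]))
  }
  cases <- 0L
  for (q_strand in c("+", "-")) {
    for (nb in combos) {
      q_tss <- 50000
      tss <- c(q_tss, if (nrow(nb)) q_tss + nb$off)
      strands <- c(q_strand, if (nrow(nb)) nb$strand)
      prom <- toy_promoters(tss = tss, strand = strands, flank = flank,
                            chrom_len = 1e5)
      got <- classify_neighbor(prom, query = "g01", distance = 1000)
      expect_equal(unname(got), truth(q_strand, nb),
                   label = paste("strand", q_strand, "offs",
                                 paste(nb$off, collapse = ","), "strands",
                                 paste(nb$strand, collapse = ",")))
      cases <- cases + 1L
    }
  }
  expect_gt(cases, 200)
  ## isolated gene and the printed bidirectional example
  iso <- toy_promoters(tss = c(10000, 40000), strand = c("+", "+"),
                       flank = flank, chrom_len = 1e5)
  expect_equal(unname(classify_neighbor(iso, "g01")), "none")
  bid <- toy_promoters(tss = c(10000, 9500), strand = c("+", "-"),
                       flank = flank, chrom_len = 1e5)
  expect_equal(unname(classify_neighbor(bid, "g01")), "bidirectional")
  expect_error(classify_neighbor(iso, "nope"), "absent")
})

test_that("5-gene windows average the four flanking genes", {
  prom <- toy_promoters(tss = seq(10000, 50000, by = 10000),
                        strand = rep("+", 5), flank = 1000)
  ids <- mcols(prom)$gene_id
  occ <- mk_occ(setNames(c(2, 2, 10, 2, 2), ids))
  tpm <- setNames(c(1, 2, 3, 4, 5), ids)
  calls <- call_reservoirs(occ, setNames(c(1, 1, 0, 1, 1), ids))
  calls$se_overlap <- FALSE
  w <- window_neighborhood_expression(prom, tpm, calls, k = 5)
  ## only the middle gene has a full window: (1 + 2 + 4 + 5)/4 = 3
  expect_equal(nrow(w$records), 1L)
  expect_equal(w$records$window_mean, 3)
  ## constant input: all means equal, rank-sum p = 1
  prom9 <- toy_promoters(tss = seq(10000, 90000, by = 10000),
                         strand = rep("+", 9), flank = 1000)
  ids9 <- mcols(prom9)$gene_id
  occ9 <- mk_occ(setNames(c(2, 2, 10, 2, 2, 2, 2, 2, 2), ids9))
  calls9 <- call_reservoirs(occ9, setNames(c(1, 1, 0, 1, 1, 1, 1, 1, 1),
                                           ids9))
  calls9$se_overlap <- FALSE
  w9 <- window_neighborhood_expression(prom9, setNames(rep(1, 9), ids9),
                                       calls9, k = 5)
  expect_true(all(w9$records$window_mean == 1))
  expect_equal(w9$reservoir_test$p, 1)
  ## planted low-expression neighborhoods around reservoirs
  set.seed(44)
  n <- 80
  promn <- toy_promoters(tss = seq(5000, by = 8000, length.out = n),
                         strand = rep("+", n), flank = 1000,
                         chrom_len = 1e6)
  idsn <- mcols(promn)$gene_id
  res_centers <- seq(10, 70, by = 10)
  nd <- rep(2, n); nd[res_centers] <- 12
  tpmn <- setNames(runif(n, 40, 60), idsn)
  for (rc in res_centers) tpmn[rc + c(-2, -1, 1, 2)] <- runif(4, 0, 2)
  tt <- rep(1, n); tt[res_centers] <- 0
  callsn <- call_reservoirs(mk_occ(setNames(nd, idsn)), setNames(tt, idsn))
  callsn$se_overlap <- FALSE
  wn <- window_neighborhood_expression(promn, tpmn, callsn, k = 5)
  expect_lt(wn$reservoir_test$mean_in, wn$reservoir_test$mean_out)
  expect_lt(wn$reservoir_test$p, 0.05)
})

test_that("ghost/zombie split partitions reservoirs by nascent output", {
  occ <- mk_occ(c(a = 10, b = 12, c = 3))
  calls <- call_reservoirs(occ, c(a = 0, b = 0, c = 0))
  calls <- classify_ghost_zombie(calls, c(a = 0, b = 2, c = 0))
  expect_equal(calls$subclass, c("ghost", "zombie", "none"))
  ## partition: every reservoir is exactly one of ghost/zombie
  expect_true(all((calls$subclass != "none") == calls$is_reservoir))
  expect_error(classify_ghost_zombie(calls, c(a = 0)), "missing PRO-seq")
})

test_that("the conservative set needs silence in every RNA sample", {
  occ <- mk_occ(c(a = 10, b = 10, c = 10))
  calls <- call_reservoirs(occ, c(a = 0, b = 0, c = 0.5))
  wt <- rbind(a = c(0, 0, 0), b = c(0, 0.5, 0), c = c(0, 0, 0))
  colnames(wt) <- c("total_1", "polya_1", "polya_2")
  calls <- conservative_set(calls, wt)
  expect_equal(calls$conservative, c(TRUE, FALSE, FALSE))
  ## enumeration over mixed sample patterns
  pats <- expand.grid(s1 = c(0, 0.01), s2 = c(0, 0.01), s3 = c(0, 0.01))
  ids <- sprintf("p%d", seq_len(nrow(pats)))
  occ8 <- mk_occ(setNames(rep(10, nrow(pats)), ids))
  c8 <- call_reservoirs(occ8, setNames(rep(0, nrow(pats)), ids))
  m8 <- as.matrix(pats)
  rownames(m8) <- ids
  c8 <- conservative_set(c8, m8)
  expect_equal(c8$conservative, unname(rowSums(m8 >= 0.001) == 0))
})

test_that("neighbor expression status produces the textbook chi-squared", {
  ## 6 genes in 3 adjacent pairs: reservoirs paired with silent/expressed
  prom <- toy_promoters(tss = c(10000, 10800, 30000, 30800, 60000, 60800),
                        strand = rep("+", 6), flank = 300)
  ids <- mcols(prom)$gene_id
  occ <- mk_occ(setNames(c(10, 2, 10, 2, 2, 2), ids))
  tpm <- setNames(c(0, 5, 0, 0, 3, 3), ids)
  calls <- call_reservoirs(occ, tpm)
  ns <- neighbor_expression_status(calls, prom, tpm, distance = 1000)
  expect_equal(ns$fraction_reservoir, 0.5)    # g01 yes, g03 no
  expect_true(all(ns$table >= 0))
  ## all neighbors silent / all expressed edge cases
  tpm0 <- setNames(rep(0, 6), ids)
  calls0 <- call_reservoirs(occ, tpm0)
  expect_equal(neighbor_expression_status(calls0, prom, tpm0,
                                          distance = 1000)$fraction_reservoir,
               0)
})

test_that("chromatin marks associate with planted nascent differences", {
  prom <- toy_promoters(tss = seq(5000, by = 8000, length.out = 40),
                        strand = rep("+", 40), flank = 1000, chrom_len = 1e6)
  ids <- mcols(prom)$gene_id
  marked <- seq_len(20)
  mark <- granges(prom[marked])
  set.seed(50)
  tpm <- setNames(c(runif(20, 3.6, 4.4), runif(20, 0.9, 1.1)), ids)
  ca <- chromatin_association(prom, mark, tpm)
  expect_equal(ca$ratio, 4, tolerance = 0.15)
  expect_lt(ca$p, 1e-5)
  ## identical TPM everywhere -> ratio 1, p 1
  flat <- chromatin_association(prom, mark, setNames(rep(2, 40), ids))
  expect_equal(flat$ratio, 1)
  expect_equal(flat$p, 1)
  ## mark on every promoter -> NA with warning
  expect_warning(na <- chromatin_association(prom, granges(prom), tpm),
                 "empty")
  expect_true(is.na(na$ratio))
})

test_that("Pol II machinery flag follows the configured name list", {
  occ <- mk_occ(c(a = 10, b = 2))
  calls <- call_reservoirs(occ, c(a = 0, b = 1))
  calls <- flag_polII(calls, occ, c("DBP01", "DBP02"))
  expect_equal(calls$polII_bound, c(TRUE, TRUE))
  calls2 <- flag_polII(calls, occ, "DBP25")
  expect_equal(calls2$polII_bound, c(FALSE, FALSE))
})
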