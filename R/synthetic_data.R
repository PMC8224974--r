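#' Configuration for the synthetic-data generator
#'
#' The generator lays out a small genome on a regular grid of gene slots so
#' every planted property is recoverable exactly: each slot carries one gene
#' whose promoter window never touches a neighboring slot, and the planted
#' repeat family lives in the slot tails, away from every promoter.
#'
#' Defaults describe the study conditions the rest of the package is
#' validated under: 2 chromosomes x 10 Mb, 1,000 genes (30% lncRNA), 40 DBPs
#' x 2 replicates, a log-linear binding-to-expression relationship
#' (`log10(TPM + eps) = slope * n_dbps + Normal(0, sd)`), 50 planted
#' reservoirs (60% ghosts), and one planted repeat family (200 copies) bound
#' by a dedicated 3-DBP subset.
#'
#' @param seed Master seed; every randomized step derives its own substream
#'   from it via [derive_seed()].
#' @param n_chromosomes,chrom_length,n_genes,lnc_fraction Genome layout.
#' @param n_dbps,n_replicates,n_low_affinity DBP panel; the `n_low_affinity`
#'   lowest-affinity DBPs are never used for reservoir planting (they are the
#'   ones a reproducibility filter may drop).
#' @param peak_width_meanlog,peak_width_sdlog,peak_width_min,peak_width_max
#'   Log-normal peak width model (bp), clamped.
#' @param jitter_bp,dropout Replicate model: each replicate shifts each peak
#'   by uniform jitter up to `jitter_bp` and drops it with probability
#'   `dropout`.
#' @param bg_peaks_per_dbp Background peaks per DBP, scattered uniformly but
#'   kept clear of promoter windows.
#' @param expr_slope,expr_sd,rep_sd Expression model parameters; `rep_sd` is
#'   the per-replicate log10 jitter.
#' @param n_reservoirs,ghost_fraction Planted reservoirs and their ghost
#'   share.
#' @param repeat_family_copies,repeat_length,n_repeat_binders The planted
#'   repeat family and the size of its dedicated binder set.
#' @param n_superenhancers Super-enhancer intervals to plant.
#' @param n_total_rna,n_polya,n_proseq Samples per assay.
#' @param tpm_off Off threshold, also the pseudocount eps.
#' @param promoter_flank Promoter half-width (bp).
#' @return A validated list of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1, n_chromosomes = 2, chrom_length = 1e7,
                       n_genes = 1000, lnc_fraction = 0.3, n_dbps = 40,
                       n_replicates = 2, n_low_affinity = 8,
                       peak_width_meanlog = log(300), peak_width_sdlog = 0.4,
                       peak_width_min = 150, peak_width_max = 2500,
                       jitter_bp = 50, dropout = 0, bg_peaks_per_dbp = 300,
                       expr_slope = 0.1, expr_sd = 0.5, rep_sd = 0.05,
                       n_reservoirs = 50, ghost_fraction = 0.6,
                       repeat_family_copies = 200, repeat_length = 1500,
                       n_repeat_binders = 3, n_superenhancers = 20,
                       n_total_rna = 2, n_polya = 3, n_proseq = 2,
                       tpm_off = 0.001, promoter_flank = 3000) {
  cfg <- as.list(environment())
  stopifnot(lnc_fraction >= 0, lnc_fraction <= 1,
            ghost_fraction >= 0, ghost_fraction <= 1,
            dropout >= 0, dropout <= 1,
            n_reservoirs <= n_genes, n_repeat_binders <= n_dbps,
            n_low_affinity < n_dbps, n_replicates >= 2,
            peak_width_min > 2 * jitter_bp)
  slots <- ceiling(n_genes / n_chromosomes)
  cfg$slot_width <- floor(chrom_length / slots)
  if (cfg$slot_width < 19500)
    stop("genome too small for the requested number of genes ",
         "(need >= 19.5 kb per gene slot)", call. = FALSE)
  structure(cfg, class = "SimulationConfig")
}

#' Simulate the genome annotation and ground-truth manifest
#'
#' Lays out non-overlapping gene spans (one per slot, strand random, TSS at
#' the slot midpoint), assigns biotypes and the planted reservoir/ghost/
#' zombie classes (reservoirs over-sample lncRNA promoters 3:1, echoing
#' their real-data over-representation), draws each promoter's planted DBP
#' set from affinity-weighted sampling, places the planted repeat family in
#' slot tails away from all promoter windows plus three uniform background
#' families, and plants super-enhancer intervals (mostly on heavily bound
#' expressed promoters, a couple on reservoirs). Deterministic given the
#' seed.
#'
#' @param config A `SimulationConfig`.
#' @return List with `genome` (`GenomeAssembly`), `genes` (GRanges as
#'   [read_gtf_genes()] returns), `repeats` (GRanges as [read_repeats()]
#'   returns), `se` (GRanges), and `manifest` (list with `genes` and `dbps`
#'   data.frames plus the planted family name and binder set).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$n_genes
  sizes <- setNames(rep(config$chrom_length, config$n_chromosomes),
                    paste0("chr", seq_len(config$n_chromosomes)))
  genome <- genome_assembly(sizes)
  slots_per_chrom <- ceiling(n / config$n_chromosomes)
  sw <- config$slot_width
  chrom <- rep(names(sizes), each = slots_per_chrom)[seq_len(n)]
  slot <- (seq_len(n) - 1L) %% slots_per_chrom
  anchor <- slot * sw + floor(sw / 2)        # 1-based TSS position

  set.seed(derive_seed(config$seed, "annotation"))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_len <- 8000L
  span_start <- ifelse(strand == "+", anchor, anchor - gene_len + 1L)
  span_end <- ifelse(strand == "+", anchor + gene_len - 1L, anchor)
  ids <- sprintf("gene%04d", seq_len(n))
  biotype <- rep("mRNA", n)
  biotype[sample.int(n, round(config$lnc_fraction * n))] <- "lncRNA"

  ## planted classes: reservoirs over-sample lncRNA 3:1
  w <- ifelse(biotype == "lncRNA", 3, 1)
  res_idx <- sample.int(n, config$n_reservoirs, prob = w)
  n_ghost <- round(config$ghost_fraction * config$n_reservoirs)
  ghost_idx <- res_idx[seq_len(n_ghost)]
  class <- rep("normal", n)
  class[res_idx] <- "reservoir_zombie"
  class[ghost_idx] <- "reservoir_ghost"

  ## DBP panel: a low-affinity block and a well-separated high block
  dbps <- sprintf("DBP%02d", seq_len(config$n_dbps))
  affinity <- c(rep(0.3, config$n_low_affinity),
                seq(1, 3, length.out = config$n_dbps - config$n_low_affinity))
  binder_set <- dbps[seq(config$n_dbps - config$n_repeat_binders + 1L,
                         config$n_dbps)]
  high_pool <- seq(config$n_low_affinity + 1L, config$n_dbps)

  ## planted per-promoter binding-event counts: bimodal mixture
  planted_n <- integer(n)
  lowmode <- runif(n) < 0.55
  planted_n[lowmode] <- pmin(rpois(sum(lowmode), 3), 7L)
  planted_n[!lowmode] <- sample(8:30, sum(!lowmode), replace = TRUE)
  planted_n[res_idx] <- sample(12:25, config$n_reservoirs, replace = TRUE)
  planted_sets <- vector("list", n)
  for (g in seq_len(n)) {
    pool <- if (class[g] == "normal") seq_len(config$n_dbps) else high_pool
    k <- min(planted_n[g], length(pool))
    planted_n[g] <- k
    planted_sets[[g]] <- if (k > 0) sort(sample(pool, k, prob = affinity[pool]))
      else integer()
  }

  ## planted repeat family in slot tails (never touches a promoter window)
  fam_slots <- sort(sample.int(n, config$repeat_family_copies))
  fs <- (fam_slots - 1L) %% slots_per_chrom
  fchrom <- rep(names(sizes), each = slots_per_chrom)[fam_slots]
  fstart <- fs * sw + sw - 200L - config$repeat_length + 1L
  rep_fam <- GRanges(fchrom, IRanges(fstart, width = config$repeat_length),
                     strand = sample(c("+", "-"), length(fam_slots),
                                     replace = TRUE))
  mcols(rep_fam)$rep_name <- sprintf("SVA_sim_%03d", seq_along(rep_fam))
  mcols(rep_fam)$rep_class <- "Retroposon"
  mcols(rep_fam)$rep_family <- "SVA"
  bg_fams <- list(c("LINE", "L1"), c("SINE", "Alu"), c("SINE", "MIR"))
  bg <- lapply(bg_fams, function(f) {
    m <- 300L
    ch <- sample(names(sizes), m, replace = TRUE)
    st <- floor(runif(m) * (sizes[ch] - 300L)) + 1L
    gr <- GRanges(ch, IRanges(as.integer(st), width = 300L),
                  strand = sample(c("+", "-"), m, replace = TRUE))
    mcols(gr)$rep_name <- sprintf("%s_sim_%03d", f[2], seq_len(m))
    mcols(gr)$rep_class <- f[1]
    mcols(gr)$rep_family <- f[2]
    gr
  })
  repeats <- suppressWarnings(c(rep_fam, bg[[1]], bg[[2]], bg[[3]]))
  seqlevels(repeats) <- names(sizes)
  GenomeInfoDb::seqinfo(repeats) <- assembly_seqinfo(genome)

  ## super-enhancers: mostly on heavily bound expressed promoters, a couple
  ## on reservoirs (overlap is tested, not assumed away)
  n_se_res <- min(2L, config$n_superenhancers, config$n_reservoirs)
  hot <- setdiff(which(planted_n > 7 & class == "normal"), res_idx)
  se_centers <- c(res_idx[seq_len(n_se_res)],
                  sample(hot, min(config$n_superenhancers - n_se_res,
                                  length(hot))))
  se <- GRanges(chrom[se_centers],
                IRanges(pmax(1L, anchor[se_centers] - 4000L),
                        anchor[se_centers] + 3999L),
                seqinfo = assembly_seqinfo(genome))
  mcols(se)$name <- sprintf("SE_%03d", seq_along(se))

  genes <- GRanges(chrom, IRanges(span_start, span_end), strand = strand,
                   seqinfo = assembly_seqinfo(genome))
  mcols(genes)$gene_id <- ids
  mcols(genes)$biotype <- biotype
  mcols(genes)$tss <- as.integer(anchor)
  mcols(genes)$effective_length <- width(genes)

  manifest <- list(
    genes = data.frame(gene_id = ids, chrom = chrom, strand = strand,
                       tss = anchor, span_start = span_start,
                       span_end = span_end, biotype = biotype,
                       planted_class = class, planted_n_dbps = planted_n,
                       planted_dbps = vapply(planted_sets, function(s)
                         paste(dbps[s], collapse = ","), ""),
                       stringsAsFactors = FALSE),
    dbps = data.frame(dbp = dbps, affinity = affinity,
                      low_affinity = seq_len(config$n_dbps) <=
                        config$n_low_affinity,
                      repeat_binder = dbps %in% binder_set,
                      stringsAsFactors = FALSE),
    planted_sets = planted_sets, planted_family = "SVA",
    binder_set = binder_set, se_centers = ids[se_centers])
  list(genome = genome, genes = genes, repeats = repeats, se = se,
       manifest = manifest)
}

## clamped log-normal peak widths
draw_widths <- function(config, m) {
  w <- round(stats::rlnorm(m, config$peak_width_meanlog,
                           config$peak_width_sdlog))
  pmin(pmax(w, config$peak_width_min), config$peak_width_max)
}

#' Simulate replicate peak sets for every DBP
#'
#' Each promoter receives one peak from every DBP in its planted set,
#' centered within 1 kb of the TSS (so the peak always stays inside the
#' promoter window, jitter included); DBPs in the planted-family binder set
#' additionally get one peak inside every family copy; background peaks are
#' scattered uniformly away from promoter windows. Replicates are the
#' planted peaks shifted independently by uniform jitter and thinned by the
#' dropout probability.
#'
#' @param config A `SimulationConfig`.
#' @param ann Result of [simulate_annotation()].
#' @return List with `replicates` (per DBP: list of per-replicate GRanges)
#'   and `planted` (per DBP: the unjittered GRanges).
#' @export
simulate_peaksets <- function(config, ann) {
  genome <- ann$genome
  dbps <- ann$manifest$dbps$dbp
  anchor <- ann$manifest$genes$tss
  chrom <- ann$manifest$genes$chrom
  windows <- extract_promoters(ann$genes, flank = config$promoter_flank,
                               genome = genome)
  fam <- ann$repeats[mcols(ann$repeats)$rep_family == ann$manifest$planted_family]
  planted <- replicates <- setNames(vector("list", length(dbps)), dbps)
  for (d in seq_along(dbps)) {
    set.seed(derive_seed(config$seed, "peaks", dbps[d]))
    gidx <- which(vapply(ann$manifest$planted_sets, function(s) d %in% s, TRUE))
    centers <- anchor[gidx] + round(runif(length(gidx), -1000, 1000))
    w <- draw_widths(config, length(gidx))
    prom_peaks <- GRanges(chrom[gidx],
                          IRanges(centers - floor(w / 2), width = w))
    fam_peaks <- GRanges()
    if (ann$manifest$dbps$repeat_binder[d] && length(fam))
      fam_peaks <- GRanges(seqnames(fam),
                           IRanges(start(fam) + 100L, end(fam) - 100L))
    ## background: uniform, rejected out of promoter windows
    bg <- GRanges()
    need <- config$bg_peaks_per_dbp
    while (need > 0) {
      m <- need * 2L
      ch <- sample(names(genome$sizes), m, replace = TRUE)
      bw <- draw_widths(config, m)
      st <- floor(runif(m) * (genome$sizes[ch] - bw - 2 * config$jitter_bp)) +
        config$jitter_bp + 1L
      cand <- GRanges(ch, IRanges(as.integer(st), width = bw))
      cand <- cand[!overlapsAny(cand, windows, maxgap = config$jitter_bp,
                                ignore.strand = TRUE)]
      take <- min(length(cand), need)
      bg <- suppressWarnings(c(bg, cand[seq_len(take)]))
      need <- need - take
    }
    pk <- suppressWarnings(c(prom_peaks, fam_peaks, bg))
    seqlevels(pk) <- names(genome$sizes)
    GenomeInfoDb::seqinfo(pk) <- assembly_seqinfo(genome)
    planted[[d]] <- pk
    reps <- vector("list", config$n_replicates)
    for (r in seq_len(config$n_replicates)) {
      shift_by <- round(runif(length(pk), -config$jitter_bp, config$jitter_bp))
      keep <- runif(length(pk)) >= config$dropout
      gr <- GenomicRanges::shift(pk[keep], shift_by[keep])
      mcols(gr)$dbp <- dbps[d]
      mcols(gr)$replicate <- r
      mcols(gr)$score <- round(runif(sum(keep), 5, 50), 2)
      reps[[r]] <- sort(gr)
    }
    replicates[[d]] <- reps
  }
  list(replicates = replicates, planted = planted)
}

#' Simulate expression counts and read intervals
#'
#' Normal genes follow the planted log-linear model
#' `log10(TPM + eps) = slope * n_dbps + Normal(0, sd)` (with `TPM` clamped
#' to at least 0.01 for non-reservoir genes above the binding threshold, the
#' planting margin that keeps reservoir recovery unambiguous); reservoirs
#' get zero steady-state RNA in every total and polyA sample; zombies get
#' strong nascent (PRO-seq) signal over the promoter window while ghosts get
#' none. Counts are scaled so every planted expression level survives
#' rounding; read intervals are placed in the 1.5 kb downstream of the TSS
#' so window quantification sees them.
#'
#' @param config A `SimulationConfig`.
#' @param ann Result of [simulate_annotation()].
#' @return List with `counts_total`, `counts_polya` (genes x samples),
#'   `gene_lengths`, `reads` (named list of GRanges: `total_rna_*`,
#'   `polya_rna_*`, `pro_seq_*`), `assay` (tags for the read samples), and
#'   `target_tpm` (the planted per-gene expression level, pre-normalization).
#' @export
simulate_expression <- function(config, ann) {
  g <- ann$manifest$genes
  n <- nrow(g)
  set.seed(derive_seed(config$seed, "expression"))
  eps <- config$tpm_off
  t0 <- 10^(config$expr_slope * g$planted_n_dbps +
              rnorm(n, 0, config$expr_sd)) - eps
  t0 <- pmax(t0, 0)
  margin <- g$planted_class == "normal" & g$planted_n_dbps > 7
  t0[margin] <- pmax(t0[margin], 0.01)
  is_res <- g$planted_class != "normal"
  t0[is_res] <- 0

  rep_tpm <- function(tag, k) {
    m <- vapply(seq_len(k), function(i)
      t0 * 10^rnorm(n, 0, config$rep_sd), numeric(n))
    m[is_res, ] <- 0
    colnames(m) <- paste0(tag, "_", seq_len(k))
    rownames(m) <- g$gene_id
    m
  }
  t_total <- rep_tpm("total_rna", config$n_total_rna)
  t_polya <- rep_tpm("polya_rna", config$n_polya)
  L_kb <- (g$span_end - g$span_start + 1) / 1000
  counts_total <- round(t_total * L_kb * 100)
  counts_polya <- round(t_polya * L_kb * 100)

  make_reads <- function(level) {
    nr <- round(level * 3)
    idx <- rep.int(seq_len(n), nr)
    if (!length(idx)) return(GRanges(seqinfo = assembly_seqinfo(ann$genome)))
    off <- round(runif(length(idx), 0, 1500))
    st <- ifelse(g$strand[idx] == "+", g$tss[idx] + off,
                 g$tss[idx] - off - 99L)
    GRanges(g$chrom[idx], IRanges(as.integer(st), width = 100L),
            seqinfo = assembly_seqinfo(ann$genome))
  }
  reads <- list()
  assay <- character()
  for (i in seq_len(config$n_total_rna)) {
    reads[[paste0("total_rna_", i)]] <- make_reads(t_total[, i])
    assay[paste0("total_rna_", i)] <- "total_rna"
  }
  for (i in seq_len(config$n_polya)) {
    reads[[paste0("polya_rna_", i)]] <- make_reads(t_polya[, i])
    assay[paste0("polya_rna_", i)] <- "polya_rna"
  }
  pro_level <- t0
  pro_level[g$planted_class == "reservoir_zombie"] <- 35
  pro_level[g$planted_class == "reservoir_ghost"] <- 0
  for (i in seq_len(config$n_proseq)) {
    lv <- pro_level * 10^rnorm(n, 0, config$rep_sd)
    lv[g$planted_class == "reservoir_ghost"] <- 0
    lv[g$planted_class == "reservoir_zombie"] <-
      pmax(lv[g$planted_class == "reservoir_zombie"], 10 * eps)
    reads[[paste0("pro_seq_", i)]] <- make_reads(lv)
    assay[paste0("pro_seq_", i)] <- "pro_seq"
  }
  list(counts_total = counts_total, counts_polya = counts_polya,
       gene_lengths = setNames(g$span_end - g$span_start + 1, g$gene_id),
       reads = reads, assay = assay,
       target_tpm = setNames(t0, g$gene_id))
}

#' Simulate coverage tracks consistent with the planted data
#'
#' Per-DBP tracks are the pileup of the DBP's planted peaks (so coverage is
#' at least 1 under every planted peak). An H3K4me1-like track is 5'-skewed
#' over the planted repeat family (value 3 on the 5' 30% of each element, 1
#' on the rest); an H3K27ac-like track marks promoter windows of expressed
#' genes and an H3K27me3-like track marks silent ones.
#'
#' @param config A `SimulationConfig`.
#' @param ann Result of [simulate_annotation()].
#' @param peaks Result of [simulate_peaksets()].
#' @param expr Result of [simulate_expression()].
#' @return Named list of coverage tracks (RleList): one per DBP plus
#'   `H3K4me1`, `H3K27ac`, `H3K27me3`.
#' @export
simulate_coverage <- function(config, ann, peaks, expr) {
  genome <- ann$genome
  tracks <- lapply(peaks$planted, function(gr)
    track_from_intervals(gr, genome))
  fam <- ann$repeats[mcols(ann$repeats)$rep_family == ann$manifest$planted_family]
  minus <- as.character(strand(fam)) == "-"
  head_len <- pmax(1L, round(width(fam) * 0.3))
  head5 <- GRanges(seqnames(fam),
                   IRanges(ifelse(minus, end(fam) - head_len + 1L, start(fam)),
                           width = head_len))
  parts <- suppressWarnings(c(granges(fam), head5, head5))
  tracks$H3K4me1 <- track_from_intervals(parts, genome)
  windows <- extract_promoters(ann$genes, flank = config$promoter_flank,
                               genome = genome)
  tpm <- expr$target_tpm[mcols(windows)$gene_id]
  tracks$H3K27ac <- track_from_intervals(granges(windows[tpm >= 0.137]), genome)
  tracks$H3K27me3 <- track_from_intervals(granges(windows[tpm < config$tpm_off]),
                                          genome)
  tracks
}

#' Write a complete synthetic dataset to disk
#'
#' Emits exactly the formats the pipeline reads: `chrom.sizes`, a GTF with
#' gene and exon records, an rmsk-style repeat table, per-DBP per-replicate
#' broadPeak files, per-sample read BEDs, counts TSVs, bedGraph coverage
#' tracks, a super-enhancer BED and the ground-truth manifest TSVs.
#' Byte-identical for a given config.
#'
#' @param config A `SimulationConfig`.
#' @param dir Output directory (created).
#' @param coverage Also write bedGraph tracks (default TRUE; they are the
#'   bulkiest outputs).
#' @return Invisibly, a list with the in-memory objects (`ann`, `peaks`,
#'   `expr`, `tracks`) and `dir`.
#' @export
write_synthetic_dataset <- function(config, dir, coverage = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(config)
  peaks <- simulate_peaksets(config, ann)
  expr <- simulate_expression(config, ann)

  write.table(data.frame(names(ann$genome$sizes),
                         format(ann$genome$sizes, scientific = FALSE,
                                trim = TRUE)),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  g <- ann$manifest$genes
  gt <- ifelse(g$biotype == "mRNA", "protein_coding", "lncRNA")
  attr_str <- sprintf('gene_id "%s"; gene_type "%s";', g$gene_id, gt)
  gene_lines <- sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        g$chrom, g$span_start, g$span_end, g$strand, attr_str)
  len <- g$span_end - g$span_start + 1L
  e1e <- g$span_start + floor(len * 0.4) - 1L
  e2s <- g$span_end - floor(len * 0.3) + 1L
  exon_lines <- c(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                          g$chrom, g$span_start, e1e, g$strand, attr_str),
                  sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                          g$chrom, e2s, g$span_end, g$strand, attr_str))
  writeLines(c(gene_lines, exon_lines), file.path(dir, "genes.gtf"))

  rmsk <- data.frame(genoName = as.character(seqnames(ann$repeats)),
                     genoStart = start(ann$repeats) - 1L,
                     genoEnd = end(ann$repeats),
                     strand = as.character(strand(ann$repeats)),
                     repName = mcols(ann$repeats)$rep_name,
                     repClass = mcols(ann$repeats)$rep_class,
                     repFamily = mcols(ann$repeats)$rep_family)
  write.table(rmsk, file.path(dir, "rmsk.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  for (d in names(peaks$replicates))
    for (r in seq_along(peaks$replicates[[d]])) {
      gr <- peaks$replicates[[d]][[r]]
      df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                       ".", 0L, ".", mcols(gr)$score, -1L, -1L)
      write.table(df, file.path(dir, "peaks",
                                sprintf("%s_rep%d.broadPeak", d, r)),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }

  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  for (s in names(expr$reads))
    write_bed(expr$reads[[s]], file.path(dir, "reads", paste0(s, ".bed")))

  for (tab in c("counts_total", "counts_polya")) {
    df <- data.frame(gene_id = rownames(expr[[tab]]),
                     length = expr$gene_lengths[rownames(expr[[tab]])],
                     expr[[tab]], check.names = FALSE)
    write.table(df, file.path(dir, paste0(tab, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  write_bed(ann$se, file.path(dir, "superenhancers.bed"))
  write.table(ann$manifest$genes, file.path(dir, "manifest_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ann$manifest$dbps, file.path(dir, "manifest_dbps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  tracks <- NULL
  if (coverage) {
    tracks <- simulate_coverage(config, ann, peaks, expr)
    dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
    for (nm in names(tracks))
      write_track_bedgraph(tracks[[nm]],
                           file.path(dir, "coverage", paste0(nm, ".bedGraph")))
  }
  invisible(list(ann = ann, peaks = peaks, expr = expr, tracks = tracks,
                 dir = dir))
}

#' Write a coverage track as bedGraph (non-zero runs only)
#' @param track RleList.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  rows <- list()
  for (ch in names(track)) {
    r <- track[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    val <- S4Vectors::runValue(r)
    nz <- val != 0
    if (any(nz))
      rows[[ch]] <- data.frame(ch, starts[nz] - 1L, ends[nz], val[nz])
  }
  if (!length(rows)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
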