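#' Analysis thresholds
#'
#' Central, validated container for every tunable cutoff in the pipeline.
#' Unknown names error rather than warn: silent misconfiguration is the main
#' reproducibility hazard in a multi-stage analysis.
#'
#' @param promoter_flank Promoter half-width, bp.
#' @param element_flank Flank around repeat elements for scaled profiles, bp.
#' @param tts_flank TTS half-width for peak feature annotation, bp.
#' @param min_consensus_peaks Minimum consensus peaks per DBP.
#' @param peak_percentile Percentile floor for the peak-count filter.
#' @param n_permutations Permutations per enrichment test.
#' @param expression_bin_edges Off/low, low/medium, medium/high TPM edges.
#' @param reservoir_min_dbps Binding-event threshold (strict >).
#' @param reservoir_tpm Steady-state off threshold, TPM (strict <).
#' @param ghost_proseq_tpm Nascent off threshold, TPM (strict <).
#' @param neighbor_distance TSS-to-TSS neighbor distance, bp.
#' @param window_genes Genes per neighborhood window (odd).
#' @param dbp_bias_p,dbp_bias_fold Thresholds for reservoir DBP bias.
#' @param profile_cut_height Dendrogram cut for profile-shape clusters.
#' @param polII_dbps DBP names counted as Pol II machinery.
#' @param seed Master seed for all randomized stages.
#' @return A validated list of class `AnalysisThresholds`.
#' @export
analysis_thresholds <- function(promoter_flank = 3000, element_flank = 5000,
                                tts_flank = 1000, min_consensus_peaks = 250,
                                peak_percentile = 15, n_permutations = 1000,
                                expression_bin_edges = c(0.001, 0.137, 3),
                                reservoir_min_dbps = 7, reservoir_tpm = 0.001,
                                ghost_proseq_tpm = 0.001,
                                neighbor_distance = 1000, window_genes = 5,
                                dbp_bias_p = 0.001, dbp_bias_fold = 2,
                                profile_cut_height = 65,
                                polII_dbps = character(), seed = 1) {
  th <- as.list(environment())
  num <- th[!(names(th) %in% "polII_dbps")]
  if (any(!vapply(num, is.numeric, TRUE)))
    stop("all thresholds except polII_dbps must be numeric", call. = FALSE)
  if (any(unlist(num) < 0))
    stop("thresholds must be non-negative", call. = FALSE)
  stopifnot(length(th$expression_bin_edges) == 3,
            all(diff(th$expression_bin_edges) > 0),
            th$window_genes %% 2 == 1)
  structure(th, class = "AnalysisThresholds")
}

#' Update thresholds from a named list, rejecting unknown keys
#' @param overrides Named list.
#' @return An `AnalysisThresholds`.
#' @keywords internal
thresholds_from_list <- function(overrides) {
  allowed <- names(formals(analysis_thresholds))
  unknown <- setdiff(names(overrides), allowed)
  if (length(unknown))
    stop("unknown threshold key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_thresholds, overrides)
}

#' Read a pipeline configuration file (YAML)
#'
#' Recognised top-level keys: `input_dir`, `outdir`, `stages`, `thresholds`
#' (validated against [analysis_thresholds()]); anything else errors.
#'
#' @param path YAML file.
#' @return List with `input_dir`, `outdir`, `stages`, `thresholds`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("input_dir", "outdir", "stages", "thresholds")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg$thresholds <- thresholds_from_list(as.list(cfg$thresholds))
  cfg
}

#' Run the promoter-occupancy pipeline on a dataset directory
#'
#' Expects the directory layout [write_synthetic_dataset()] emits (the same
#' formats any upstream peak-calling produces): `chrom.sizes`, `genes.gtf`,
#' `rmsk.tsv`, `peaks/<dbp>_rep<k>.broadPeak`, `reads/<sample>.bed`,
#' `counts_total.tsv`, `counts_polya.tsv`, `superenhancers.bed` and
#' optionally `coverage/*.bedGraph`. Stages run in dependency order;
#' identical inputs and seed give byte-identical outputs.
#'
#' @param input_dir Dataset directory.
#' @param outdir Output directory (created).
#' @param thresholds An [analysis_thresholds()] object.
#' @param stages Character subset of
#'   `c("consensus", "occupancy", "enrich", "profile", "expression",
#'   "reservoirs", "report")`; dependencies of requested stages are added
#'   automatically.
#' @param seed Optional master-seed override.
#' @return Invisibly, a list of the in-memory stage results (including
#'   `master`, the per-promoter summary data.frame).
#' @export
run_pipeline <- function(input_dir, outdir,
                         thresholds = analysis_thresholds(),
                         stages = c("consensus", "occupancy", "enrich",
                                    "profile", "expression", "reservoirs",
                                    "report"),
                         seed = NULL) {
  t0 <- Sys.time()
  all_stages <- c("consensus", "occupancy", "enrich", "profile",
                  "expression", "reservoirs", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  deps <- list(occupancy = "consensus", enrich = "consensus",
               profile = "consensus",
               reservoirs = c("consensus", "occupancy", "expression"),
               report = c("consensus", "occupancy", "expression",
                          "reservoirs"))
  repeat {
    need <- unique(unlist(deps[stages]))
    if (all(need %in% stages)) break
    stages <- union(stages, need)
  }
  stages <- intersect(all_stages, stages)
  if (!is.null(seed)) thresholds$seed <- seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  req <- function(p) {
    if (!file.exists(p)) stop("missing input: ", p, call. = FALSE)
    p
  }
  genome <- read_genome(req(file.path(input_dir, "chrom.sizes")))
  genes <- read_gtf_genes(req(file.path(input_dir, "genes.gtf")), genome)
  exons <- read_gtf_exons(file.path(input_dir, "genes.gtf"))
  promoters <- extract_promoters(genes, flank = thresholds$promoter_flank,
                                 genome = genome)
  out <- list(genome = genome, genes = genes, promoters = promoters,
              thresholds = thresholds)
  timings <- list(io = as.numeric(Sys.time() - t0, units = "secs"))

  manifest_path <- file.path(outdir, "run_manifest.yaml")
  inputs <- list.files(input_dir, recursive = TRUE, full.names = TRUE)
  yaml::write_yaml(list(
    package_version = as.character(utils::packageVersion("reservoiR")),
    seed = thresholds$seed, stages = stages,
    thresholds = unclass(thresholds),
    input_md5 = as.list(tools::md5sum(inputs))), manifest_path)

  if ("consensus" %in% stages) {
    t1 <- Sys.time()
    peak_files <- list.files(file.path(input_dir, "peaks"),
                             pattern = "_rep[0-9]+\\.(broadPeak|bed)$",
                             full.names = TRUE)
    if (!length(peak_files)) stop("missing input: peaks/", call. = FALSE)
    info <- regmatches(basename(peak_files),
                       regexec("^(.*)_rep([0-9]+)\\.", basename(peak_files)))
    dbp <- vapply(info, `[`, "", 2)
    repl <- as.integer(vapply(info, `[`, "", 3))
    sets <- lapply(split(seq_along(peak_files), dbp), function(i) {
      i <- i[order(repl[i])]
      reps <- lapply(i, function(j)
        filter_canonical(read_peaks(peak_files[j], dbp[j], repl[j], genome),
                         genome))
      build_consensus(reps, dbp = dbp[i[1]])
    })
    filt <- filter_by_min_peaks(sets,
                                min_peaks = thresholds$min_consensus_peaks,
                                percentile = thresholds$peak_percentile)
    dir.create(file.path(outdir, "consensus"), showWarnings = FALSE)
    for (s in filt$kept)
      write_bed(s$peaks, file.path(outdir, "consensus",
                                   paste0(s$dbp, "_consensus.bed")))
    write.table(filt$report, file.path(outdir, "dbp_filter_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$consensus <- filt$kept
    out$filter_report <- filt$report
    timings$consensus <- as.numeric(Sys.time() - t1, units = "secs")
  }

  if ("occupancy" %in% stages) {
    t1 <- Sys.time()
    occ <- build_occupancy_matrix(out$consensus, promoters)
    write_occupancy_tsv(occ, file.path(outdir, "occupancy.tsv"))
    n_peaks <- vapply(out$consensus, function(s) s$n_peaks, 1L)
    n_prom <- vapply(out$consensus, function(s)
      count_feature_overlaps(s, promoters), 1L)
    out$occupancy <- occ
    out$promoter_regression <- fit_peaknum_regression(n_peaks, n_prom)
    out$feature_annotation <- annotate_peak_features(
      out$consensus, genes, promoter_flank = thresholds$promoter_flank,
      tts_flank = thresholds$tts_flank, exons = exons)
    timings$occupancy <- as.numeric(Sys.time() - t1, units = "secs")
  }

  if ("enrich" %in% stages) {
    t1 <- Sys.time()
    repeats <- read_repeats(req(file.path(input_dir, "rmsk.tsv")), genome)
    prom_res <- lapply(out$consensus, permutation_enrichment,
                       features = promoters, genome = genome,
                       n_perm = thresholds$n_permutations,
                       seed = thresholds$seed, feature_set = "promoters")
    write_enrichment_tsv(prom_res,
                         file.path(outdir, "promoter_enrichment.tsv"))
    fam <- repeat_enrichment_matrix(out$consensus, repeats, genome,
                                    by = "family",
                                    n_perm = thresholds$n_permutations,
                                    seed = thresholds$seed)
    cls <- repeat_enrichment_matrix(out$consensus, repeats, genome,
                                    by = "class",
                                    n_perm = thresholds$n_permutations,
                                    seed = thresholds$seed)
    write.table(data.frame(dbp = rownames(fam$z), fam$z, check.names = FALSE),
                file.path(outdir, "repeat_family_z.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(dbp = rownames(cls$z), cls$z, check.names = FALSE),
                file.path(outdir, "repeat_class_z.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$promoter_enrichment <- prom_res
    out$repeat_family <- fam
    out$repeat_class <- cls
    out$repeats <- repeats
    timings$enrich <- as.numeric(Sys.time() - t1, units = "secs")
  }

  if ("profile" %in% stages) {
    t1 <- Sys.time()
    cov_files <- list.files(file.path(input_dir, "coverage"),
                            pattern = "\\.bedGraph$", full.names = TRUE)
    if (length(cov_files)) {
      dbp_names <- vapply(out$consensus, function(s) s$dbp, "")
      use <- cov_files[sub("\\.bedGraph$", "", basename(cov_files)) %in%
                         dbp_names]
      profs <- lapply(use, function(f)
        compute_tss_profile(read_bedgraph(f, genome), promoters,
                            flank = thresholds$promoter_flank,
                            genome = genome))
      names(profs) <- sub("\\.bedGraph$", "", basename(use))
      pm <- do.call(rbind, lapply(profs, `[[`, "mean"))
      write.table(data.frame(dbp = rownames(pm), pm, check.names = FALSE),
                  file.path(outdir, "tss_profiles.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      out$tss_profiles <- profs
      if (nrow(pm) >= 2) {
        cl <- cluster_profile_shapes(pm,
                                     cut_height = thresholds$profile_cut_height)
        write.table(data.frame(dbp = names(cl$labels), cluster = cl$labels),
                    file.path(outdir, "profile_clusters.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        out$profile_clusters <- cl
      }
    }
    timings$profile <- as.numeric(Sys.time() - t1, units = "secs")
  }

  if ("expression" %in% stages) {
    t1 <- Sys.time()
    read_counts <- function(p) {
      tab <- read.table(req(p), header = TRUE, sep = "\t", check.names = FALSE)
      m <- as.matrix(tab[, -(1:2), drop = FALSE])
      rownames(m) <- tab[[1]]
      list(counts = m, lengths = setNames(tab[[2]], tab[[1]]))
    }
    ct <- read_counts(file.path(input_dir, "counts_total.tsv"))
    cp <- read_counts(file.path(input_dir, "counts_polya.tsv"))
    expr <- tpm_from_counts(cbind(ct$counts, cp$counts), ct$lengths,
                            assay = c(rep("total_rna", ncol(ct$counts)),
                                      rep("polya_rna", ncol(cp$counts))))
    read_files <- list.files(file.path(input_dir, "reads"),
                             pattern = "\\.bed$", full.names = TRUE)
    reads <- lapply(read_files, function(f) {
      tab <- read.table(f, header = FALSE, sep = "\t")
      granges_from_bed0(as.character(tab[[1]]), tab[[2]], tab[[3]],
                        genome = genome)
    })
    names(reads) <- sub("\\.bed$", "", basename(read_files))
    wq <- quantify_window(reads, promoters)
    wtpm <- tpm_from_counts(wq$counts + 0, wq$lengths,
                            assay = sub("_[0-9]+$", "", names(reads)))
    ## windows with zero reads in a sample are legitimate; guard the
    ## all-zero-sample error only for truly empty samples
    out$expression <- expr
    out$window_tpm <- wtpm
    out$tpm_total <- average_assay_tpm(expr, "total_rna")
    out$proseq_window <- average_assay_tpm(wtpm, "pro_seq")
    timings$expression <- as.numeric(Sys.time() - t1, units = "secs")
  }

  if ("reservoirs" %in% stages) {
    t1 <- Sys.time()
    se <- {
      p <- file.path(input_dir, "superenhancers.bed")
      if (file.exists(p)) {
        tab <- read.table(p, header = FALSE, sep = "\t")
        granges_from_bed0(as.character(tab[[1]]), tab[[2]], tab[[3]],
                          genome = genome)
      } else GRanges()
    }
    calls <- call_reservoirs(out$occupancy, out$tpm_total,
                             min_dbps = thresholds$reservoir_min_dbps,
                             tpm_off = thresholds$reservoir_tpm)
    calls <- flag_superenhancer_overlap(calls, promoters, se)
    calls$neighbor_class <- unname(
      classify_neighbor(promoters, distance = thresholds$neighbor_distance)[
        calls$gene_id])
    calls <- classify_ghost_zombie(calls, out$proseq_window,
                                   ghost_tpm = thresholds$ghost_proseq_tpm)
    rna_cols <- names(out$window_tpm$assay)[
      out$window_tpm$assay %in% c("total_rna", "polya_rna")]
    calls <- conservative_set(calls,
                              out$window_tpm$tpm[, rna_cols, drop = FALSE],
                              tpm_off = thresholds$reservoir_tpm)
    calls <- flag_polII(calls, out$occupancy, thresholds$polII_dbps)
    out$reservoir_calls <- calls
    out$window_expression <- window_neighborhood_expression(
      promoters, out$tpm_total, calls, k = thresholds$window_genes)
    out$dbp_bias <- reservoir_dbp_bias(
      out$occupancy, setNames(calls$is_reservoir, calls$gene_id),
      p_threshold = thresholds$dbp_bias_p, fold = thresholds$dbp_bias_fold)
    n_lnc <- sum(out$occupancy$biotype == "lncRNA")
    out$lnc_overrepresentation_p <- hypergeometric_overrepresentation(
      k = sum(calls$is_reservoir & calls$biotype == "lncRNA"),
      K = n_lnc, n = sum(calls$is_reservoir), N = nrow(calls))
    timings$reservoirs <- as.numeric(Sys.time() - t1, units = "secs")
  }

  if ("report" %in% stages) {
    t1 <- Sys.time()
    calls <- out$reservoir_calls
    idx <- match(calls$gene_id, mcols(promoters)$gene_id)
    master <- data.frame(
      gene_id = calls$gene_id,
      chrom = as.character(seqnames(promoters))[idx],
      tss = mcols(promoters)$tss[idx],
      strand = as.character(strand(promoters))[idx],
      biotype = calls$biotype,
      n_dbps = calls$n_dbps,
      tpm_total = calls$tpm_total,
      tpm_proseq_window = calls$tpm_proseq_window,
      expression_bin = as.character(
        classify_expression_bin(calls$tpm_total,
                                edges = thresholds$expression_bin_edges)),
      is_reservoir = calls$is_reservoir,
      subclass = calls$subclass,
      neighbor_class = calls$neighbor_class,
      se_overlap = calls$se_overlap,
      conservative = calls$conservative,
      polII_bound = calls$polII_bound,
      stringsAsFactors = FALSE)
    wm <- out$window_expression$records
    master$window_mean_tpm <- wm$window_mean[match(master$gene_id,
                                                   wm$gene_id)]
    write.table(master, file.path(outdir, "master_promoters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$master <- master
    timings$report <- as.numeric(Sys.time() - t1, units = "secs")
  }

  man <- yaml::read_yaml(manifest_path)
  man$timings_sec <- lapply(timings, function(x) round(x, 3))
  man$total_sec <- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  yaml::write_yaml(man, manifest_path)
  invisible(out)
}
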