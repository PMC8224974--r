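#' @import GenomicRanges IRanges S4Vectors
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlevels "seqlevels<-"
#'   seqlengths "seqinfo<-" seqinfo
#' @importFrom stats approx chisq.test cor cor.test cutree density dist fisher.test
#'   hclust lm phyper quantile rnorm runif rpois sd setNames var wilcox.test
#' @importFrom utils read.table write.table
#' @importFrom methods is as
NULL

#' Default canonical chromosome names
#'
#' The canonical human set (chr1-chr22, chrX, chrY). Assemblies restrict this
#' to the chromosomes they actually contain.
#' @keywords internal
default_canonical <- function() c(paste0("chr", 1:22), "chrX", "chrY")

#' Read a chrom.sizes file into a genome assembly
#'
#' A genome assembly is the ordered set of chromosome names and lengths the
#' whole pipeline validates coordinates against, plus a "canonical" subset
#' (autosomes and sex chromosomes by default) used to filter peaks away from
#' unplaced scaffolds.
#'
#' @param path Two-column whitespace-delimited text file: chromosome name,
#'   length in bp.
#' @param canonical Character vector of canonical chromosome names, or `NULL`
#'   to use the default human set intersected with the names present (falling
#'   back to all names when the intersection is empty).
#' @return An object of class `GenomeAssembly`: a list with `sizes` (named
#'   numeric vector) and `canonical` (character vector).
#' @export
read_genome <- function(path, canonical = NULL) {
  tab <- tryCatch(
    read.table(path, header = FALSE, col.names = c("chrom", "size"),
               colClasses = c("character", "numeric")),
    error = function(e) stop("cannot parse chrom.sizes file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0L) stop("empty chrom.sizes file: ", path, call. = FALSE)
  genome_assembly(setNames(tab$size, tab$chrom), canonical = canonical)
}

#' Construct a genome assembly from a named length vector
#'
#' @param sizes Named numeric vector of chromosome lengths (bp).
#' @param canonical Canonical subset of names; `NULL` for the default rule
#'   (see [read_genome()]).
#' @return A `GenomeAssembly` object.
#' @export
genome_assembly <- function(sizes, canonical = NULL) {
  if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
    stop("chromosome sizes must be named", call. = FALSE)
  if (anyDuplicated(names(sizes)))
    stop("duplicate chromosome name(s): ",
         paste(unique(names(sizes)[duplicated(names(sizes))]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  if (is.null(canonical)) {
    canonical <- intersect(default_canonical(), names(sizes))
    if (length(canonical) == 0L) canonical <- names(sizes)
  } else {
    if (!all(canonical %in% names(sizes)))
      stop("canonical set contains unknown chromosome(s): ",
           paste(setdiff(canonical, names(sizes)), collapse = ", "),
           call. = FALSE)
  }
  structure(list(sizes = sizes, canonical = canonical),
            class = "GenomeAssembly")
}

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat("GenomeAssembly:", length(x$sizes), "chromosomes,",
      format(sum(x$sizes), big.mark = ","), "bp total;",
      length(x$canonical), "canonical\n")
  invisible(x)
}

#' Seqinfo view of a genome assembly
#' @param genome A `GenomeAssembly`.
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @keywords internal
assembly_seqinfo <- function(genome) {
  Seqinfo(seqnames = names(genome$sizes),
          seqlengths = as.integer(genome$sizes))
}

## Build a GRanges from 0-based half-open coordinates, validated against the
## assembly. All on-disk formats here (BED, broadPeak, bedGraph, chrom.sizes,
## rmsk) are 0-based half-open; GRanges is the in-memory container (1-based
## closed), so conversion happens exactly once, at the I/O boundary.
granges_from_bed0 <- function(chrom, start0, end0, strand = "*", genome = NULL) {
  if (any(start0 < 0)) stop("negative start coordinate", call. = FALSE)
  if (any(start0 >= end0)) stop("interval with start >= end", call. = FALSE)
  si <- if (!is.null(genome)) assembly_seqinfo(genome) else NULL
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (!is.null(si)) {
    seqlevels(gr) <- seqlevels(si)
    suppressWarnings(GenomeInfoDb::seqinfo(gr) <- si)
    bad <- end(gr) > seqlengths(si)[as.character(seqnames(gr))]
    if (any(bad)) stop(sum(bad), " interval(s) extend past chromosome end",
                       call. = FALSE)
  }
  gr
}

#' Read ChIP-seq peak calls (ENCODE broadPeak or BED3+)
#'
#' Columns 1-3 are chrom/start/end (BED, 0-based half-open). When a 7th
#' column is present (broadPeak signalValue) it is stored as the peak score.
#'
#' @param path Tab-delimited peak file.
#' @param dbp Name of the DNA-binding protein the peaks belong to.
#' @param replicate Replicate number (>= 1).
#' @param genome A `GenomeAssembly` to validate coordinates against.
#' @param on_unknown What to do with peaks on chromosomes absent from the
#'   assembly: `"skip"` drops them with a message, `"fail"` errors.
#' @return A [GenomicRanges::GRanges] with metadata columns `dbp`,
#'   `replicate` and `score` (NA when absent), in file order.
#' @export
read_peaks <- function(path, dbp, replicate, genome,
                       on_unknown = c("skip", "fail")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(is.numeric(replicate), replicate >= 1)
  tab <- read.table(path, header = FALSE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("peak file must have >= 3 columns: ", path,
                           call. = FALSE)
  chrom <- as.character(tab[[1L]])
  known <- chrom %in% names(genome$sizes)
  if (!all(known)) {
    if (on_unknown == "fail")
      stop(sum(!known), " peak(s) on unknown chromosome(s) in ", path,
           call. = FALSE)
    message("read_peaks: skipping ", sum(!known),
            " peak(s) on chromosomes absent from the assembly")
    tab <- tab[known, , drop = FALSE]
    chrom <- chrom[known]
  }
  score <- if (ncol(tab) >= 7L) suppressWarnings(as.numeric(tab[[7L]])) else
    rep(NA_real_, nrow(tab))
  gr <- granges_from_bed0(chrom, as.numeric(tab[[2L]]), as.numeric(tab[[3L]]),
                          genome = genome)
  mcols(gr)$dbp <- dbp
  mcols(gr)$replicate <- as.integer(replicate)
  mcols(gr)$score <- score
  gr
}

#' Read gene models from a GTF file
#'
#' Keeps `gene`-type records and maps GENCODE biotypes onto the two classes
#' the analysis distinguishes: `protein_coding` becomes `mRNA` and `lncRNA`
#' stays `lncRNA`; other biotypes are dropped with a message. The TSS is the
#' 5' end of the annotated span (strand-aware) and the effective length used
#' for TPM is the span width.
#'
#' @param path GTF file (1-based closed coordinates, converted on read by the
#'   importer).
#' @param genome Optional `GenomeAssembly`; genes on chromosomes absent from
#'   it raise an error.
#' @return A [GenomicRanges::GRanges] of gene spans with metadata columns
#'   `gene_id`, `biotype` (`mRNA`/`lncRNA`), `tss` (1-based position) and
#'   `effective_length`.
#' @export
read_gtf_genes <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[mcols(gr)$type == "gene"]
  bt <- as.character(mcols(gr)$gene_type)
  if (is.null(mcols(gr)$gene_type) && !is.null(mcols(gr)$gene_biotype))
    bt <- as.character(mcols(gr)$gene_biotype)
  keep <- bt %in% c("protein_coding", "lncRNA")
  if (!all(keep))
    message("read_gtf_genes: dropping ", sum(!keep),
            " gene(s) with biotypes other than protein_coding/lncRNA")
  gr <- gr[keep]
  bt <- ifelse(bt[keep] == "protein_coding", "mRNA", "lncRNA")
  out <- GRanges(seqnames(gr), ranges(gr), strand = strand(gr))
  mcols(out)$gene_id <- as.character(mcols(gr)$gene_id)
  mcols(out)$biotype <- bt
  mcols(out)$tss <- ifelse(as.character(strand(out)) == "-", end(out), start(out))
  mcols(out)$effective_length <- width(out)
  if (!is.null(genome)) {
    bad <- !(as.character(seqnames(out)) %in% names(genome$sizes))
    if (any(bad))
      stop("gene(s) on chromosome(s) absent from the assembly: ",
           paste(unique(as.character(seqnames(out))[bad]), collapse = ", "),
           call. = FALSE)
    seqlevels(out) <- names(genome$sizes)
    GenomeInfoDb::seqinfo(out) <- assembly_seqinfo(genome)
  }
  out
}

#' Read exon records from a GTF file
#'
#' Used by the peak feature annotator to tell exonic from intronic gene-body
#' positions.
#' @param path GTF file.
#' @return A [GenomicRanges::GRanges] of exon intervals with `gene_id`.
#' @export
read_gtf_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[mcols(gr)$type == "exon"]
  out <- GRanges(seqnames(gr), ranges(gr), strand = strand(gr))
  mcols(out)$gene_id <- as.character(mcols(gr)$gene_id)
  out
}

#' Derive strand-aware promoter windows around TSSs
#'
#' The promoter is `tss - flank .. tss + flank` (a 2*flank window, the "6 kb
#' window" at the default 3 kb flank), anchored at the strand-aware TSS and
#' clipped to the chromosome.
#'
#' @param genes Gene models as returned by [read_gtf_genes()] (needs `gene_id`,
#'   `tss` metadata and strand).
#' @param flank Flank size in bp on each side of the TSS (default 3000).
#' @param genome A `GenomeAssembly` used for clipping; genes on chromosomes
#'   absent from it raise an error.
#' @return A [GenomicRanges::GRanges] of promoter windows with metadata
#'   columns `gene_id`, `biotype` (when present on `genes`), `tss` and
#'   `flank`; strand copied from the gene.
#' @export
extract_promoters <- function(genes, flank = 3000, genome) {
  stopifnot(flank > 0)
  chrom <- as.character(seqnames(genes))
  bad <- !(chrom %in% names(genome$sizes))
  if (any(bad))
    stop("gene(s) on chromosome(s) absent from the assembly: ",
         paste(unique(chrom[bad]), collapse = ", "), call. = FALSE)
  tss <- mcols(genes)$tss
  if (is.null(tss))
    tss <- ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
  ## window in 1-based closed coords: [tss - flank, tss + flank - 1]
  s <- pmax(1L, as.integer(tss - flank))
  e <- pmin(as.integer(genome$sizes[chrom]), as.integer(tss + flank - 1L))
  out <- GRanges(chrom, IRanges(s, e), strand = strand(genes),
                 seqinfo = assembly_seqinfo(genome))
  mcols(out)$gene_id <- mcols(genes)$gene_id
  if (!is.null(mcols(genes)$biotype)) mcols(out)$biotype <- mcols(genes)$biotype
  mcols(out)$tss <- as.integer(tss)
  mcols(out)$flank <- as.integer(flank)
  out
}

#' Read a UCSC RepeatMasker-style repeat table
#'
#' Expects a header line naming at least `genoName`, `genoStart`, `genoEnd`,
#' `repName`, `repClass` and `repFamily` (a `strand` column is honoured when
#' present). Coordinates are 0-based half-open as in the UCSC rmsk table.
#'
#' @param path Tab-delimited repeat table.
#' @param genome Optional `GenomeAssembly` for coordinate validation.
#' @return A [GenomicRanges::GRanges] with metadata columns `rep_name`,
#'   `rep_class` and `rep_family`.
#' @export
read_repeats <- function(path, genome = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
  need <- c("genoName", "genoStart", "genoEnd", "repName", "repClass",
            "repFamily")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("repeat table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L)
    return(GRanges(rep_name = character(), rep_class = character(),
                   rep_family = character()))
  start0 <- suppressWarnings(as.numeric(tab$genoStart))
  end0 <- suppressWarnings(as.numeric(tab$genoEnd))
  bad <- which(is.na(start0) | is.na(end0) | start0 >= end0 |
                 !nzchar(tab$repClass) | !nzchar(tab$repFamily))
  if (length(bad))
    stop("malformed repeat row at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  str <- if ("strand" %in% colnames(tab))
    ifelse(tab$strand %in% c("+", "-"), tab$strand, "*") else "*"
  gr <- granges_from_bed0(tab$genoName, start0, end0, strand = str,
                          genome = genome)
  mcols(gr)$rep_name <- tab$repName
  mcols(gr)$rep_class <- tab$repClass
  mcols(gr)$rep_family <- tab$repFamily
  gr
}

#' Write intervals as a BED file (0-based half-open)
#'
#' @param gr A GRanges.
#' @param path Output path.
#' @param score Optional numeric vector for BED column 5.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, score = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(score) || any(as.character(strand(gr)) != "*")) {
    df$name <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else "."
    df$score <- if (!is.null(score)) score else 0
    df$strand <- as.character(strand(gr))
    df$strand[df$strand == "*"] <- "."
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
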