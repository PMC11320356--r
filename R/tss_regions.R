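#' Read a transcript annotation
#'
#' Accepts either a simplified transcript TSV (header: `gene_id`,
#' `transcript_id`, `chrom`, `strand`, `start`, `end`, `biotype`; 1-based
#' inclusive coordinates) or a GTF file (`feature == "transcript"` records;
#' biotype taken from the `transcript_biotype` or `gene_biotype` attribute).
#' GTF import requires the rtracklayer package.
#'
#' @param path Annotation file path.
#' @param format `"tsv"` or `"gtf"`; guessed from the file extension by
#'   default.
#' @return `data.frame` of transcript records.
#' @export
read_transcript_annotation <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  if (format == "tsv") {
    ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    req <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end",
             "biotype")
    miss <- setdiff(req, names(ann))
    if (length(miss)) stop("annotation missing column(s): ",
                           paste(miss, collapse = ", "))
    return(ann[, req])
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("GTF input requires the 'rtracklayer' package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  bt <- if (!is.null(gr$transcript_biotype)) gr$transcript_biotype else gr$gene_biotype
  if (is.null(bt)) bt <- rep(NA_character_, length(gr))
  data.frame(gene_id = gr$gene_id, transcript_id = gr$transcript_id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             biotype = bt, stringsAsFactors = FALSE)
}

#' Extract transcription start sites of protein-coding transcripts
#'
#' The TSS is the 5' end of the transcript: the annotation start for `+`
#' transcripts and the annotation end for `-` transcripts. Only
#' `protein_coding` records are retained.
#'
#' @param annotation Transcript records (`gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, `biotype`).
#' @return `data.frame` with `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `tss_pos` (1-based).
#' @export
extract_tss <- function(annotation) {
  ann <- annotation[annotation$biotype == "protein_coding", , drop = FALSE]
  bad <- !ann$strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand symbol '", ann$strand[which(bad)[1L]],
         "' for transcript ", ann$transcript_id[which(bad)[1L]])
  }
  data.frame(gene_id = ann$gene_id, transcript_id = ann$transcript_id,
             chrom = ann$chrom, strand = ann$strand,
             tss_pos = ifelse(ann$strand == "+", ann$start, ann$end),
             stringsAsFactors = FALSE)
}

#' Discard transcripts with ambiguous TSS assignment
#'
#' A transcript is removed when any TSS of a *different* gene on the same
#' chromosome lies closer than `min_sep` bp to its own TSS (strict
#' inequality, distance = |delta position|). Removal is symmetric: both
#' conflicting genes lose the transcripts involved. Alternative TSS of the
#' same gene never conflict with each other.
#'
#' @param tss TSS table from [extract_tss()].
#' @param min_sep Minimum separation in bp (default 2000).
#' @return The retained subset of `tss`.
#' @export
filter_ambiguous_tss <- function(tss, min_sep = 2000) {
  if (nrow(tss) == 0L) stop("empty TSS table")
  drop <- logical(nrow(tss))
  for (chr in unique(tss$chrom)) {
    idx <- which(tss$chrom == chr)
    o <- idx[order(tss$tss_pos[idx])]
    pos <- tss$tss_pos[o]
    gene <- tss$gene_id[o]
    n <- length(o)
    for (i in seq_len(n)) {
      j <- i + 1L
      while (j <= n && pos[j] - pos[i] < min_sep) {
        if (gene[j] != gene[i]) drop[o[i]] <- drop[o[j]] <- TRUE
        j <- j + 1L
      }
    }
  }
  tss[!drop, , drop = FALSE]
}

#' Build candidate TSS regions
#'
#' Each TSS is extended by `flank` bp up- and downstream, giving the closed
#' 1-based interval `[tss - flank, tss + flank]` (2 * flank + 1 bp), stored
#' 0-based half-open as `[tss - flank - 1, tss + flank)`.
#'
#' @param tss TSS table ([extract_tss()] / [filter_ambiguous_tss()]).
#' @param flank Flank size in bp (default 1000).
#' @return `data.frame` with `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `tss_pos`, `start` and `end` (0-based half-open).
#' @export
tss_regions <- function(tss, flank = 1000) {
  data.frame(tss[, c("gene_id", "transcript_id", "chrom", "strand", "tss_pos")],
             start = pmax(tss$tss_pos - flank - 1L, 0L),
             end = tss$tss_pos + flank,
             stringsAsFactors = FALSE)
}

# indices of matrix sites falling in each region (1-based pos inside the
# 0-based half-open [start, end))
region_site_hits <- function(regions, mm) {
  sites_gr <- GenomicRanges::GRanges(mm$sites$chrom,
                                     IRanges::IRanges(mm$sites$pos, width = 1L))
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L,
                                                    regions$end))
  GenomicRanges::findOverlaps(reg_gr, sites_gr)
}

#' Count measured CpGs per candidate region
#'
#' @param regions Region table from [tss_regions()].
#' @param mm `MethylationMatrix` restricted to all-samples-covered sites.
#' @return `regions` with an added `n_cpgs` column.
#' @export
count_region_cpgs <- function(regions, mm) {
  hits <- region_site_hits(regions, mm)
  tab <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(regions))
  regions$n_cpgs <- as.integer(tab)
  regions
}

#' Select one TSS region per gene
#'
#' For each gene, the candidate region with the largest number of CpGs
#' measured in the data set is selected. Ties are broken deterministically:
#' smallest region start, then lexicographically smallest transcript id.
#' Genes whose best region contains no measured CpG are dropped.
#'
#' @param regions Region table with `n_cpgs` (see [count_region_cpgs()]).
#' @return One-row-per-gene region table.
#' @export
select_gene_region <- function(regions) {
  regions <- regions[regions$n_cpgs > 0L, , drop = FALSE]
  if (nrow(regions) == 0L) return(regions)
  o <- order(regions$gene_id, -regions$n_cpgs, regions$start,
             regions$transcript_id)
  regions <- regions[o, , drop = FALSE]
  regions[!duplicated(regions$gene_id), , drop = FALSE]
}

#' Aggregate per-sample region methylation
#'
#' The region methylation (beta value) of each sample is the
#' coverage-weighted average over the CpGs in the region: pooled methylated
#' reads divided by pooled total reads. The mean coverage is pooled total
#' reads divided by the number of measured CpGs.
#'
#' @param regions One-region-per-gene table ([select_gene_region()]).
#' @param mm `MethylationMatrix`.
#' @return A `RegionMethylation`: list with `regions` (`data.frame`), `beta`
#'   and `mean_coverage` (regions x samples matrices, rownames = gene ids),
#'   `min_coverage` (per-CpG minimum total, same shape), and `samples`.
#' @export
aggregate_region_methylation <- function(regions, mm) {
  hits <- region_site_hits(regions, mm)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  n <- nrow(regions)
  meth_sum  <- matrix(0, n, length(mm$samples))
  total_sum <- matrix(0, n, length(mm$samples))
  min_cov   <- matrix(Inf, n, length(mm$samples))
  if (length(q)) {
    present <- sort(unique(q))
    meth_sum[present, ]  <- rowsum(mm$meth[s, , drop = FALSE], q)
    total_sum[present, ] <- rowsum(mm$total[s, , drop = FALSE], q)
    grp <- factor(q, levels = present)
    for (j in seq_along(mm$samples)) {
      min_cov[present, j] <- tapply(mm$total[s, j], grp, min)
    }
  }
  n_cpgs <- if (!is.null(regions$n_cpgs)) regions$n_cpgs else
    as.integer(tabulate(q, nbins = n))
  beta <- meth_sum / total_sum            # NaN where total 0 (flagged later)
  mean_coverage <- sweep(total_sum, 1L, pmax(n_cpgs, 1L), "/")
  dimnames(beta) <- dimnames(mean_coverage) <- dimnames(min_cov) <-
    list(regions$gene_id, mm$samples)
  regions$n_cpgs <- n_cpgs
  structure(list(regions = regions, beta = as.matrix(beta),
                 mean_coverage = as.matrix(mean_coverage),
                 min_coverage = min_cov, samples = mm$samples),
            class = "RegionMethylation")
}

#' @export
print.RegionMethylation <- function(x, ...) {
  cat("RegionMethylation:", nrow(x$regions), "TSS regions x",
      length(x$samples), "samples\n")
  cat("  CpGs per region: median", stats::median(x$regions$n_cpgs), "\n")
  invisible(x)
}

#' Filter regions on coverage and variability
#'
#' Keeps a region only if its coverage reaches `min_cov` in *every* sample
#' and its beta values vary across samples (non-zero variance). Coverage is
#' the per-sample mean total reads per CpG by default
#' (`coverage_mode = "mean"`); `"per_cpg"` instead requires every individual
#' CpG to reach `min_cov`. Regions with an undefined beta (zero pooled reads
#' in some sample) are always removed.
#'
#' @param rm A `RegionMethylation`.
#' @param min_cov Coverage threshold (default 5).
#' @param coverage_mode `"mean"` or `"per_cpg"`.
#' @return Filtered `RegionMethylation`.
#' @export
filter_regions <- function(rm, min_cov = 5, coverage_mode = c("mean", "per_cpg")) {
  coverage_mode <- match.arg(coverage_mode)
  covm <- if (coverage_mode == "mean") rm$mean_coverage else rm$min_coverage
  cov_ok <- apply(covm >= min_cov, 1L, all)
  defined <- apply(is.finite(rm$beta), 1L, all)
  v <- apply(rm$beta, 1L, stats::var)
  keep <- cov_ok & defined & !is.na(v) & v > 0
  structure(list(regions = rm$regions[keep, , drop = FALSE],
                 beta = rm$beta[keep, , drop = FALSE],
                 mean_coverage = rm$mean_coverage[keep, , drop = FALSE],
                 min_coverage = rm$min_coverage[keep, , drop = FALSE],
                 samples = rm$samples),
            class = "RegionMethylation")
}

#' Build filtered per-gene TSS region methylation from counts
#'
#' Convenience composition of the region-building stage: extract
#' protein-coding TSS, discard ambiguous ones (2-kb rule), build candidate
#' regions, select the best-measured region per gene, aggregate
#' coverage-weighted betas, and apply the coverage/variability filter.
#'
#' @param annotation Transcript annotation `data.frame`.
#' @param mm `MethylationMatrix`.
#' @param flank,min_sep,min_cov,coverage_mode Stage parameters (defaults
#'   1000 bp, 2000 bp, 5, `"mean"`).
#' @return A filtered `RegionMethylation`; attribute `"funnel"` records the
#'   row counts after each step.
#' @export
build_tss_methylation <- function(annotation, mm, flank = 1000,
                                  min_sep = 2000, min_cov = 5,
                                  coverage_mode = "mean") {
  tss <- extract_tss(annotation)
  kept <- filter_ambiguous_tss(tss, min_sep = min_sep)
  regions <- count_region_cpgs(tss_regions(kept, flank = flank), mm)
  sel <- select_gene_region(regions)
  rm_all <- aggregate_region_methylation(sel, mm)
  out <- filter_regions(rm_all, min_cov = min_cov,
                        coverage_mode = coverage_mode)
  attr(out, "funnel") <- c(transcripts = nrow(tss),
                           after_ambiguity_filter = nrow(kept),
                           genes_with_cpgs = nrow(sel),
                           after_region_filter = nrow(out$regions))
  out
}

#' Write a region methylation table as TSV
#'
#' @param rm A `RegionMethylation`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_region_methylation <- function(rm, path) {
  tab <- cbind(rm$regions,
               stats::setNames(as.data.frame(rm$beta),
                               paste0("beta.", rm$samples)),
               stats::setNames(as.data.frame(rm$mean_coverage),
                               paste0("cov.", rm$samples)))
  rownames(tab) <- NULL
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
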