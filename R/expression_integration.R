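#' Build an embryo x tissue pseudobulk matrix from single-cell counts
#'
#' Raw counts of all cells from the same tissue (or stage) within the same
#' embryo are summed, so that embryos serve as biological replicates.
#' Tissues represented by fewer than two embryos are flagged and excluded
#' from downstream testing.
#'
#' @param counts Genes x cells non-negative integer matrix (colnames = cell
#'   ids).
#' @param cell_meta `data.frame` with `cell_id`, `embryo_id`, `tissue` (and
#'   optionally `species`), one row per cell.
#' @return List (class `pseudobulk`) with `counts` (genes x pseudobulk
#'   samples), `samples` (`data.frame` of `embryo_id`, `tissue`,
#'   `n_cells`), and `underpowered_tissues` (tissues with < 2 embryos).
#' @export
build_pseudobulk <- function(counts, cell_meta) {
  req <- c("cell_id", "embryo_id", "tissue")
  miss <- setdiff(req, names(cell_meta))
  if (length(miss)) stop("cell metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(colnames(counts))) stop("'counts' must have cell id colnames")
  i <- match(colnames(counts), cell_meta$cell_id)
  if (any(is.na(i))) {
    stop("cell(s) lacking metadata: ",
         paste(utils::head(colnames(counts)[is.na(i)], 5L), collapse = ", "))
  }
  meta <- cell_meta[i, , drop = FALSE]
  if (any(is.na(meta$embryo_id)) || any(is.na(meta$tissue))) {
    stop("cell metadata contains missing embryo_id or tissue")
  }
  grp <- paste(meta$embryo_id, meta$tissue, sep = "|")
  levels <- unique(grp)
  pb <- t(rowsum(t(counts), grp, reorder = FALSE))
  pb <- pb[, levels, drop = FALSE]
  parts <- do.call(rbind, strsplit(levels, "|", fixed = TRUE))
  samples <- data.frame(embryo_id = parts[, 1L], tissue = parts[, 2L],
                        n_cells = as.integer(table(grp)[levels]),
                        stringsAsFactors = FALSE)
  colnames(pb) <- levels
  n_embryos <- tapply(samples$embryo_id, samples$tissue,
                      function(e) length(unique(e)))
  under <- names(n_embryos)[n_embryos < 2]
  structure(list(counts = pb, samples = samples,
                 underpowered_tissues = under), class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("Pseudobulk:", nrow(x$counts), "genes x", ncol(x$counts),
      "embryo-tissue samples (", length(unique(x$samples$tissue)),
      "tissues )\n")
  if (length(x$underpowered_tissues)) {
    cat("  tissues with < 2 embryos (excluded from tests):",
        paste(x$underpowered_tissues, collapse = ", "), "\n")
  }
  invisible(x)
}

#' CP10K + 1 normalization
#'
#' Scales each pseudobulk column to counts per 10,000 library reads and
#' adds 1: `value = count / column_total * 1e4 + 1`.
#'
#' @param counts Genes x samples count matrix (or a `pseudobulk` object).
#' @return Normalized matrix, same shape.
#' @export
normalize_cp10k <- function(counts) {
  if (inherits(counts, "pseudobulk")) counts <- counts$counts
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop("zero total count in column(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  }
  sweep(counts, 2L, tot, "/") * 1e4 + 1
}

#' Wilcoxon rank-sum test
#'
#' Mid-ranks for ties; the exact null distribution is enumerated when both
#' groups have at most `exact_max` observations and there are no ties,
#' otherwise the normal approximation with tie and continuity correction is
#' used. Two-sided by default.
#'
#' @param x,y Numeric samples for the two groups.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternative on the location of `x` relative to `y`).
#' @param exact_max Group-size bound for the exact path (default 10).
#' @return List with `statistic` (Mann-Whitney U of `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater"),
                              exact_max = 10) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = use_exact,
                       correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1      # degenerate: every pooled value tied
  list(statistic = unname(wt$statistic), p = p)
}

#' Expression of hyper- vs hypomethylated gene strata
#'
#' For each tissue, every gene contributes one value — its mean normalized
#' pseudobulk expression across that tissue's embryos — and the
#' hypermethylated gene stratum is compared with the hypomethylated stratum
#' by a Wilcoxon rank-sum test. Gene classes come from the sperm
#' methylation of the same species ([classify_bimodal()]).
#'
#' @param normalized Genes x pseudobulk-samples normalized matrix
#'   ([normalize_cp10k()]).
#' @param samples Pseudobulk sample table (`embryo_id`, `tissue`).
#' @param gene_classes Named character vector (`hypo` / `hyper` /
#'   `intermediate`) for (a superset of) the matrix genes.
#' @param tissues Tissues to test (default: all with >= 2 embryos).
#' @param alternative Passed to [wilcoxon_rank_sum()] with `x` = hyper
#'   stratum; `"less"` tests for lower expression of hypermethylated genes.
#' @return `data.frame` with `tissue`, `n_hyper`, `n_hypo`,
#'   `median_hyper`, `median_hypo`, `statistic`, `p`.
#' @export
test_methylation_strata <- function(normalized, samples, gene_classes,
                                    tissues = NULL,
                                    alternative = "two.sided") {
  cls <- gene_classes[intersect(rownames(normalized), names(gene_classes))]
  hyper <- names(cls)[cls == "hyper"]
  hypo <- names(cls)[cls == "hypo"]
  if (is.null(tissues)) {
    n_embryos <- tapply(samples$embryo_id, samples$tissue,
                        function(e) length(unique(e)))
    tissues <- names(n_embryos)[n_embryos >= 2]
  }
  rows <- lapply(tissues, function(ti) {
    cols <- which(samples$tissue == ti)
    if (length(hyper) == 0L || length(hypo) == 0L) {
      warning("empty methylation stratum; skipping tissue ", ti)
      return(NULL)
    }
    mh <- rowMeans(normalized[hyper, cols, drop = FALSE])
    ml <- rowMeans(normalized[hypo, cols, drop = FALSE])
    wt <- wilcoxon_rank_sum(mh, ml, alternative = alternative)
    data.frame(tissue = ti, n_hyper = length(hyper), n_hypo = length(hypo),
               median_hyper = stats::median(mh), median_hypo = stats::median(ml),
               statistic = wt$statistic, p = wt$p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(tissue = character(0), n_hyper = integer(0),
                      n_hypo = integer(0), median_hyper = numeric(0),
                      median_hypo = numeric(0), statistic = numeric(0),
                      p = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Cross-species differential expression for one stage
#'
#' Per gene: log2 fold change of the mean CP10K+1 between species, a Welch
#' t-test on the log2(CP10K+1) replicate values (embryos as replicates), BH
#' adjustment across genes within the stage, and significance tiers on the
#' adjusted p: `*` < 0.01, `**` < 1e-5, `***` < 1e-10, else `ns`.
#'
#' @param norm_a,norm_b Normalized pseudobulk matrices for species A and B
#'   (shared gene rownames).
#' @param samples_a,samples_b Pseudobulk sample tables.
#' @param stage Tissue/stage label to test.
#' @return `data.frame` with `gene`, `log2fc` (A over B), `t`, `df`, `p`,
#'   `adj_p`, `tier`; NULL with a warning if either species has < 2
#'   replicates at this stage.
#' @export
stage_de <- function(norm_a, norm_b, samples_a, samples_b, stage) {
  ca <- which(samples_a$tissue == stage)
  cb <- which(samples_b$tissue == stage)
  if (length(ca) < 2L || length(cb) < 2L) {
    warning("fewer than 2 replicates at stage ", stage, "; skipped")
    return(NULL)
  }
  genes <- intersect(rownames(norm_a), rownames(norm_b))
  a <- norm_a[genes, ca, drop = FALSE]
  b <- norm_b[genes, cb, drop = FALSE]
  la <- log2(a)
  lb <- log2(b)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1L, stats::var) / ncol(la)
  vb <- apply(lb, 1L, stats::var) / ncol(lb)
  se2 <- va + vb
  tstat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (va^2 / (ncol(la) - 1) + vb^2 / (ncol(lb) - 1)), 1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df = df), 1)
  adj <- adjust_bh(p)
  tier <- ifelse(adj < 1e-10, "***", ifelse(adj < 1e-5, "**",
                                            ifelse(adj < 0.01, "*", "ns")))
  data.frame(gene = genes, log2fc = log2(rowMeans(a) / rowMeans(b)),
             t = tstat, df = df, p = p, adj_p = adj, tier = tier,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cluster relative expression profiles
#'
#' Z-scores each gene across stage columns ("relative expression"), then
#' clusters genes by hierarchical agglomeration (Euclidean distance,
#' complete linkage). Genes are ordered by id beforehand so the dendrogram
#' is deterministic under ties. Constant genes are centered to zero with a
#' warning.
#'
#' @param stage_means Genes x stages matrix of per-stage mean expression
#'   (typically log2 CP10K+1 means).
#' @param k Optional number of clusters to cut the tree into.
#' @return List with `hclust` (the tree), `order` (gene ids in leaf order),
#'   `z` (the z-scored matrix), and `clusters` (named integer vector, if
#'   `k` given).
#' @export
cluster_relative_expression <- function(stage_means, k = NULL) {
  if (nrow(stage_means) < 2L) stop("need at least 2 genes to cluster")
  stage_means <- stage_means[order(rownames(stage_means)), , drop = FALSE]
  mu <- rowMeans(stage_means)
  sd <- apply(stage_means, 1L, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    warning(sum(flat), " constant gene profile(s) centered to zero")
    sd[flat] <- 1
  }
  z <- (stage_means - mu) / sd
  hc <- stats::hclust(stats::dist(z), method = "complete")
  out <- list(hclust = hc, order = rownames(z)[hc$order], z = z)
  if (!is.null(k)) {
    out$clusters <- stats::cutree(hc, k = k)
  }
  out
}
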