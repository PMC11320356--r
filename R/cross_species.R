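#' Load a one2one orthologue map
#'
#' Keeps rows whose homology type is a unique one-to-one mapping
#' (`"ortholog_one2one"` or `"one2one"`) and, by default, whose confidence
#' flag marks high confidence (`"high"`, `"1"` or `1`). After filtering,
#' every gene must appear at most once per species.
#'
#' @param path TSV with header columns `gene_a`, `gene_b`, `homology_type`,
#'   `confidence`.
#' @param require_high_confidence Drop low-confidence rows (default TRUE).
#' @return `data.frame` with `gene_a`, `gene_b`.
#' @export
load_orthologue_map <- function(path, require_high_confidence = TRUE) {
  om <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("gene_a", "gene_b", "homology_type", "confidence")
  miss <- setdiff(req, names(om))
  if (length(miss)) stop("orthologue map missing column(s): ",
                         paste(miss, collapse = ", "))
  keep <- om$homology_type %in% c("ortholog_one2one", "one2one")
  if (require_high_confidence) {
    keep <- keep & as.character(om$confidence) %in% c("high", "1")
  }
  om <- om[keep, c("gene_a", "gene_b")]
  dup_a <- unique(om$gene_a[duplicated(om$gene_a)])
  dup_b <- unique(om$gene_b[duplicated(om$gene_b)])
  if (length(dup_a) || length(dup_b)) {
    stop("genes mapped more than once after one2one filtering: ",
         paste(c(dup_a, dup_b), collapse = ", "))
  }
  rownames(om) <- NULL
  om
}

#' Classify bimodal methylation states
#'
#' Promoter methylation in sperm is strongly bimodal; regions are labelled
#' `hypo` when the mean beta is below `lo`, `hyper` when above `hi`, and
#' `intermediate` otherwise (strict inequalities on both sides).
#'
#' @param mean_beta Mean region beta values in \[0, 1\].
#' @param lo,hi Class thresholds (defaults 0.05 and 0.95).
#' @return Character vector of class labels.
#' @export
classify_bimodal <- function(mean_beta, lo = 0.05, hi = 0.95) {
  if (lo >= hi) stop("'lo' must be smaller than 'hi'")
  if (any(mean_beta < 0 | mean_beta > 1, na.rm = TRUE)) {
    stop("mean beta values must lie in [0, 1]")
  }
  ifelse(mean_beta < lo, "hypo", ifelse(mean_beta > hi, "hyper",
                                        "intermediate"))
}

#' Join two species' region methylation over orthologue pairs
#'
#' Inner join of the one2one orthologue map with both species' filtered
#' region tables; per species, the pair's methylation is the unweighted mean
#' across samples of the region betas. Bimodal classes and the concordance
#' category are derived from the two mean betas.
#'
#' @param pairs Orthologue map (`gene_a`, `gene_b`).
#' @param rm_a,rm_b `RegionMethylation` objects for species A and B.
#' @param lo,hi Bimodal class thresholds (defaults 0.05, 0.95).
#' @return `data.frame` with `gene_a`, `gene_b`, `mean_beta_a`,
#'   `mean_beta_b`, `class_a`, `class_b`, `concordance`; attribute
#'   `"n_unmatched"` counts map rows dropped by the join.
#' @export
join_methylation <- function(pairs, rm_a, rm_b, lo = 0.05, hi = 0.95) {
  ia <- match(pairs$gene_a, rm_a$regions$gene_id)
  ib <- match(pairs$gene_b, rm_b$regions$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  out <- data.frame(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
                    mean_beta_a = rowMeans(rm_a$beta[ia[keep], , drop = FALSE]),
                    mean_beta_b = rowMeans(rm_b$beta[ib[keep], , drop = FALSE]),
                    stringsAsFactors = FALSE)
  out$class_a <- classify_bimodal(out$mean_beta_a, lo, hi)
  out$class_b <- classify_bimodal(out$mean_beta_b, lo, hi)
  out$concordance <- ifelse(
    out$class_a == "hypo" & out$class_b == "hypo", "both_hypo",
    ifelse(out$class_a == "hyper" & out$class_b == "hyper", "both_hyper",
           ifelse(out$class_a == "hypo" & out$class_b == "hyper",
                  "a_specific_hypo",
                  ifelse(out$class_a == "hyper" & out$class_b == "hypo",
                         "b_specific_hypo", "other"))))
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- sum(!keep)
  out
}

#' Pearson correlation with a two-sided t test
#'
#' Standard product-moment correlation; the p-value comes from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' two-sided.
#'
#' @param x,y Equal-length finite numeric vectors, length >= 3, each with
#'   non-zero variance.
#' @return List with `rho`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance input")
  }
  n <- length(x)
  rho <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Species-specifically hypomethylated gene sets
#'
#' From a joined pair table, extracts the genes unmethylated in one species
#' whose orthologue is fully methylated in the other.
#'
#' @param pair_tab Output of [join_methylation()].
#' @return List with `a_specific_hypo` and `b_specific_hypo` (character
#'   vectors of `gene_a` / `gene_b` ids) and `summary` (counts and
#'   percentages of joined pairs).
#' @export
species_specific_sets <- function(pair_tab) {
  a_spec <- pair_tab$gene_a[pair_tab$concordance == "a_specific_hypo"]
  b_spec <- pair_tab$gene_b[pair_tab$concordance == "b_specific_hypo"]
  n <- nrow(pair_tab)
  list(a_specific_hypo = a_spec, b_specific_hypo = b_spec,
       summary = c(n_pairs = n, n_a_specific = length(a_spec),
                   n_b_specific = length(b_spec),
                   pct_a_specific = if (n) 100 * length(a_spec) / n else NA,
                   pct_b_specific = if (n) 100 * length(b_spec) / n else NA))
}

#' Compare model-based age effects between species
#'
#' Pairs the per-region age coefficients (M units per year) of both species
#' over the orthologue map, counts pairs significant in both, and
#' correlates the coefficients.
#'
#' @param tab_a,tab_b `age_tss` tables for species A and B (region ids =
#'   gene ids).
#' @param pairs Orthologue map (`gene_a`, `gene_b`).
#' @return List with `pairs` (`data.frame` of paired coefficients and
#'   significance flags), `n_both_significant`, `correlation`
#'   ([pearson_correlation()] result, or NULL for degenerate input).
#' @export
compare_age_effects <- function(tab_a, tab_b, pairs) {
  ia <- match(pairs$gene_a, tab_a$region)
  ib <- match(pairs$gene_b, tab_b$region)
  keep <- !is.na(ia) & !is.na(ib)
  ptab <- data.frame(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
                     beta_hat_a = tab_a$beta_hat[ia[keep]],
                     beta_hat_b = tab_b$beta_hat[ib[keep]],
                     significant_a = tab_a$significant[ia[keep]],
                     significant_b = tab_b$significant[ib[keep]],
                     stringsAsFactors = FALSE)
  corr <- if (nrow(ptab) >= 3L && stats::var(ptab$beta_hat_a) > 0 &&
              stats::var(ptab$beta_hat_b) > 0) {
    pearson_correlation(ptab$beta_hat_a, ptab$beta_hat_b)
  } else NULL
  list(pairs = ptab,
       n_both_significant = sum(ptab$significant_a & ptab$significant_b),
       n_significant_a = sum(ptab$significant_a),
       n_significant_b = sum(ptab$significant_b),
       correlation = corr)
}
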