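#' Run the single-species methylation analysis end to end
#'
#' Composes the IO, region-building, and age differential methylation
#' stages: read coverage files, keep all-samples-covered CpGs, build
#' filtered per-gene TSS region methylation, fit the age model with
#' moderated t-statistics, call ageTSS, and ordinate the cohort by
#' classical MDS on the top variant regions. When `out_dir` is given, the
#' region table, ageTSS table, MDS coordinates and a JSON manifest (all
#' parameters plus the filter funnel) are written there.
#'
#' @param coverage Either a named character vector of coverage file paths
#'   (names = sample ids) or a named list of already-parsed site tables.
#' @param metadata Sample metadata: path or `data.frame`
#'   (see [read_sample_metadata()]).
#' @param annotation Transcript annotation: path or `data.frame`.
#' @param out_dir Optional output directory.
#' @param min_total,flank,min_sep,min_cov,coverage_mode,epsilon,alpha,k_top
#'   Stage parameters (documented defaults 1, 1000, 2000, 5, "mean", 0.01,
#'   0.05, 1000).
#' @return List (class `species_analysis`) with `region_meth`
#'   (`RegionMethylation`), `age_tss`, `mds`, `top_regions`, `metadata`,
#'   `funnel`, `params`.
#' @export
run_species_analysis <- function(coverage, metadata, annotation,
                                 out_dir = NULL, min_total = 1,
                                 flank = 1000, min_sep = 2000, min_cov = 5,
                                 coverage_mode = "mean", epsilon = 0.01,
                                 alpha = 0.05, k_top = 1000) {
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  if (is.character(annotation)) {
    annotation <- read_transcript_annotation(annotation)
  }
  if (is.character(coverage)) {
    if (is.null(names(coverage))) {
      stop("stage methylation_io: coverage paths must be named by sample id")
    }
    missing <- coverage[!file.exists(coverage)]
    if (length(missing)) {
      stop("stage methylation_io: coverage file(s) not found: ",
           paste(missing, collapse = ", "))
    }
    coverage <- lapply(coverage, read_bismark_coverage,
                       min_total = min_total)
  }
  mm <- merge_common_sites(coverage, metadata)
  rm <- build_tss_methylation(annotation, mm, flank = flank,
                              min_sep = min_sep, min_cov = min_cov,
                              coverage_mode = coverage_mode)
  tab <- run_age_analysis(rm, metadata$age_years, epsilon = epsilon,
                          alpha = alpha)
  M <- attr(tab, "M")
  k_use <- min(k_top, nrow(M))
  top <- top_variant_regions(M, k = k_use)
  mds <- classical_mds(M[top, , drop = FALSE])
  funnel <- c(common_sites = nrow(mm$sites), attr(rm, "funnel"))
  params <- list(min_total = min_total, flank = flank, min_sep = min_sep,
                 min_cov = min_cov, coverage_mode = coverage_mode,
                 epsilon = epsilon, alpha = alpha, k_top = k_top)
  res <- structure(list(region_meth = rm, age_tss = tab, mds = mds,
                        top_regions = top, metadata = metadata,
                        funnel = funnel, params = params),
                   class = "species_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_region_methylation(rm, file.path(out_dir, "region_methylation.tsv"))
    utils::write.table(as.data.frame(tab),
                       file.path(out_dir, "age_tss.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mds_tab <- data.frame(sample_id = rownames(mds$points),
                          axis1 = mds$points[, 1L], axis2 = mds$points[, 2L])
    utils::write.table(mds_tab, file.path(out_dir, "mds_coordinates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(top, file.path(out_dir, "top_variant_regions.txt"))
    manifest <- list(params = params, funnel = as.list(funnel),
                     n_samples = length(mm$samples),
                     n_significant = unname(attr(tab, "summary")["n_significant"]))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' @export
print.species_analysis <- function(x, ...) {
  cat("Species analysis:", length(x$metadata$sample_id), "samples\n")
  cat("  funnel:", paste(names(x$funnel), x$funnel, sep = "=",
                         collapse = "  "), "\n")
  print(x$age_tss)
  invisible(x)
}

#' Run the cross-species comparison stage
#'
#' Joins two species' analyses over a one2one orthologue map, computes the
#' mean-beta correlation, bimodal concordance classes, species-specifically
#' hypomethylated gene sets, the paired age-effect comparison, and
#' (optionally) hypergeometric enrichment of the species-specific sets
#' against a GMT collection, using the joined orthologue genes as
#' background.
#'
#' @param res_a,res_b `species_analysis` results.
#' @param orthologues Orthologue map: path or `data.frame`
#'   (`gene_a`, `gene_b`).
#' @param gene_sets Optional GMT path or named list of gene sets (ids in
#'   species A namespace for the A-query, species B for the B-query).
#' @param out_dir Optional output directory (pair table, gene lists,
#'   summary JSON).
#' @param lo,hi Bimodal thresholds (defaults 0.05, 0.95).
#' @param require_high_confidence Passed to [load_orthologue_map()] when
#'   `orthologues` is a path.
#' @return List (class `comparison_analysis`) with `pairs`, `correlation`,
#'   `specific_sets`, `age_comparison`, `enrichment` (possibly NULL), and
#'   `summary` (named numeric vector of the headline quantities).
#' @export
run_comparison <- function(res_a, res_b, orthologues, gene_sets = NULL,
                           out_dir = NULL, lo = 0.05, hi = 0.95,
                           require_high_confidence = TRUE) {
  if (is.character(orthologues)) {
    orthologues <- load_orthologue_map(
      orthologues, require_high_confidence = require_high_confidence)
  }
  pair_tab <- join_methylation(orthologues, res_a$region_meth,
                               res_b$region_meth, lo = lo, hi = hi)
  corr <- pearson_correlation(pair_tab$mean_beta_a, pair_tab$mean_beta_b)
  sets <- species_specific_sets(pair_tab)
  age_cmp <- compare_age_effects(res_a$age_tss, res_b$age_tss, orthologues)
  enr <- NULL
  if (!is.null(gene_sets)) {
    if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
    enr <- list(
      a_specific = hypergeom_enrich(sets$a_specific_hypo, gene_sets,
                                    universe = pair_tab$gene_a),
      b_specific = hypergeom_enrich(sets$b_specific_hypo, gene_sets,
                                    universe = pair_tab$gene_b))
  }
  cls_n <- table(factor(pair_tab$concordance,
                        levels = c("both_hypo", "both_hyper",
                                   "a_specific_hypo", "b_specific_hypo",
                                   "other")))
  summary <- c(n_pairs = nrow(pair_tab), rho = corr$rho, rho_p = corr$p,
               n_both_hypo = unname(cls_n["both_hypo"]),
               n_both_hyper = unname(cls_n["both_hyper"]),
               sets$summary[c("n_a_specific", "n_b_specific",
                              "pct_a_specific", "pct_b_specific")],
               n_age_tss_overlap = age_cmp$n_both_significant)
  res <- structure(list(pairs = pair_tab, correlation = corr,
                        specific_sets = sets, age_comparison = age_cmp,
                        enrichment = enr, summary = summary),
                   class = "comparison_analysis")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(pair_tab, file.path(out_dir, "orthologue_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(sets$a_specific_hypo,
               file.path(out_dir, "a_specific_hypo.txt"))
    writeLines(sets$b_specific_hypo,
               file.path(out_dir, "b_specific_hypo.txt"))
    if (!is.null(enr)) {
      utils::write.table(enr$a_specific,
                         file.path(out_dir, "enrichment_a_specific.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(enr$b_specific,
                         file.path(out_dir, "enrichment_b_specific.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(as.list(summary),
                         file.path(out_dir, "comparison_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' @export
print.comparison_analysis <- function(x, ...) {
  s <- x$summary
  cat("Cross-species comparison:", s[["n_pairs"]], "orthologue pairs\n")
  cat(sprintf("  mean-beta correlation rho = %.3f (p = %.3g)\n",
              s[["rho"]], s[["rho_p"]]))
  cat(sprintf("  species-specific hypomethylated: %d (A, %.1f%%), %d (B, %.1f%%)\n",
              as.integer(s[["n_a_specific"]]), s[["pct_a_specific"]],
              as.integer(s[["n_b_specific"]]), s[["pct_b_specific"]]))
  cat("  ageTSS significant in both species:", s[["n_age_tss_overlap"]], "\n")
  invisible(x)
}

#' Run the shipped end-to-end demonstration analysis
#'
#' Simulates a reduced two-species cohort with the packaged generator,
#' writes every input file in its on-disk dialect, and runs the full
#' pipeline from those files: per-species region building and ageTSS
#' calling, MDS, and the cross-species comparison. All outputs are written
#' under `dir`. The run is fully determined by `seed`.
#'
#' @param dir Output directory.
#' @param seed Random seed (default 1).
#' @param n_genes,n_samples Cohort size (defaults 800 genes, 8 samples per
#'   species — small enough to complete in well under ten minutes on one
#'   CPU).
#' @return Invisibly, a list with the species analyses, the comparison and
#'   the output directory.
#' @export
run_demo <- function(dir, seed = 1L, n_genes = 800, n_samples = 8) {
  cfg <- methylome_sim_config(
    n_genes = n_genes, n_samples_a = n_samples, n_samples_b = n_samples,
    ages_b = seq(25, 51, length.out = n_samples),
    age_effect_frac_a = 0.05, age_effect_frac_b = 0.01,
    n_a_specific = max(1L, round(0.013 * n_genes)),
    n_b_specific = max(1L, round(0.02 * n_genes)),
    n_decoy_conflicts = 5, seed = seed)
  sim <- simulate_methylomes(cfg)
  paths <- write_methylome_sim(sim, file.path(dir, "inputs"))
  res <- lapply(c(a = "species_a", b = "species_b"), function(sp) {
    covs <- paths[[sp]]$coverage
    names(covs) <- sub("\\.cov$", "", basename(covs))
    run_species_analysis(covs, paths[[sp]]$metadata, paths[[sp]]$annotation,
                         out_dir = file.path(dir, sp),
                         k_top = min(1000, n_genes))
  })
  cmp <- run_comparison(res$a, res$b, paths$orthologues,
                        out_dir = file.path(dir, "comparison"))
  invisible(list(species_a = res$a, species_b = res$b, comparison = cmp,
                 dir = dir))
}
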