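#' Configuration for the synthetic methylome generator
#'
#' Defaults describe the cohorts the pipeline is designed around: 13,914
#' promoter regions, 15 marmoset-like sperm samples aged 1.7-12.5 years and
#' 73 human-like samples aged 25-51 years, a strongly bimodal beta-value
#' mixture (76% hypomethylated, 6.3% hypermethylated), a ~1.5% planted
#' age-effect fraction with an 85% gain / 15% loss direction mix in species
#' A (0.2% and 4% gain in species B), a cross-species mean-beta correlation
#' target of 0.611, and 132 / 197 planted species-specifically
#' hypomethylated discordant genes.
#'
#' @param n_genes Number of orthologous genes simulated.
#' @param n_samples_a,n_samples_b Samples per species.
#' @param ages_a,ages_b Donor ages in years (defaults: a young/prime/old
#'   marmoset-like spread over 1.7-12.5, and an even human-like spread over
#'   25-51).
#' @param p_hypo,p_hyper Class proportions (intermediate takes the rest).
#' @param age_effect_frac_a,age_effect_frac_b Fraction of genes with a
#'   planted linear age effect per species.
#' @param age_effect_magnitude Planted slope magnitude, M units per year.
#' @param p_gain_a,p_gain_b Probability a planted effect gains methylation.
#' @param rho_target Target Pearson correlation of latent mean betas
#'   between species.
#' @param n_a_specific,n_b_specific Planted discordant genes (hypo in one
#'   species, hyper in the other).
#' @param coverage_mu,coverage_size Negative-binomial per-CpG read coverage.
#' @param cpgs_per_region_mean,cpgs_min CpGs per promoter region (Poisson
#'   mean, lower clamp).
#' @param sigma_m Per-sample biological noise on the M scale.
#' @param cpg_jitter_sd Per-CpG deviation from the region methylation, M
#'   scale.
#' @param shape_hypo,shape_hyper,shape_intermediate Beta shape parameters
#'   of the three class distributions.
#' @param frac_multi_tss Fraction of genes with a second same-gene TSS.
#' @param n_decoy_conflicts Planted pairs of extra genes with TSS < 2 kb
#'   apart (exercise the ambiguity filter).
#' @param frac_map_noise Fraction of decoy orthologue-map rows (one2many /
#'   low confidence).
#' @param seed Random seed.
#' @return List of class `methylome_sim_config`.
#' @export
methylome_sim_config <- function(n_genes = 13914,
                                 n_samples_a = 15, n_samples_b = 73,
                                 ages_a = NULL, ages_b = NULL,
                                 p_hypo = 0.76, p_hyper = 0.063,
                                 age_effect_frac_a = 204 / 13914,
                                 age_effect_frac_b = 27 / 13718,
                                 age_effect_magnitude = 0.08,
                                 p_gain_a = 0.85, p_gain_b = 1 / 27,
                                 rho_target = 0.611,
                                 n_a_specific = 132, n_b_specific = 197,
                                 coverage_mu = 30, coverage_size = 5,
                                 cpgs_per_region_mean = 12, cpgs_min = 3,
                                 sigma_m = 0.1, cpg_jitter_sd = 0.25,
                                 shape_hypo = c(0.5, 30),
                                 shape_hyper = c(30, 0.5),
                                 shape_intermediate = c(2, 2),
                                 frac_multi_tss = 0.1,
                                 n_decoy_conflicts = 10,
                                 frac_map_noise = 0.1,
                                 seed = 1L) {
  if (p_hypo + p_hyper >= 1) stop("class proportions must sum to < 1")
  if (n_a_specific + n_b_specific > n_genes) {
    stop("more planted discordant genes than genes")
  }
  if (is.null(ages_a)) {
    ages_a <- stats::quantile(c(seq(1.7, 2, length.out = 4),
                                seq(2.5, 8, length.out = 6),
                                seq(8.5, 12.5, length.out = 5)),
                              probs = seq(0, 1, length.out = n_samples_a),
                              names = FALSE, type = 1)
  }
  if (is.null(ages_b)) ages_b <- seq(25, 51, length.out = n_samples_b)
  if (length(ages_a) != n_samples_a || length(ages_b) != n_samples_b) {
    stop("age vectors must match the sample counts")
  }
  structure(list(
    n_genes = n_genes, n_samples_a = n_samples_a, n_samples_b = n_samples_b,
    ages_a = ages_a, ages_b = ages_b, p_hypo = p_hypo, p_hyper = p_hyper,
    age_effect_frac_a = age_effect_frac_a,
    age_effect_frac_b = age_effect_frac_b,
    age_effect_magnitude = age_effect_magnitude,
    p_gain_a = p_gain_a, p_gain_b = p_gain_b, rho_target = rho_target,
    n_a_specific = n_a_specific, n_b_specific = n_b_specific,
    coverage_mu = coverage_mu, coverage_size = coverage_size,
    cpgs_per_region_mean = cpgs_per_region_mean, cpgs_min = cpgs_min,
    sigma_m = sigma_m, cpg_jitter_sd = cpg_jitter_sd,
    shape_hypo = shape_hypo, shape_hyper = shape_hyper,
    shape_intermediate = shape_intermediate,
    frac_multi_tss = frac_multi_tss, n_decoy_conflicts = n_decoy_conflicts,
    frac_map_noise = frac_map_noise, seed = as.integer(seed)),
    class = "methylome_sim_config")
}

# class supports: labels are definitional, so each class draws from a Beta
# distribution truncated to its own window; a guard band separates the
# intermediate class from the thresholds so read-sampling noise cannot
# flip a truth label across a class boundary
# The extreme windows are floored slightly away from 0 and 1 (default
# 0.002): regions whose latent methylation is numerically zero would emit
# all-zero counts and be removed by the non-zero-variability filter,
# detaching the truth table from the analyzed set (and real RRBS regions
# are never exactly zero across a whole cohort at high coverage).
class_windows <- function(lo = 0.05, hi = 0.95, guard = 0.01,
                          floor = 0.002) {
  rbind(hypo = c(floor, lo), hyper = c(hi, 1 - floor),
        intermediate = c(lo + guard, hi - guard))
}

# mean / variance of Beta(a, b) truncated to [lo, hi]
truncated_beta_moments <- function(a, b, lo, hi) {
  lo <- unname(lo); hi <- unname(hi)
  z <- stats::pbeta(hi, a, b) - stats::pbeta(lo, a, b)
  m1 <- a / (a + b) *
    (stats::pbeta(hi, a + 1, b) - stats::pbeta(lo, a + 1, b)) / z
  m2 <- a * (a + 1) / ((a + b) * (a + b + 1)) *
    (stats::pbeta(hi, a + 2, b) - stats::pbeta(lo, a + 2, b)) / z
  c(mean = m1, var = m2 - m1^2)
}

rtruncbeta <- function(n, a, b, lo, hi) {
  u <- stats::runif(n, stats::pbeta(lo, a, b), stats::pbeta(hi, a, b))
  stats::qbeta(u, a, b)
}

# truncated mean/variance per class, in order (hypo, hyper, inter)
class_beta_moments <- function(config) {
  shp <- rbind(config$shape_hypo, config$shape_hyper,
               config$shape_intermediate)
  win <- class_windows()
  mom <- sapply(1:3, function(i) {
    truncated_beta_moments(shp[i, 1L], shp[i, 2L], win[i, 1L], win[i, 2L])
  })
  list(mean = mom["mean", ], var = mom["var", ])
}

# Joint class distribution given the sharing parameter q: classes are
# shared between species with probability 1 - q and redrawn conditionally
# otherwise (never producing an extreme-opposite pair by chance); the
# planted discordant mass sits explicitly in the off-diagonal corners.
class_joint <- function(q, p, frac_a_spec, frac_b_spec) {
  cond <- matrix(0, 3, 3)
  for (i in 1:3) {
    allowed <- rep(TRUE, 3)
    if (i == 1L) allowed[2L] <- FALSE      # hypo never redrawn as hyper
    if (i == 2L) allowed[1L] <- FALSE      # hyper never redrawn as hypo
    cond[i, allowed] <- p[i] * p[allowed] / sum(p[allowed])
  }
  J <- (1 - q) * diag(p) + q * cond
  f <- frac_a_spec + frac_b_spec
  J <- (1 - f) * J
  J[1L, 2L] <- J[1L, 2L] + frac_a_spec
  J[2L, 1L] <- J[2L, 1L] + frac_b_spec
  J
}

# Solve for the class-sharing parameter q that hits the target latent
# mean-beta correlation, from closed-form Beta-mixture moments.
calibrate_class_sharing <- function(config) {
  p <- c(config$p_hypo, config$p_hyper,
         1 - config$p_hypo - config$p_hyper)
  mom <- class_beta_moments(config)
  fa <- config$n_a_specific / config$n_genes
  fb <- config$n_b_specific / config$n_genes
  rho_of <- function(q) {
    J <- class_joint(q, p, fa, fb)
    pa <- rowSums(J); pb <- colSums(J)
    ea <- sum(pa * mom$mean); eb <- sum(pb * mom$mean)
    eab <- sum(J * outer(mom$mean, mom$mean))
    va <- sum(pa * (mom$var + mom$mean^2)) - ea^2
    vb <- sum(pb * (mom$var + mom$mean^2)) - eb^2
    (eab - ea * eb) / sqrt(va * vb)
  }
  if (rho_of(1) >= config$rho_target) return(1)
  if (rho_of(0) <= config$rho_target) return(0)
  stats::uniroot(function(q) rho_of(q) - config$rho_target,
                 c(0, 1), tol = 1e-9)$root
}

inv_logit2 <- function(m) 1 / (1 + 2^(-m))
logit2 <- function(b, eps = 1e-6) {
  b <- pmin(pmax(b, eps), 1 - eps)
  log2(b / (1 - b))
}

# Lay genes on a 10-kb grid over synthetic chromosomes (1000 genes each)
gene_grid <- function(n, prefix = "chr", genes_per_chrom = 1000L,
                      step = 10000L) {
  chrom_idx <- (seq_len(n) - 1L) %/% genes_per_chrom + 1L
  slot <- (seq_len(n) - 1L) %% genes_per_chrom
  list(chrom = paste0(prefix, chrom_idx), tss = 10000L + slot * step)
}

# One species' methylome: annotation, per-sample site tables, metadata
simulate_species_methylome <- function(config, species, gene_ids, latent,
                                       slopes, ages, sample_prefix) {
  n <- length(gene_ids)
  grid <- gene_grid(n)
  strand <- rep(c("+", "-"), length.out = n)
  base_m <- logit2(latent)

  n_cpg <- pmax(config$cpgs_min,
                stats::rpois(n, config$cpgs_per_region_mean))
  gene_of_site <- rep.int(seq_len(n), n_cpg)
  offsets <- unlist(lapply(n_cpg, function(k) sample.int(2001L, k) - 1001L))
  pos <- grid$tss[gene_of_site] + offsets
  site_chrom <- grid$chrom[gene_of_site]
  delta <- stats::rnorm(length(pos), 0, config$cpg_jitter_sd)

  ns <- length(ages)
  M <- base_m + outer(slopes, ages - mean(ages)) +
    matrix(stats::rnorm(n * ns, 0, config$sigma_m), n, ns)
  beta_site <- inv_logit2(M[gene_of_site, , drop = FALSE] + delta)
  total <- matrix(stats::rnbinom(length(pos) * ns, mu = config$coverage_mu,
                                 size = config$coverage_size),
                  length(pos), ns)
  meth <- matrix(stats::rbinom(length(pos) * ns, as.vector(total),
                               as.vector(beta_site)), length(pos), ns)

  # decoy conflict pairs: extra genes whose TSS are 1500 bp apart
  nd <- config$n_decoy_conflicts
  decoy_ann <- NULL
  if (nd > 0) {
    dgrid <- gene_grid(nd, prefix = "chrD")
    d1 <- paste0(species, "_DEC", seq_len(nd), "a")
    d2 <- paste0(species, "_DEC", seq_len(nd), "b")
    dk <- pmax(config$cpgs_min, stats::rpois(2L * nd,
                                             config$cpgs_per_region_mean))
    dg <- rep.int(seq_len(2L * nd), dk)
    doff <- unlist(lapply(seq_along(dk), function(i) {
      if (i <= nd) sample(100:1000, dk[i]) * -1L else sample(100:1000, dk[i])
    }))
    dtss <- c(dgrid$tss, dgrid$tss + 1500L)[dg]
    dchrom <- c(dgrid$chrom, dgrid$chrom)[dg]
    dpos <- dtss + doff
    dtotal <- matrix(stats::rnbinom(length(dpos) * ns,
                                    mu = config$coverage_mu,
                                    size = config$coverage_size),
                     length(dpos), ns)
    dmeth <- matrix(stats::rbinom(length(dpos) * ns, as.vector(dtotal), 0.5),
                    length(dpos), ns)
    site_chrom <- c(site_chrom, dchrom)
    pos <- c(pos, dpos)
    total <- rbind(total, dtotal)
    meth <- rbind(meth, dmeth)
    decoy_ann <- data.frame(
      gene_id = c(d1, d2), transcript_id = paste0(c(d1, d2), ".t1"),
      chrom = c(dgrid$chrom, dgrid$chrom), strand = "+",
      start = c(dgrid$tss, dgrid$tss + 1500L),
      end = c(dgrid$tss, dgrid$tss + 1500L) + 1200L,
      biotype = "protein_coding", stringsAsFactors = FALSE)
  }

  # annotation: one transcript per gene, a second TSS for a fraction,
  # plus a few non-coding rows that must be ignored
  tlen <- 1500L
  ann <- data.frame(gene_id = gene_ids,
                    transcript_id = paste0(gene_ids, ".t1"),
                    chrom = grid$chrom, strand = strand,
                    start = ifelse(strand == "+", grid$tss, grid$tss - tlen),
                    end = ifelse(strand == "+", grid$tss + tlen, grid$tss),
                    biotype = "protein_coding", stringsAsFactors = FALSE)
  n_multi <- round(config$frac_multi_tss * n)
  if (n_multi > 0) {
    mi <- sample.int(n, n_multi)
    off2 <- sample(c(-600L, -400L, -200L, 200L, 400L, 600L), n_multi,
                   replace = TRUE)
    tss2 <- grid$tss[mi] + off2
    ann2 <- data.frame(gene_id = gene_ids[mi],
                       transcript_id = paste0(gene_ids[mi], ".t2"),
                       chrom = grid$chrom[mi], strand = strand[mi],
                       start = ifelse(strand[mi] == "+", tss2, tss2 - tlen),
                       end = ifelse(strand[mi] == "+", tss2 + tlen, tss2),
                       biotype = "protein_coding", stringsAsFactors = FALSE)
    ann <- rbind(ann, ann2)
  }
  nc <- data.frame(gene_id = paste0(species, "_NC", 1:3),
                   transcript_id = paste0(species, "_NC", 1:3, ".t1"),
                   chrom = "chrNC", strand = "+",
                   start = c(1e4, 3e4, 5e4), end = c(1e4, 3e4, 5e4) + tlen,
                   biotype = "lincRNA", stringsAsFactors = FALSE)
  ann <- rbind(ann, decoy_ann, nc)

  sample_ids <- sprintf("%s%02d", sample_prefix, seq_len(ns))
  o <- order(site_chrom, pos)
  tables <- lapply(seq_len(ns), function(j) {
    keep <- total[o, j] > 0L
    data.frame(chrom = site_chrom[o][keep], pos = pos[o][keep],
               meth = meth[o, j][keep], total = total[o, j][keep],
               stringsAsFactors = FALSE)
  })
  names(tables) <- sample_ids
  grp <- cut(ages, breaks = c(-Inf, 2, 8, Inf),
             labels = c("Young", "Prime Adult", "Old Age"))
  metadata <- data.frame(sample_id = sample_ids, species = species,
                         age_years = ages, age_group = as.character(grp),
                         stringsAsFactors = FALSE)
  list(tables = tables, annotation = ann, metadata = metadata,
       latent_mean_beta = stats::setNames(latent, gene_ids))
}

#' Simulate a two-species sperm methylome cohort
#'
#' Generates, from one seeded configuration, everything the comparative
#' pipeline consumes: per-sample per-CpG count tables in the coverage
#' dialect for two species, transcript annotations with planted 2-kb
#' TSS conflicts and multi-TSS genes, sample metadata, a one2one orthologue
#' map with decoy rows, and a truth table (class per species, planted age
#' slope per species, planted discordance).
#'
#' Per gene, a latent region beta value is drawn from the bimodal
#' class mixture; planted genes receive a linear-in-age drift on the M
#' scale which is pushed back through the inverse logit; CpGs scattered in
#' the region get negative-binomial coverage and binomial methylated reads
#' at the region beta with a per-CpG jitter.
#'
#' @param config A [methylome_sim_config()].
#' @return List with `species_a`, `species_b` (each: `tables` — named list
#'   of per-sample site tables, `annotation`, `metadata`,
#'   `latent_mean_beta`), `orthologues`, `truth`, `config`, and
#'   `class_sharing` (the calibrated sharing parameter).
#' @export
simulate_methylomes <- function(config) {
  stopifnot(inherits(config, "methylome_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  p <- c(config$p_hypo, config$p_hyper, 1 - config$p_hypo - config$p_hyper)
  cls_levels <- c("hypo", "hyper", "intermediate")

  q <- calibrate_class_sharing(config)
  class_a <- sample(cls_levels, n, replace = TRUE, prob = p)
  shared <- stats::runif(n) < (1 - q)
  class_b <- class_a
  redraw <- which(!shared)
  for (i in redraw) {
    allowed <- cls_levels
    if (class_a[i] == "hypo") allowed <- setdiff(allowed, "hyper")
    if (class_a[i] == "hyper") allowed <- setdiff(allowed, "hypo")
    pw <- p[match(allowed, cls_levels)]
    class_b[i] <- sample(allowed, 1L, prob = pw / sum(pw))
  }
  discordant <- rep("none", n)
  if (config$n_a_specific + config$n_b_specific > 0) {
    planted <- sample.int(n, config$n_a_specific + config$n_b_specific)
    ia <- planted[seq_len(config$n_a_specific)]
    ib <- setdiff(planted, ia)
    class_a[ia] <- "hypo";  class_b[ia] <- "hyper"
    class_a[ib] <- "hyper"; class_b[ib] <- "hypo"
    discordant[ia] <- "a_specific"
    discordant[ib] <- "b_specific"
  }

  # age-effect sets are disjoint between species: planted drift emulates
  # species-specific epigenetic aging with no shared ageTSS
  plant_slopes <- function(classes, frac, p_gain, exclude = integer(0)) {
    slopes <- numeric(n)
    eligible <- setdiff(which(classes == "intermediate" &
                                discordant == "none"), exclude)
    n_eff <- min(round(frac * n), length(eligible))
    if (n_eff > 0) {
      idx <- sample(eligible, n_eff)
      n_gain <- round(p_gain * n_eff)          # exact direction composition
      sign <- sample(rep(c(1, -1), c(n_gain, n_eff - n_gain)))
      slopes[idx] <- sign * config$age_effect_magnitude
    }
    slopes
  }
  slopes_a <- plant_slopes(class_a, config$age_effect_frac_a, config$p_gain_a)
  slopes_b <- plant_slopes(class_b, config$age_effect_frac_b, config$p_gain_b,
                           exclude = which(slopes_a != 0))

  # latent region betas: truncated to the class window; planted discordant
  # genes sit well inside the extreme windows so that read-sampling noise
  # never moves them across a threshold and pooled counts never degenerate
  # to an all-zero (variance-filtered) region
  shp <- rbind(config$shape_hypo, config$shape_hyper,
               config$shape_intermediate)
  win <- class_windows()
  draw_latent <- function(classes) {
    ci <- match(classes, c("hypo", "hyper", "intermediate"))
    lat <- numeric(n)
    for (k in 1:3) {
      i <- which(ci == k)
      lat[i] <- rtruncbeta(length(i), shp[k, 1L], shp[k, 2L],
                           win[k, 1L], win[k, 2L])
    }
    planted <- discordant != "none"
    hyp <- planted & classes == "hypo"
    hypr <- planted & classes == "hyper"
    lo <- win["hypo", 2L]; hi <- win["hyper", 1L]
    lat[hyp] <- rtruncbeta(sum(hyp), shp[1L, 1L], shp[1L, 2L],
                           0.1 * lo, 0.6 * lo)
    lat[hypr] <- rtruncbeta(sum(hypr), shp[2L, 1L], shp[2L, 2L],
                            1 - 0.6 * (1 - hi), 1 - 0.1 * (1 - hi))
    lat
  }
  latent_a <- draw_latent(class_a)
  latent_b <- draw_latent(class_b)

  ids <- sprintf("G%05d", seq_len(n))
  gene_a <- paste0("A_", ids)
  gene_b <- paste0("B_", ids)
  sa <- simulate_species_methylome(config, "A", gene_a, latent_a, slopes_a,
                                   config$ages_a, "A")
  sb <- simulate_species_methylome(config, "B", gene_b, latent_b, slopes_b,
                                   config$ages_b, "B")

  map <- data.frame(gene_a = gene_a, gene_b = gene_b,
                    homology_type = "ortholog_one2one", confidence = "high",
                    stringsAsFactors = FALSE)
  n_noise <- round(config$frac_map_noise * n)
  if (n_noise > 0) {
    half <- n_noise %/% 2L
    noise <- rbind(
      data.frame(gene_a = paste0("A_FAKE", seq_len(n_noise - half)),
                 gene_b = paste0("B_FAKE", seq_len(n_noise - half)),
                 homology_type = "ortholog_one2many", confidence = "high",
                 stringsAsFactors = FALSE),
      if (half > 0) data.frame(gene_a = paste0("A_LOW", seq_len(half)),
                               gene_b = paste0("B_LOW", seq_len(half)),
                               homology_type = "ortholog_one2one",
                               confidence = "low", stringsAsFactors = FALSE))
    map <- rbind(map, noise)
    map <- map[sample.int(nrow(map)), , drop = FALSE]
    rownames(map) <- NULL
  }

  truth <- data.frame(gene = ids, gene_a = gene_a, gene_b = gene_b,
                      class_a = class_a, class_b = class_b,
                      slope_a = slopes_a, slope_b = slopes_b,
                      discordant = discordant, stringsAsFactors = FALSE)
  list(species_a = sa, species_b = sb, orthologues = map, truth = truth,
       config = config, class_sharing = q)
}

#' Write a simulated methylome cohort to disk in the pipeline's dialects
#'
#' Emits exactly the files the IO layer reads: one coverage TSV per sample
#' under `<dir>/<species>/`, per-species annotation and metadata TSVs, the
#' orthologue map TSV, and the truth table TSV.
#'
#' @param sim Output of [simulate_methylomes()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_methylome_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (sp in c("species_a", "species_b")) {
    sdir <- file.path(dir, sp)
    dir.create(sdir, showWarnings = FALSE)
    cov <- character(0)
    for (sid in names(sim[[sp]]$tables)) {
      f <- file.path(sdir, paste0(sid, ".cov"))
      write_bismark_coverage(sim[[sp]]$tables[[sid]], f)
      cov <- c(cov, f)
    }
    ann <- file.path(sdir, "annotation.tsv")
    utils::write.table(sim[[sp]]$annotation, ann, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    md <- file.path(sdir, "metadata.tsv")
    utils::write.table(sim[[sp]]$metadata, md, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[sp]] <- list(coverage = cov, annotation = ann, metadata = md)
  }
  paths$orthologues <- file.path(dir, "orthologues.tsv")
  utils::write.table(sim$orthologues, paths$orthologues, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Configuration for the synthetic embryo expression generator
#'
#' Defaults emulate a pre-implantation single-cell design: seven stages /
#' blastocyst tissues from zygote to trophectoderm, four embryos per
#' tissue per species, negative-binomial counts with log-normal library
#' sizes, halved expression (one log2 unit down) of genes whose sperm TSS
#' is fully methylated in that species, and a set of planted cross-species
#' differentially expressed genes.
#'
#' @param tissues Stage / tissue labels.
#' @param embryos_per_tissue Embryos (replicates) per tissue per species.
#' @param cells_per_embryo Cells sequenced per embryo.
#' @param base_meanlog,base_sdlog Log-normal per-gene baseline mean counts.
#' @param dispersion Negative-binomial size parameter.
#' @param meth_effect_log2 Log2 expression effect of a hypermethylated
#'   sperm TSS (default -1: halved).
#' @param n_de,de_log2fc Number and magnitude (species A over B) of planted
#'   cross-species DE genes; each gene is differential at one stage.
#' @param libsize_sdlog Log-normal spread of per-cell library factors.
#' @param seed Random seed.
#' @return List of class `expression_sim_config`.
#' @export
expression_sim_config <- function(tissues = c("zygote", "four_cell",
                                              "eight_cell", "morula",
                                              "epiblast", "hypoblast",
                                              "trophectoderm"),
                                  embryos_per_tissue = 4,
                                  cells_per_embryo = 20,
                                  base_meanlog = log(5), base_sdlog = 1,
                                  dispersion = 2,
                                  meth_effect_log2 = -1,
                                  n_de = 30, de_log2fc = 2,
                                  libsize_sdlog = 0.3, seed = 1L) {
  if (embryos_per_tissue < 2) stop("tested tissues need >= 2 embryos")
  structure(list(tissues = tissues,
                 embryos_per_tissue = embryos_per_tissue,
                 cells_per_embryo = cells_per_embryo,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 dispersion = dispersion,
                 meth_effect_log2 = meth_effect_log2,
                 n_de = n_de, de_log2fc = de_log2fc,
                 libsize_sdlog = libsize_sdlog, seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate embryo single-cell counts coupled to a methylome truth table
#'
#' Genes live in the common orthologue namespace of the methylome truth
#' table. Each cell's counts are negative binomial around a shared per-gene
#' baseline, scaled down by `2^meth_effect_log2` for genes whose sperm TSS
#' is hypermethylated in that species, multiplied by the planted
#' cross-species fold change at the DE gene's stage, and by a log-normal
#' per-cell library factor.
#'
#' @param config An [expression_sim_config()].
#' @param truth Methylome truth table ([simulate_methylomes()]`$truth`).
#' @return List with `counts` (genes x cells integer matrix), `cell_meta`
#'   (`cell_id`, `embryo_id`, `tissue`, `species`), and `truth_expr`
#'   (per-gene DE status: `gene`, `de_stage`, `de_log2fc`).
#' @export
simulate_embryo_counts <- function(config, truth) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  genes <- truth$gene
  ng <- length(genes)
  base <- stats::rlnorm(ng, config$base_meanlog, config$base_sdlog)
  eff_a <- ifelse(truth$class_a == "hyper", 2^config$meth_effect_log2, 1)
  eff_b <- ifelse(truth$class_b == "hyper", 2^config$meth_effect_log2, 1)

  # DE is planted on well-expressed genes (top baseline quartile): a fold
  # change on a near-silent gene is unobservable on the CP10K + 1 scale
  n_de <- min(config$n_de, ng)
  candidates <- which(base >= stats::quantile(base, 0.75))
  de_idx <- sample(candidates, min(n_de, length(candidates)))
  de_stage <- sample(config$tissues, n_de, replace = TRUE)
  de_sign <- sample(c(1, -1), n_de, replace = TRUE)
  truth_expr <- data.frame(gene = genes, de_stage = NA_character_,
                           de_log2fc = 0, stringsAsFactors = FALSE)
  truth_expr$de_stage[de_idx] <- de_stage
  truth_expr$de_log2fc[de_idx] <- de_sign * config$de_log2fc

  cells <- list(); metas <- list(); ci <- 0L
  for (sp in c("A", "B")) {
    eff <- if (sp == "A") eff_a else eff_b
    for (ti in config$tissues) {
      de_fc <- rep(1, ng)
      at_stage <- de_idx[de_stage == ti]
      if (length(at_stage) && sp == "A") {
        de_fc[at_stage] <- 2^(truth_expr$de_log2fc[at_stage])
      }
      mu_gene <- base * eff * de_fc
      for (e in seq_len(config$embryos_per_tissue)) {
        eid <- paste(sp, ti, paste0("E", e), sep = "_")
        for (cc in seq_len(config$cells_per_embryo)) {
          ci <- ci + 1L
          lib <- stats::rlnorm(1L, 0, config$libsize_sdlog)
          cells[[ci]] <- stats::rnbinom(ng, mu = mu_gene * lib,
                                        size = config$dispersion)
          metas[[ci]] <- data.frame(cell_id = paste0(eid, "_c", cc),
                                    embryo_id = eid, tissue = ti,
                                    species = sp, stringsAsFactors = FALSE)
        }
      }
    }
  }
  counts <- do.call(cbind, cells)
  cell_meta <- do.call(rbind, metas)
  dimnames(counts) <- list(genes, cell_meta$cell_id)
  list(counts = counts, cell_meta = cell_meta, truth_expr = truth_expr)
}
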