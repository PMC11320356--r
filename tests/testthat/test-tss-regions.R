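# small helpers to build annotations in code
ann_row <- function(gene, tx, chrom, strand, start, end,
                    biotype = "protein_coding") {
  data.frame(gene_id = gene, transcript_id = tx, chrom = chrom,
             strand = strand, start = start, end = end, biotype = biotype,
             stringsAsFactors = FALSE)
}

test_that("the TSS is the 5' end of a protein-coding transcript", {
  ann <- rbind(ann_row("g1", "t1", "chr1", "+", 5000, 7000),
               ann_row("g2", "t2", "chr1", "-", 5000, 7000),
               ann_row("g3", "t3", "chr1", "+", 100, 200, biotype = "lincRNA"))
  tss <- extract_tss(ann)
  expect_equal(tss$tss_pos, c(5000, 7000))
  expect_equal(tss$gene_id, c("g1", "g2"))
  expect_error(extract_tss(ann_row("g", "t", "chr1", "*", 1, 2)),
               "strand")
})

test_that("GTF and TSV annotation inputs agree", {
  skip_if_not_installed("rtracklayer")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\ttranscript\t5000\t7000\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";'),
    paste0("chr1\tsrc\ttranscript\t9000\t9500\t.\t-\t.\t",
           'gene_id "g2"; transcript_id "t2"; transcript_biotype "lincRNA";')),
    gtf)
  ann <- read_transcript_annotation(gtf)
  tss <- extract_tss(ann)
  expect_equal(tss$gene_id, "g1")
  expect_equal(tss$tss_pos, 5000)
})

test_that("the 2-kb ambiguity rule removes conflicting genes symmetrically", {
  ann <- rbind(ann_row("gA", "tA", "chr1", "+", 10000, 11000),
               ann_row("gB", "tB", "chr1", "+", 11500, 12500))
  tss <- extract_tss(ann)
  expect_equal(nrow(filter_ambiguous_tss(tss)), 0L)    # 1500 < 2000: both go

  # same-gene alternative TSS never conflict
  ann2 <- rbind(ann_row("gA", "tA1", "chr1", "+", 10000, 12000),
                ann_row("gA", "tA2", "chr1", "+", 11000, 12000))
  expect_equal(nrow(filter_ambiguous_tss(extract_tss(ann2))), 2L)

  # boundary: exactly min_sep apart is retained
  ann3 <- rbind(ann_row("gA", "tA", "chr1", "+", 10000, 11000),
                ann_row("gB", "tB", "chr1", "+", 12000, 13000))
  expect_equal(nrow(filter_ambiguous_tss(extract_tss(ann3))), 2L)
})

test_that("ambiguity filtering matches an all-pairs brute-force oracle", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 100
    tss <- data.frame(
      gene_id = paste0("g", sample.int(60, n, replace = TRUE)),
      transcript_id = paste0("t", seq_len(n)),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      strand = "+",
      tss_pos = sample.int(60000, n), stringsAsFactors = FALSE)
    kept <- filter_ambiguous_tss(tss)
    drop <- vapply(seq_len(n), function(i) {
      any(tss$chrom == tss$chrom[i] & tss$gene_id != tss$gene_id[i] &
            abs(tss$tss_pos - tss$tss_pos[i]) < 2000)
    }, TRUE)
    expect_setequal(kept$transcript_id, tss$transcript_id[!drop])
  }
})

test_that("regions span tss +/- flank and CpG counting respects bounds", {
  tss <- data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
                    strand = "+", tss_pos = 5000)
  reg <- tss_regions(tss)
  expect_equal(reg$end - reg$start, 2001)
  mm <- list(sites = data.frame(chrom = "chr1",
                                pos = c(3999, 4000, 6000, 6001)),
             samples = "S1",
             meth = matrix(1L, 4, 1), total = matrix(2L, 4, 1))
  class(mm) <- "MethylationMatrix"
  counted <- count_region_cpgs(reg, mm)
  expect_equal(counted$n_cpgs, 2L)     # 4000 and 6000 inside, ends excluded
})

test_that("per-gene region selection maximizes measured CpGs with a
           deterministic tie-break", {
  reg <- data.frame(gene_id = c("g1", "g1", "g2", "g3", "g3"),
                    transcript_id = c("t1", "t2", "t3", "t5", "t4"),
                    chrom = "chr1", strand = "+",
                    tss_pos = c(1e4, 2e4, 3e4, 4e4, 4e4),
                    start = c(1e4, 2e4, 3e4, 4e4, 4e4) - 1001,
                    end = c(1e4, 2e4, 3e4, 4e4, 4e4) + 1000,
                    n_cpgs = c(5L, 9L, 0L, 3L, 3L),
                    stringsAsFactors = FALSE)
  sel <- select_gene_region(reg)
  expect_equal(sel$transcript_id[sel$gene_id == "g1"], "t2")  # argmax
  expect_false("g2" %in% sel$gene_id)                         # 0 CpGs
  expect_equal(sel$transcript_id[sel$gene_id == "g3"], "t4")  # id tie-break
})

test_that("aggregation equals both the pooled-count ratio and the
           coverage-weighted mean of per-CpG betas", {
  reg <- data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
                    strand = "+", tss_pos = 5000, start = 3999, end = 6000,
                    n_cpgs = 2L, stringsAsFactors = FALSE)
  mm <- list(sites = data.frame(chrom = "chr1", pos = c(4500, 5500)),
             samples = "X",
             meth = matrix(c(2L, 8L), 2, 1),
             total = matrix(c(10L, 10L), 2, 1))
  class(mm) <- "MethylationMatrix"
  rm <- aggregate_region_methylation(reg, mm)
  expect_equal(unname(rm$beta[1, 1]), 0.5)

  # single CpG (0, 7)
  mm$sites <- data.frame(chrom = "chr1", pos = 5000)
  mm$meth <- matrix(0L, 1, 1); mm$total <- matrix(7L, 1, 1)
  reg$n_cpgs <- 1L
  rm <- aggregate_region_methylation(reg, mm)
  expect_equal(unname(rm$beta[1, 1]), 0)
  expect_equal(unname(rm$mean_coverage[1, 1]), 7)

  # random 12-CpG region, 6 samples: two-formula agreement
  set.seed(5)
  total <- matrix(1L + rpois(72, 15), 12, 6)
  meth <- matrix(rbinom(72, as.vector(total), 0.3), 12, 6)
  mm <- list(sites = data.frame(chrom = "chr1", pos = 4100 + 1:12),
             samples = paste0("S", 1:6), meth = meth, total = total)
  class(mm) <- "MethylationMatrix"
  reg$n_cpgs <- 12L
  rm <- aggregate_region_methylation(reg, mm)
  weighted <- colSums((meth / total) * total) / colSums(total)
  expect_equal(unname(rm$beta[1, ]), unname(weighted), tolerance = 1e-14)
  # conservation: beta * pooled total = pooled meth, exactly
  expect_equal(unname(rm$beta[1, ]) * colSums(total), colSums(meth))
})

test_that("the coverage and variability filters use every sample", {
  mk_rm <- function(beta, cov) {
    structure(list(
      regions = data.frame(gene_id = paste0("g", seq_len(nrow(beta))),
                           n_cpgs = 2L),
      beta = beta, mean_coverage = cov,
      min_coverage = cov, samples = paste0("S", seq_len(ncol(beta)))),
      class = "RegionMethylation")
  }
  rm <- mk_rm(matrix(c(0.1, 0.2, 0.3), 1), matrix(c(6, 6, 4.9), 1))
  expect_equal(nrow(filter_regions(rm)$regions), 0L)   # one sample below 5
  rm <- mk_rm(matrix(0.4, 1, 3), matrix(10, 1, 3))
  expect_equal(nrow(filter_regions(rm)$regions), 0L)   # zero variance

  set.seed(6)
  n <- 500
  beta <- matrix(runif(n * 4), n, 4)
  beta[sample.int(n, 20), ] <- 0.5                      # constant rows
  cov <- matrix(runif(n * 4, 2, 12), n, 4)
  rm <- mk_rm(beta, cov)
  kept <- filter_regions(rm, min_cov = 5)
  oracle <- vapply(seq_len(n), function(i) {
    all(cov[i, ] >= 5) && stats::var(beta[i, ]) > 0
  }, TRUE)
  expect_equal(kept$regions$gene_id, paste0("g", which(oracle)))
})

test_that("the full region build matches a brute-force implementation on
           small synthetic cohorts", {
  set.seed(71)
  cfg <- methylome_sim_config(n_genes = 40, n_samples_a = 4, n_samples_b = 3,
                              ages_b = 1:3, n_a_specific = 2,
                              n_b_specific = 2, n_decoy_conflicts = 3,
                              frac_multi_tss = 0.3, seed = 71)
  sim <- simulate_methylomes(cfg)
  sp <- sim$species_a
  mm <- merge_common_sites(sp$tables, sp$metadata)
  built <- build_tss_methylation(sp$annotation, mm)
  oracle <- brute_region_build(sp$annotation, sp$tables, sp$metadata)
  expect_setequal(built$regions$gene_id, names(oracle))
  for (g in names(oracle)) {
    i <- match(g, built$regions$gene_id)
    expect_equal(built$regions$transcript_id[i], oracle[[g]]$transcript_id)
    expect_equal(built$regions$n_cpgs[i], oracle[[g]]$n_cpgs)
    expect_equal(unname(built$beta[i, ]), oracle[[g]]$beta,
                 tolerance = 1e-12)
    expect_equal(unname(built$mean_coverage[i, ]), oracle[[g]]$cov,
                 tolerance = 1e-12)
  }
})

test_that("region building is deterministic", {
  cfg <- methylome_sim_config(n_genes = 30, n_samples_a = 3, n_samples_b = 3,
                              ages_b = 1:3, n_a_specific = 1,
                              n_b_specific = 1, seed = 5)
  sim <- simulate_methylomes(cfg)
  mm <- merge_common_sites(sim$species_a$tables, sim$species_a$metadata)
  b1 <- build_tss_methylation(sim$species_a$annotation, mm)
  b2 <- build_tss_methylation(sim$species_a$annotation, mm)
  expect_identical(b1$beta, b2$beta)
  expect_identical(b1$regions, b2$regions)
})
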