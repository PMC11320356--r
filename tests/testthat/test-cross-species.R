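make_rm <- function(genes, beta) {
  structure(list(regions = data.frame(gene_id = genes,
                                      n_cpgs = 5L,
                                      stringsAsFactors = FALSE),
                 beta = matrix(beta, nrow = length(genes),
                               dimnames = list(genes, NULL)),
                 mean_coverage = matrix(10, length(genes),
                                        ncol(as.matrix(beta))),
                 min_coverage = matrix(10, length(genes),
                                       ncol(as.matrix(beta))),
                 samples = paste0("S", seq_len(ncol(as.matrix(beta))))),
            class = "RegionMethylation")
}

test_that("orthologue maps are filtered to unique high-confidence one2one
           pairs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\thomology_type\tconfidence",
               "a1\tb1\tortholog_one2one\thigh",
               "a2\tb2\tortholog_one2one\thigh",
               "a3\tb3\tortholog_one2many\thigh",
               "a4\tb4\tortholog_one2one\tlow",
               "a5\tb5\tortholog_one2one\thigh"), f)
  om <- load_orthologue_map(f)
  expect_equal(om$gene_a, c("a1", "a2", "a5"))
  om2 <- load_orthologue_map(f, require_high_confidence = FALSE)
  expect_equal(nrow(om2), 4L)

  writeLines(c("gene_a\tgene_b\thomology_type\tconfidence",
               "a1\tb1\tortholog_one2one\thigh",
               "a1\tb2\tortholog_one2one\thigh"), f)
  expect_error(load_orthologue_map(f), "a1")

  # randomized predicate oracle
  set.seed(9)
  n <- 500
  tab <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                    homology_type = sample(c("ortholog_one2one",
                                             "ortholog_one2many"), n,
                                           replace = TRUE, prob = c(.9, .1)),
                    confidence = sample(c("high", "low"), n, replace = TRUE,
                                        prob = c(.9, .1)))
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  om3 <- load_orthologue_map(f)
  keep <- tab$homology_type == "ortholog_one2one" & tab$confidence == "high"
  expect_equal(om3$gene_a, tab$gene_a[keep])
})

test_that("methylation joining is an inner join with per-species sample
           means", {
  rm_a <- make_rm(c("a1", "a2"), cbind(c(0, 0.9), c(0.02, 1), c(0.04, 0.95)))
  rm_b <- make_rm("b1", cbind(0.5, 0.6))
  pairs <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "bX"))
  tab <- join_methylation(pairs, rm_a, rm_b)
  expect_equal(nrow(tab), 1L)                       # a2/bX unmatched
  expect_equal(tab$mean_beta_a, 0.02)
  expect_equal(tab$mean_beta_b, 0.55)
  expect_equal(attr(tab, "n_unmatched"), 1L)

  # randomized nested-loop oracle
  set.seed(10)
  ga <- paste0("a", 1:50); gb <- paste0("b", 1:50)
  rm_a <- make_rm(sample(ga, 30), matrix(runif(30 * 4), 30))
  rm_b <- make_rm(sample(gb, 35), matrix(runif(35 * 4), 35))
  pairs <- data.frame(gene_a = ga, gene_b = gb)
  tab <- join_methylation(pairs, rm_a, rm_b)
  expected <- 0L
  for (i in seq_len(nrow(pairs))) {
    ia <- which(rm_a$regions$gene_id == pairs$gene_a[i])
    ib <- which(rm_b$regions$gene_id == pairs$gene_b[i])
    if (length(ia) && length(ib)) {
      expected <- expected + 1L
      j <- which(tab$gene_a == pairs$gene_a[i])
      expect_equal(tab$mean_beta_a[j], mean(rm_a$beta[ia, ]))
      expect_equal(tab$mean_beta_b[j], mean(rm_b$beta[ib, ]))
    }
  }
  expect_equal(nrow(tab), expected)
})

test_that("Pearson correlation and its t-based p match the reference", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$rho, 1)
  y <- c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1)   # orthogonal to centered x?
  y <- y - mean(y)
  y <- y - sum(y * (x - mean(x))) / sum((x - mean(x))^2) * (x - mean(x))
  expect_lt(abs(pearson_correlation(x, y)$rho), 1e-12)
  expect_error(pearson_correlation(x, rep(1, 10)), "variance")
  expect_error(pearson_correlation(x, 1:9), "equal length")

  set.seed(11)
  a <- rnorm(200); b <- 0.6 * a + rnorm(200)
  mine <- pearson_correlation(a, b)
  ref <- cor.test(a, b)
  expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  # invariance to row order
  o <- sample.int(200)
  expect_equal(pearson_correlation(a[o], b[o])$rho, mine$rho,
               tolerance = 1e-12)
})

test_that("bimodal classification uses strict thresholds", {
  expect_equal(classify_bimodal(c(0.049, 0.05, 0.951, 0.95, 0.5)),
               c("hypo", "intermediate", "hyper", "intermediate",
                 "intermediate"))
  expect_error(classify_bimodal(0.5, lo = 0.9, hi = 0.1), "smaller")
  expect_error(classify_bimodal(1.5), "0, 1")

  # planted-class fixture: recovered counts equal planted counts
  set.seed(12)
  n <- 10000
  cls <- sample(c("hypo", "hyper", "intermediate"), n, replace = TRUE,
                prob = c(0.76, 0.063, 0.177))
  mb <- numeric(n)
  mb[cls == "hypo"] <- runif(sum(cls == "hypo"), 0, 0.0499)
  mb[cls == "hyper"] <- runif(sum(cls == "hyper"), 0.9501, 1)
  mb[cls == "intermediate"] <- runif(sum(cls == "intermediate"), 0.05, 0.95)
  expect_equal(as.vector(table(classify_bimodal(mb))[c("hypo", "hyper",
                                                       "intermediate")]),
               as.vector(table(cls)[c("hypo", "hyper", "intermediate")]))
})

test_that("species-specific sets partition discordant extremes and are
           antisymmetric", {
  tab <- data.frame(gene_a = c("a1", "a2", "a3"),
                    gene_b = c("b1", "b2", "b3"),
                    mean_beta_a = c(0.01, 0.01, 0.99),
                    mean_beta_b = c(0.99, 0.5, 0.01))
  tab$class_a <- classify_bimodal(tab$mean_beta_a)
  tab$class_b <- classify_bimodal(tab$mean_beta_b)
  tab$concordance <- c("a_specific_hypo", "other", "b_specific_hypo")
  sets <- species_specific_sets(tab)
  expect_equal(sets$a_specific_hypo, "a1")   # (hypo, hyper)
  expect_equal(sets$b_specific_hypo, "b3")
  # (hypo, intermediate) is in neither list
  expect_false("a2" %in% c(sets$a_specific_hypo, sets$b_specific_hypo))

  # antisymmetry under swapping species labels
  swapped <- data.frame(gene_a = tab$gene_b, gene_b = tab$gene_a,
                        mean_beta_a = tab$mean_beta_b,
                        mean_beta_b = tab$mean_beta_a)
  swapped$class_a <- classify_bimodal(swapped$mean_beta_a)
  swapped$class_b <- classify_bimodal(swapped$mean_beta_b)
  swapped$concordance <- ifelse(
    swapped$class_a == "hypo" & swapped$class_b == "hyper",
    "a_specific_hypo",
    ifelse(swapped$class_a == "hyper" & swapped$class_b == "hypo",
           "b_specific_hypo", "other"))
  sets2 <- species_specific_sets(swapped)
  expect_equal(sets2$a_specific_hypo, sets$b_specific_hypo)
  expect_equal(sets2$b_specific_hypo, sets$a_specific_hypo)
})

test_that("class categories always partition the joined pairs", {
  set.seed(13)
  rm_a <- make_rm(paste0("a", 1:200), matrix(runif(600), 200))
  rm_b <- make_rm(paste0("b", 1:200), matrix(runif(600), 200))
  pairs <- data.frame(gene_a = paste0("a", 1:200),
                      gene_b = paste0("b", 1:200))
  tab <- join_methylation(pairs, rm_a, rm_b)
  expect_equal(sum(table(tab$class_a)), nrow(tab))
  expect_equal(sum(tab$concordance %in%
                     c("both_hypo", "both_hyper", "a_specific_hypo",
                       "b_specific_hypo", "other")), nrow(tab))
})

test_that("age-effect comparison counts shared significance and pairs
           coefficients", {
  ta <- data.frame(region = paste0("a", 1:6),
                   beta_hat = c(1, 1, -1, 0.5, 0, 0),
                   significant = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  tb <- data.frame(region = paste0("b", 1:6),
                   beta_hat = c(0, 1, 1, -0.5, 0, 1),
                   significant = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE))
  pairs <- data.frame(gene_a = paste0("a", 1:6), gene_b = paste0("b", 1:6))
  cmp <- compare_age_effects(ta, tb, pairs)
  expect_equal(cmp$n_both_significant, 1L)
  expect_equal(cmp$n_significant_a, 2L)
  expect_equal(nrow(cmp$pairs), 6L)

  # disjoint significance sets give zero overlap
  tb$significant <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  ta$significant <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(compare_age_effects(ta, tb, pairs)$n_both_significant, 0L)
})
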