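# Independent oracle implementations used across the suite. These are kept
# deliberately naive (plain loops, no shared code with the package
# internals) so agreement is a genuine dual-route check.

# line-by-line coverage parser
oracle_parse_coverage <- function(path, min_total = 1) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    data.frame(chrom = f[1], pos = as.integer(f[2]),
               meth = as.integer(round(as.numeric(f[5]))),
               total = as.integer(round(as.numeric(f[5]) +
                                          as.numeric(f[6]))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$total >= min_total, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# set-algebra intersection of site keys
oracle_common_keys <- function(tables) {
  keys <- lapply(tables, function(t) paste(t$chrom, t$pos))
  common <- keys[[1]]
  for (k in keys[-1]) common <- common[common %in% k]
  common
}

# brute-force full region build: ambiguity filter by all-pairs scan,
# per-gene argmax selection, pooled-count aggregation, coverage/variance
# filter; returns a named list per retained gene
brute_region_build <- function(annotation, tables, metadata, flank = 1000,
                               min_sep = 2000, min_cov = 5) {
  ids <- metadata$sample_id
  common <- oracle_common_keys(tables[ids])
  t1 <- tables[[ids[1]]]
  idx <- match(common, paste(t1$chrom, t1$pos))
  sites <- data.frame(chrom = t1$chrom[idx], pos = t1$pos[idx],
                      stringsAsFactors = FALSE)
  meth <- matrix(0L, nrow(sites), length(ids))
  total <- matrix(0L, nrow(sites), length(ids))
  for (j in seq_along(ids)) {
    tj <- tables[[ids[j]]]
    i <- match(common, paste(tj$chrom, tj$pos))
    meth[, j] <- tj$meth[i]
    total[, j] <- tj$total[i]
  }
  ann <- annotation[annotation$biotype == "protein_coding", , drop = FALSE]
  tss <- ifelse(ann$strand == "+", ann$start, ann$end)
  drop <- rep(FALSE, nrow(ann))
  for (i in seq_len(nrow(ann))) {
    for (j in seq_len(nrow(ann))) {
      if (i != j && ann$chrom[i] == ann$chrom[j] &&
          ann$gene_id[i] != ann$gene_id[j] &&
          abs(tss[i] - tss[j]) < min_sep) {
        drop[i] <- TRUE
      }
    }
  }
  ann <- ann[!drop, , drop = FALSE]
  tss <- tss[!drop]
  ncp <- vapply(seq_len(nrow(ann)), function(i) {
    sum(sites$chrom == ann$chrom[i] & sites$pos >= tss[i] - flank &
          sites$pos <= tss[i] + flank)
  }, 0L)
  res <- list()
  for (g in sort(unique(ann$gene_id))) {
    gi <- which(ann$gene_id == g)
    best <- max(ncp[gi])
    if (best == 0L) next
    cand <- gi[ncp[gi] == best]
    cand <- cand[order(tss[cand], ann$transcript_id[cand])][1]
    sel <- which(sites$chrom == ann$chrom[cand] &
                   sites$pos >= tss[cand] - flank &
                   sites$pos <= tss[cand] + flank)
    beta <- colSums(meth[sel, , drop = FALSE]) /
      colSums(total[sel, , drop = FALSE])
    covg <- colSums(total[sel, , drop = FALSE]) / length(sel)
    if (all(is.finite(beta)) && all(covg >= min_cov) &&
        stats::var(beta) > 0) {
      res[[g]] <- list(transcript_id = ann$transcript_id[cand],
                       tss = tss[cand], n_cpgs = best, beta = unname(beta),
                       cov = unname(covg))
    }
  }
  res
}

# Procrustes residual: best similarity transform (rotation/reflection +
# translation + scale) of Y onto X, returning the RMS residual
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% t(s$u)
  scale_f <- sum(s$d) / sum(Yc^2)
  sqrt(mean((Xc - scale_f * Yc %*% R)^2))
}

# hypergeometric upper tail by direct summation of binomial coefficients
enum_hypergeom_p <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# exact Wilcoxon p by enumeration over all group assignments
enum_wilcox_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  w_all <- apply(combs, 2L, function(i) sum(r[i]) - n * (n + 1) / 2)
  switch(alternative,
         less = mean(w_all <= w_obs),
         greater = mean(w_all >= w_obs),
         two.sided = min(1, 2 * min(mean(w_all <= w_obs),
                                    mean(w_all >= w_obs))))
}

# small random single-sample site table
random_site_table <- function(n, chroms = c("chr1", "chr2")) {
  pos <- sample.int(1e6, n)
  tab <- data.frame(chrom = sample(chroms, n, replace = TRUE), pos = pos,
                    meth = 0L, total = 1L + stats::rpois(n, 20),
                    stringsAsFactors = FALSE)
  tab$meth <- stats::rbinom(n, tab$total, stats::runif(n))
  tab <- tab[!duplicated(paste(tab$chrom, tab$pos)), , drop = FALSE]
  tab[order(tab$chrom, tab$pos), , drop = FALSE]
}
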