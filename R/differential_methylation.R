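#' Beta-to-M transformation
#'
#' Maps methylation beta values (proportions in \[0, 1\]) to the
#' variance-stabilized M scale, `M = log2(b / (1 - b))`, after clamping
#' `b` into `[epsilon, 1 - epsilon]` so fully (un)methylated regions keep
#' finite leverage.
#'
#' @param beta Numeric vector or matrix of beta values in \[0, 1\].
#' @param epsilon Clamp parameter, `0 < epsilon < 0.5` (default 0.01).
#' @return M-values, same shape as `beta`.
#' @examples
#' beta_to_m(c(0, 0.5, 1))
#' @export
beta_to_m <- function(beta, epsilon = 0.01) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 0.5) {
    stop("'epsilon' must be a single number in (0, 0.5)")
  }
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Inverse of the M transformation
#'
#' @param m M-values.
#' @return Beta values `2^m / (1 + 2^m)`.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Per-region linear age model on the M scale
#'
#' Ordinary least squares of each region's M-value row on `[1, age]`. The
#' returned pieces are exactly what the moderated t needs: the age
#' coefficient, the residual variance `s2 = RSS / d` with `d = n - 2`
#' residual degrees of freedom, and the unscaled variance multiplier of the
#' age coefficient, `v11 = 1 / sum((age - mean(age))^2)`.
#'
#' @param M Regions x samples numeric matrix of M-values (rownames = region
#'   ids).
#' @param ages Numeric vector of donor ages in years, one per column of `M`.
#' @return `data.frame` (class `age_fit`) with `region`, `beta_hat`,
#'   `intercept`, `s2`; attributes `d` (residual df) and `v11`.
#' @export
fit_age_model <- function(M, ages) {
  M <- as.matrix(M)
  n <- ncol(M)
  if (n < 3L) stop("need at least 3 samples to fit the age model")
  if (length(ages) != n) stop("'ages' must have one entry per sample")
  if (isTRUE(all.equal(stats::var(ages), 0)) || stats::var(ages) == 0) {
    stop("ages are constant; the age coefficient is not identifiable")
  }
  xc <- ages - mean(ages)
  sxx <- sum(xc^2)
  beta_hat <- as.vector(M %*% xc) / sxx
  intercept <- rowMeans(M) - beta_hat * mean(ages)
  fitted <- outer(beta_hat, ages) + intercept
  rss <- rowSums((M - fitted)^2)
  d <- n - 2L
  out <- data.frame(region = if (!is.null(rownames(M))) rownames(M) else
    as.character(seq_len(nrow(M))),
    beta_hat = beta_hat, intercept = intercept,
    s2 = pmax(rss / d, 0), stringsAsFactors = FALSE)
  class(out) <- c("age_fit", "data.frame")
  attr(out, "d") <- d
  attr(out, "v11") <- 1 / sxx
  out
}

# Newton inversion of the trigamma function (solve trigamma(y) = x, x > 0)
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (iter in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Estimate empirical-Bayes variance moderation hyperparameters
#'
#' Moment matching on log residual variances: with
#' `e = log(s2) - digamma(d/2) + log(d/2)`, the prior degrees of freedom
#' `d0` solve `trigamma(d0/2) = var(e) - trigamma(d/2)` (monotone
#' root-finding via the trigamma inverse) and the prior variance is
#' `s02 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the observed
#' spread of log variances is no larger than expected from sampling alone
#' (`var(e) <= trigamma(d/2)`), `d0` is infinite and `s02 = exp(mean(e))`.
#' Regions with `s2 = 0` (perfect fits) are excluded from estimation; their
#' count is reported as attribute `"n_zero"`.
#'
#' @param s2 Residual variances.
#' @param d Residual degrees of freedom (scalar).
#' @return List with `d0` (possibly `Inf`) and `s02`.
#' @export
estimate_moderation <- function(s2, d) {
  pos <- s2[s2 > 0 & is.finite(s2)]
  n_zero <- sum(s2 == 0, na.rm = TRUE)
  if (length(pos) == 0L) stop("all residual variances are zero")
  if (length(pos) < 10L) {
    warning("fewer than 10 positive residual variances; ",
            "hyperparameter estimates will be unstable")
  }
  z <- log(pos)
  e <- z - digamma(d / 2) + log(d / 2)
  ve <- stats::var(e)
  rhs <- ve - trigamma(d / 2)
  if (!is.finite(rhs) || rhs <= 0) {
    out <- list(d0 = Inf, s02 = exp(mean(e)))
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    out <- list(d0 = d0, s02 = s02)
  }
  attr(out, "n_zero") <- n_zero
  out
}

#' Moderated t-statistics for the age coefficient
#'
#' Shrinks each region's residual variance toward the prior,
#' `s2_post = (d0 * s02 + d * s2) / (d0 + d)` (equal to `s02` when `d0` is
#' infinite), and tests the age coefficient with
#' `t = beta_hat / sqrt(s2_post * v11)` on `d + d0` degrees of freedom
#' (standard normal in the infinite-prior limit). Two-sided p-values.
#'
#' @param fit An `age_fit` from [fit_age_model()].
#' @param params Moderation hyperparameters from [estimate_moderation()].
#' @return `data.frame` with `region`, `beta_hat`, `t_mod`, `df_total`, `p`.
#' @export
moderated_t <- function(fit, params) {
  d <- attr(fit, "d")
  v11 <- attr(fit, "v11")
  d0 <- params$d0
  s02 <- params$s02
  s2_post <- if (is.infinite(d0)) rep(s02, nrow(fit)) else
    (d0 * s02 + d * fit$s2) / (d0 + d)
  t_mod <- fit$beta_hat / sqrt(s2_post * v11)
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(region = fit$region, beta_hat = fit$beta_hat, t_mod = t_mod,
             df_total = df_total, p = p, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_p(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1 and mapped back to
#' the input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

#' Call age-related differentially methylated TSS regions
#'
#' Applies BH adjustment, flags regions significant at `alpha` (strict
#' `adj_p < alpha`) and assigns a direction: methylation `gain` with age for
#' a positive age coefficient, `loss` otherwise.
#'
#' @param tab Moderated-t table from [moderated_t()].
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @return `data.frame` (class `age_tss`) adding `adj_p`, `significant`,
#'   `direction`; attribute `"summary"` holds the call counts and per-
#'   direction percentages.
#' @export
call_age_tss <- function(tab, alpha = 0.05) {
  tab$adj_p <- adjust_bh(tab$p)
  tab$significant <- tab$adj_p < alpha
  tab$direction <- ifelse(tab$beta_hat > 0, "gain", "loss")
  n_sig <- sum(tab$significant)
  n_gain <- sum(tab$significant & tab$direction == "gain")
  smry <- c(n_regions = nrow(tab), n_significant = n_sig,
            n_gain = n_gain, n_loss = n_sig - n_gain,
            pct_gain = if (n_sig > 0) 100 * n_gain / n_sig else NA_real_)
  class(tab) <- c("age_tss", "data.frame")
  attr(tab, "summary") <- smry
  attr(tab, "alpha") <- alpha
  tab
}

#' @export
print.age_tss <- function(x, ...) {
  s <- attr(x, "summary")
  cat("ageTSS calls:", s[["n_significant"]], "of", s[["n_regions"]],
      "regions significant (BH-adjusted p <", attr(x, "alpha"), ")\n")
  if (s[["n_significant"]] > 0) {
    cat(sprintf("  gain %d (%.1f%%), loss %d (%.1f%%)\n", s[["n_gain"]],
                s[["pct_gain"]], s[["n_loss"]], 100 - s[["pct_gain"]]))
  }
  invisible(x)
}

#' Select the top variant regions
#'
#' Ranks regions by the sample variance of their M-values across the entire
#' cohort (age-blind) and returns the `k` most variable region ids; ties are
#' broken by region id.
#'
#' @param M Regions x samples M-value matrix with rownames.
#' @param k Number of regions (default 1000).
#' @return Character vector of `k` region ids.
#' @export
top_variant_regions <- function(M, k = 1000) {
  if (k > nrow(M)) stop("k (", k, ") exceeds the number of regions (",
                        nrow(M), ")")
  v <- apply(M, 1L, stats::var)
  ids <- rownames(M)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(M)))
  ids[order(-v, ids)][seq_len(k)]
}

#' Classical multidimensional scaling of samples
#'
#' Principal-coordinates analysis of the pairwise Euclidean distances
#' between sample columns of an M-value matrix (double-centering of the
#' squared distance matrix; negative eigenvalues truncated to zero). Used
#' on the top variant regions for cohort ordination.
#'
#' @param M Regions x samples M-value matrix (typically restricted to the
#'   top variant regions).
#' @param k Number of output axes (default 2).
#' @return List (class `mds_result`) with `points` (samples x k, centered
#'   per axis), `eig` (eigenvalues, non-negative), `region_ids`.
#' @export
classical_mds <- function(M, k = 2) {
  n <- ncol(M)
  if (n < 3L) stop("need at least 3 samples for MDS")
  d <- stats::dist(t(M))
  if (all(d < .Machine$double.eps^0.5)) {
    warning("all samples are identical; MDS coordinates are zero")
    pts <- matrix(0, n, k, dimnames = list(colnames(M), NULL))
    return(structure(list(points = pts, eig = rep(0, n),
                          region_ids = rownames(M)), class = "mds_result"))
  }
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {           # degenerate: pad collapsed axes with zeros
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  rownames(pts) <- colnames(M)
  structure(list(points = pts, eig = pmax(fit$eig, 0),
                 region_ids = rownames(M)), class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  ev <- x$eig[x$eig > 0]
  cat("Classical MDS:", nrow(x$points), "samples,",
      ncol(x$points), "axes\n")
  if (length(ev)) {
    cat("  variance explained by axes:",
        paste0(round(100 * x$eig[seq_len(ncol(x$points))] / sum(ev), 1),
               "%", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.mds_result <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) "black" else as.integer(factor(groups)) + 1L
  graphics::plot(x$points[, 1L], x$points[, 2L], col = col, pch = 19,
                 xlab = "MDS axis 1", ylab = "MDS axis 2", ...)
  invisible(x)
}

#' Full age differential methylation stage
#'
#' Composes the M transform, per-region OLS age fit, empirical-Bayes
#' moderation, moderated t, BH adjustment and ageTSS calling.
#'
#' @param rm A filtered `RegionMethylation`.
#' @param ages Donor ages in years (one per sample).
#' @param epsilon M-transform clamp (default 0.01).
#' @param alpha BH significance threshold (default 0.05).
#' @return An `age_tss` table; attribute `"moderation"` holds the estimated
#'   hyperparameters, `"M"` the M-value matrix.
#' @export
run_age_analysis <- function(rm, ages, epsilon = 0.01, alpha = 0.05) {
  M <- beta_to_m(rm$beta, epsilon = epsilon)
  fit <- fit_age_model(M, ages)
  params <- estimate_moderation(fit$s2, attr(fit, "d"))
  tab <- call_age_tss(moderated_t(fit, params), alpha = alpha)
  attr(tab, "moderation") <- params
  attr(tab, "M") <- M
  attr(tab, "fit") <- fit
  tab
}
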