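# Differential expression: a deliberately simple negative-binomial Wald
# test. Counts are normalised by median-of-ratios size factors, gene-wise
# dispersion comes from a method-of-moments estimate on normalised counts,
# and the Wald statistic is log2FC / SE(log2FC) under the NB variance
# model with a normal reference distribution. Heavier machinery (dispersion
# shrinkage, outlier filtering) is intentionally out of scope; any method
# that yields disjoint up/down gene lists can feed the downstream scoring.

#' Median-of-ratios size factors
#'
#' factor_j = median over reference genes g of count_gj / geomean_g, where
#' the reference set is the genes with nonzero counts in every sample.
#'
#' @param cm a [count_matrix()] or plain counts matrix.
#' @return Named numeric vector of per-sample size factors (all > 0).
#' @export
size_factors <- function(cm) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  all_nonzero <- rowSums(m == 0) == 0
  if (!any(all_nonzero))
    stop(paste("no gene has nonzero counts in all samples; a",
               "pseudo-reference fallback would be required"))
  ref <- m[all_nonzero, , drop = FALSE]
  log_geomean <- rowMeans(log(ref))
  sf <- apply(ref, 2, function(col) exp(stats::median(log(col) - log_geomean)))
  names(sf) <- colnames(m)
  sf
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up with monotonicity enforcement, capped at 1.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  adj
}

#' Build an up/down differential-expression signature from counts
#'
#' Per gene: normalise by [size_factors()], estimate a gene-wise NB
#' dispersion by method of moments on normalised counts (computed per
#' group, the larger estimate wins; floored at 1e-8),
#' compute log2 fold change from group means (pseudocount 0.5 replaces a
#' zero group mean), form a
#' Wald statistic log2FC / SE(log2FC) under the NB variance model, take a
#' two-sided p-value from the normal reference, and BH-adjust across all
#' tested genes. The signature is the genes with p_adj < alpha, split by
#' log2FC sign. Genes with all-zero counts are excluded before testing.
#'
#' @param cm a [count_matrix()].
#' @param treated,controls disjoint character vectors of sample ids, at
#'   least two samples each.
#' @param alpha FDR threshold for signature membership (default 0.05).
#' @param query_id identifier stored in the returned signature.
#' @return List with `signature` (a [query_signature()]) and `stats`
#'   (data.frame: gene, base_mean, log2fc, wald, p, p_adj).
#' @export
build_signature <- function(cm, treated, controls, alpha = 0.05,
                            query_id = "query") {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(intersect(treated, controls)))
    stop("treated and control sample sets overlap")
  if (length(treated) < 2 || length(controls) < 2)
    stop("need at least 2 samples per group")
  miss <- setdiff(c(treated, controls), colnames(cm$counts))
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))

  m <- cm$counts[, c(treated, controls), drop = FALSE]
  keep <- rowSums(m) > 0
  if (!any(keep)) stop("no gene with nonzero counts to test")
  m <- m[keep, , drop = FALSE]

  sf <- size_factors(count_matrix(m, cm$sample_meta[
    match(colnames(m), cm$sample_meta$sample), , drop = FALSE]))
  q <- sweep(m, 2, sf, "/")
  ti <- seq_along(treated)
  ci <- length(treated) + seq_along(controls)
  nT <- length(treated); nC <- length(controls)

  mu_t <- rowMeans(q[, ti, drop = FALSE])
  mu_c <- rowMeans(q[, ci, drop = FALSE])
  var_t <- apply(q[, ti, drop = FALSE], 1, stats::var)
  var_c <- apply(q[, ci, drop = FALSE], 1, stats::var)
  # method of moments per group; the larger estimate wins so that a small
  # treated group cannot understate the within-group variability
  disp_t <- (var_t - mu_t) / mu_t^2
  disp_c <- (var_c - mu_c) / mu_c^2
  disp <- pmax(disp_t, disp_c, 1e-8, na.rm = TRUE)
  mu_all <- rowMeans(q)

  # pseudocount 0.5 only where a group mean is zero, so the fold change of
  # ordinarily expressed genes is scale-invariant
  mu_t_ps <- ifelse(mu_t == 0, 0.5, mu_t)
  mu_c_ps <- ifelse(mu_c == 0, 0.5, mu_c)
  log2fc <- log2(mu_t_ps / mu_c_ps)
  # NB variance on the normalised scale: Var(K_j / s_j) = mu/s_j + disp*mu^2
  var_mean_t <- (mu_t_ps * sum(1 / sf[ti]) / nT^2) + disp * mu_t_ps^2 / nT
  var_mean_c <- (mu_c_ps * sum(1 / sf[ci]) / nC^2) + disp * mu_c_ps^2 / nC
  ln2 <- log(2)
  se2 <- var_mean_t / (mu_t_ps^2 * ln2^2) +
         var_mean_c / (mu_c_ps^2 * ln2^2)
  se <- sqrt(se2)
  wald <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(wald))
  p_adj <- bh_adjust(p)

  base_mean <- mu_all
  stats_df <- data.frame(gene = rownames(m), base_mean = base_mean,
                         log2fc = log2fc, wald = wald, p = p, p_adj = p_adj,
                         row.names = NULL, stringsAsFactors = FALSE)
  sig_genes <- stats_df$p_adj < alpha
  sig <- query_signature(query_id,
                         up = stats_df$gene[sig_genes & stats_df$log2fc > 0],
                         down = stats_df$gene[sig_genes & stats_df$log2fc < 0])
  list(signature = sig, stats = stats_df)
}
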