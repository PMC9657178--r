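## Negative-binomial Wald-test engine (median-of-ratios normalized).
##
## Estimates the mean-variance dependence first (moment dispersions shrunk
## towards a fitted a/mu + b trend in log space), then tests the log2 fold
## change of size-factor-normalized condition means with a delta-method
## standard error and a normal reference distribution.

#' Negative-binomial Wald test
#'
#' Condition means are means of size-factor-normalized counts (with the
#' engines' shared 0.5 pseudocount, so the fold change is always finite);
#' the variance of a normalized count is approximated by
#' `mu / s_i + phi * mu^2`, propagated to the log2 fold change by the
#' delta method. `z = log2fc / SE(log2fc)`, `p = 2 * pnorm(-|z|)`.
#'
#' @param ds a [harmonize()]d dataset.
#' @param disp optional `dispersion_model` over the filtered genes; by
#'   default estimated from MOR-normalized counts with trend shrinkage.
#' @param cpm_cut expression-filter CPM threshold.
#' @param w shrinkage weight when `disp` is estimated internally.
#' @return a `deg_result` data frame (`raw_score` = Wald p-value,
#'   `fdr` = BH-adjusted).
#' @export
nb_wald_test <- function(ds, disp = NULL, cpm_cut = 1, w = 0.7) {
  idx <- .cond_idx(ds)
  keep <- expression_filter(ds, cpm_cut)
  counts_f <- count_matrix(unclass(ds$counts)[keep, , drop = FALSE])
  factors <- size_factors_mor(counts_f)
  norm <- normalized_counts(counts_f, factors)
  if (is.null(disp))
    disp <- estimate_dispersion(norm, idx$ref, idx$trt, shrink = "trend", w = w)
  fc <- .log2fc_from_means(norm, idx$ref, idx$trt)

  sf <- factors$scale_factors
  pseudo <- 0.5
  var_of_mean <- function(mu, cols) {
    # Var(mean_c) = (1/n^2) * sum_i Var(y_i / s_i),
    # Var(y_i / s_i) ~ mu / s_i + phi * mu^2
    n <- length(cols)
    v <- outer(mu, 1 / sf[cols]) + disp$phi_shrunk * mu^2
    rowSums(v) / n^2
  }
  m_ref <- fc$mu_ref + pseudo
  m_trt <- fc$mu_trt + pseudo
  v_log2 <- (var_of_mean(m_ref, idx$ref) / m_ref^2 +
             var_of_mean(m_trt, idx$trt) / m_trt^2) / log(2)^2
  se <- sqrt(v_log2)
  z <- ifelse(se > 0, fc$log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  .deg_result("nb_wald", rownames(counts_f), fc$log2fc, p, bh_adjust(p))
}
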