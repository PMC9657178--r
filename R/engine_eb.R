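## Empirical-Bayes beta-negative-binomial mixture engine.
##
## Each gene's counts are NB(r_gj, q_g) with per-sample size r_gj scaled
## by the MOR size factor; the success probability q_g carries a Beta
## prior. Two hypotheses: equal expression (one shared Beta draw across
## all samples) vs differential expression (independent draws per
## condition). The Beta-NB marginals are closed-form via Beta functions;
## an EM over the mixture weight pi yields the posterior probability of
## differential expression (PPDE) per gene.

#' Empirical-Bayes posterior probability of differential expression
#'
#' Gene size parameters come from moments of the normalized counts
#' (`r_g = mu^2 / max(var - mu, eps)`); Beta hyperparameters `(alpha,
#' beta)` from pooled moments of the per-gene `q` estimates; the mixture
#' weight `pi` is estimated by EM on the marginal likelihoods with
#' deterministic initialization `pi = 0.5`. `raw_score = fdr = 1 - PPDE`.
#'
#' @param ds a [harmonize()]d dataset with at least one replicate per
#'   condition.
#' @param em_max_iter maximum EM iterations (default 100).
#' @param em_tol convergence tolerance on `pi` (default 1e-6).
#' @param pi_fixed optionally fix the mixture weight (skips the EM).
#' @param cpm_cut expression-filter CPM threshold.
#' @return a `deg_result` data frame (`log2fc` from MOR-normalized
#'   condition means with the shared 0.5 pseudocount).
#' @export
eb_test <- function(ds, em_max_iter = 100L, em_tol = 1e-6, pi_fixed = NULL,
                    cpm_cut = 1) {
  idx <- .cond_idx(ds)
  if (length(idx$ref) < 1L || length(idx$trt) < 1L)
    stop("empirical-Bayes engine needs both conditions", call. = FALSE)
  keep <- expression_filter(ds, cpm_cut)
  counts_f <- count_matrix(unclass(ds$counts)[keep, , drop = FALSE])
  factors <- size_factors_mor(counts_f)
  norm <- normalized_counts(counts_f, factors)
  fc <- .log2fc_from_means(norm, idx$ref, idx$trt)

  hyper <- eb_hyperparameters(norm, factors$scale_factors, idx)
  ll <- eb_marginal_loglik(unclass(counts_f), factors$scale_factors,
                           hyper$r, hyper$alpha, hyper$beta, idx)

  if (is.null(pi_fixed)) {
    pi_de <- 0.5
    for (it in seq_len(em_max_iter)) {
      ppde <- .posterior_de(ll, pi_de)
      pi_new <- mean(ppde)
      if (abs(pi_new - pi_de) < em_tol) {
        pi_de <- pi_new
        break
      }
      pi_de <- pi_new
      if (it == em_max_iter)
        warning("EM did not converge in ", em_max_iter,
                " iterations; using last iterate", call. = FALSE)
    }
  } else {
    pi_de <- pi_fixed
  }
  ppde <- .posterior_de(ll, pi_de)
  out <- .deg_result("eb", rownames(counts_f), fc$log2fc, 1 - ppde, 1 - ppde)
  attr(out, "pi_de") <- pi_de
  out
}

.posterior_de <- function(ll, pi_de) {
  if (pi_de <= 0) return(rep(0, nrow(ll)))
  if (pi_de >= 1) return(rep(1, nrow(ll)))
  num <- log(pi_de) + ll[, "de"]
  den <- log1p(-pi_de) + ll[, "ee"]
  1 / (1 + exp(den - num))
}

#' Moment estimates of the Beta-NB hyperparameters
#'
#' Per-gene NB size `r_g = mu^2 / max(var - mu, mu * 1e-3)` from
#' normalized-count moments (capped to keep Poisson-like genes finite);
#' per-gene `q_g = r_g / (r_g + mu_g)`; `(alpha, beta)` by matching the
#' mean and variance of a Beta distribution to the pooled `q_g` (variance
#' clamped into the feasible range).
#'
#' @param norm normalized count matrix (filtered genes).
#' @param sf per-sample size factors.
#' @param idx list with `ref` and `trt` column indices.
#' @return list with `r` (per gene), `alpha`, `beta`, `q` (per gene).
#' @export
eb_hyperparameters <- function(norm, sf, idx) {
  mu <- rowMeans(norm)
  # without any within-condition replicates fall back to Poisson moments
  v <- tryCatch(.pooled_var(norm, idx$ref, idx$trt), error = function(e) mu)
  r <- mu^2 / pmax(v - mu, mu * 1e-3)
  r <- pmin(pmax(r, 1e-2), 1e6)
  q <- r / (r + mu)
  m <- mean(q)
  s2 <- stats::var(q)
  # Beta feasibility: 0 < s2 < m (1 - m)
  s2 <- min(max(s2, 1e-8), 0.999 * m * (1 - m))
  k <- m * (1 - m) / s2 - 1
  list(r = r, alpha = m * k, beta = (1 - m) * k, q = q)
}

#' Beta-NB marginal log-likelihoods under EE and DE
#'
#' For a group of samples with counts `x_j` and sizes `r_gj = r_g * s_j`,
#' the Beta-NB marginal (up to the combinatorial constant, identical
#' under both hypotheses and therefore dropped) is
#' `Beta(alpha + sum r, beta + sum x) / Beta(alpha, beta)`. EE integrates
#' one shared `q` over all samples; DE uses independent `q` per condition.
#'
#' @param counts integer count matrix (filtered genes).
#' @param sf per-sample size factors.
#' @param r per-gene NB size parameters.
#' @param alpha,beta Beta hyperparameters.
#' @param idx list with `ref` and `trt` column indices.
#' @return matrix with columns `ee` and `de` of per-gene log-likelihoods
#'   (constants common to both hypotheses omitted).
#' @export
eb_marginal_loglik <- function(counts, sf, r, alpha, beta, idx) {
  grp <- function(cols) {
    sum_x <- rowSums(counts[, cols, drop = FALSE])
    sum_r <- r * sum(sf[cols])
    lbeta(alpha + sum_r, beta + sum_x) - lbeta(alpha, beta)
  }
  ll_ref <- grp(idx$ref)
  ll_trt <- grp(idx$trt)
  ll_all <- grp(c(idx$ref, idx$trt))
  out <- cbind(ee = ll_all, de = ll_ref + ll_trt)
  rownames(out) <- rownames(counts)
  out
}
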