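## Negative-binomial exact-test engine (TMM-normalized).
##
## Conditions on the library-size-equalized total count of each gene and
## enumerates all splits of that total between the two condition groups;
## group sums are modeled as negative binomial with means proportional to
## replicate numbers and dispersion scaled by replicate number. The
## two-sided p-value is the summed probability of all splits no more
## likely than the observed one (ties included; no doubling).

#' Negative-binomial exact test
#'
#' @param ds a [harmonize()]d dataset with at least one replicate per
#'   condition.
#' @param disp optional `dispersion_model` over the filtered genes; by
#'   default estimated from the TMM-normalized counts with shrinkage
#'   towards the common value (weight `w`).
#' @param cpm_cut expression-filter CPM threshold (see
#'   [expression_filter()]).
#' @param w shrinkage weight when `disp` is estimated internally.
#' @return a `deg_result` data frame: `gene`, `log2fc` (treatment over
#'   reference, TMM-normalized means + 0.5), `raw_score` (exact p-value),
#'   `fdr` (BH-adjusted), `status`.
#' @export
nb_exact_test <- function(ds, disp = NULL, cpm_cut = 1, w = 0.7) {
  idx <- .cond_idx(ds)
  if (length(idx$ref) < 1L || length(idx$trt) < 1L)
    stop("exact test needs at least one replicate per condition", call. = FALSE)
  keep <- expression_filter(ds, cpm_cut)
  counts <- unclass(ds$counts)[keep, , drop = FALSE]
  factors <- tmm_factors(ds$counts)
  norm <- normalized_counts(ds$counts, factors)[keep, , drop = FALSE]
  if (is.null(disp))
    disp <- estimate_dispersion(norm, idx$ref, idx$trt, shrink = "common", w = w)
  fc <- .log2fc_from_means(norm, idx$ref, idx$trt)

  n_ref <- length(idx$ref); n_trt <- length(idx$trt)
  # library-size-equalized group totals: normalized counts are already on
  # a common (geometric-mean) library scale, so their rounded group sums
  # play the role of equal-library pseudo-counts
  s_ref <- pmax(0, round(rowSums(norm[, idx$ref, drop = FALSE])))
  s_trt <- pmax(0, round(rowSums(norm[, idx$trt, drop = FALSE])))
  p <- vapply(seq_len(nrow(counts)), function(g) {
    exact_split_pvalue(s_ref[g], s_trt[g], n_ref, n_trt, disp$phi_shrunk[g])
  }, numeric(1))
  .deg_result("nb_exact", rownames(counts), fc$log2fc, p, bh_adjust(p))
}

#' Conditional exact NB p-value for one gene
#'
#' Two-sided conditional exact p-value for the split `(a_obs, b_obs)` of
#' total `s = a_obs + b_obs` between groups of `n_ref` and `n_trt`
#' replicates with NB dispersion `phi`. Under equal per-sample means the
#' group sums are NB with means proportional to replicate numbers and
#' size `n_c / phi`; conditioning on the total and summing the
#' probabilities of all splits no more likely than the observed one gives
#' the p-value. At `phi = 0` the conditional distribution is exactly
#' `Binomial(s, n_ref / (n_ref + n_trt))`.
#'
#' @param a_obs,b_obs observed (library-size-equalized) group totals.
#' @param n_ref,n_trt replicate numbers.
#' @param phi NB dispersion (`Var = mu + phi * mu^2`).
#' @return p-value in \[0, 1\].
#' @export
exact_split_pvalue <- function(a_obs, b_obs, n_ref, n_trt, phi) {
  s <- a_obs + b_obs
  if (s == 0) return(1)
  a <- 0:s
  pr <- n_ref / (n_ref + n_trt)
  if (phi < 1e-12) {
    # Poisson limit: conditional distribution is exactly binomial(s, pr)
    logp <- stats::dbinom(a, s, pr, log = TRUE)
  } else {
    mu_ref <- s * pr
    mu_trt <- s - mu_ref
    logp <- stats::dnbinom(a, size = n_ref / phi, mu = mu_ref, log = TRUE) +
      stats::dnbinom(s - a, size = n_trt / phi, mu = mu_trt, log = TRUE)
    logp <- logp - .logsumexp(logp)
  }
  obs <- logp[a_obs + 1L]
  # ties included; tolerance guards against floating-point ties
  min(1, sum(exp(logp[logp <= obs + 1e-12])))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
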