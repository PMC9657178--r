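## Nonparametric noise-distribution engine.
##
## Compares each gene's between-condition signal (M, D) with an empirical
## noise distribution of (M0, D0) values pooled over all within-condition
## replicate pairs and all genes. A gene's probability of differential
## expression is the fraction of noise points strictly dominated by its
## signal in both coordinates.

#' Nonparametric noise-distribution test
#'
#' Signal per gene: `M = log2(mean_trt / mean_ref)` and
#' `D = |mean_trt - mean_ref|` of CPM values computed with a prior count
#' of 0.5. Noise: for every within-condition pair of replicates, the
#' per-gene `(M0, D0)` of the same statistics between the two replicates,
#' pooled across pairs and genes. The probability of differential
#' expression is `P(|M0| < |M| and D0 < D)` over the pooled noise set;
#' `raw_score = fdr = 1 - probability`.
#'
#' @param ds a [harmonize()]d dataset; at least one condition must have
#'   two or more replicates.
#' @param cpm_cut expression-filter CPM threshold.
#' @param prior CPM prior count (default 0.5).
#' @return a `deg_result` data frame (`log2fc` = M).
#' @export
noise_test <- function(ds, cpm_cut = 1, prior = 0.5) {
  idx <- .cond_idx(ds)
  pairs <- c(.replicate_pairs(idx$ref), .replicate_pairs(idx$trt))
  if (!length(pairs))
    stop("nonparametric engine requires replicates in at least one condition",
         call. = FALSE)
  keep <- expression_filter(ds, cpm_cut)
  x <- cpm(ds$counts, prior = prior)[keep, , drop = FALSE]

  mu_ref <- rowMeans(x[, idx$ref, drop = FALSE])
  mu_trt <- rowMeans(x[, idx$trt, drop = FALSE])
  M <- log2(mu_trt / mu_ref)
  D <- abs(mu_trt - mu_ref)

  noise_absM <- numeric(0)
  noise_D <- numeric(0)
  for (p in pairs) {
    a <- x[, p[1L]]; b <- x[, p[2L]]
    noise_absM <- c(noise_absM, abs(log2(a / b)))
    noise_D <- c(noise_D, abs(a - b))
  }
  prob <- noise_probability(abs(M), D, noise_absM, noise_D)
  .deg_result("noise", rownames(x), M, 1 - prob, 1 - prob)
}

.replicate_pairs <- function(cols) {
  if (length(cols) < 2L) return(list())
  cmb <- utils::combn(cols, 2L)
  lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
}

#' Empirical probability of dominating the noise distribution
#'
#' For each signal point `(abs_m[g], d[g])`, the fraction of noise points
#' with `noise_abs_m < abs_m[g]` and `noise_d < d[g]` (both strict).
#'
#' @param abs_m,d signal coordinates (vectors of equal length).
#' @param noise_abs_m,noise_d pooled noise coordinates.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
noise_probability <- function(abs_m, d, noise_abs_m, noise_d) {
  n <- length(noise_abs_m)
  stopifnot(length(noise_d) == n, length(abs_m) == length(d))
  if (n == 0L) return(rep(0, length(abs_m)))
  # Sweep both sets in increasing |M0|, inserting passed noise points into
  # a Fenwick tree indexed by D0 rank; each signal then queries the count
  # of inserted points with D0 strictly below its D. O((n + G) log n).
  ord_noise <- order(noise_abs_m)
  nm <- noise_abs_m[ord_noise]
  nd <- noise_d[ord_noise]
  sorted_d <- sort(noise_d)
  pos_d <- rank(noise_d, ties.method = "first")[ord_noise]
  bit <- integer(n)
  bit_add <- function(i) {
    while (i <= n) {
      bit[i] <<- bit[i] + 1L
      i <- i + bitwAnd(i, -i)
    }
  }
  bit_sum <- function(i) {
    s <- 0L
    while (i > 0L) {
      s <- s + bit[i]
      i <- i - bitwAnd(i, -i)
    }
    s
  }
  ord_sig <- order(abs_m)
  res <- numeric(length(abs_m))
  pos <- 0L
  for (g in ord_sig) {
    while (pos < n && nm[pos + 1L] < abs_m[g]) {
      pos <- pos + 1L
      bit_add(pos_d[pos])
    }
    q <- findInterval(d[g], sorted_d, left.open = TRUE)  # noise D0 < D_g
    res[g] <- if (q > 0L) bit_sum(q) / n else 0
  }
  res
}
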