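## Library-size and composition normalization shared by the engines.
##
## Two scale-factor schemes are provided: trimmed mean of M-values (TMM),
## used by the negative-binomial exact-test engine, and median-of-ratios
## (MOR) size factors, used by the Wald and empirical-Bayes engines.

#' Per-sample library sizes
#'
#' @param counts a [count_matrix()] (or plain counts matrix).
#' @return named numeric vector of column sums.
#' @export
library_sizes <- function(counts) {
  tot <- colSums(unclass(counts))
  if (any(tot == 0))
    stop("sample(s) with zero library size: ",
         paste(names(tot)[tot == 0], collapse = ", "), call. = FALSE)
  tot
}

#' Construct a normalization-factor object
#'
#' @param library_sizes positive per-sample totals.
#' @param scale_factors positive per-sample scale factors (1 = none).
#' @param method_tag one of `"tmm"`, `"mor"`, `"none"`.
#' @return list of class `norm_factors`.
#' @export
norm_factors <- function(library_sizes, scale_factors = rep(1, length(library_sizes)),
                         method_tag = "none") {
  stopifnot(all(library_sizes > 0), all(scale_factors > 0),
            length(library_sizes) == length(scale_factors))
  method_tag <- match.arg(method_tag, c("none", "tmm", "mor"))
  names(scale_factors) <- names(library_sizes)
  structure(list(library_sizes = library_sizes, scale_factors = scale_factors,
                 method_tag = method_tag),
            class = "norm_factors")
}

#' Counts per million effective library size
#'
#' `cpm[g, j] = (count[g, j] + prior) / (library_size[j] * scale_factor[j]) * 1e6`.
#'
#' @param counts a [count_matrix()].
#' @param factors a [norm_factors()] aligned with `counts`; default: library
#'   sizes from `counts` with unit scale factors.
#' @param prior small non-negative count added before scaling (default 0).
#' @return real-valued matrix with the dimensions and dimnames of `counts`.
#' @export
cpm <- function(counts, factors = NULL, prior = 0) {
  m <- unclass(counts)
  if (is.null(factors))
    factors <- norm_factors(library_sizes(counts))
  if (length(factors$library_sizes) != ncol(m) ||
      (!is.null(names(factors$library_sizes)) &&
       !identical(names(factors$library_sizes), colnames(m))))
    stop("normalization factors do not match the counts samples", call. = FALSE)
  eff <- factors$library_sizes * factors$scale_factors
  sweep(m + prior, 2L, eff, "/") * 1e6
}

#' Trimmed-mean-of-M-values (TMM) scale factors
#'
#' Composition-robust scale factors. The reference sample is the one whose
#' upper-quartile CPM is closest to the mean upper-quartile (ties broken by
#' sample order). For each other sample, genes positive in both sample and
#' reference contribute a log-ratio M and log-abundance A; after trimming
#' the most extreme 30% of M values and 5% of A values (each side), the
#' factor is `2^` the precision-weighted mean of the remaining M values,
#' with inverse asymptotic (delta-method) binomial variances as weights.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts a [count_matrix()] with at least 2 samples.
#' @return a [norm_factors()] with `method_tag = "tmm"`.
#' @export
tmm_factors <- function(counts) {
  m <- unclass(counts)
  if (ncol(m) < 2L) stop("TMM needs at least 2 samples", call. = FALSE)
  lib <- library_sizes(counts)
  uq <- apply(sweep(m, 2L, lib, "/"), 2L, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(m[, j], m[, ref], lib[j], lib[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  norm_factors(lib, f, "tmm")
}

# TMM factor for one sample against the reference; edgeR-style doubly
# trimmed precision-weighted mean of M-values.
.tmm_pair <- function(obs, ref, n_obs, n_ref,
                      logratio_trim = 0.30, abundance_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    warning("no gene positive in both sample and TMM reference; factor set to 1",
            call. = FALSE)
    return(1)
  }
  obs <- obs[keep]; ref <- ref[keep]
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  M <- log2(p_obs / p_ref)
  A <- 0.5 * log2(p_obs * p_ref)
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A) & w > 0
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (!length(M)) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abundance_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over all-positive genes
#' of the ratio between that sample's count and the gene's geometric mean
#' across samples.
#'
#' @param counts a [count_matrix()].
#' @return a [norm_factors()] with `method_tag = "mor"`; `scale_factors`
#'   hold the size factors and `library_sizes` the raw totals (the
#'   effective normalizer for engines using this scheme is the size factor
#'   alone; see [normalized_counts()]).
#' @export
size_factors_mor <- function(counts) {
  m <- unclass(counts)
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos))
    stop("no gene with positive counts in every sample; ",
         "filter low-count genes before computing size factors", call. = FALSE)
  lg <- rowMeans(log(m[allpos, , drop = FALSE]))
  sf <- apply(m[allpos, , drop = FALSE], 2L, function(x) {
    stats::median(exp(log(x) - lg))
  })
  norm_factors(library_sizes(counts), sf, "mor")
}

#' Size-factor-normalized counts
#'
#' Divides each sample's counts by its normalizer and rescales so values
#' stay on the count scale: for `"mor"` factors the normalizer is the size
#' factor itself; for `"tmm"` (and `"none"`) it is the effective library
#' size divided by the geometric-mean effective library size.
#'
#' @param counts a [count_matrix()].
#' @param factors a [norm_factors()].
#' @return real-valued matrix on the scale of raw counts.
#' @export
normalized_counts <- function(counts, factors) {
  m <- unclass(counts)
  if (factors$method_tag == "mor") {
    norm <- factors$scale_factors
  } else {
    eff <- factors$library_sizes * factors$scale_factors
    norm <- eff / exp(mean(log(eff)))
  }
  sweep(m, 2L, norm, "/")
}
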