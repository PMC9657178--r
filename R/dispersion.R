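## Shared engine plumbing: expression filter, NB dispersion estimation,
## Benjamini-Hochberg adjustment, and regulatory-status assignment.

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted values in \[0, 1\], in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  n <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * pvalues[o]))
  adj[order(o)]
}

#' Shared expression filter
#'
#' Keeps genes with CPM above `cpm_cut` in at least `min(n_ref, n_trt)`
#' samples, so every engine tests the same gene universe. Unfiltered
#' all-zero genes would break every engine.
#'
#' @param ds a [harmonize()]d dataset.
#' @param cpm_cut CPM threshold (default 1).
#' @return logical vector over genes (TRUE = keep), named by gene id.
#' @export
expression_filter <- function(ds, cpm_cut = 1) {
  idx <- .cond_idx(ds)
  need <- min(length(idx$ref), length(idx$trt))
  x <- cpm(ds$counts)
  keep <- rowSums(x > cpm_cut) >= need
  names(keep) <- rownames(ds$counts)
  keep
}

#' Moment-based NB dispersion estimation with shrinkage
#'
#' Per-gene moment estimates on normalized counts,
#' `phi_g = max(0, (s2_pooled - mu) / mu^2)` with `s2_pooled` the pooled
#' within-condition sample variance and `mu` the grand mean. The common
#' value is the median over genes. Two shrinkage modes:
#' `"common"` gives `phi_tilde = w * common + (1 - w) * phi_g`;
#' `"trend"` fits `a / mu + b` by least squares and shrinks towards the
#' fitted value in log space, `phi_tilde = exp(w * log(trend) + (1 - w) *
#' log(phi_g))` (with a small floor so zero estimates stay usable).
#'
#' @param norm real-valued normalized count matrix (filtered genes only).
#' @param ref_idx,trt_idx column indices of the two conditions.
#' @param shrink `"common"` or `"trend"`.
#' @param w shrinkage weight in \[0, 1\] given to the common/trend value.
#' @return list of class `dispersion_model` with `phi` (raw per-gene),
#'   `common`, `trend` (per-gene or NULL), `phi_shrunk`, `w`, `shrink`.
#' @export
estimate_dispersion <- function(norm, ref_idx, trt_idx,
                                shrink = c("common", "trend"), w = 0.7) {
  shrink <- match.arg(shrink)
  stopifnot(w >= 0, w <= 1)
  mu <- rowMeans(norm)
  s2 <- .pooled_var(norm, ref_idx, trt_idx)
  phi <- pmax((s2 - mu) / mu^2, 0)
  names(phi) <- rownames(norm)
  common <- stats::median(phi)
  floor_phi <- 1e-8
  if (shrink == "common") {
    trend <- NULL
    phi_shrunk <- w * common + (1 - w) * phi
  } else {
    inv_mu <- 1 / mu
    fit <- stats::lm.fit(cbind(inv_mu, 1), phi)
    a <- max(0, fit$coefficients[[1L]])
    b <- max(floor_phi, fit$coefficients[[2L]])
    trend <- a * inv_mu + b
    phi_shrunk <- exp(w * log(trend) + (1 - w) * log(pmax(phi, floor_phi)))
  }
  structure(list(phi = phi, common = common, trend = trend,
                 phi_shrunk = phi_shrunk, w = w, shrink = shrink),
            class = "dispersion_model")
}

# Pooled within-condition sample variance per gene (n-1 denominators,
# pooled over the two conditions).
.pooled_var <- function(m, ref_idx, trt_idx) {
  v <- function(idx) {
    if (length(idx) < 2L) return(list(ss = rep(0, nrow(m)), df = 0L))
    x <- m[, idx, drop = FALSE]
    mu <- rowMeans(x)
    list(ss = rowSums((x - mu)^2), df = length(idx) - 1L)
  }
  a <- v(ref_idx); b <- v(trt_idx)
  df <- a$df + b$df
  if (df == 0L)
    stop("dispersion estimation needs at least one condition with replicates",
         call. = FALSE)
  (a$ss + b$ss) / df
}

#' Regulatory status from a log2 fold change
#'
#' `"up"` when the log2 fold change is greater than zero, `"down"` when it
#' is less than zero, and `"zero_value"` when it equals zero.
#'
#' @param log2fc finite numeric vector.
#' @return character vector in `{"up", "down", "zero_value"}`.
#' @export
assign_status <- function(log2fc) {
  if (any(!is.finite(log2fc)))
    stop("log2 fold change must be finite", call. = FALSE)
  ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "zero_value"))
}

# Uniform per-engine result container.
.deg_result <- function(method, gene, log2fc, raw_score, fdr) {
  out <- data.frame(gene = gene, log2fc = log2fc, raw_score = raw_score,
                    fdr = fdr, status = assign_status(log2fc),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "method") <- method
  class(out) <- c("deg_result", class(out))
  out
}

#' Write a per-method DEG result as TSV
#'
#' @param result a `deg_result` (from one of the engines).
#' @param path output file path.
#' @export
write_deg_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Condition means of normalized counts with the engines' shared 0.5
# pseudocount, and the resulting log2 fold change (treatment / reference).
.log2fc_from_means <- function(norm, ref_idx, trt_idx, pseudo = 0.5) {
  mu_ref <- rowMeans(norm[, ref_idx, drop = FALSE])
  mu_trt <- rowMeans(norm[, trt_idx, drop = FALSE])
  list(mu_ref = mu_ref, mu_trt = mu_trt,
       log2fc = log2((mu_trt + pseudo) / (mu_ref + pseudo)))
}
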