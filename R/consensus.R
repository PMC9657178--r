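## Consensus stage: per-method DEG sets, intersection with
## direction-consistency marking, log2FC aggregation, and Venn partition.

#' Threshold a per-method result into a DEG set
#'
#' A gene is called differentially expressed by a method when
#' `|log2fc| >= lfc_cut` and `fdr < fdr_cut` (for the frequentist engines
#' `fdr` is the BH-adjusted p-value; for the nonparametric and
#' empirical-Bayes engines it is 1 - probability of DE). The boundary
#' conventions are inclusive for the fold-change cut and strict for the
#' FDR cut.
#'
#' @param result a `deg_result`.
#' @param lfc_cut non-negative log2 fold-change threshold (default 2).
#' @param fdr_cut FDR threshold in (0, 1\] (default 0.01).
#' @return a list of class `deg_set`: `method`, `genes` (character),
#'   `status` (named by gene), `universe` (all tested genes).
#' @export
deg_set <- function(result, lfc_cut = 2, fdr_cut = 0.01) {
  stopifnot(lfc_cut >= 0, fdr_cut > 0, fdr_cut <= 1)
  sel <- abs(result$log2fc) >= lfc_cut & result$fdr < fdr_cut
  status <- result$status[sel]
  names(status) <- result$gene[sel]
  structure(list(method = attr(result, "method"), genes = result$gene[sel],
                 status = status, universe = result$gene),
            class = "deg_set")
}

#' Intersect per-method DEG sets into the consensus table
#'
#' The consensus genes are the intersection of all selected methods' DEG
#' sets. Each consensus gene carries the common per-method regulatory
#' status, or `"Inconsistent"` when the methods disagree; the mean and
#' (sample) standard deviation of the selected methods' log2 fold
#' changes; each method's log2 fold change; and each method's
#' FDR/probability score in the last columns.
#'
#' @param sets list of 1-4 `deg_set` objects.
#' @param results list of the matching `deg_result` objects (same order).
#' @param mean_lfc_cut optional post-hoc threshold: after intersection,
#'   keep only genes with `|mean_log2fc| >= mean_lfc_cut`. The default
#'   (`NULL`) applies no post-hoc cut, since per-method thresholds are
#'   normally applied before intersection via [deg_set()].
#' @return data frame of class `consensus_table`: `gene`, `status`,
#'   `mean_log2fc`, `sd_log2fc`, `log2fc_<method>`..., `fdr_<method>`...
#' @export
consensus_table <- function(sets, results, mean_lfc_cut = NULL) {
  if (length(sets) < 1L) stop("at least one method must be selected", call. = FALSE)
  if (length(sets) > 4L) stop("at most 4 methods are supported", call. = FALSE)
  if (length(sets) != length(results))
    stop("sets and results must match", call. = FALSE)
  methods <- vapply(sets, `[[`, character(1), "method")
  genes <- Reduce(intersect, lapply(sets, `[[`, "genes"))

  lfc <- matrix(NA_real_, length(genes), length(sets),
                dimnames = list(genes, paste0("log2fc_", methods)))
  fdr <- matrix(NA_real_, length(genes), length(sets),
                dimnames = list(genes, paste0("fdr_", methods)))
  stat <- matrix(NA_character_, length(genes), length(sets))
  for (k in seq_along(results)) {
    r <- results[[k]]
    i <- match(genes, r$gene)
    lfc[, k] <- r$log2fc[i]
    fdr[, k] <- r$fdr[i]
    stat[, k] <- r$status[i]
  }
  status <- apply(stat, 1L, function(s)
    if (length(unique(s)) == 1L) s[1L] else "Inconsistent")
  if (!length(genes)) status <- character(0)
  sd_lfc <- if (length(sets) == 1L) rep(NA_real_, length(genes))
            else apply(lfc, 1L, stats::sd)
  out <- data.frame(gene = genes, status = status,
                    mean_log2fc = rowMeans(lfc), sd_log2fc = sd_lfc,
                    lfc, fdr, check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(mean_lfc_cut))
    out <- out[abs(out$mean_log2fc) >= mean_lfc_cut, , drop = FALSE]
  attr(out, "methods") <- methods
  class(out) <- c("consensus_table", class(out))
  out
}

#' Venn partition of 1-4 DEG sets
#'
#' Counts the genes in each of the `2^k - 1` non-empty membership regions
#' of the union of the selected methods' DEG sets.
#'
#' @param sets list of 1-4 `deg_set` objects.
#' @return data frame of class `venn_partition`: one logical column per
#'   method plus `count`; one row per membership pattern.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 1L) stop("at least one set is required", call. = FALSE)
  if (length(sets) > 4L) stop("at most 4 sets are supported", call. = FALSE)
  methods <- vapply(sets, `[[`, character(1), "method")
  k <- length(sets)
  universe <- unique(unlist(lapply(sets, `[[`, "genes")))
  member <- vapply(sets, function(s) universe %in% s$genes,
                   logical(length(universe)))
  member <- matrix(member, ncol = k)
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))[-1L, ,
                                                                   drop = FALSE]
  counts <- apply(patterns, 1L, function(p) {
    if (length(universe) == 0L) return(0L)
    sum(colSums(t(member) == p) == k)
  })
  out <- data.frame(patterns, count = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(out) <- c(methods, "count")
  class(out) <- c("venn_partition", class(out))
  out
}

#' Write a consensus table or Venn partition as TSV
#'
#' @param x a `consensus_table` or `venn_partition`.
#' @param path output file path.
#' @export
write_consensus <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
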