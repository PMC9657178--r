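## Confusion-matrix evaluation of DEG calls against a gold standard.

#' Construct a gold-standard label table
#'
#' @param gene character vector of unique gene ids.
#' @param is_deg logical vector: is the gene a true DEG.
#' @param direction `"Up"`, `"Down"`, or `NA`; non-NA only for DEGs.
#' @return data frame of class `gold_standard`.
#' @export
gold_standard <- function(gene, is_deg, direction = NA_character_) {
  gene <- as.character(gene)
  if (anyDuplicated(gene))
    stop("duplicate gene id in gold standard", call. = FALSE)
  direction <- rep_len(as.character(direction), length(gene))
  if (any(!is.na(direction) & !direction %in% c("Up", "Down")))
    stop("direction must be 'Up', 'Down', or NA", call. = FALSE)
  if (any(!is.na(direction) & !is_deg))
    stop("direction must be NA for non-DEG genes", call. = FALSE)
  out <- data.frame(gene = gene, is_deg = as.logical(is_deg),
                    direction = direction, stringsAsFactors = FALSE)
  class(out) <- c("gold_standard", class(out))
  out
}

#' Parse a gold-standard TSV
#'
#' Three tab-separated columns with a header: gene id, DEG flag
#' (`DEG`/`not`), and direction (`Up`/`Down`/`NA`).
#'
#' @param path path to the TSV file.
#' @return a [gold_standard()] table.
#' @export
parse_gold <- function(path) {
  if (!file.exists(path))
    stop("gold-standard file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", na.strings = "NA")
  if (ncol(df) < 3L)
    stop("gold-standard file needs 3 columns: gene, DEG flag, direction",
         call. = FALSE)
  gold_standard(df[[1L]], tolower(df[[2L]]) == "deg", df[[3L]])
}

#' Write a gold-standard table as TSV
#'
#' @param gold a [gold_standard()] table.
#' @param path output file path.
#' @export
write_gold <- function(gold, path) {
  df <- data.frame(gene = gold$gene,
                   is_deg = ifelse(gold$is_deg, "DEG", "not"),
                   direction = gold$direction, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Derive gold labels from a generic score table
#'
#' Applies the conventional rule for calling DEGs from an external score
#' table: `|log2fc| >= lfc_cut` and `p <= p_cut` (defaults 2 and 0.05).
#'
#' @param gene,log2fc,pvalue parallel vectors.
#' @param lfc_cut,p_cut thresholds.
#' @return a [gold_standard()] table with directions from the sign of
#'   `log2fc`.
#' @export
gold_from_scores <- function(gene, log2fc, pvalue, lfc_cut = 2, p_cut = 0.05) {
  is_deg <- abs(log2fc) >= lfc_cut & pvalue <= p_cut
  direction <- ifelse(is_deg, ifelse(log2fc > 0, "Up", "Down"), NA_character_)
  gold_standard(gene, is_deg, direction)
}

#' Confusion matrix of predicted vs gold-standard DEG calls
#'
#' The positive class is "gene called a DEG". `TP` are predicted DEGs
#' that are gold DEGs, `FP` predicted but not gold, `FN` gold but not
#' predicted, `TN` the remainder of the evaluation universe.
#'
#' @param predicted character vector of predicted DEG gene ids (or a
#'   `deg_set` / `consensus_table`, whose genes are used).
#' @param gold a [gold_standard()] table (restricted to the universe).
#' @param universe character vector of evaluated gene ids; must contain
#'   every predicted gene.
#' @return list of class `confusion_matrix` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(predicted, gold, universe) {
  if (inherits(predicted, "deg_set")) predicted <- predicted$genes
  if (inherits(predicted, "consensus_table")) predicted <- predicted$gene
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("evaluation universe is empty", call. = FALSE)
  if (!all(predicted %in% universe))
    stop("predicted gene(s) outside the evaluation universe: ",
         paste(utils::head(setdiff(predicted, universe), 5L), collapse = ", "),
         call. = FALSE)
  gold_deg <- gold$gene[gold$is_deg]
  pred <- universe %in% predicted
  truth <- universe %in% gold_deg
  structure(list(tp = sum(pred & truth), fp = sum(pred & !truth),
                 fn = sum(!pred & truth), tn = sum(!pred & !truth)),
            class = "confusion_matrix")
}

#' Sensitivity, specificity, and precision from a confusion matrix
#'
#' Sensitivity (recall, true-positive rate) is `TP / (TP + FN)`,
#' specificity (true-negative rate) `TN / (TN + FP)`, and precision
#' (positive predictive value) `TP / (TP + FP)`, each as a percentage.
#' A metric whose denominator is zero is reported as `NA`.
#'
#' @param cm a [confusion()] matrix.
#' @return list of class `performance_metrics` with `sensitivity`,
#'   `specificity`, `precision` (percent).
#' @export
metrics <- function(cm) {
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(sensitivity = ratio(cm$tp, cm$tp + cm$fn),
                 specificity = ratio(cm$tn, cm$tn + cm$fp),
                 precision = ratio(cm$tp, cm$tp + cm$fp)),
            class = "performance_metrics")
}

#' Evaluate per-method and consensus predictions against a gold standard
#'
#' Builds the per-row report: one row per method plus the consensus, with
#' the confusion counts, the three headline metrics, and a supplementary
#' direction-accuracy column (fraction of true positives whose predicted
#' regulatory direction matches the gold direction; headline metrics are
#' presence/absence only).
#'
#' @param sets list of `deg_set` objects (per method).
#' @param consensus a `consensus_table` (or NULL to skip the row).
#' @param gold a [gold_standard()] table.
#' @param universe evaluation universe; by default the intersection of the
#'   methods' tested universes with the gold-standard genes.
#' @return data frame: `method`, `n_deg`, `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `precision`, `direction_accuracy`.
#' @export
evaluate_predictions <- function(sets, consensus = NULL, gold,
                                 universe = NULL) {
  if (is.null(universe)) {
    tested <- Reduce(intersect, lapply(sets, `[[`, "universe"))
    universe <- intersect(tested, gold$gene)
  }
  gold_dir <- gold$direction
  names(gold_dir) <- gold$gene
  row_for <- function(name, genes, status) {
    genes <- intersect(genes, universe)
    cm <- confusion(genes, gold, universe)
    pm <- metrics(cm)
    tp_genes <- genes[genes %in% gold$gene[gold$is_deg]]
    dir_ok <- NA_real_
    if (length(tp_genes)) {
      pred_dir <- c(up = "Up", down = "Down", zero_value = NA,
                    Inconsistent = NA)[status[tp_genes]]
      dir_ok <- mean(!is.na(pred_dir) & pred_dir == gold_dir[tp_genes])
    }
    data.frame(method = name, n_deg = length(genes), tp = cm$tp, fp = cm$fp,
               fn = cm$fn, tn = cm$tn, sensitivity = pm$sensitivity,
               specificity = pm$specificity, precision = pm$precision,
               direction_accuracy = dir_ok, stringsAsFactors = FALSE)
  }
  rows <- lapply(sets, function(s) row_for(s$method, s$genes, s$status))
  if (!is.null(consensus)) {
    st <- consensus$status
    names(st) <- consensus$gene
    rows <- c(rows, list(row_for("consensus", consensus$gene, st)))
  }
  do.call(rbind, rows)
}
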