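#' degconsensus: consensus differential expression for two-condition RNA-seq
#'
#' Runs up to four statistically distinct differential-expression testing
#' engines on a genes x samples count table and intersects their DEG calls
#' into a consensus result. See `vignette("degconsensus-methods")` for the
#' statistical models and design choices.
#'
#' @keywords internal
"_PACKAGE"

## ---- count matrix -------------------------------------------------------

#' Construct a validated count matrix
#'
#' A count matrix is an integer matrix, genes in rows and samples in
#' columns, with unique gene identifiers as rownames and unique sample
#' names as colnames. All counts must be non-negative integers; at least
#' one gene and two samples are required.
#'
#' @param counts numeric matrix of counts (genes x samples) with dimnames.
#' @return an integer matrix of class `count_matrix`.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  gene_ids <- rownames(counts)
  sample_names <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_names))
    stop("count matrix needs gene rownames and sample colnames", call. = FALSE)
  if (nrow(counts) < 1L)
    stop("count matrix needs at least 1 gene", call. = FALSE)
  if (ncol(counts) < 2L)
    stop("count matrix needs at least 2 sample columns, got ",
         ncol(counts), call. = FALSE)
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup))
    stop("duplicate gene id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- sample_names[duplicated(sample_names)]
  if (length(dup))
    stop("duplicate sample name: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  .check_counts_numeric(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_matrix", class(counts))
  counts
}

.check_counts_numeric <- function(counts) {
  bad <- which(is.na(counts), arr.ind = TRUE)
  if (nrow(bad))
    stop("missing count for gene '", rownames(counts)[bad[1, 1]],
         "', sample '", colnames(counts)[bad[1, 2]], "'", call. = FALSE)
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative count for gene '", rownames(counts)[bad[1, 1]],
         "', sample '", colnames(counts)[bad[1, 2]], "'", call. = FALSE)
  bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer count (", counts[bad[1, , drop = FALSE]],
         ") for gene '", rownames(counts)[bad[1, 1]],
         "', sample '", colnames(counts)[bad[1, 2]], "'", call. = FALSE)
  invisible(TRUE)
}

#' Parse a read-counts table from a TSV file
#'
#' The file must be tab-separated with a header row; the first column holds
#' transcript/gene identifiers (its header cell is free text and ignored),
#' the remaining columns hold integer read counts for each sample. Row and
#' column order are preserved.
#'
#' @param path path to the TSV file.
#' @return a [count_matrix()].
#' @export
parse_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 3L)
    stop("counts file needs a gene-id column plus at least 2 sample columns, got ",
         ncol(df) - 1L, " sample column(s)", call. = FALSE)
  gene_ids <- df[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene id: ", paste(dup, collapse = ", "), call. = FALSE)
  m <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
              dimnames = list(gene_ids, colnames(df)[-1L]))
  for (j in seq_len(ncol(df) - 1L)) {
    x <- df[[j + 1L]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) | x == "")
    if (length(bad))
      stop("missing or non-numeric count '", x[bad[1L]], "' for gene '",
           gene_ids[bad[1L]], "', sample '", colnames(df)[j + 1L], "'",
           call. = FALSE)
    m[, j] <- v
  }
  count_matrix(m)
}

#' Write a count matrix as TSV
#'
#' Inverse of [parse_counts()]: tab-separated, header row, gene ids in the
#' first column (headed `gene_id`), no quoting.
#'
#' @param counts a [count_matrix()].
#' @param path output file path.
#' @param id_header header text for the gene-id column.
#' @export
write_counts <- function(counts, path, id_header = "gene_id") {
  df <- data.frame(id = rownames(counts), unclass(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_header
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## ---- sample information -------------------------------------------------

#' Construct a validated sample-information table
#'
#' @param sample_names character vector of unique sample names, in the
#'   order the samples appear in the experiment.
#' @param condition character vector, one condition label per sample;
#'   exactly two distinct levels are allowed. Levels are case-sensitive.
#' @return a `data.frame` of class `sample_info` with columns
#'   `sample_name` and `condition`.
#' @export
sample_info <- function(sample_names, condition) {
  sample_names <- as.character(sample_names)
  condition <- as.character(condition)
  if (length(sample_names) != length(condition))
    stop("sample_names and condition lengths differ", call. = FALSE)
  dup <- unique(sample_names[duplicated(sample_names)])
  if (length(dup))
    stop("duplicate sample name: ", paste(dup, collapse = ", "), call. = FALSE)
  lev <- unique(condition)
  if (length(lev) != 2L)
    stop("condition must have exactly two values, got ", length(lev),
         " (", paste(lev, collapse = ", "), ")", call. = FALSE)
  ok <- startsWith(tolower(sample_names), tolower(condition))
  if (!all(ok))
    warning("sample name(s) not starting with their condition label: ",
            paste(sample_names[!ok], collapse = ", "), call. = FALSE)
  out <- data.frame(sample_name = sample_names, condition = condition,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_info", class(out))
  out
}

#' Parse a sample-information table from a TSV file
#'
#' Two tab-separated columns with a header row: sample names first, then
#' the experimental condition. The second header must read `condition`
#' (matched case-insensitively) and the column may carry exactly two
#' distinct values.
#'
#' @param path path to the TSV file.
#' @return a [sample_info()] table.
#' @export
parse_sample_info <- function(path) {
  if (!file.exists(path))
    stop("sample-information file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (ncol(df) != 2L)
    stop("sample-information file must have exactly 2 columns, got ",
         ncol(df), call. = FALSE)
  hdr <- gsub("^\\*+|\\*+$", "", trimws(colnames(df)[2L]))
  if (tolower(hdr) != "condition")
    stop("second column must be headed 'condition', got '",
         colnames(df)[2L], "'", call. = FALSE)
  sample_info(df[[1L]], df[[2L]])
}

#' Write a sample-information table as TSV
#'
#' @param design a [sample_info()] table.
#' @param path output file path.
#' @export
write_sample_info <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## ---- harmonized dataset -------------------------------------------------

#' Match and order counts against the sample-information table
#'
#' Matches every design sample name to exactly one counts column and
#' reorders the counts columns into design order, yielding the harmonized
#' dataset all downstream engines consume. Matching is case-insensitive by
#' default (with a warning when capitalization differs); `strict = TRUE`
#' requires exact names.
#'
#' @param counts a [count_matrix()].
#' @param design a [sample_info()] table.
#' @param reference reference (denominator) condition level for log2
#'   fold changes; defaults to the first condition value in design order.
#' @param strict require exact sample-name matches.
#' @return a list of class `deg_dataset` with elements `counts` (columns in
#'   design order, renamed to design sample names), `design`, and
#'   `condition_order` (reference level first, treatment level second).
#' @export
harmonize <- function(counts, design, reference = NULL, strict = FALSE) {
  cn <- colnames(counts)
  sn <- design$sample_name
  if (strict) {
    idx <- match(sn, cn)
    if (anyNA(idx))
      stop("sample name(s) in design not found in counts: ",
           paste(sn[is.na(idx)], collapse = ", "), call. = FALSE)
  } else {
    lc <- tolower(cn)
    idx <- integer(length(sn))
    for (i in seq_along(sn)) {
      hit <- which(lc == tolower(sn[i]))
      if (length(hit) == 0L)
        stop("sample name(s) in design not found in counts: ", sn[i],
             call. = FALSE)
      if (length(hit) > 1L)
        stop("ambiguous case-insensitive match for design sample '", sn[i],
             "': counts columns ", paste(cn[hit], collapse = ", "),
             call. = FALSE)
      idx[i] <- hit
    }
    if (any(cn[idx] != sn))
      warning("sample names matched case-insensitively: ",
              paste0(cn[idx][cn[idx] != sn], " ~ ", sn[cn[idx] != sn],
                     collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(cn, cn[idx])
  if (length(extra))
    stop("counts column(s) not present in design: ",
         paste(extra, collapse = ", "), call. = FALSE)
  m <- unclass(counts)[, idx, drop = FALSE]
  colnames(m) <- sn
  lev <- unique(design$condition)
  if (is.null(reference)) reference <- lev[1L]
  if (!reference %in% lev)
    stop("reference condition '", reference, "' not a condition level (",
         paste(lev, collapse = ", "), ")", call. = FALSE)
  ds <- list(counts = count_matrix(m), design = design,
             condition_order = c(reference, setdiff(lev, reference)))
  class(ds) <- "deg_dataset"
  ds
}

#' @export
print.deg_dataset <- function(x, ...) {
  cat("deg_dataset: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  tab <- table(x$design$condition)[x$condition_order]
  cat("conditions: ", x$condition_order[1L], " (reference, n=", tab[1L],
      ") vs ", x$condition_order[2L], " (n=", tab[2L], ")\n", sep = "")
  invisible(x)
}

# Column indices of reference / treatment samples in a deg_dataset.
.cond_idx <- function(ds) {
  list(ref = which(ds$design$condition == ds$condition_order[1L]),
       trt = which(ds$design$condition == ds$condition_order[2L]))
}
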