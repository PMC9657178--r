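## Pipeline orchestration: parse -> harmonize -> selected engines ->
## status -> per-method DEG sets -> consensus -> Venn partition, with all
## tables, a run log and a machine-readable manifest written to disk.

ENGINE_NAMES <- c("nb_exact", "nb_wald", "noise", "eb")

#' Pipeline run configuration
#'
#' @param methods subset of `c("nb_exact", "nb_wald", "noise", "eb")`.
#' @param lfc_cut log2 fold-change threshold (default 2).
#' @param fdr_cut FDR/probability-score threshold (default 0.01).
#' @param reference reference condition level (default: first level in
#'   the sample-information file).
#' @param strict require exact sample-name matches.
#' @param cpm_cut expression-filter CPM threshold shared by all engines.
#' @param post_hoc_lfc apply the fold-change threshold to the consensus
#'   mean log2FC after intersection instead of per method before it.
#' @return list of class `run_config`.
#' @export
run_config <- function(methods = ENGINE_NAMES, lfc_cut = 2, fdr_cut = 0.01,
                       reference = NULL, strict = FALSE, cpm_cut = 1,
                       post_hoc_lfc = FALSE) {
  if (!length(methods)) stop("at least one method must be selected", call. = FALSE)
  methods <- match.arg(methods, ENGINE_NAMES, several.ok = TRUE)
  stopifnot(lfc_cut >= 0, fdr_cut > 0, fdr_cut <= 1)
  structure(list(methods = methods, lfc_cut = lfc_cut, fdr_cut = fdr_cut,
                 reference = reference, strict = strict, cpm_cut = cpm_cut,
                 post_hoc_lfc = isTRUE(post_hoc_lfc)),
            class = "run_config")
}

.engine_fun <- function(method) {
  switch(method,
         nb_exact = function(ds, cpm_cut) nb_exact_test(ds, cpm_cut = cpm_cut),
         nb_wald = function(ds, cpm_cut) nb_wald_test(ds, cpm_cut = cpm_cut),
         noise = function(ds, cpm_cut) noise_test(ds, cpm_cut = cpm_cut),
         eb = function(ds, cpm_cut) eb_test(ds, cpm_cut = cpm_cut),
         stop("unknown method: ", method, call. = FALSE))
}

#' Run the consensus differential-expression pipeline
#'
#' Parses and harmonizes the two input tables, runs the selected engines,
#' thresholds each result into a DEG set, intersects the sets into the
#' consensus table, counts the Venn partition, and writes everything to
#' `out_dir`: one `<method>.tsv` per engine, `consensus.tsv`, `venn.tsv`,
#' a `run_log.txt` (configuration, normalization factors, filter counts,
#' warnings), and `manifest.json` listing every file written. Outputs are
#' deterministic: re-running with identical inputs is byte-identical.
#'
#' @param counts_path path to the read-counts TSV.
#' @param coldata_path path to the sample-information TSV.
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) list with `dataset`, `results`, `sets`,
#'   `consensus`, `venn`, `paths`.
#' @export
run_pipeline <- function(counts_path, coldata_path, config = run_config(),
                         out_dir) {
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  counts <- parse_counts(counts_path)
  design <- parse_sample_info(coldata_path)
  ds <- collect(harmonize(counts, design, reference = config$reference,
                          strict = config$strict))

  keep <- expression_filter(ds, config$cpm_cut)
  results <- lapply(config$methods, function(m)
    collect(.engine_fun(m)(ds, config$cpm_cut)))
  names(results) <- config$methods
  if (config$post_hoc_lfc) {
    sets <- lapply(results, deg_set, lfc_cut = 0, fdr_cut = config$fdr_cut)
    cons <- consensus_table(sets, results, mean_lfc_cut = config$lfc_cut)
  } else {
    sets <- lapply(results, deg_set, lfc_cut = config$lfc_cut,
                   fdr_cut = config$fdr_cut)
    cons <- consensus_table(sets, results)
  }
  venn <- venn_counts(sets)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in config$methods) {
    p <- file.path(out_dir, paste0(m, ".tsv"))
    write_deg_result(results[[m]], p)
    paths[m] <- p
  }
  paths["consensus"] <- write_consensus(cons, file.path(out_dir, "consensus.tsv"))
  paths["venn"] <- write_consensus(venn, file.path(out_dir, "venn.tsv"))

  tmm <- if ("nb_exact" %in% config$methods)
    collect(tmm_factors(ds$counts))$scale_factors else NULL
  mor <- if (any(c("nb_wald", "eb") %in% config$methods))
    collect(size_factors_mor(
      count_matrix(unclass(ds$counts)[keep, , drop = FALSE])))$scale_factors
    else NULL
  log_lines <- c(
    "degconsensus run log",
    paste0("methods: ", paste(config$methods, collapse = ",")),
    paste0("lfc_cut: ", config$lfc_cut),
    paste0("fdr_cut: ", config$fdr_cut),
    paste0("reference: ", ds$condition_order[1L]),
    paste0("treatment: ", ds$condition_order[2L]),
    paste0("genes_total: ", nrow(ds$counts)),
    paste0("genes_tested: ", sum(keep)),
    paste0("genes_filtered_out: ", sum(!keep)),
    if (!is.null(tmm)) paste0("tmm_factors: ",
                              paste(signif(tmm, 6), collapse = ",")),
    if (!is.null(mor)) paste0("mor_size_factors: ",
                              paste(signif(mor, 6), collapse = ",")),
    "note: the fdr column holds BH-adjusted p-values for nb_exact/nb_wald",
    "note: and 1 - probability of DE for noise/eb; one cut is applied to both",
    if (length(warnings_log)) paste0("warning: ", warnings_log))
  paths["run_log"] <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, paths[["run_log"]])

  paths["manifest"] <- file.path(out_dir, "manifest.json")
  manifest <- list(files = as.list(basename(paths)),
                   config = list(methods = config$methods,
                                 lfc_cut = config$lfc_cut,
                                 fdr_cut = config$fdr_cut,
                                 reference = ds$condition_order[1L]))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(dataset = ds, results = results, sets = sets,
                 consensus = cons, venn = venn, paths = paths))
}
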