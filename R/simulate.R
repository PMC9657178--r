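## Seeded two-condition negative-binomial count simulator with known
## truth. Emulates a bulk RNA-seq benchmark experiment: lognormal
## baseline expression, a fixed fraction of DE genes with a symmetric
## fold-change split, NB sampling noise, and moderate library-size
## variation between samples.

#' Simulation design
#'
#' Validates and assembles the parameters of a simulated two-condition
#' experiment. Defaults describe a desk-scale bulk RNA-seq benchmark:
#' 2000 genes, 5 vs 5 replicates, 10% DE genes at |log2FC| = 2, NB
#' dispersion 0.1, lognormal baseline means (meanlog 4.6, sdlog 1.3,
#' i.e. a median of ~100 counts), and library sizes varying by +/-30%.
#'
#' @param G number of genes.
#' @param n_ref,n_trt replicates per condition.
#' @param pi_de fraction of DE genes in \[0, 1\]; realized exactly as
#'   `round(G * pi_de)` genes.
#' @param lfc_magnitude true |log2 fold change| of DE genes.
#' @param mean_log_mu,sd_log_mu lognormal baseline-mean parameters
#'   (natural-log scale).
#' @param dispersion NB dispersion: a single `phi >= 0`, or `c(a0, a1)`
#'   for the trend `phi_g = a0 / mu_g + a1`.
#' @param libsize_range range of multiplicative per-sample library-size
#'   factors (drawn uniformly).
#' @param seed integer RNG seed.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(G = 2000L, n_ref = 5L, n_trt = 5L, pi_de = 0.1,
                       lfc_magnitude = 2, mean_log_mu = 4.6, sd_log_mu = 1.3,
                       dispersion = 0.1, libsize_range = c(0.7, 1.3),
                       seed = 1L) {
  stopifnot(G >= 1, n_ref >= 1, n_trt >= 1, pi_de >= 0, pi_de <= 1,
            lfc_magnitude >= 0, sd_log_mu >= 0, all(dispersion >= 0),
            length(dispersion) %in% 1:2, length(libsize_range) == 2L,
            libsize_range[1L] > 0, libsize_range[2L] >= libsize_range[1L])
  structure(list(G = as.integer(G), n_ref = as.integer(n_ref),
                 n_trt = as.integer(n_trt), pi_de = pi_de,
                 lfc_magnitude = lfc_magnitude, mean_log_mu = mean_log_mu,
                 sd_log_mu = sd_log_mu, dispersion = dispersion,
                 libsize_range = libsize_range, seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate a two-condition NB count dataset with known truth
#'
#' A single RNG stream seeded from `design$seed` drives all draws, in
#' this order: (1) baseline means `mu_g` (lognormal), (2) the DE gene
#' subset (simple random sample of exactly `round(G * pi_de)` genes; the
#' first half up, the rest down), (3) per-sample library factors
#' (uniform), (4) NB counts gene-major. DE genes get the symmetric
#' fold-change split `2^(+lfc/2)` (treatment) vs `2^(-lfc/2)`
#' (reference) so the two conditions keep comparable library sizes.
#' Identical designs reproduce bit-identical output.
#'
#' @param design a [sim_design()].
#' @return list of class `sim_result` with `dataset` (a [harmonize()]d
#'   dataset, reference condition `"control"`, treatment `"treated"`),
#'   `truth` (data frame: `gene`, `is_de`, `true_log2fc`, `true_mu`,
#'   `true_phi`), and `gold` (a [gold_standard()] table).
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  G <- design$G
  n <- design$n_ref + design$n_trt
  gene <- sprintf("gene%0*d", nchar(G), seq_len(G))

  mu <- exp(stats::rnorm(G, design$mean_log_mu, design$sd_log_mu))
  n_de <- round(G * design$pi_de)
  de_idx <- if (n_de > 0) sample.int(G, n_de) else integer(0)
  n_up <- ceiling(n_de / 2)
  lfc <- numeric(G)
  lfc[de_idx] <- design$lfc_magnitude *
    rep(c(1, -1), c(n_up, n_de - n_up))
  lib <- stats::runif(n, design$libsize_range[1L], design$libsize_range[2L])

  phi <- if (length(design$dispersion) == 1L) rep(design$dispersion, G)
         else design$dispersion[1L] / mu + design$dispersion[2L]
  cond <- rep(c("control", "treated"), c(design$n_ref, design$n_trt))
  # symmetric split: reference means mu * 2^(-lfc/2), treatment 2^(+lfc/2)
  shift <- cbind(outer(2^(-lfc / 2), rep(1, design$n_ref)),
                 outer(2^(+lfc / 2), rep(1, design$n_trt)))
  mean_mat <- (mu * shift) %*% diag(lib)
  counts <- matrix(0L, G, n)
  for (g in seq_len(G)) {
    counts[g, ] <- if (phi[g] > 0)
      stats::rnbinom(n, size = 1 / phi[g], mu = mean_mat[g, ])
    else stats::rpois(n, mean_mat[g, ])
  }
  sample_names <- c(paste0("control", seq_len(design$n_ref)),
                    paste0("treated", seq_len(design$n_trt)))
  dimnames(counts) <- list(gene, sample_names)

  ds <- harmonize(count_matrix(counts), sample_info(sample_names, cond),
                  reference = "control")
  truth <- data.frame(gene = gene, is_de = lfc != 0, true_log2fc = lfc,
                      true_mu = mu, true_phi = phi, stringsAsFactors = FALSE)
  gold <- gold_standard(gene, truth$is_de,
                        ifelse(truth$is_de, ifelse(lfc > 0, "Up", "Down"),
                               NA_character_))
  structure(list(dataset = ds, truth = truth, gold = gold, design = design),
            class = "sim_result")
}

#' Write a simulation to disk in the pipeline's input dialects
#'
#' Emits `cts.tsv` (read counts), `coldata.tsv` (sample information),
#' `truth.tsv`, and `gold.tsv` into `dir`.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cts = file.path(dir, "cts.tsv"),
             coldata = file.path(dir, "coldata.tsv"),
             truth = file.path(dir, "truth.tsv"),
             gold = file.path(dir, "gold.tsv"))
  write_counts(sim$dataset$counts, paths[["cts"]],
               id_header = "Transcript_name")
  write_sample_info(sim$dataset$design, paths[["coldata"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  write_gold(sim$gold, paths[["gold"]])
  paths
}

#' Read a simulation configuration file
#'
#' Accepts either flat `key=value` lines or YAML; keys are the
#' [sim_design()] arguments.
#'
#' @param path path to the configuration file.
#' @return a [sim_design()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (all(grepl("=", lines, fixed = TRUE))) {
    kv <- strsplit(lines, "=", fixed = TRUE)
    cfg <- lapply(kv, function(x) {
      v <- trimws(x[2L])
      num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1L]]))
      if (anyNA(num)) v else num
    })
    names(cfg) <- trimws(vapply(kv, `[[`, character(1), 1L))
  } else {
    cfg <- yaml::read_yaml(path)
  }
  bad <- setdiff(names(cfg), names(formals(sim_design)))
  if (length(bad))
    stop("unknown simulation parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(sim_design, cfg)
}
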