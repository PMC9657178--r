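# Shared fixtures and independent brute-force oracles.

fixture_counts <- function() {
  system.file("extdata", "pasilla_counts_head.tsv", package = "degconsensus")
}

fixture_coldata <- function() {
  system.file("extdata", "pasilla_coldata.tsv", package = "degconsensus")
}

toy_dataset <- function() {
  suppressWarnings(harmonize(parse_counts(fixture_counts()),
                             parse_sample_info(fixture_coldata())))
}

# small random count matrix
random_counts <- function(G = 50, n = 4, mu = 100, size = 5,
                          names_prefix = "g") {
  m <- matrix(rnbinom(G * n, mu = mu, size = size), G, n,
              dimnames = list(paste0(names_prefix, seq_len(G)),
                              paste0("s", seq_len(n))))
  count_matrix(m)
}

# write a counts/coldata pair for a matrix with a two-condition design
write_toy_inputs <- function(counts, conditions, dir = NULL,
                             .env = parent.frame()) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = .env)
  cts <- file.path(dir, "cts.tsv")
  col <- file.path(dir, "coldata.tsv")
  write_counts(counts, cts, id_header = "Transcript_name")
  write_sample_info(sample_info(colnames(counts), conditions), col)
  list(cts = cts, coldata = col, dir = dir)
}

# --- independent oracles -------------------------------------------------

# BH step-up by direct definition: adj_(i) = min_{j >= i} min(1, n p_(j) / j)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(pmin(1, n * sorted[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# TMM by direct enumeration of the doubly trimmed, weighted set for one
# sample against a fixed reference (no rank shortcuts: explicit sort and
# positional slicing)
tmm_pair_oracle <- function(obs, ref, n_obs, n_ref) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * 0.30) + 1; hiM <- n + 1 - loM
  loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
  # brute-force midranks (ties averaged), no library rank function
  midrank <- function(x) vapply(x, function(v)
    sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
  rM <- midrank(M); rA <- midrank(A)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(sel)) return(1)
  2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
}

# per-gene membership tally for venn regions
venn_oracle <- function(gene_sets) {
  universe <- unique(unlist(gene_sets))
  k <- length(gene_sets)
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))[-1, ,
                                                                   drop = FALSE]
  counts <- integer(nrow(patterns))
  for (g in universe) {
    mem <- vapply(gene_sets, function(s) g %in% s, logical(1))
    row <- which(apply(patterns, 1, function(p) all(p == mem)))
    counts[row] <- counts[row] + 1L
  }
  counts
}

# direct-counting noise probability
noise_prob_oracle <- function(abs_m, d, noise_abs_m, noise_d) {
  vapply(seq_along(abs_m), function(g)
    mean(noise_abs_m < abs_m[g] & noise_d < d[g]), numeric(1))
}

# minimal dispersion model with a fixed phi for every gene
fixed_disp <- function(phi, G) {
  structure(list(phi = rep(phi, G), common = phi, trend = NULL,
                 phi_shrunk = rep(phi, G), w = 1, shrink = "common"),
            class = "dispersion_model")
}
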