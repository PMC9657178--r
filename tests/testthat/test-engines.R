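# The four DE testing engines and their shared plumbing.

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.005, 0.04, 0.05)), c(0.015, 0.05, 0.05))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("bh_adjust equals the brute-force oracle and p.adjust", {
  set.seed(21)
  for (rep in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-14)
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-14)
  }
})

test_that("assign_status maps the sign of log2FC to up/down/zero_value", {
  expect_equal(assign_status(c(1.5, -0.3, 0)), c("up", "down", "zero_value"))
  expect_error(assign_status(c(1, NaN)), "finite")
  expect_error(assign_status(Inf), "finite")
})

test_that("exact split p-values match the binomial oracle at phi = 0", {
  # 1 vs 1 samples, equal libraries: conditional distribution is
  # Binomial(s, 1/2); two-sided p sums binomial probabilities <= observed
  for (s in 1:50) {
    for (a in c(0L, s %/% 3L, s %/% 2L, s)) {
      probs <- dbinom(0:s, s, 0.5)
      expected <- sum(probs[probs <= probs[a + 1] + 1e-12])
      expect_equal(exact_split_pvalue(a, s - a, 1, 1, 0),
                   min(1, expected), tolerance = 1e-9)
    }
  }
  # the worked case: split (3,1) of total 4
  expect_equal(exact_split_pvalue(3, 1, 1, 1, 0), 0.625, tolerance = 1e-12)
})

test_that("exact split p-value is 1 for a balanced split and symmetric", {
  expect_equal(exact_split_pvalue(20, 20, 3, 3, 0.1), 1)
  expect_equal(exact_split_pvalue(0, 0, 3, 3, 0.1), 1)
  expect_equal(exact_split_pvalue(5, 15, 2, 2, 0.2),
               exact_split_pvalue(15, 5, 2, 2, 0.2), tolerance = 1e-12)
})

test_that("nb_exact returns p = 1 for equal group sums and flags nothing", {
  m <- matrix(rep(c(50L, 80L, 120L), each = 4), 3, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  ds <- suppressWarnings(harmonize(count_matrix(m),
                                   sample_info(colnames(m),
                                               rep(c("a", "b"), each = 2))))
  r <- nb_exact_test(ds)
  expect_equal(r$raw_score, rep(1, 3))
  expect_equal(r$log2fc, rep(0, 3))
  expect_equal(r$status, rep("zero_value", 3))
})

test_that("every engine negates log2fc and keeps scores on label swap", {
  set.seed(31)
  sim <- simulate_dataset(sim_design(G = 150, n_ref = 3, n_trt = 3,
                                     pi_de = 0.2, seed = 5))
  ds <- sim$dataset
  ds_sw <- harmonize(ds$counts, ds$design, reference = "treated")
  engines <- list(nb_exact = nb_exact_test, nb_wald = nb_wald_test,
                  noise = noise_test, eb = eb_test)
  for (nm in names(engines)) {
    r1 <- engines[[nm]](ds)
    r2 <- engines[[nm]](ds_sw)
    expect_equal(r2$log2fc, -r1$log2fc, tolerance = 1e-10,
                 label = paste(nm, "log2fc"))
    expect_equal(r2$raw_score, r1$raw_score, tolerance = 1e-10,
                 label = paste(nm, "raw_score"))
  }
})

test_that("all engines test the identical filtered gene universe", {
  sim <- simulate_dataset(sim_design(G = 300, n_ref = 3, n_trt = 3,
                                     pi_de = 0.1, mean_log_mu = 2,
                                     sd_log_mu = 2, seed = 8))
  ds <- sim$dataset
  keep <- expression_filter(ds)
  expect_true(sum(keep) < nrow(ds$counts))  # the filter actually bites
  genes <- rownames(ds$counts)[keep]
  for (fun in list(nb_exact_test, nb_wald_test, noise_test, eb_test)) {
    expect_equal(fun(ds)$gene, genes)
  }
})

test_that("wald test: equal means give p = 1; z follows the SE", {
  m <- matrix(rep(c(100L, 40L), each = 4), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  ds <- suppressWarnings(harmonize(count_matrix(m),
                                   sample_info(colnames(m),
                                               rep(c("a", "b"), each = 2))))
  r <- nb_wald_test(ds)
  expect_equal(r$log2fc, c(0, 0))
  expect_equal(r$raw_score, c(1, 1))
  # z = 2 corresponds to p = 2 * pnorm(-2) = 0.0455 (3 sf)
  expect_equal(round(2 * pnorm(-2), 4), 0.0455)
})

test_that("wald test recovers the simulated fold change", {
  sim <- simulate_dataset(sim_design(G = 2000, n_ref = 5, n_trt = 5,
                                     pi_de = 0.1, lfc_magnitude = 2,
                                     dispersion = 0.1, seed = 1))
  r <- nb_wald_test(sim$dataset)
  tr <- sim$truth[match(r$gene, sim$truth$gene), ]
  expect_equal(mean(abs(r$log2fc[tr$is_de])), 2, tolerance = 0.1)
  expect_true(abs(mean(abs(r$log2fc[tr$is_de])) - 2) < 0.2)
})

test_that("noise probability counts strictly dominated noise points", {
  # direct worked case: exactly one of two noise points qualifies
  expect_equal(noise_probability(0.8, 15, c(0.5, 1.0), c(10, 20)), 0.5)
  # boundary: nothing strictly below zero signal
  expect_equal(noise_probability(0, 0, c(0.5, 1.0), c(10, 20)), 0)
  # a signal dominating every noise point has probability 1
  expect_equal(noise_probability(2, 100, c(0.5, 1.0), c(10, 20)), 1)
  # randomized equivalence with the direct-counting oracle
  set.seed(41)
  for (rep in 1:10) {
    nm <- abs(rnorm(200)); nd <- abs(rnorm(200, sd = 5))
    sm <- abs(rnorm(57)); sd_ <- abs(rnorm(57, sd = 5))
    expect_equal(noise_probability(sm, sd_, nm, nd),
                 noise_prob_oracle(sm, sd_, nm, nd), tolerance = 1e-12)
  }
  # ties on either coordinate are excluded by strictness
  expect_equal(noise_probability(0.5, 10, c(0.5, 0.4), c(10, 5)), 0.5)
  expect_equal(noise_probability(0.5, 10, c(0.5, 0.5), c(10, 3)), 0)
})

test_that("noise engine scores extremes as the spec's trivial cases", {
  sim <- simulate_dataset(sim_design(G = 200, n_ref = 3, n_trt = 3,
                                     pi_de = 0.1, seed = 3))
  r <- noise_test(sim$dataset)
  expect_true(all(r$raw_score >= 0 & r$raw_score <= 1))
  expect_identical(r$raw_score, r$fdr)
  # refuse a replicate-free design
  m <- unclass(sim$dataset$counts)[, c(1, 4)]
  ds11 <- suppressWarnings(harmonize(count_matrix(m),
                                     sample_info(colnames(m),
                                                 c("control", "treated"))))
  expect_error(noise_test(ds11), "requires replicates")
})

test_that("eb posterior is degenerate when pi is forced to 0 or 1", {
  sim <- simulate_dataset(sim_design(G = 100, n_ref = 3, n_trt = 3,
                                     pi_de = 0.2, seed = 6))
  r0 <- eb_test(sim$dataset, pi_fixed = 0)
  expect_equal(r0$raw_score, rep(1, nrow(r0)))  # PPDE = 0 for every gene
  r1 <- eb_test(sim$dataset, pi_fixed = 1)
  expect_equal(r1$raw_score, rep(0, nrow(r1)))  # PPDE = 1 for every gene
})

test_that("eb marginals prefer DE for separated conditions", {
  # fixed hyperparameters; compare a flat gene against a 10-fold one via
  # an independent numerical Beta-function evaluation of both marginals
  counts <- rbind(flat = rep(50L, 6), sep = c(10L, 12L, 11L, 100L, 120L, 110L))
  sf <- rep(1, 6)
  idx <- list(ref = 1:3, trt = 4:6)
  r <- c(5, 5); alpha <- 2; beta <- 2
  ll <- eb_marginal_loglik(counts, sf, r, alpha, beta, idx)
  post <- function(llrow) {
    # pi = 0.5 cancels; PPDE from the two marginals directly
    1 / (1 + exp(llrow["ee"] - llrow["de"]))
  }
  # oracle: same quantities via direct beta() evaluation in log space
  oracle_ll <- function(x, rr, cols) {
    lbeta(alpha + rr * length(cols), beta + sum(x[cols])) - lbeta(alpha, beta)
  }
  for (g in 1:2) {
    expect_equal(unname(ll[g, "ee"]), oracle_ll(counts[g, ], r[g], 1:6),
                 tolerance = 1e-12)
    expect_equal(unname(ll[g, "de"]),
                 oracle_ll(counts[g, ], r[g], 1:3) +
                   oracle_ll(counts[g, ], r[g], 4:6),
                 tolerance = 1e-12)
  }
  expect_gt(post(ll["sep", ]), post(ll["flat", ]))
})

test_that("eb EM shrinks pi on null data and grows it with signal", {
  null_sim <- simulate_dataset(sim_design(G = 400, n_ref = 4, n_trt = 4,
                                          pi_de = 0, seed = 12))
  r_null <- eb_test(null_sim$dataset)
  de_sim <- simulate_dataset(sim_design(G = 400, n_ref = 4, n_trt = 4,
                                        pi_de = 0.3, lfc_magnitude = 3,
                                        seed = 12))
  r_de <- eb_test(de_sim$dataset)
  expect_lt(attr(r_null, "pi_de"), 0.1)
  expect_gt(attr(r_de, "pi_de"), attr(r_null, "pi_de"))
  expect_lt(mean(1 - r_null$raw_score), 0.2)
})

test_that("dispersion estimation is moment-correct and shrinkage blends", {
  # two genes engineered so pooled var and mean give known phi
  norm <- rbind(g1 = c(10, 20, 10, 20), g2 = c(100, 100, 100, 100))
  dm <- estimate_dispersion(norm, 1:2, 3:4, shrink = "common", w = 0)
  mu1 <- 15; s2_1 <- mean(c(var(c(10, 20)), var(c(10, 20))))
  expect_equal(unname(dm$phi["g1"]), max(0, (s2_1 - mu1) / mu1^2),
               ignore_attr = TRUE)
  expect_equal(unname(dm$phi[2]), 0)  # variance below mean floors at 0
  dm2 <- estimate_dispersion(norm, 1:2, 3:4, shrink = "common", w = 1)
  expect_equal(unname(dm2$phi_shrunk), rep(dm2$common, 2))
  dmt <- estimate_dispersion(norm + 0.5, 1:2, 3:4, shrink = "trend", w = 0.7)
  expect_true(all(dmt$phi_shrunk >= 0))
})
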