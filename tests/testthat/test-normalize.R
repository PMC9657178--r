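# Library sizes, CPM, TMM and median-of-ratios factors.

test_that("library sizes are column sums and zero columns are rejected", {
  cm <- parse_counts(fixture_counts())
  expect_equal(library_sizes(cm)[c("Treated1", "Treated2")],
               c(Treated1 = 8780, Treated2 = 4163))
  m <- matrix(c(5, 0, 7, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(library_sizes(count_matrix(m))), c(5, 7))
  m[, 2] <- 0
  expect_error(library_sizes(count_matrix(m)), "zero library size.*s2")
})

test_that("cpm scales counts by effective library size plus prior", {
  m <- matrix(c(10, 999990, 0, 10, 999990, 0), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  x <- cpm(count_matrix(m))
  expect_equal(x["g1", "s1"], 10)
  expect_equal(x["g3", "s1"], 0)
  cm <- parse_counts(fixture_counts())
  expect_equal(cpm(cm)["FBgn0000008", "Treated1"], 140 / 8780 * 1e6,
               tolerance = 1e-12)
  expect_equal(round(cpm(cm)["FBgn0000008", "Treated1"], 2), 15945.33)
  # prior shifts every count before scaling
  x2 <- cpm(count_matrix(m), prior = 0.5)
  expect_equal(x2["g3", "s1"], 0.5 / 1e6 * 1e6)
  # misaligned factors are refused
  f <- norm_factors(c(a = 1, b = 2, c = 3))
  expect_error(cpm(cm, f), "do not match")
})

test_that("tmm factors are 1 for identical or depth-scaled samples", {
  set.seed(3)
  base <- rnbinom(200, mu = 50, size = 10) + 1L
  m <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(m) <- paste0("g", 1:200)
  f <- tmm_factors(count_matrix(m))
  expect_equal(unname(f$scale_factors), rep(1, 3), tolerance = 1e-12)
  m2 <- cbind(s1 = base, s2 = 2L * base)
  rownames(m2) <- paste0("g", 1:200)
  f2 <- tmm_factors(count_matrix(m2))
  expect_equal(unname(f2$scale_factors), c(1, 1), tolerance = 1e-12)
})

test_that("tmm matches the brute-force trim-and-weight oracle", {
  set.seed(11)
  for (rep in 1:10) {
    m <- unclass(random_counts(80, 2, mu = 60, size = 3))
    m[1, 1] <- m[1, 1] + 3000L  # composition skew
    cm <- count_matrix(m)
    f <- tmm_factors(cm)
    lib <- colSums(m)
    uq <- apply(sweep(m, 2, lib, "/"), 2, quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
    other <- setdiff(1:2, ref)
    raw <- c(1, 1)
    raw[other] <- tmm_pair_oracle(m[, other], m[, ref], lib[other], lib[ref])
    expected <- raw / exp(mean(log(raw)))
    expect_equal(unname(f$scale_factors), unname(expected), tolerance = 1e-10)
  }
})

test_that("tmm agrees with edgeR and geometric mean of factors is 1", {
  skip_if_not_installed("edgeR")
  set.seed(5)
  m <- unclass(random_counts(300, 4, mu = 100, size = 5))
  m[1, 1] <- 20000L
  f <- tmm_factors(count_matrix(m))
  expect_equal(exp(mean(log(f$scale_factors))), 1, tolerance = 1e-9)
  fe <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(f$scale_factors), unname(fe), tolerance = 1e-8)
})

test_that("tmm falls back to factor 1 when no gene is shared with the reference", {
  m <- matrix(c(5L, 0L, 8L, 0L, 0L, 7L, 0L, 9L), 4, 2,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  expect_warning(f <- tmm_factors(count_matrix(m)), "factor set to 1")
  expect_equal(unname(f$scale_factors), c(1, 1))
})

test_that("median-of-ratios size factors follow their defining formula", {
  m <- matrix(c(100, 10, 200, 20), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- size_factors_mor(count_matrix(m))
  expect_equal(round(unname(sf$scale_factors), 4), c(0.7071, 1.4142))
  # identical samples
  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(10, 20, 30))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(size_factors_mor(count_matrix(m2))$scale_factors),
               c(1, 1))
  # a zero in every gene
  m3 <- matrix(c(0L, 5L, 3L, 0L), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors_mor(count_matrix(m3)), "filter")
})

test_that("mor factors agree with DESeq2 and scale as c^((m-1)/m)", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  m <- unclass(random_counts(200, 4, mu = 80, size = 8)) + 1L
  sf <- size_factors_mor(count_matrix(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf$scale_factors), unname(ref), tolerance = 1e-2)
  # exact scaling law: multiplying one sample by c multiplies its factor
  # by c^((m-1)/m) and the others by c^(-1/m)
  c0 <- 3
  m2 <- m
  m2[, 2] <- m2[, 2] * c0
  sf2 <- size_factors_mor(count_matrix(m2))
  mm <- ncol(m)
  expect_equal(sf2$scale_factors[2], sf$scale_factors[2] * c0^((mm - 1) / mm),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sf2$scale_factors[-2], sf$scale_factors[-2] * c0^(-1 / mm),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("permuting samples permutes both factor schemes identically", {
  set.seed(13)
  m <- unclass(random_counts(150, 5, mu = 70, size = 4)) + 1L
  perm <- c(3, 1, 5, 2, 4)
  for (fun in list(tmm_factors, size_factors_mor)) {
    f1 <- fun(count_matrix(m))
    f2 <- fun(count_matrix(m[, perm]))
    expect_equal(unname(f2$scale_factors), unname(f1$scale_factors[perm]),
                 tolerance = 1e-12)
  }
})

test_that("tmm factors are near-invariant to depth scaling of one sample", {
  # M-values and the trimmed set are exactly invariant; only the
  # precision weights move, so factors agree to well under 1%
  set.seed(17)
  m <- unclass(random_counts(200, 3, mu = 90, size = 6)) + 1L
  f1 <- tmm_factors(count_matrix(m))
  m2 <- m
  m2[, 3] <- m2[, 3] * 4L
  f2 <- tmm_factors(count_matrix(m2))
  expect_equal(unname(f2$scale_factors), unname(f1$scale_factors),
               tolerance = 0.01)
})
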