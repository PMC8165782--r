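geno_fixture <- function(dos, pops = NULL) {
  n <- nrow(dos)
  if (is.null(pops)) pops <- rep(c("lean", "fat"), length.out = n)
  geno_matrix(dos,
              samples = tibble::tibble(sample_id = paste0("s_", seq_len(n)),
                                       population = pops),
              variants = tibble::tibble(snp_id = paste0("rs", seq_len(ncol(dos))),
                                        chrom = "Z",
                                        pos_bp = as.integer(seq_len(ncol(dos)) * 1000)))
}

test_that("duplicated samples have GRM entries equal to their diagonal", {
  withr::with_seed(11, {
    dos <- matrix(rbinom(10 * 50, 2, runif(50, 0.2, 0.8)), nrow = 10,
                  byrow = FALSE)
    dos[2, ] <- dos[1, ]
    k <- grm(geno_fixture(dos))
    expect_equal(k[1, 2], k[1, 1], tolerance = 1e-12)
    expect_equal(k[1, 2], k[2, 2], tolerance = 1e-12)
  })
})

test_that("the GRM matches a double-loop covariance oracle", {
  withr::with_seed(13, {
    dos <- matrix(rbinom(10 * 50, 2, runif(50, 0.2, 0.8)), nrow = 10)
    dos[dos == 2 & matrix(runif(500) < 0.05, 10)] <- NA  # some missing
    g <- geno_fixture(dos)
    k <- grm(g)
    p <- colMeans(dos, na.rm = TRUE) / 2
    z <- sweep(sweep(dos, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
    z[is.na(z)] <- 0
    want <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10) {
      want[i, j] <- sum(z[i, ] * z[j, ]) / 50
    }
    expect_equal(unname(k), want, tolerance = 1e-12)
  })
})

test_that("the GRM is symmetric with near-unit diagonal under HWE", {
  sim <- small_sim(seed = 19, fst = 0, m = 400, miss = 0)
  k <- grm(qc_filter(sim$geno)$geno)
  expect_true(isSymmetric(unname(k), tol = 1e-10))
  expect_equal(mean(diag(k)), 1, tolerance = 0.05)
  expect_error(grm(geno_fixture(matrix(2L, 6, 3))), class = "zsweep_invalid")
})

test_that("eigendecomposition is ordered, orthonormal and sign-fixed", {
  expect_error(eigendecompose(diag(4), k = 5), class = "zsweep_invalid")
  d_id <- eigendecompose(diag(4), k = 4)
  expect_equal(d_id$values, rep(1, 4))
  expect_equal(d_id$variance_explained, rep(0.25, 4))

  sim <- small_sim(seed = 29, fst = 0.3, m = 300, miss = 0)
  q <- qc_filter(sim$geno)$geno
  d <- eigendecompose(grm(q), k = 5)
  expect_true(all(diff(d$values) <= 1e-10))
  expect_equal(unname(crossprod(d$vectors)), diag(5), tolerance = 1e-8)
  expect_true(all(apply(d$vectors, 2,
                        function(v) v[which(abs(v) > 1e-12)[1]] > 0)))
  d2 <- eigendecompose(grm(q), k = 5)
  expect_identical(d$vectors, d2$vectors)
})

test_that("PC1 sign-partitions two well-separated populations", {
  sim <- small_sim(seed = 37, fst = 0.3, n_a = 60, n_b = 60, m = 500,
                   miss = 0)
  q <- qc_filter(sim$geno)$geno
  d <- eigendecompose(grm(q), k = 3)
  pc1 <- d$vectors[, 1]
  pop <- q$samples$population
  split1 <- all(pc1[pop == "lean"] > 0) && all(pc1[pop == "fat"] < 0)
  split2 <- all(pc1[pop == "lean"] < 0) && all(pc1[pop == "fat"] > 0)
  expect_true(split1 || split2)
})

test_that("the regression matches lm coefficient by coefficient", {
  sim <- small_sim(seed = 61, m = 60, miss = 0.05)
  q <- qc_filter(sim$geno)$geno
  sc <- eigengwas_scan(q, gc = FALSE)
  y <- sc$decomp$vectors[, 1]
  for (j in c(1, 5, 20, ncol(q$dosage))) {
    x <- q$dosage[, j]
    fit <- summary(stats::lm(y ~ x))$coefficients
    expect_equal(sc$results$b[j], fit["x", "Estimate"], tolerance = 1e-10)
    expect_equal(sc$results$se[j], fit["x", "Std. Error"], tolerance = 1e-10)
    expect_equal(sc$results$chi2_raw[j], fit["x", "t value"]^2,
                 tolerance = 1e-8)
  }
})

test_that("a response orthogonal to the dosage gives b = 0", {
  dos <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L), ncol = 1)
  g <- geno_fixture(cbind(dos, c(0L, 1L, 1L, 0L, 2L, 1L)))
  d <- eigendecompose(diag(6), k = 2)
  d$vectors[, 1] <- c(-1, 0, 1, 1, 0, -1) / 2  # orthogonal to centred x1
  sc <- eigengwas_scan(g, decomp = d, gc = FALSE)
  expect_equal(sc$results$b[1], 0, tolerance = 1e-12)
  expect_equal(sc$results$chi2_raw[1], 0, tolerance = 1e-12)
})

test_that("allele-label swap negates b and preserves the statistic", {
  sim <- small_sim(seed = 67, m = 50, miss = 0)
  g <- qc_filter(sim$geno)$geno
  sc1 <- eigengwas_scan(g, gc = FALSE)
  g2 <- g
  g2$dosage <- 2L - g2$dosage
  sc2 <- eigengwas_scan(g2, decomp = sc1$decomp, gc = FALSE)
  expect_equal(sc2$results$b, -sc1$results$b, tolerance = 1e-10)
  expect_equal(sc2$results$chi2_raw, sc1$results$chi2_raw, tolerance = 1e-8)
})

test_that("a fixed-difference SNP dominates the scan", {
  sim <- small_sim(seed = 71, fst = 0.3, m = 200, miss = 0)
  g <- qc_filter(sim$geno)$geno
  fixed <- as.integer(g$samples$population == "fat") * 2L
  g$dosage[, 100] <- fixed
  sc <- eigengwas_scan(g)
  expect_identical(which.max(sc$results$chi2_raw), 100L)
})

test_that("null-data inflation equals the leading GRM eigenvalue", {
  # regressing PC1 of the GRM on the SNPs that built it inflates the median
  # chi-square to the top eigenvalue (the Marchenko-Pastur bulk edge
  # (1 + sqrt(n/M))^2 when there is no structure), which is precisely what
  # the genomic-control division removes; calibrated over pilot seeds
  lam <- sapply(1:3, function(s) {
    sim <- simulate_divergent_pops(pop_sim_config(
      n_pop_A = 50, n_pop_B = 50, n_snps = 1000, fst_target = 0,
      missing_rate = 0, seed = s))
    sc <- eigengwas_scan(qc_filter(sim$geno)$geno)
    c(sc$lambda_gc, sc$decomp$values[1], sum(sc$results$significant))
  })
  edge <- (1 + sqrt(100 / 1000))^2
  expect_true(all(lam[1, ] / lam[2, ] > 0.85 & lam[1, ] / lam[2, ] < 1.15))
  expect_true(all(lam[1, ] / edge > 0.8 & lam[1, ] / edge < 1.2))
  # after genomic control, family-wise error is held in almost all seeds
  expect_lte(sum(lam[3, ] > 0), 1)
})

test_that("the Bonferroni threshold is alpha over the test count", {
  expect_equal(signif(bonferroni_threshold(0.05, 1937), 3), 2.58e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 50), 0.001)
})
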