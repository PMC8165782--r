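dos_from_gametes <- function(n_gametes, n_alt) {
  # pack gamete counts into diploid dosages (pairs of gametes)
  stopifnot(n_gametes %% 2 == 0)
  g <- c(rep(1L, n_alt), rep(0L, n_gametes - n_alt))
  g[seq(1, n_gametes, 2)] + g[seq(2, n_gametes, 2)]
}

test_that("complete fixation between populations gives F_ST of 1", {
  res <- snp_fst(dos_from_gametes(10, 10), dos_from_gametes(10, 0))
  expect_equal(res$fst, 1)
})

test_that("identical allele frequencies give a non-positive estimate", {
  res <- snp_fst(dos_from_gametes(20, 10), dos_from_gametes(20, 10))
  expect_lte(res$fst, 0)
})

test_that("the estimator matches the brute-force ANOVA oracle", {
  # the worked 8/10 vs 2/10 gamete table
  res <- snp_fst(dos_from_gametes(10, 8), dos_from_gametes(10, 2))
  orc <- oracle_fst(10, 8, 10, 2)
  expect_equal(res$fst, orc$fst, tolerance = 1e-12)
  expect_equal(res$msp, orc$msp, tolerance = 1e-12)
  expect_equal(res$msg, orc$msg, tolerance = 1e-12)
  expect_equal(res$n_c, orc$n_c, tolerance = 1e-12)

  # 200 random count tables, including unbalanced sizes
  withr::with_seed(101, {
    for (i in 1:200) {
      n1 <- 2 * sample(2:30, 1)
      n2 <- 2 * sample(2:30, 1)
      c1 <- sample(0:n1, 1)
      c2 <- sample(0:n2, 1)
      if (c1 + c2 == 0 || c1 + c2 == n1 + n2) next  # monomorphic handled below
      res <- snp_fst(dos_from_gametes(n1, c1), dos_from_gametes(n2, c2))
      orc <- oracle_fst(n1, c1, n2, c2)
      expect_equal(res$fst, orc$fst, tolerance = 1e-12,
                   label = sprintf("table %d/%d %d/%d", c1, n1, c2, n2))
    }
  })
})

test_that("the estimator is invariant to swapping allele labels", {
  withr::with_seed(7, {
    for (i in 1:20) {
      a <- sample(0:2, 12, replace = TRUE)
      b <- sample(0:2, 16, replace = TRUE)
      if ((sum(a) + sum(b)) %in% c(0, 2 * (12 + 16))) next
      expect_equal(snp_fst(a, b)$fst, snp_fst(2L - a, 2L - b)$fst,
                   tolerance = 1e-12)
    }
  })
})

test_that("degenerate inputs are flagged, not silently scored", {
  res <- snp_fst(c(0L, 0L, 0L), c(0L, 0L))
  expect_identical(res$fst, 0)
  expect_true(res$monomorphic)
  expect_error(snp_fst(c(NA_integer_, NA_integer_), c(1L, 1L)),
               class = "zsweep_invalid")
})

test_that("the Tukey fence follows the quartile formula", {
  expect_equal(tukey_threshold(c(0.2, 0.2, 0.4, 0.4)), 0.7)
  expect_equal(tukey_threshold(rep(0.3, 10)), 0.3)
  withr::with_seed(5, {
    x <- runif(1000)
    q <- unname(quantile(x, c(0.25, 0.75), type = 7))
    expect_equal(tukey_threshold(x), q[2] + 1.5 * (q[2] - q[1]),
                 tolerance = 1e-12)
  })
  expect_error(tukey_threshold(c(1, 2, 3)), class = "zsweep_invalid")
})

test_that("windows cover a lone SNP exactly and average within windows", {
  one <- tibble::tibble(pos_bp = 50000, fst = 0.6)
  w <- window_scan(one)
  expect_identical(w$start_bp, seq(0, 50000, by = 10000))
  expect_true(all(w$mean_fst == 0.6))
  expect_true(all(w$end_bp - w$start_bp == 100000))

  two <- tibble::tibble(pos_bp = c(20000, 30000), fst = c(0.2, 0.4))
  w2 <- window_scan(two)
  expect_equal(w2$mean_fst[w2$start_bp == 0], 0.3)
})

test_that("window means equal a brute-force per-window recomputation", {
  sim <- small_sim(seed = 21, m = 400)
  fs <- snp_fst_table(sim$geno)
  w <- window_scan(fs)
  for (i in seq_len(nrow(w))) {
    inside <- fs$pos_bp >= w$start_bp[i] & fs$pos_bp < w$end_bp[i] &
      !is.na(fs$fst)
    expect_identical(w$n_snps[i], sum(inside))
    expect_equal(w$mean_fst[i], mean(fs$fst[inside]), tolerance = 1e-12)
  }
  # no empty windows are reported
  expect_true(all(w$n_snps >= 1))
})

test_that("window means are invariant to SNP input order", {
  sim <- small_sim(seed = 22, m = 200)
  fs <- snp_fst_table(sim$geno)
  shuffled <- fs[sample(nrow(fs)), ]
  expect_equal(window_scan(fs), window_scan(shuffled))
})

test_that("outlier calling is strict and data-driven", {
  flat <- tibble::tibble(start_bp = seq(0, 9e4, 1e4), end_bp = seq(1e5, 1.9e5, 1e4),
                         n_snps = 1L, mean_fst = 0.3)
  expect_identical(sum(call_outlier_windows(flat)$is_outlier), 0L)
  spike <- flat
  spike$mean_fst[5] <- 3
  called <- call_outlier_windows(spike)
  expect_identical(which(called$is_outlier), 5L)
})

test_that("a simulated sweep produces outlier windows over the sweep span", {
  sim <- simulate_divergent_pops(pop_sim_config(
    n_pop_A = 80, n_pop_B = 80, n_snps = 600, chrom_length_bp = 20e6,
    fst_target = 0.05, missing_rate = 0, seed = 33))
  swept <- inject_sweep(sim$haps, sweep_config("fat", 10e6, 2e6,
                                               carrier_fraction = 1,
                                               seed = 33))
  g <- haplotypes_to_geno(swept)
  scan <- fst_scan(g)
  out <- scan$windows[scan$windows$is_outlier, ]
  expect_gt(nrow(out), 0)
  expect_true(any(out$start_bp <= 11e6 & out$end_bp >= 9e6))
})

test_that("few windows breach the fence when nothing is selected", {
  frac <- sapply(1:3, function(s) {
    sim <- simulate_divergent_pops(pop_sim_config(
      n_pop_A = 50, n_pop_B = 50, n_snps = 500, chrom_length_bp = 20e6,
      fst_target = 0, missing_rate = 0, seed = s))
    scan <- fst_scan(sim$geno)
    mean(scan$windows$is_outlier)
  })
  expect_true(all(frac < 0.10))
})
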