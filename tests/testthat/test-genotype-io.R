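vcf_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a small VCF is transcribed into dosages exactly", {
  path <- vcf_fixture(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "lean_1", "lean_2", "fat_1", sep = "\t"),
    paste("Z", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("Z", "250", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0|1", "./.", "0|0", sep = "\t")
  ))
  g <- read_genotypes(path, "vcf")
  expect_identical(dim(g), c(3L, 2L))
  expect_identical(unname(g$dosage[, 1]), c(0L, 1L, 2L))
  expect_identical(unname(g$dosage[, 2]), c(1L, NA_integer_, 0L))
  expect_identical(g$variants$pos_bp, c(100L, 250L))
  # population from sample-name convention
  expect_identical(g$samples$population, c("lean", "lean", "fat"))
})

test_that("multi-allelic sites are rejected with the offending id", {
  path <- vcf_fixture(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s_1", sep = "\t"),
    paste("Z", "100", "rs_tri", "A", "G,T", ".", "PASS", ".", "GT",
          "0/1", sep = "\t")
  ))
  expect_error(read_genotypes(path, "vcf"), "rs_tri",
               class = "zsweep_multiallelic")
})

test_that("write/read round-trips preserve dosages, ids and positions", {
  sim <- small_sim(seed = 5, miss = 0.05)
  g <- sim$geno
  for (fmt in c("vcf", "matrix_tsv", "plink_text")) {
    ext <- c(vcf = ".vcf", matrix_tsv = ".tsv", plink_text = ".ped")[[fmt]]
    path <- withr::local_tempfile(fileext = ext)
    write_genotypes(g, path, fmt)
    g2 <- read_genotypes(path, fmt,
                         variants = if (fmt == "matrix_tsv")
                           paste0(path, ".variants.tsv") else NULL)
    expect_identical(unname(g2$dosage), unname(g$dosage), label = fmt)
    expect_identical(g2$variants$snp_id, g$variants$snp_id, label = fmt)
    expect_identical(g2$variants$pos_bp, g$variants$pos_bp, label = fmt)
    expect_identical(g2$samples$population, g$samples$population, label = fmt)
  }
})

test_that("phased VCF round-trips the haplotypes themselves", {
  sim <- small_sim(seed = 9, n_a = 10, n_b = 10, m = 40, miss = 0)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(sim$geno, path, "vcf", haplotypes = sim$haps)
  h2 <- read_haplotypes(path)
  ord <- order(match(h2$sample_id, sim$haps$sample_id))
  expect_identical(unname(h2$hap[ord, ]), unname(sim$haps$hap))
  expect_identical(h2$positions_bp, sim$haps$positions_bp)
  # unphased files refuse to masquerade as haplotypes
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(sim$geno, path2, "vcf")
  expect_error(read_haplotypes(path2), class = "zsweep_parse_error")
})

test_that("QC removes low call rate and low MAF in the documented order", {
  set.seed(1)
  n <- 100
  dos <- matrix(1L, nrow = n, ncol = 4)
  dos[, 1] <- rbinom(n, 2, 0.5)
  dos[1:6, 1] <- NA         # call rate 0.94 < 0.95
  dos[, 2] <- rbinom(n, 2, 0.5)
  dos[, 3] <- 0L; dos[1, 3] <- 1L   # MAF 0.005 < 0.01
  dos[, 4] <- rbinom(n, 2, 0.4)
  g <- geno_matrix(
    dos,
    samples = tibble::tibble(sample_id = paste0("s_", 1:n),
                             population = rep(c("lean", "fat"), n / 2)),
    variants = tibble::tibble(snp_id = paste0("rs", 1:4), chrom = "Z",
                              pos_bp = c(100L, 200L, 300L, 400L))
  )
  out <- qc_filter(g)
  rem <- out$report$removed
  expect_setequal(rem$id, c("rs1", "rs3"))
  expect_identical(rem$reason[rem$id == "rs1"], "call_rate")
  expect_identical(rem$reason[rem$id == "rs3"], "maf")
  expect_identical(out$report$n_snps_out, 2L)
  expect_identical(out$geno$variants$snp_id, c("rs2", "rs4"))
})

test_that("QC keeps boundary values and is idempotent", {
  sim <- small_sim(seed = 3, miss = 0.03)
  out1 <- qc_filter(sim$geno, snp_call_rate = 0.9, sample_call_rate = 0.9,
                    maf_min = 0.05)
  out2 <- qc_filter(out1$geno, snp_call_rate = 0.9, sample_call_rate = 0.9,
                    maf_min = 0.05)
  expect_identical(out2$geno$dosage, out1$geno$dosage)
  expect_identical(nrow(out2$report$removed), 0L)

  # a zero-missingness MAF-0.5 SNP survives any threshold <= 0.5
  dos <- cbind(rep(c(0L, 2L), 10), rep(1L, 20))
  g <- geno_matrix(
    dos,
    samples = tibble::tibble(sample_id = paste0("s_", 1:20),
                             population = rep(c("lean", "fat"), 10)),
    variants = tibble::tibble(snp_id = c("a", "b"), chrom = "Z",
                              pos_bp = c(10L, 20L))
  )
  out <- qc_filter(g, maf_min = 0.5)
  expect_identical(out$report$n_snps_out, 2L)

  # exact 0.95 call rate survives (keep-if->=-threshold semantics)
  dos2 <- matrix(rbinom(40 * 2, 2, 0.5), ncol = 2)
  dos2[1:2, 1] <- NA  # call rate exactly 0.95
  g2 <- geno_matrix(
    dos2,
    samples = tibble::tibble(sample_id = paste0("s_", 1:40),
                             population = rep(c("lean", "fat"), 20)),
    variants = tibble::tibble(snp_id = c("x", "y"), chrom = "Z",
                              pos_bp = c(10L, 20L))
  )
  expect_identical(qc_filter(g2)$report$n_snps_out, 2L)
})

test_that("container validators reject inconsistent inputs", {
  expect_error(
    geno_matrix(matrix(0L, 2, 2),
                samples = tibble::tibble(sample_id = c("a", "a"),
                                         population = c("x", "y")),
                variants = tibble::tibble(snp_id = c("r1", "r2"), chrom = "Z",
                                          pos_bp = c(1L, 2L))),
    class = "zsweep_invalid")
  expect_error(
    haplotype_set(matrix(0L, 3, 2), positions_bp = c(5L, 10L),
                  sample_id = c("a", "a", "b"),
                  population = c("x", "x", "y")),
    class = "zsweep_invalid")
  expect_error(
    haplotype_set(matrix(0L, 2, 2), positions_bp = c(10L, 5L),
                  sample_id = c("a", "a"), population = c("x", "x")),
    class = "zsweep_invalid")
})
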