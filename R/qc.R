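#' Quality-control filtering of a genotype matrix
#'
#' Applies the three chip-QC filters in a fixed order: (1) SNP call rate,
#' (2) sample call rate (on the surviving SNPs), (3) minor allele frequency
#' recomputed on the surviving samples. Thresholds are "keep if >= threshold"
#' (PLINK semantics), so boundary values survive. Applying the filter twice
#' is a no-op: the second report is empty.
#'
#' @param g a [geno_matrix()].
#' @param snp_call_rate minimum fraction of called samples per SNP.
#' @param sample_call_rate minimum fraction of called SNPs per sample.
#' @param maf_min minimum minor allele frequency.
#' @return a list with elements `geno` (the filtered [geno_matrix()]) and
#'   `report` (a `qc_report`: counts in/out per axis, a `removed` tibble with
#'   one row per removal carrying `axis`, `id`, `reason`, `value`, and the
#'   thresholds used).
#' @export
qc_filter <- function(g, snp_call_rate = 0.95, sample_call_rate = 0.95,
                      maf_min = 0.01) {
  if (nrow(g$dosage) == 0 || ncol(g$dosage) == 0) {
    abort("empty genotype matrix", class = "zsweep_invalid")
  }
  n_snps_in <- ncol(g$dosage)
  n_samples_in <- nrow(g$dosage)
  removed <- list()

  called <- !is.na(g$dosage)
  snp_cr <- colMeans(called)
  drop_snp <- snp_cr < snp_call_rate
  if (any(drop_snp)) {
    removed$snp_cr <- tibble(axis = "snp", id = g$variants$snp_id[drop_snp],
                             reason = "call_rate", value = snp_cr[drop_snp])
  }
  dos <- g$dosage[, !drop_snp, drop = FALSE]
  variants <- g$variants[!drop_snp, ]

  samp_cr <- rowMeans(!is.na(dos))
  drop_samp <- samp_cr < sample_call_rate
  if (any(drop_samp)) {
    removed$samp_cr <- tibble(axis = "sample",
                              id = g$samples$sample_id[drop_samp],
                              reason = "call_rate", value = samp_cr[drop_samp])
  }
  dos <- dos[!drop_samp, , drop = FALSE]
  samples <- g$samples[!drop_samp, ]

  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # SNP with zero calls left after sample removal
  drop_maf <- maf < maf_min
  if (any(drop_maf)) {
    removed$maf <- tibble(axis = "snp", id = variants$snp_id[drop_maf],
                          reason = "maf", value = maf[drop_maf])
  }
  dos <- dos[, !drop_maf, drop = FALSE]
  variants <- variants[!drop_maf, ]

  if (ncol(dos) == 0) {
    abort("QC removed every SNP", class = "zsweep_empty_result")
  }

  removed <- if (length(removed)) bind_rows(removed) else
    tibble(axis = character(), id = character(), reason = character(),
           value = double())
  report <- structure(
    list(n_snps_in = n_snps_in, n_snps_out = ncol(dos),
         n_samples_in = n_samples_in, n_samples_out = nrow(dos),
         removed = removed,
         thresholds = list(snp_call_rate = snp_call_rate,
                           sample_call_rate = sample_call_rate,
                           maf_min = maf_min)),
    class = "qc_report"
  )
  stopifnot(report$n_snps_out == n_snps_in - sum(removed$axis == "snp"),
            report$n_samples_out == n_samples_in - sum(removed$axis == "sample"))
  list(geno = geno_matrix(dos, samples, variants), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n",
      "  SNPs:    ", x$n_snps_in, " -> ", x$n_snps_out, "\n",
      "  samples: ", x$n_samples_in, " -> ", x$n_samples_out, "\n", sep = "")
  if (nrow(x$removed)) {
    tab <- table(x$removed$axis, x$removed$reason)
    print(tab)
  }
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) x$removed

#' @export
glance.qc_report <- function(x, ...) {
  tibble(n_snps_in = x$n_snps_in, n_snps_out = x$n_snps_out,
         n_samples_in = x$n_samples_in, n_samples_out = x$n_samples_out,
         snp_call_rate = x$thresholds$snp_call_rate,
         sample_call_rate = x$thresholds$sample_call_rate,
         maf_min = x$thresholds$maf_min)
}
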