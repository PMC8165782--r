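#' Genotype matrix container
#'
#' Bundles a dosage matrix (samples x SNPs, counted-allele copies 0/1/2,
#' `NA` = missing) with its sample table (id + population label) and variant
#' table (id, chromosome, 1-based position in bp). All downstream scans
#' consume this container.
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}`. `NA` is the missing sentinel and is never conflated
#'   with dosage 0.
#' @param samples data frame with columns `sample_id`, `population`.
#' @param variants data frame with columns `snp_id`, `chrom`, `pos_bp`
#'   (integer, 1-based). Must be sorted by (`chrom`, `pos_bp`).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, samples, variants) {
  samples <- as_tibble(samples)
  variants <- as_tibble(variants)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  g <- structure(
    list(dosage = dosage, samples = samples, variants = variants),
    class = "geno_matrix"
  )
  validate_geno_matrix(g)
}

validate_geno_matrix <- function(g) {
  stopifnot(is.matrix(g$dosage))
  if (nrow(g$dosage) != nrow(g$samples)) {
    abort("dosage rows must match the sample table", class = "zsweep_invalid")
  }
  if (ncol(g$dosage) != nrow(g$variants)) {
    abort("dosage columns must match the variant table", class = "zsweep_invalid")
  }
  if (!all(c("sample_id", "population") %in% names(g$samples))) {
    abort("sample table needs sample_id and population columns", class = "zsweep_invalid")
  }
  if (!all(c("snp_id", "chrom", "pos_bp") %in% names(g$variants))) {
    abort("variant table needs snp_id, chrom and pos_bp columns", class = "zsweep_invalid")
  }
  if (anyDuplicated(g$samples$sample_id)) {
    abort("duplicate sample ids", class = "zsweep_invalid")
  }
  if (anyDuplicated(g$variants$snp_id)) {
    abort("duplicate SNP ids", class = "zsweep_invalid")
  }
  if (any(g$variants$pos_bp < 1, na.rm = TRUE)) {
    abort("positions must be >= 1 (1-based bp)", class = "zsweep_invalid")
  }
  ord <- order(g$variants$chrom, g$variants$pos_bp)
  if (!identical(ord, seq_len(nrow(g$variants)))) {
    abort("variants must be sorted by (chrom, pos_bp)", class = "zsweep_invalid")
  }
  bad <- g$dosage[!is.na(g$dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    abort("dosages must be 0, 1, 2 or NA", class = "zsweep_invalid")
  }
  dimnames(g$dosage) <- list(g$samples$sample_id, g$variants$snp_id)
  g
}

#' @export
print.geno_matrix <- function(x, ...) {
  pops <- table(x$samples$population)
  cat("<geno_matrix> ", nrow(x$dosage), " samples x ", ncol(x$dosage), " SNPs\n",
      sep = "")
  cat("  populations: ",
      paste(names(pops), pops, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  missing dosage: ",
      sprintf("%.2f%%", 100 * mean(is.na(x$dosage))), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Dosages of one population
#'
#' @param g a [geno_matrix()].
#' @param population population label to extract.
#' @return integer matrix of dosages for the samples of that population.
#' @export
pop_dosage <- function(g, population) {
  keep <- g$samples$population == population
  if (!any(keep)) abort(paste0("no samples in population '", population, "'"),
                        class = "zsweep_invalid")
  g$dosage[keep, , drop = FALSE]
}

#' Phased haplotype container
#'
#' Holds binary haplotypes (two rows per diploid sample; the study design is
#' all-male ZZ birds, so every sample is diploid for Z) at strictly increasing
#' physical positions.
#'
#' @param hap binary matrix, `2 * n_samples` rows by `n_snps` columns,
#'   entries 0/1 (copies of the counted allele).
#' @param positions_bp strictly increasing integer positions (bp, 1-based).
#' @param sample_id character, one entry per haplotype row (each sample id
#'   appears exactly twice).
#' @param population population label per haplotype row.
#' @param snp_id optional SNP ids (default `snp1..snpM`).
#' @param chrom chromosome name (single chromosome per set).
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(hap, positions_bp, sample_id, population,
                          snp_id = NULL, chrom = "Z") {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(ncol(hap)))
  h <- structure(
    list(hap = hap, positions_bp = as.integer(positions_bp),
         sample_id = as.character(sample_id),
         population = as.character(population),
         snp_id = as.character(snp_id), chrom = chrom),
    class = "haplotype_set"
  )
  validate_haplotype_set(h)
}

validate_haplotype_set <- function(h) {
  if (length(h$positions_bp) != ncol(h$hap)) {
    abort("positions must match haplotype columns", class = "zsweep_invalid")
  }
  if (is.unsorted(h$positions_bp, strictly = TRUE)) {
    abort("positions must be strictly increasing", class = "zsweep_invalid")
  }
  if (!all(h$hap %in% c(0L, 1L))) {
    abort("haplotype entries must be 0/1", class = "zsweep_invalid")
  }
  if (length(h$sample_id) != nrow(h$hap) ||
      length(h$population) != nrow(h$hap)) {
    abort("one sample id and population per haplotype row",
          class = "zsweep_invalid")
  }
  cnt <- table(h$sample_id)
  if (any(cnt != 2L)) {
    abort("exactly 2 haplotype rows per sample (diploid ZZ design)",
          class = "zsweep_invalid")
  }
  h
}

#' @export
print.haplotype_set <- function(x, ...) {
  pops <- table(x$population)
  cat("<haplotype_set> ", nrow(x$hap), " haplotypes (",
      nrow(x$hap) / 2, " samples) x ", ncol(x$hap), " SNPs on ", x$chrom,
      "\n  haplotypes per population: ",
      paste(names(pops), pops, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Haplotype rows of one population
#'
#' @param h a [haplotype_set()].
#' @param population population label.
#' @return binary matrix of that population's haplotype rows.
#' @export
pop_haplotypes <- function(h, population) {
  keep <- h$population == population
  if (sum(keep) < 2) abort("need >= 2 haplotypes in the population",
                           class = "zsweep_invalid")
  h$hap[keep, , drop = FALSE]
}

#' Collapse haplotypes to genotype dosages
#'
#' Sums the two haplotype rows of each sample into counted-allele dosage and
#' wraps the result as a [geno_matrix()].
#'
#' @param h a [haplotype_set()].
#' @return a [geno_matrix()] with no missing dosages.
#' @export
haplotypes_to_geno <- function(h) {
  ids <- unique(h$sample_id)
  dos <- vapply(ids, function(s) {
    colSums(h$hap[h$sample_id == s, , drop = FALSE])
  }, numeric(ncol(h$hap)))
  dos <- t(dos)
  pops <- h$population[match(ids, h$sample_id)]
  geno_matrix(
    dosage = dos,
    samples = tibble(sample_id = ids, population = pops),
    variants = tibble(snp_id = h$snp_id, chrom = h$chrom,
                      pos_bp = h$positions_bp)
  )
}
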