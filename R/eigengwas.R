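#' Genomic relationship matrix
#'
#' Standardised GRM: per SNP, dosages are centred by `2p` and scaled by
#' `sqrt(2p(1-p))` (`p` = counted-allele frequency over called samples);
#' missing entries are set to 0 after centring (mean imputation on the
#' standardised scale); `GRM = Z Z' / M` over the M SNPs.
#'
#' @param g a [geno_matrix()] after QC; every SNP must be polymorphic.
#' @return samples x samples numeric matrix with sample ids as dimnames.
#' @export
grm <- function(g) {
  x <- g$dosage
  p <- colMeans(x, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1)) {
    abort("monomorphic SNP present; run qc_filter first",
          class = "zsweep_invalid")
  }
  z <- sweep(x, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  k <- tcrossprod(z) / ncol(x)
  dimnames(k) <- list(g$samples$sample_id, g$samples$sample_id)
  k
}

#' Eigendecomposition of a relationship matrix
#'
#' Top-k eigenpairs in descending order. The variance explained by component
#' i is `lambda_i / sum(lambda_+)` over the non-negative eigenvalues.
#' Eigenvector signs are fixed by forcing the first nonzero loading positive,
#' so the output is deterministic across runs and platforms.
#'
#' @param k_mat symmetric relationship matrix (e.g. [grm()]).
#' @param k number of components to keep.
#' @return object of class `eigen_decomp`: `values` (length k),
#'   `vectors` (samples x k), `variance_explained` (length k).
#' @export
eigendecompose <- function(k_mat, k = 10) {
  if (!isSymmetric(unname(k_mat), tol = 1e-8)) {
    abort("relationship matrix must be symmetric", class = "zsweep_invalid")
  }
  if (k > nrow(k_mat)) abort("k exceeds matrix dimension",
                             class = "zsweep_invalid")
  e <- eigen(k_mat, symmetric = TRUE)
  vals <- e$values[seq_len(k)]
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    nz <- which(abs(vecs[, j]) > 1e-12)[1]
    if (!is.na(nz) && vecs[nz, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- rownames(k_mat)
  colnames(vecs) <- paste0("PC", seq_len(k))
  total <- sum(pmax(e$values, 0))
  structure(
    list(values = vals, vectors = vecs,
         variance_explained = vals / total),
    class = "eigen_decomp"
  )
}

#' @export
print.eigen_decomp <- function(x, ...) {
  cat("<eigen_decomp> ", ncol(x$vectors), " components\n", sep = "")
  ve <- sprintf("%.1f%%", 100 * x$variance_explained[seq_len(min(3, length(x$values)))])
  cat("  variance explained: ", paste(ve, collapse = ", "),
      if (length(x$values) > 3) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.eigen_decomp <- function(x, ...) {
  as_tibble(x$vectors) |>
    mutate(sample_id = rownames(x$vectors) %||%
             as.character(seq_len(nrow(x$vectors))), .before = 1)
}

#' @export
glance.eigen_decomp <- function(x, ...) {
  tibble(component = seq_along(x$values), eigenvalue = x$values,
         variance_explained = x$variance_explained)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' EigenGWAS scan: regress an eigenvector on each SNP
#'
#' Fits the single-marker model `y = mu + b x + e` per SNP, where `y` is the
#' chosen eigenvector of the GRM (an axis of population structure) and `x`
#' the dosage; SNPs whose allele frequencies drive that axis get large
#' statistics. Missing dosages are dropped per SNP (complete-case OLS).
#' `chi2_raw = (b / se)^2`; genomic control divides by
#' `lambda_GC = median(chi2_raw) / 0.4549` (the 1-df chi-square null median)
#' to deflate the drift-driven inflation; p-values come from the 1-df
#' chi-square upper tail and significance is Bonferroni at `alpha / M`.
#'
#' @param g a [geno_matrix()] after QC.
#' @param eigvec eigenvector (component) index to test; PC1 by default, the
#'   axis that separates two diverged lines.
#' @param k number of components computed.
#' @param gc apply genomic control (`TRUE` by default; set `FALSE` for the
#'   uncorrected scan).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param decomp optionally a precomputed [eigendecompose()] result.
#' @return object of class `eigengwas_scan`: list with `results` (tibble
#'   `snp_id`, `pos_bp`, `b`, `se`, `chi2_raw`, `chi2_gc`, `p_value`,
#'   `significant`), `lambda_gc`, `threshold`, `decomp`, `n_unscored`,
#'   `params`.
#' @export
eigengwas_scan <- function(g, eigvec = 1, k = 10, gc = TRUE, alpha = 0.05,
                           decomp = NULL) {
  k <- min(k, nrow(g$dosage))
  if (is.null(decomp)) decomp <- eigendecompose(grm(g), k = k)
  y <- decomp$vectors[, eigvec]
  x <- g$dosage
  called <- !is.na(x)
  nj <- unname(colSums(called))
  sx <- unname(colSums(x, na.rm = TRUE))
  sx2 <- unname(colSums(x^2, na.rm = TRUE))
  sy <- unname(crossprod(called, y)[, 1])
  sy2 <- unname(crossprod(called, y^2)[, 1])
  sxy <- unname(colSums(x * y, na.rm = TRUE))
  sxx <- sx2 - sx^2 / nj
  syy <- sy2 - sy^2 / nj
  sxy_c <- sxy - sx * sy / nj
  scorable <- nj >= 3 & sxx > 0
  b <- ifelse(scorable, sxy_c / sxx, NA_real_)
  ss_res <- pmax(syy - b * sxy_c, 0)
  se <- sqrt(ss_res / (nj - 2) / sxx)
  chi2_raw <- (b / se)^2
  chi2_raw[!scorable] <- NA_real_
  lambda <- median(chi2_raw, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
  chi2_gc <- if (gc) chi2_raw / lambda else chi2_raw
  p <- pchisq(chi2_gc, df = 1, lower.tail = FALSE)
  m_tests <- sum(scorable)
  thr <- bonferroni_threshold(alpha, m_tests)
  results <- tibble(
    snp_id = g$variants$snp_id, pos_bp = g$variants$pos_bp,
    b = b, se = se, chi2_raw = chi2_raw, chi2_gc = chi2_gc,
    p_value = p, significant = !is.na(p) & p < thr
  )
  structure(
    list(results = results, lambda_gc = lambda, threshold = thr,
         decomp = decomp, n_unscored = sum(!scorable),
         params = list(eigvec = eigvec, gc = gc, alpha = alpha,
                       m_tests = m_tests)),
    class = "eigengwas_scan"
  )
}

#' @export
print.eigengwas_scan <- function(x, ...) {
  cat("<eigengwas_scan> PC", x$params$eigvec, " on ", nrow(x$results),
      " SNPs (", x$n_unscored, " unscored)\n",
      "  lambda_GC = ", sprintf("%.3f", x$lambda_gc),
      "; Bonferroni threshold = ", format(x$threshold, digits = 3),
      "; significant: ", sum(x$results$significant), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.eigengwas_scan <- function(x, ...) as_tibble(x$results)

#' @export
glance.eigengwas_scan <- function(x, ...) {
  tibble(n_snps = nrow(x$results), n_unscored = x$n_unscored,
         n_significant = sum(x$results$significant),
         lambda_gc = x$lambda_gc, threshold = x$threshold,
         eigvec = x$params$eigvec,
         variance_explained = x$decomp$variance_explained[x$params$eigvec])
}
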