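#' Extended haplotype homozygosity curve
#'
#' EHH at a site j outward from a core SNP is the probability that two
#' haplotypes drawn at random from the population carry identical alleles at
#' every SNP from the core through j: haplotypes are partitioned by their
#' extended haplotype (core included) and
#' `EHH = sum_h C(n_h, 2) / C(n, 2)` over the partition classes. The curve
#' starts at the core with the core-site homozygosity and is non-increasing
#' outward. All haplotypes of the population enter the partition (single-core
#' population convention, the one used for cross-population comparison).
#'
#' @param h a [haplotype_set()].
#' @param core_index column index of the core SNP.
#' @param population population label.
#' @param direction `"left"` or `"right"` of the core.
#' @return tibble of curve points `pos_bp`, `ehh` (the first row is the core
#'   site), with attributes `core_index` and `direction`.
#' @export
ehh <- function(h, core_index, population, direction = c("left", "right")) {
  direction <- match.arg(direction)
  if (core_index < 1 || core_index > ncol(h$hap)) {
    abort("core index out of range", class = "zsweep_invalid")
  }
  hapm <- pop_haplotypes(h, population)
  idx <- if (direction == "left") seq(core_index, 1L) else
    seq(core_index, ncol(h$hap))
  vals <- ehh_walk(hapm, idx)
  structure(tibble(pos_bp = h$positions_bp[idx], ehh = vals),
            core_index = core_index, direction = direction)
}

# homozygosity along a path of SNP columns, refining the haplotype partition
# one SNP at a time; stops once ehh < stop_below (that point included)
ehh_walk <- function(hapm, idx, stop_below = 0) {
  n <- nrow(hapm)
  pairs_total <- n * (n - 1) / 2
  ids <- rep(1L, n)
  out <- numeric(length(idx))
  for (k in seq_along(idx)) {
    key <- ids * 2L + hapm[, idx[k]]
    ids <- match(key, unique(key))
    cnt <- tabulate(ids)
    out[k] <- sum(cnt * (cnt - 1) / 2) / pairs_total
    if (out[k] < stop_below) {
      out <- out[seq_len(k)]
      break
    }
  }
  out
}

#' Integrated haplotype homozygosity at a core SNP
#'
#' Trapezoidal integral of the left and right EHH curves over physical
#' distance (bp), truncated at the first point where EHH falls below
#' `ehh_cutoff` (the segment reaching that point is included). Gaps between
#' adjacent SNPs larger than `max_gap_bp` contribute at most `max_gap_bp` of
#' width, guarding sparse regions. A chromosome edge simply ends the curve on
#' that side.
#'
#' @inheritParams ehh
#' @param ehh_cutoff truncation level for the integral.
#' @param max_gap_bp maximum width a single inter-SNP gap can contribute.
#' @return the integral in bp x EHH units; `NA` with a degenerate-core
#'   condition when the core-site homozygosity itself is below the cutoff.
#' @export
ihh <- function(h, core_index, population, ehh_cutoff = 0.05,
                max_gap_bp = 200000) {
  hapm <- pop_haplotypes(h, population)
  ihh_core(hapm, h$positions_bp, core_index, ehh_cutoff, max_gap_bp)
}

ihh_core <- function(hapm, pos, core, ehh_cutoff, max_gap_bp) {
  m <- length(pos)
  side_area <- function(idx) {
    vals <- ehh_walk(hapm, idx, stop_below = ehh_cutoff)
    if (vals[1] < ehh_cutoff) return(NA_real_)
    if (length(vals) < 2) return(0)
    w <- pmin(abs(diff(pos[idx[seq_along(vals)]])), max_gap_bp)
    sum(w * (head(vals, -1) + tail(vals, -1)) / 2)
  }
  left <- side_area(seq(core, 1L))
  right <- side_area(seq(core, m))
  if (is.na(left) || is.na(right)) return(NA_real_)
  left + right
}

#' Cross-population XPEHH scan
#'
#' For every SNP, integrates haplotype homozygosity in each population
#' ([ihh()]), takes `raw = ln(iHH_A / iHH_B)` and standardises the raw scores
#' chromosome-wide to mean 0, sd 1. A SNP is significant when
#' `|standardised| > 2` (the two-sided 0.05 rule on an approximately
#' standard-normal score). Positive scores mean longer haplotype homozygosity
#' in population A, the sweep signature when A carries the selected allele.
#'
#' @param h a [haplotype_set()].
#' @param pops length-2 character, populations (A, B); default the two
#'   labels in `h` in order of appearance.
#' @param ehh_cutoff,max_gap_bp passed to [ihh()].
#' @param threshold significance cutoff on the standardised score.
#' @return object of class `xpehh_scan`: list with `scores` (tibble
#'   `snp_id`, `pos_bp`, `ihh_a`, `ihh_b`, `raw`, `standardized`,
#'   `significant`), `n_unscored` and `params`.
#' @export
xpehh_scan <- function(h, pops = NULL, ehh_cutoff = 0.05,
                       max_gap_bp = 200000, threshold = 2) {
  if (is.null(pops)) pops <- unique(h$population)
  if (length(pops) != 2) {
    abort("xpehh_scan needs exactly two populations", class = "zsweep_invalid")
  }
  hap_a <- pop_haplotypes(h, pops[1])
  hap_b <- pop_haplotypes(h, pops[2])
  m <- ncol(h$hap)
  ihh_a <- ihh_b <- numeric(m)
  for (j in seq_len(m)) {
    ihh_a[j] <- ihh_core(hap_a, h$positions_bp, j, ehh_cutoff, max_gap_bp)
    ihh_b[j] <- ihh_core(hap_b, h$positions_bp, j, ehh_cutoff, max_gap_bp)
  }
  raw <- ifelse(!is.na(ihh_a) & !is.na(ihh_b) & ihh_a > 0 & ihh_b > 0,
                log(ihh_a / ihh_b), NA_real_)
  scored <- !is.na(raw)
  std <- rep(NA_real_, m)
  std[scored] <- (raw[scored] - mean(raw[scored])) / stats::sd(raw[scored])
  scores <- tibble(
    snp_id = h$snp_id, pos_bp = h$positions_bp,
    ihh_a = ihh_a, ihh_b = ihh_b, raw = raw, standardized = std,
    significant = !is.na(std) & abs(std) > threshold
  )
  structure(
    list(scores = scores, n_unscored = sum(!scored),
         params = list(pop_a = pops[1], pop_b = pops[2],
                       ehh_cutoff = ehh_cutoff, max_gap_bp = max_gap_bp,
                       threshold = threshold)),
    class = "xpehh_scan"
  )
}

#' @export
print.xpehh_scan <- function(x, ...) {
  cat("<xpehh_scan> ", nrow(x$scores), " SNPs (", x$n_unscored,
      " unscored), ", x$params$pop_a, " vs ", x$params$pop_b, "\n",
      "  significant (|score| > ", x$params$threshold, "): ",
      sum(x$scores$significant, na.rm = TRUE), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.xpehh_scan <- function(x, ...) as_tibble(x$scores)

#' @export
glance.xpehh_scan <- function(x, ...) {
  tibble(n_snps = nrow(x$scores), n_unscored = x$n_unscored,
         n_significant = sum(x$scores$significant, na.rm = TRUE),
         max_abs_score = max(abs(x$scores$standardized), na.rm = TRUE),
         threshold = x$params$threshold)
}
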