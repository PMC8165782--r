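#' Per-SNP Weir-Cockerham F_ST from two dosage vectors
#'
#' Computes the two-population fixation index from the allele-count ANOVA on
#' gametes (two per diploid sample): `F_ST = (MSP - MSG) / (MSP + (n_c - 1) * MSG)`
#' with `MSP` the mean square among populations, `MSG` the mean square among
#' gametes within populations, and `n_c` the corrected average gamete count
#' `n - (n_A^2 + n_B^2)/n` (for r = 2 populations). Missing dosages are
#' masked; a SNP monomorphic across both populations gets `fst = 0` with a
#' `monomorphic` flag. Negative estimates are a known property of the
#' estimator and are retained.
#'
#' @param dos_a,dos_b integer dosage vectors (0/1/2/NA) for populations A
#'   and B at one SNP.
#' @return one-row tibble: `fst`, `msp`, `msg`, `n_c`, `n_called_a`,
#'   `n_called_b` (gametes), `monomorphic`.
#' @export
snp_fst <- function(dos_a, dos_b) {
  res <- wc_fst_mat(matrix(dos_a, ncol = 1), matrix(dos_b, ncol = 1))
  if (res$n_called_a < 2 || res$n_called_b < 2) {
    abort("need >= 2 called gametes per population", class = "zsweep_invalid")
  }
  res
}

# vectorised Weir-Cockerham gamete-level ANOVA over the columns (SNPs) of two
# dosage matrices; returns one row per SNP
wc_fst_mat <- function(dos_a, dos_b) {
  n_a <- 2 * unname(colSums(!is.na(dos_a)))
  n_b <- 2 * unname(colSums(!is.na(dos_b)))
  c_a <- unname(colSums(dos_a, na.rm = TRUE))
  c_b <- unname(colSums(dos_b, na.rm = TRUE))
  n <- n_a + n_b
  p_a <- ifelse(n_a > 0, c_a / n_a, NA_real_)
  p_b <- ifelse(n_b > 0, c_b / n_b, NA_real_)
  p_bar <- (c_a + c_b) / n

  msp <- n_a * (p_a - p_bar)^2 + n_b * (p_b - p_bar)^2  # df = r - 1 = 1
  msg <- (n_a * p_a * (1 - p_a) + n_b * p_b * (1 - p_b)) / (n - 2)
  n_c <- n - (n_a^2 + n_b^2) / n

  denom <- msp + (n_c - 1) * msg
  fst <- ifelse(denom > 0, (msp - msg) / denom, NA_real_)
  mono <- p_bar %in% c(0, 1)
  fst[mono] <- 0
  scorable <- n_a >= 2 & n_b >= 2
  fst[!scorable] <- NA_real_
  tibble(fst = fst, msp = msp, msg = msg, n_c = n_c,
         n_called_a = n_a, n_called_b = n_b, monomorphic = mono)
}

#' Per-SNP F_ST table for a genotype matrix
#'
#' Applies [snp_fst()]'s estimator to every SNP of a two-population
#' [geno_matrix()], returning the variant table with the per-SNP estimate and
#' its ANOVA components.
#'
#' @param g a [geno_matrix()] with exactly two population labels.
#' @return tibble: variant columns plus `fst`, `msp`, `msg`, `n_c`,
#'   `n_called_a`, `n_called_b`, `monomorphic`.
#' @export
snp_fst_table <- function(g) {
  pops <- unique(g$samples$population)
  if (length(pops) != 2) {
    abort("needs exactly two populations", class = "zsweep_invalid")
  }
  bind_cols(g$variants,
            wc_fst_mat(pop_dosage(g, pops[1]), pop_dosage(g, pops[2])))
}

#' Tukey-fence outlier threshold
#'
#' `Q3 + 1.5 * (Q3 - Q1)` with quartiles by linear interpolation between
#' order statistics ([stats::quantile()] type 7).
#'
#' @param values numeric vector, at least 4 values.
#' @return the threshold (scalar).
#' @export
tukey_threshold <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) {
    abort("need >= 4 values for a Tukey fence", class = "zsweep_invalid")
  }
  q <- quantile(values, probs = c(0.25, 0.75), names = FALSE, type = 7)
  unname(q[2] + 1.5 * (q[2] - q[1]))
}

#' Sliding-window averaging of per-SNP statistics
#'
#' Windows of `window_bp` tile the chromosome from coordinate 0 at
#' `step_bp` increments, half-open `[start, end)`; a window's value is the
#' arithmetic mean of the per-SNP statistics it covers. Windows containing no
#' SNP are omitted. The tiling is anchored at 0 so it is deterministic and
#' independent of the SNP positions themselves.
#'
#' @param snp_stats data frame with `pos_bp` and a statistic column.
#' @param window_bp,step_bp window and step size in bp.
#' @param value column name of the statistic (default `"fst"`).
#' @return tibble: `start_bp`, `end_bp`, `n_snps`, `mean_fst`.
#' @export
window_scan <- function(snp_stats, window_bp = 100000, step_bp = 10000,
                        value = "fst") {
  if (step_bp > window_bp) {
    warn("step larger than window: windows will leave gaps")
  }
  df <- as_tibble(snp_stats)
  df <- df[!is.na(df[[value]]), ]
  pos <- df$pos_bp
  val <- df[[value]]
  # window starts covering position p: multiples of step in (p - window, p]
  k_hi <- floor(pos / step_bp)
  k_lo <- pmax(0, ceiling((pos - window_bp) / step_bp +
                            1e-9))  # strict p - window < start
  # enumerate (snp, window) incidences
  reps <- k_hi - k_lo + 1L
  keep <- reps > 0
  starts <- (unlist(purrr::map2(k_lo[keep], k_hi[keep], seq))) * step_bp
  vals <- rep(val[keep], reps[keep])
  out <- tibble(start_bp = starts, value = vals) |>
    group_by(.data$start_bp) |>
    summarise(n_snps = n(), mean_fst = mean(.data$value), .groups = "drop") |>
    mutate(end_bp = .data$start_bp + window_bp, .after = "start_bp") |>
    arrange(.data$start_bp)
  # half-open [start, end): a SNP exactly at end belongs to the next window
  out
}

#' Flag outlier windows with the Tukey fence
#'
#' The threshold is computed from all non-empty windows and a window is an
#' outlier iff its mean exceeds the threshold strictly.
#'
#' @param windows output of [window_scan()].
#' @return the windows tibble with an `is_outlier` column; the threshold is
#'   attached as attribute `"threshold"`.
#' @export
call_outlier_windows <- function(windows) {
  if (nrow(windows) == 0) abort("no windows", class = "zsweep_invalid")
  thr <- tukey_threshold(windows$mean_fst)
  out <- mutate(windows, is_outlier = .data$mean_fst > thr)
  attr(out, "threshold") <- thr
  out
}

#' Windowed F_ST selection scan
#'
#' Runs the full differentiation scan on a genotype matrix: per-SNP
#' Weir-Cockerham F_ST between the two populations, 100 kb / 10 kb sliding
#' window means, and Tukey-fence outlier calling on the window means.
#'
#' @param g a [geno_matrix()] with exactly two population labels.
#' @param window_bp,step_bp sliding-window size and step (bp).
#' @return an object of class `fst_scan`: list with `snp` (per-SNP tibble),
#'   `windows` (per-window tibble with `is_outlier`), `threshold`, and
#'   `params`. [tidy()] returns the window table, [glance()] a one-row
#'   summary, [autoplot()] the window Manhattan plot.
#' @export
fst_scan <- function(g, window_bp = 100000, step_bp = 10000) {
  pops <- unique(g$samples$population)
  if (length(pops) != 2) {
    abort("fst_scan needs exactly two populations", class = "zsweep_invalid")
  }
  per_snp <- snp_fst_table(g)
  windows <- window_scan(per_snp, window_bp, step_bp, value = "fst")
  windows <- call_outlier_windows(windows)
  structure(
    list(snp = per_snp, windows = windows,
         threshold = attr(windows, "threshold"),
         params = list(window_bp = window_bp, step_bp = step_bp,
                       pop_a = pops[1], pop_b = pops[2])),
    class = "fst_scan"
  )
}

#' @export
print.fst_scan <- function(x, ...) {
  cat("<fst_scan> ", nrow(x$snp), " SNPs, ", nrow(x$windows), " windows (",
      x$params$window_bp / 1000, " kb / ", x$params$step_bp / 1000, " kb)\n",
      "  populations: ", x$params$pop_a, " vs ", x$params$pop_b, "\n",
      "  Tukey threshold ", sprintf("%.4f", x$threshold), "; ",
      sum(x$windows$is_outlier), " outlier windows\n", sep = "")
  invisible(x)
}

#' @export
tidy.fst_scan <- function(x, ...) as_tibble(x$windows)

#' @export
glance.fst_scan <- function(x, ...) {
  tibble(n_snps = nrow(x$snp), n_windows = nrow(x$windows),
         n_outlier_windows = sum(x$windows$is_outlier),
         threshold = x$threshold, mean_fst = mean(x$snp$fst, na.rm = TRUE),
         window_bp = x$params$window_bp, step_bp = x$params$step_bp)
}
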